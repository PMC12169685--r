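#' Simulation specification for the synthetic-data generators
#'
#' Bundles a mandatory seed with the design parameters of the three
#' experiments the generators emulate. The defaults mirror the study
#' conditions: NMR spectra every 10 minutes (600 s) for about 9 hours
#' (46 points), triplicate runs, multiplicative log-normal noise on the
#' integrals; a linear electron-affinity-to-barrier relationship with
#' Gaussian residual sd 0.3 kcal/mol over 8 training compounds; enzyme
#' progress curves read every minute for an hour with additive
#' absorbance noise.
#'
#' @param seed Integer seed (mandatory; generators never touch hidden
#'   global state outside their own `set.seed` scope).
#' @param k_true True pseudo-first-order rate constant(s), 1/s. May be a
#'   named vector (one per compound). Default spans the observed
#'   half-life range, 22 to 6188 min.
#' @param n_replicates Replicates per compound (default 3, triplicate
#'   runs).
#' @param sampling_interval Seconds between points (default 600).
#' @param n_points Points per run (default 46).
#' @param noise_sd Log-normal sd of the multiplicative integral noise
#'   (default 0.02; integrals are positive with roughly constant
#'   relative error).
#' @param slope,intercept,residual_sd Descriptor-model truth: barrier =
#'   `slope * EA + intercept + N(0, residual_sd)`. Defaults 3.8
#'   (kcal/mol)/eV is negative in sign below - see `gen_descriptor_table`.
#' @param control_rate Control initial rate for the assay generator,
#'   absorbance/min (default 0.01).
#' @param assay_noise_sd Additive absorbance noise sd (default 0.001).
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(seed,
                     k_true = log(2) / (60 * c(fast = 22, mid = 264, slow = 6188)),
                     n_replicates = 3L,
                     sampling_interval = 600,
                     n_points = 46L,
                     noise_sd = 0.02,
                     slope = -3.8,
                     intercept = 25.0,
                     residual_sd = 0.3,
                     control_rate = 0.01,
                     assay_noise_sd = 0.001) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(noise_sd >= 0, residual_sd >= 0, assay_noise_sd >= 0,
            all(k_true > 0), n_points >= 2, sampling_interval > 0)
  structure(list(seed = as.integer(seed), k_true = k_true,
                 n_replicates = as.integer(n_replicates),
                 sampling_interval = sampling_interval,
                 n_points = as.integer(n_points),
                 noise_sd = noise_sd, slope = slope, intercept = intercept,
                 residual_sd = residual_sd, control_rate = control_rate,
                 assay_noise_sd = assay_noise_sd),
            class = "sim_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic NMR decay time series
#'
#' One exponential decay per compound and replicate,
#' `F(t) = exp(-k t) * noise`, sampled on the spec's grid with
#' multiplicative log-normal noise on the integrals. The zero-time point
#' is included and the series is re-normalized to its first observation,
#' exactly as real integral data would be.
#'
#' @param spec A [sim_spec()].
#' @return A named list of [decay_series()] objects
#'   (`"<compound>/<replicate>"`), with the true rate constants attached
#'   as `attr(, "k_true")`.
#' @export
gen_decay <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  ks <- spec$k_true
  if (is.null(names(ks))) names(ks) <- paste0("cmpd", seq_along(ks))
  t <- (seq_len(spec$n_points) - 1L) * spec$sampling_interval
  out <- with_seed(spec$seed, {
    res <- list()
    for (id in names(ks)) {
      for (r in seq_len(spec$n_replicates)) {
        noise <- if (spec$noise_sd > 0) {
          exp(stats::rnorm(length(t), 0, spec$noise_sd))
        } else {
          rep(1, length(t))
        }
        res[[paste0(id, "/r", r)]] <- decay_series(
          id, t, exp(-ks[[id]] * t) * noise,
          replicate_id = paste0("r", r), time_unit = "s")
      }
    }
    res
  })
  attr(out, "k_true") <- ks
  out
}

#' Generate a synthetic descriptor table with known truth
#'
#' Electron affinities are sampled uniformly over `ea_range` and the
#' barrier is the exact linear relationship plus Gaussian residuals:
#' `dG = slope * EA + intercept + N(0, residual_sd)`. The default slope
#' is negative - higher electron affinity means an easier one-electron
#' reduction and a lower addition barrier. Optional protonation columns
#' (`pKa_conjugate_acid`, `EA_protonated_eV`) exercise the weighted
#' prediction path.
#'
#' @param spec A [sim_spec()].
#' @param n_compounds Number of compounds (default 8, the training-set
#'   size; must be >= 3).
#' @param ea_range Range of EA values, eV (default `c(0, 1.1)`,
#'   matching the span of LUMO/EA values in the study system).
#' @param with_protonation Add the protonation columns (default FALSE).
#' @param prefix Compound-id prefix.
#' @return A `descriptor_table` with columns `compound_id`,
#'   `heteroaryl_name`, `EA_eV`, `dG_exp_kcal_mol`, ...; the generating
#'   parameters are attached as `attr(, "truth")`.
#' @export
gen_descriptor_table <- function(spec, n_compounds = 8L,
                                 ea_range = c(0, 1.1),
                                 with_protonation = FALSE,
                                 prefix = "syn") {
  stopifnot(inherits(spec, "sim_spec"), n_compounds >= 3)
  with_seed(spec$seed, {
    ea <- stats::runif(n_compounds, ea_range[1], ea_range[2])
    dg <- spec$slope * ea + spec$intercept +
      stats::rnorm(n_compounds, 0, spec$residual_sd)
    df <- data.frame(
      compound_id = sprintf("%s%02d", prefix, seq_len(n_compounds)),
      heteroaryl_name = sprintf("synthetic-het-%02d", seq_len(n_compounds)),
      EA_eV = ea,
      dG_exp_kcal_mol = dg,
      stringsAsFactors = FALSE)
    if (with_protonation) {
      # protonated species: EA raised by a fixed shift, pKa near assay pH
      df$pKa_conjugate_acid <- stats::runif(n_compounds, 5.4, 9.4)
      df$EA_protonated_eV <- ea + 0.5
    }
    tab <- as_descriptor_table(df)
    attr(tab, "truth") <- list(slope = spec$slope,
                               intercept = spec$intercept,
                               residual_sd = spec$residual_sd)
    tab
  })
}

#' Generate synthetic papain-assay progress curves
#'
#' One curve per inhibitor (plus a control), read every minute for an
#' hour: linear at the planted rate inside the initial-rate window, with
#' optional saturation afterwards and additive Gaussian absorbance
#' noise. Planted rates are `ratio * control_rate` for each entry of
#' `ratios`, so the pipeline's recovered E/E0 can be compared with the
#' construction.
#'
#' @param spec A [sim_spec()].
#' @param ratios Named numeric vector of treated/control rate ratios
#'   (default eight values spanning 0.07 to 0.62, the observed residual-
#'   activity range).
#' @param control_id Identifier for the control wells (default "DMSO").
#' @param n_minutes Curve length in minutes (default 60).
#' @param saturate_after Minutes after which the curve flattens
#'   exponentially (default 20; set `Inf` for fully linear curves).
#' @return A list of [progress_curve()] objects with `attr(, "ratios")`.
#' @export
gen_progress_curves <- function(spec,
                                ratios = stats::setNames(
                                  seq(0.07, 0.62, length.out = 8),
                                  sprintf("inh%02d", 1:8)),
                                control_id = "DMSO",
                                n_minutes = 60,
                                saturate_after = 20) {
  stopifnot(inherits(spec, "sim_spec"), all(ratios >= 0))
  t <- 0:n_minutes
  ramp <- function(rate) {
    # linear to saturate_after, then exponential approach to a plateau
    lin <- pmin(t, saturate_after) * rate
    extra <- pmax(t - saturate_after, 0)
    lin + ifelse(extra > 0, rate * 10 * (1 - exp(-extra / 10)), 0)
  }
  rates <- c(stats::setNames(spec$control_rate, control_id),
             ratios * spec$control_rate)
  with_seed(spec$seed, {
    out <- lapply(names(rates), function(id) {
      noise <- if (spec$assay_noise_sd > 0) {
        stats::rnorm(length(t), 0, spec$assay_noise_sd)
      } else {
        0
      }
      progress_curve(paste0("well_", id), t, signal = ramp(rates[[id]]) + noise,
                     inhibitor_id = id)
    })
    names(out) <- paste0("well_", names(rates))
    attr(out, "ratios") <- ratios
    out
  })
}
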