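#' Construct a decay time series for one monitored reaction
#'
#' Represents a single pseudo-first-order reaction-monitoring run: the
#' fraction of electrophile remaining (from NMR methylene-proton integrals)
#' at each time point. Times are stored internally in seconds; integrals
#' are normalized to the first observation so the series starts at 1.
#' Non-positive integrals cannot be log-transformed and are dropped with a
#' warning before any fitting.
#'
#' @param compound_id Compound identifier.
#' @param time Numeric vector of acquisition times, strictly increasing.
#' @param integral Numeric vector of peak integrals (or already-normalized
#'   fractions) at each time.
#' @param replicate_id Replicate identifier (default "r1").
#' @param time_unit Unit of `time`: `"s"`, `"min"` or `"h"`. NMR reaction
#'   monitoring is conventionally reported in minutes.
#' @param normalize If `TRUE` (default) divide by the first integral.
#' @return An object of class `decay_series`: a list with `compound_id`,
#'   `replicate_id`, `time` (seconds), `fraction_remaining`, and `n_dropped`.
#' @examples
#' s <- decay_series("1a", time = c(0, 10, 20), integral = c(100, 90, 81),
#'                   time_unit = "min")
#' s$fraction_remaining
#' @export
decay_series <- function(compound_id, time, integral, replicate_id = "r1",
                         time_unit = c("min", "s", "h"), normalize = TRUE) {
  time_unit <- match.arg(time_unit)
  if (length(time) != length(integral)) {
    stop("`time` and `integral` must have the same length", call. = FALSE)
  }
  keep <- is.finite(time) & is.finite(integral)
  time <- time[keep]
  integral <- integral[keep]
  if (is.unsorted(time, strictly = TRUE)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  n_dropped <- sum(integral <= 0)
  if (n_dropped > 0) {
    warning(sprintf(
      "%s/%s: dropping %d point(s) with non-positive integrals",
      compound_id, replicate_id, n_dropped), call. = FALSE)
    time <- time[integral > 0]
    integral <- integral[integral > 0]
  }
  fraction <- if (normalize && length(integral)) integral / integral[1] else integral
  time_s <- switch(time_unit, s = time, min = time * 60, h = time * 3600)
  structure(
    list(compound_id = as.character(compound_id),
         replicate_id = as.character(replicate_id),
         time = time_s,
         fraction_remaining = fraction,
         n_dropped = n_dropped),
    class = "decay_series")
}

#' @export
print.decay_series <- function(x, ...) {
  cat(sprintf("<decay_series> %s / %s: %d points over %.1f min\n",
              x$compound_id, x$replicate_id, length(x$time),
              diff(range(x$time)) / 60))
  invisible(x)
}

#' Fit a pseudo-first-order rate constant to a decay series
#'
#' Ordinary least squares of the natural log of the fraction of
#' electrophile remaining against time: under pseudo-first-order
#' conditions (10-fold excess GSH) the decay is exponential and
#' `ln F(t) = -k t + ln F(0)`, so the rate constant is minus the fitted
#' slope. The fit also reports the half-life `ln(2)/k` and the Eyring
#' activation free energy at the stated temperature.
#'
#' @param series A [decay_series()].
#' @param max_conversion Fraction of conversion up to which points are
#'   used: points with `fraction_remaining >= 1 - max_conversion` enter the
#'   fit. The default 1.0 uses the full monitored window.
#' @param temperature Kelvin; default 310.15 (37 degrees C).
#' @return An object of class `rate_fit`: list with `compound_id`,
#'   `replicate_id`, `k` (1/s), `intercept` (ln fraction at t = 0),
#'   `r_squared`, `k_stderr`, `n_points`, `t_half` (s), `dg_exp`
#'   (kcal/mol), `temperature`, and `decaying` (FALSE when the fitted
#'   slope is non-negative, in which case `t_half` and `dg_exp` are `NA`).
#' @examples
#' s <- gen_decay(sim_spec(seed = 1, k_true = 1e-4, noise_sd = 0))[[1]]
#' fit_pseudo_first_order(s)$k
#' @export
fit_pseudo_first_order <- function(series, max_conversion = 1.0,
                                   temperature = crg_constants()$T_default) {
  stopifnot(inherits(series, "decay_series"))
  if (!is.numeric(max_conversion) || max_conversion <= 0 || max_conversion > 1) {
    stop("`max_conversion` must be in (0, 1]", call. = FALSE)
  }
  keep <- series$fraction_remaining >= 1 - max_conversion
  t <- series$time[keep]
  f <- series$fraction_remaining[keep]
  if (length(t) < 3L) {
    stop(sprintf("%s/%s: need at least 3 usable points, have %d",
                 series$compound_id, series$replicate_id, length(t)),
         call. = FALSE)
  }
  fit <- stats::lm(log(f) ~ t)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  k <- -slope
  decaying <- k > 0
  structure(
    list(compound_id = series$compound_id,
         replicate_id = series$replicate_id,
         k = k,
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         k_stderr = unname(sm$coefficients[2, 2]),
         n_points = length(t),
         t_half = if (decaying) half_life(k) else NA_real_,
         dg_exp = if (decaying) rate_to_dg(k, temperature) else NA_real_,
         temperature = temperature,
         decaying = decaying),
    class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  if (x$decaying) {
    cat(sprintf(
      "<rate_fit> %s/%s  k = %.3e 1/s (SE %.1e), R2 = %.4f, t1/2 = %.1f min, dG = %.2f kcal/mol\n",
      x$compound_id, x$replicate_id, x$k, x$k_stderr, x$r_squared,
      x$t_half / 60, x$dg_exp))
  } else {
    cat(sprintf("<rate_fit> %s/%s  non-decaying (slope >= 0), k = %.3e 1/s\n",
                x$compound_id, x$replicate_id, x$k))
  }
  invisible(x)
}

#' Half-life from a first-order rate constant
#'
#' @param k Rate constant, 1/s; must be positive.
#' @return Half-life in seconds, `log(2)/k`.
#' @examples
#' half_life(log(2))       # 1 s
#' half_life(log(2) / 1320) # 22 minutes in seconds
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be positive and finite", call. = FALSE)
  }
  log(2) / k
}

#' Convert a rate constant to an Eyring activation free energy
#'
#' Inverts the Eyring equation `k = (k_B T / h) exp(-dG / (R T))` (unit
#' transmission coefficient):
#' `dG = R T ln(k_B T / (h k))` in kcal/mol.
#'
#' @param k Rate constant, 1/s; positive.
#' @param temperature Kelvin; positive. Default 310.15.
#' @return Activation free energy, kcal/mol.
#' @seealso [dg_to_rate()]
#' @export
rate_to_dg <- function(k, temperature = crg_constants()$T_default) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0)) {
    stop("`k` must be positive and finite", call. = FALSE)
  }
  .assert_scalar_positive(temperature, "temperature")
  cc <- crg_constants()
  cc$R * temperature * log(cc$k_B * temperature / (cc$h * k))
}

#' Convert an activation free energy to a rate constant
#'
#' Eyring equation `k = (k_B T / h) exp(-dG / (R T))`; exact inverse of
#' [rate_to_dg()].
#'
#' @param dg Activation free energy, kcal/mol.
#' @param temperature Kelvin; positive. Default 310.15.
#' @return Rate constant, 1/s.
#' @export
dg_to_rate <- function(dg, temperature = crg_constants()$T_default) {
  if (!is.numeric(dg) || any(!is.finite(dg))) {
    stop("`dg` must be finite", call. = FALSE)
  }
  .assert_scalar_positive(temperature, "temperature")
  cc <- crg_constants()
  (cc$k_B * temperature / cc$h) * exp(-dg / (cc$R * temperature))
}

#' Aggregate replicate rate fits for one compound
#'
#' Kinetic runs are performed in replicate on different days; the summary
#' half-life reported per compound is the mean of the per-replicate
#' half-lives (default), or `ln(2)` over the mean rate constant when
#' `t_half_method = "from_mean_k"`. The summary activation free energy is
#' always computed from the mean rate constant.
#'
#' @param results A list of [rate_fit] objects for the same compound.
#' @param t_half_method `"mean_of_t_half"` (default) or `"from_mean_k"`.
#' @return A list of class `replicate_summary` with `compound_id`,
#'   `n_replicates`, `k_mean`, `k_sd`, `t_half_mean`, `t_half_sd`,
#'   `t_half` (per `t_half_method`), `dg_exp` (from `k_mean`), and
#'   `temperature`.
#' @export
aggregate_replicates <- function(results,
                                 t_half_method = c("mean_of_t_half", "from_mean_k")) {
  t_half_method <- match.arg(t_half_method)
  if (!length(results)) stop("need at least one rate fit", call. = FALSE)
  if (inherits(results, "rate_fit")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "rate_fit")))
  ids <- unique(vapply(results, `[[`, character(1), "compound_id"))
  if (length(ids) != 1L) {
    stop("replicates span multiple compounds: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  temps <- unique(vapply(results, `[[`, numeric(1), "temperature"))
  if (length(temps) != 1L) {
    stop("replicates fitted at different temperatures", call. = FALSE)
  }
  ks <- vapply(results, `[[`, numeric(1), "k")
  th <- vapply(results, `[[`, numeric(1), "t_half")
  k_mean <- mean(ks)
  out <- list(
    compound_id = ids,
    n_replicates = length(results),
    k_mean = k_mean,
    k_sd = stats::sd(ks),
    t_half_mean = mean(th),
    t_half_sd = stats::sd(th),
    t_half = if (t_half_method == "mean_of_t_half") mean(th) else half_life(k_mean),
    dg_exp = rate_to_dg(k_mean, temps),
    temperature = temps)
  class(out) <- "replicate_summary"
  out
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf(
    "<replicate_summary> %s (n = %d): mean k = %.3e 1/s, t1/2 = %.1f min, dG = %.2f kcal/mol\n",
    x$compound_id, x$n_replicates, x$k_mean, x$t_half / 60, x$dg_exp))
  invisible(x)
}
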