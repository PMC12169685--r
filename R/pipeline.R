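#' Pipeline configuration
#'
#' Defaults mirror the assay conditions: 310.15 K (37 degrees C),
#' pH 7.4, free-energy-space protonation weighting, base-10 logs, a
#' 15-minute initial-rate window, and the full monitored window for
#' kinetic fits.
#'
#' @param temperature_K Kelvin (default 310.15).
#' @param ph Assay pH (default 7.4).
#' @param weighting_mode `"dg_space"` (default) or `"rate_space"`.
#' @param log_base Base for reactivity logs (10; informational).
#' @param window_min Papain initial-rate window, minutes (default 15).
#' @param max_conversion Kinetic-fit conversion cutoff (default 1.0).
#' @param seed Integer seed for any stochastic stage.
#' @param time_unit Time unit of the kinetics CSV (default `"min"`).
#' @param descriptor Descriptor for the predictive model (default
#'   `"EA_eV"`).
#' @param response Response column (default `"dG_exp_kcal_mol"`).
#' @param exclude Compound ids excluded from screening/training.
#' @param control_id Control marker in the assay CSV (default `"DMSO"`).
#' @param t_half_method Replicate summary convention (default
#'   `"mean_of_t_half"`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(temperature_K = 310.15, ph = 7.4,
                            weighting_mode = "dg_space", log_base = 10,
                            window_min = 15, max_conversion = 1.0,
                            seed = 1L, time_unit = "min",
                            descriptor = "EA_eV",
                            response = "dG_exp_kcal_mol",
                            exclude = character(),
                            control_id = "DMSO",
                            t_half_method = "mean_of_t_half") {
  structure(list(temperature_K = temperature_K, ph = ph,
                 weighting_mode = weighting_mode, log_base = log_base,
                 window_min = window_min, max_conversion = max_conversion,
                 seed = as.integer(seed), time_unit = time_unit,
                 descriptor = descriptor, response = response,
                 exclude = exclude, control_id = control_id,
                 t_half_method = t_half_method),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON path.
#' @return `write_config_json` returns `path` invisibly;
#'   `read_config_json` returns a `pipeline_config`.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$exclude <- as.character(x$exclude %||% character())
  do.call(pipeline_config, x)
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full reactivity analysis
#'
#' Chains the pipeline stages: (1) pseudo-first-order kinetic fits and
#' replicate summaries from the reaction-monitoring CSV; (2) the
#' descriptor correlation screen; (3) training of the single-descriptor
#' predictive model; (4) optional test-set validation; (5) optional
#' papain-assay analysis and reactivity correlations. All outputs are
#' CSV/JSON under `out_dir`, plus a human-readable `summary.txt` and a
#' `provenance.json` recording the configuration and input checksums.
#' A failing stage aborts with the stage named; outputs of completed
#' stages are retained.
#'
#' @param config A [pipeline_config()].
#' @param timeseries_csv Reaction-monitoring CSV (required).
#' @param descriptor_csv Descriptor-table CSV (required).
#' @param test_csv Optional test-set descriptor CSV.
#' @param assay_csv Optional papain progress-curve CSV.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory results of each stage
#'   (`fits`, `kinetics_summary`, `screen`, `model`, `validation`,
#'   `papain`, `correlations`, `paths`).
#' @export
run_full_analysis <- function(config, timeseries_csv, descriptor_csv,
                              test_csv = NULL, assay_csv = NULL,
                              out_dir = "crg_results") {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(timeseries_csv, descriptor_csv, test_csv, assay_csv)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  inputs <- c(timeseries = timeseries_csv, descriptors = descriptor_csv,
              test = test_csv %||% NA, assay = assay_csv %||% NA)

  # -- stage: kinetics ------------------------------------------------
  kin <- .stage("kinetics", {
    series <- read_timeseries_csv(timeseries_csv, time_unit = config$time_unit)
    fits <- fit_kinetics_table(series, max_conversion = config$max_conversion,
                               temperature = config$temperature_K)
    summ <- summarise_kinetics(series, max_conversion = config$max_conversion,
                               temperature = config$temperature_K,
                               t_half_method = config$t_half_method)
    list(fits = fits, summary = summ)
  })
  paths$fits <- file.path(out_dir, "fits.csv")
  write_fits_csv(kin$fits, paths$fits)
  paths$kinetics_summary <- file.path(out_dir, "kinetics_summary.csv")
  write_fits_csv(kin$summary, paths$kinetics_summary)

  # -- stage: screen --------------------------------------------------
  screen <- .stage("screen", {
    tab <- read_descriptor_csv(descriptor_csv,
                               temperature = config$temperature_K)
    list(table = tab,
         report = screen_descriptors(tab, response = config$response,
                                     exclude = config$exclude))
  })
  paths$screen <- file.path(out_dir, "screen.csv")
  utils::write.csv(screen$report$results, paths$screen, row.names = FALSE)

  # -- stage: train ---------------------------------------------------
  model <- .stage("train", {
    fit_univariate(screen$table, config$descriptor,
                   response = config$response, exclude = config$exclude)
  })
  paths$model <- file.path(out_dir, "model.json")
  write_model_json(model, paths$model)

  # -- stage: validate ------------------------------------------------
  validation <- NULL
  if (!is.null(test_csv)) {
    validation <- .stage("validate", {
      test_tab <- read_descriptor_csv(test_csv,
                                      temperature = config$temperature_K)
      validate(model, test_tab, ph = config$ph,
               weighting = config$weighting_mode, response = config$response,
               temperature = config$temperature_K)
    })
    paths$validation <- file.path(out_dir, "validation.csv")
    utils::write.csv(validation$per_compound, paths$validation,
                     row.names = FALSE)
  }

  # -- stage: papain --------------------------------------------------
  papain <- NULL
  correlations <- list()
  if (!is.null(assay_csv)) {
    papain <- .stage("papain", {
      curves <- read_progress_csv(assay_csv)
      papain_activity(curves, control_id = config$control_id,
                      window_min = config$window_min)
    })
    paths$papain <- file.path(out_dir, "papain_activity.csv")
    utils::write.csv(papain, paths$papain, row.names = FALSE)
    correlations <- .stage("papain-correlate", {
      act <- stats::setNames(papain$residual_activity, papain$inhibitor_id)
      act <- act[names(act) != config$control_id]
      out <- list()
      logk <- stats::setNames(log10(kin$summary$k_mean_per_s),
                              kin$summary$compound_id)
      if (length(intersect(names(act), names(logk))) >= 3) {
        out$log_k_gsh <- correlate_inactivation(act, logk, "log_k_gsh")
      }
      shared <- intersect(names(act), screen$table$compound_id)
      pred <- tryCatch(
        predict_dg_table(model,
                         screen$table[match(shared, screen$table$compound_id), ,
                                      drop = FALSE],
                         ph = config$ph, weighting = config$weighting_mode,
                         temperature = config$temperature_K),
        error = function(e) NULL)
      if (!is.null(pred) && length(pred) >= 3) {
        out$dg_predicted <- correlate_inactivation(act, pred, "dg_predicted")
      }
      out
    })
    if (length(correlations)) {
      corr_df <- do.call(rbind, lapply(names(correlations), function(nm) {
        m <- correlations[[nm]]
        data.frame(x_kind = nm, slope = m$slope, intercept = m$intercept,
                   r_squared = m$r_squared, n = m$n_train,
                   stringsAsFactors = FALSE)
      }))
      paths$papain_correlation <- file.path(out_dir, "papain_correlation.csv")
      utils::write.csv(corr_df, paths$papain_correlation, row.names = FALSE)
    }
  }

  # -- provenance and summary -----------------------------------------
  prov <- list(config = unclass(config),
               inputs = as.list(inputs[!is.na(inputs)]),
               input_md5 = as.list(tools::md5sum(unname(inputs[!is.na(inputs)]))),
               package_version = as.character(utils::packageVersion("crgreact")))
  paths$provenance <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA)

  paths$summary <- file.path(out_dir, "summary.txt")
  .write_summary(paths$summary, kin, screen$report, model, validation,
                 papain, correlations)

  invisible(list(fits = kin$fits, kinetics_summary = kin$summary,
                 screen = screen$report, model = model,
                 validation = validation, papain = papain,
                 correlations = correlations, paths = paths))
}

.write_summary <- function(path, kin, screen, model, validation, papain,
                           correlations) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("CRG reactivity analysis summary")
  w("===============================")
  w("")
  w("Kinetics: %d replicate fit(s), %d compound(s)",
    nrow(kin$fits), nrow(kin$summary))
  for (i in seq_len(nrow(kin$summary))) {
    s <- kin$summary[i, ]
    w("  %-8s k = %.3e 1/s, t1/2 = %.1f min, dG_exp = %.2f kcal/mol",
      s$compound_id, s$k_mean_per_s, s$t_half_min, s$dG_exp_kcal_mol)
  }
  w("")
  if (!is.null(screen$results)) {
    w("Descriptor screen (response %s), ranked by R2:", screen$response)
    for (i in seq_len(nrow(screen$results))) {
      r <- screen$results[i, ]
      w("  %-18s R2 = %.3f (n = %d)", r$descriptor, r$r_squared, r$n)
    }
    w("Top-ranked descriptor: %s", screen$results$descriptor[1])
  }
  if (length(screen$skipped)) {
    w("Skipped descriptors (insufficient data): %s",
      paste(names(screen$skipped), collapse = ", "))
  }
  w("")
  w("Trained model: %s = %.4g * %s + %.4g (R2 = %.3f, s = %.3g, n = %d)",
    model$response_name, model$slope, model$descriptor_name, model$intercept,
    model$r_squared, model$residual_sd, model$n_train)
  if (!is.null(validation)) {
    w("")
    w("Validation: n = %d, MUE = %.3f kcal/mol, R2 = %s", validation$n,
      validation$mue,
      if (is.na(validation$r_squared)) "NA" else
        sprintf("%.3f", validation$r_squared))
  }
  if (!is.null(papain)) {
    w("")
    w("Papain assay: %d condition(s)", nrow(papain))
    for (i in seq_len(nrow(papain))) {
      p <- papain[i, ]
      w("  %-8s rate = %.4g A/min, E/E0 = %.3f", p$inhibitor_id,
        p$rate_mean, p$residual_activity)
    }
    for (nm in names(correlations)) {
      m <- correlations[[nm]]
      w("  log10(E/E0) vs %s: slope = %.3g, R2 = %.3f", nm, m$slope,
        m$r_squared)
    }
  }
  invisible(path)
}
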