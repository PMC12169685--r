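#' Read reaction-monitoring time series from CSV
#'
#' Expected columns: `compound_id`, `replicate_id`, `time`, `integral`.
#' One [decay_series()] is built per (compound, replicate) pair.
#'
#' @param path CSV file path.
#' @param time_unit Unit of the `time` column (`"min"` default).
#' @return A named list of `decay_series` objects
#'   (`"<compound>/<replicate>"`).
#' @export
read_timeseries_csv <- function(path, time_unit = "min") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "replicate_id", "time", "integral")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("time-series CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(df$compound_id, df$replicate_id, drop = TRUE, sep = "/")
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$time), , drop = FALSE]
    decay_series(d$compound_id[1], d$time, d$integral,
                 replicate_id = d$replicate_id[1], time_unit = time_unit)
  })
  out[order(names(out))]
}

#' Fit every series in a time-series table and tabulate the results
#'
#' @param series_list A list of [decay_series()] objects, as returned by
#'   [read_timeseries_csv()] or [gen_decay()].
#' @param max_conversion Passed to [fit_pseudo_first_order()].
#' @param temperature Kelvin.
#' @return A data.frame with one row per replicate: `compound_id`,
#'   `replicate_id`, `k_per_s`, `k_stderr`, `r2`, `t_half_min`,
#'   `dG_exp_kcal_mol`, `n_points`, `decaying`.
#' @export
fit_kinetics_table <- function(series_list, max_conversion = 1.0,
                               temperature = crg_constants()$T_default) {
  fits <- lapply(series_list, fit_pseudo_first_order,
                 max_conversion = max_conversion, temperature = temperature)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(compound_id = f$compound_id,
               replicate_id = f$replicate_id,
               k_per_s = f$k,
               k_stderr = f$k_stderr,
               r2 = f$r_squared,
               t_half_min = f$t_half / 60,
               dG_exp_kcal_mol = f$dg_exp,
               n_points = f$n_points,
               decaying = f$decaying,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Summarise per-replicate fits to one row per compound
#'
#' @param series_list List of [decay_series()] objects.
#' @param t_half_method Passed to [aggregate_replicates()].
#' @inheritParams fit_kinetics_table
#' @return A data.frame with one row per compound: `compound_id`,
#'   `n_replicates`, `k_mean_per_s`, `k_sd`, `t_half_min`, `t_half_sd_min`,
#'   `dG_exp_kcal_mol`.
#' @export
summarise_kinetics <- function(series_list, max_conversion = 1.0,
                               temperature = crg_constants()$T_default,
                               t_half_method = "mean_of_t_half") {
  fits <- lapply(series_list, fit_pseudo_first_order,
                 max_conversion = max_conversion, temperature = temperature)
  ids <- vapply(fits, `[[`, character(1), "compound_id")
  do.call(rbind, lapply(split(fits, ids), function(fs) {
    s <- aggregate_replicates(fs, t_half_method = t_half_method)
    data.frame(compound_id = s$compound_id,
               n_replicates = s$n_replicates,
               k_mean_per_s = s$k_mean,
               k_sd = s$k_sd,
               t_half_min = s$t_half / 60,
               t_half_sd_min = s$t_half_sd / 60,
               dG_exp_kcal_mol = s$dg_exp,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write fitted kinetics results to CSV
#'
#' @param fits Data.frame from [fit_kinetics_table()] or
#'   [summarise_kinetics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fits_csv <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}
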