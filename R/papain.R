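#' Construct an enzyme-assay progress curve
#'
#' A chromogenic-substrate progress curve for one well: background-
#' corrected absorbance (A400 - A790) versus time. Either a single
#' `signal` column or the raw `a400`/`a790` pair is accepted; the
#' correction is applied on construction in the latter case.
#'
#' @param sample_id Well / sample identifier.
#' @param time Time in minutes, increasing from 0.
#' @param signal Background-corrected absorbance. Omit when giving
#'   `a400`/`a790`.
#' @param a400,a790 Raw absorbances; used when `signal` is missing.
#' @param inhibitor_id Inhibitor compound id, or the control marker
#'   (e.g. `"DMSO"`).
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(sample_id, time, signal = NULL,
                           a400 = NULL, a790 = NULL,
                           inhibitor_id = NA_character_) {
  if (is.null(signal)) {
    if (is.null(a400) || is.null(a790)) {
      stop("give either `signal` or both `a400` and `a790`", call. = FALSE)
    }
    signal <- a400 - a790
  }
  if (length(time) != length(signal)) {
    stop("`time` and `signal` must have the same length", call. = FALSE)
  }
  if (is.unsorted(time)) stop("`time` must be increasing", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 inhibitor_id = as.character(inhibitor_id),
                 time = time, signal = signal),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("<progress_curve> %s (inhibitor %s): %d points over %.0f min\n",
              x$sample_id, x$inhibitor_id, length(x$time), max(x$time)))
  invisible(x)
}

#' Initial rate of an enzyme progress curve
#'
#' OLS slope of absorbance versus time restricted to the early linear
#' phase, by default the first 15 minutes of data. Points outside the
#' window never influence the fit.
#'
#' @param curve A [progress_curve()].
#' @param window_min Width of the fitting window in minutes (default 15).
#' @return Initial rate, absorbance/min.
#' @export
initial_rate <- function(curve, window_min = 15) {
  stopifnot(inherits(curve, "progress_curve"))
  .assert_scalar_positive(window_min, "window_min")
  keep <- curve$time <= window_min
  if (sum(keep) < 3L) {
    stop(sprintf("%s: fewer than 3 points inside the %.0f-min window",
                 curve$sample_id, window_min), call. = FALSE)
  }
  t <- curve$time[keep]
  s <- curve$signal[keep]
  unname(stats::coef(stats::lm(s ~ t))[2])
}

#' Residual enzymatic activity relative to an untreated control
#'
#' @param treated_rate Initial rate for the inhibitor-treated enzyme,
#'   absorbance/min.
#' @param control_rate Initial rate of the untreated control; must be
#'   positive.
#' @return `E/E0 = treated_rate / control_rate` (vectorized over
#'   `treated_rate`).
#' @export
residual_activity <- function(treated_rate, control_rate) {
  if (!is.numeric(control_rate) || length(control_rate) != 1L ||
      !is.finite(control_rate) || control_rate <= 0) {
    stop("`control_rate` must be a single positive number", call. = FALSE)
  }
  treated_rate / control_rate
}

#' Initial rates and residual activities for a set of progress curves
#'
#' Fits every curve's initial rate, identifies the control wells by
#' `inhibitor_id`, and normalizes each inhibitor's mean rate by the mean
#' control rate. Replicate wells of the same inhibitor are averaged
#' (the default), or kept per-replicate with `per_replicate = TRUE`.
#'
#' @param curves List of [progress_curve()] objects.
#' @param control_id `inhibitor_id` marking control wells (default
#'   `"DMSO"`).
#' @param window_min Passed to [initial_rate()].
#' @param per_replicate Keep one row per well instead of averaging.
#' @return A data.frame with `inhibitor_id`, `rate_mean`, `rate_sd`,
#'   `n_wells`, `residual_activity` (the control row has
#'   `residual_activity = 1`), or per-well rows when
#'   `per_replicate = TRUE`.
#' @export
papain_activity <- function(curves, control_id = "DMSO", window_min = 15,
                            per_replicate = FALSE) {
  rates <- vapply(curves, initial_rate, numeric(1), window_min = window_min)
  ids <- vapply(curves, `[[`, character(1), "inhibitor_id")
  if (!any(ids == control_id)) {
    stop(sprintf("no control wells with inhibitor_id `%s`", control_id),
         call. = FALSE)
  }
  control_rate <- mean(rates[ids == control_id])
  if (per_replicate) {
    return(data.frame(
      sample_id = vapply(curves, `[[`, character(1), "sample_id"),
      inhibitor_id = ids, rate = unname(rates),
      residual_activity = residual_activity(unname(rates), control_rate),
      stringsAsFactors = FALSE))
  }
  agg <- do.call(rbind, lapply(split(rates, ids), function(r) {
    data.frame(rate_mean = mean(r), rate_sd = stats::sd(r),
               n_wells = length(r))
  }))
  agg$inhibitor_id <- rownames(agg)
  rownames(agg) <- NULL
  agg$residual_activity <- residual_activity(agg$rate_mean, control_rate)
  agg[c("inhibitor_id", "rate_mean", "rate_sd", "n_wells",
        "residual_activity")]
}

#' Correlate papain inactivation with thiol reactivity
#'
#' OLS of `log10(E/E0)` on either the GSH reaction rate (`log10 k_GSH`)
#' or the predicted activation free energy, across the compounds shared
#' by both maps. Compounds with non-positive residual activity are
#' dropped with a warning (their log is undefined).
#'
#' @param activities Named numeric vector: compound -> E/E0.
#' @param reactivities Named numeric vector: compound -> x value
#'   (log10 k_GSH or predicted barrier, per `x_kind`).
#' @param x_kind `"log_k_gsh"` or `"dg_predicted"` (labelling only; the
#'   fit is the same OLS either way).
#' @return A `crg_linear_model` of `log10(E/E0)` on the chosen x.
#' @export
correlate_inactivation <- function(activities, reactivities,
                                   x_kind = c("log_k_gsh", "dg_predicted")) {
  x_kind <- match.arg(x_kind)
  shared <- intersect(names(activities), names(reactivities))
  bad <- shared[activities[shared] <= 0 | !is.finite(activities[shared])]
  if (length(bad)) {
    warning("dropping compound(s) with non-positive E/E0: ",
            paste(bad, collapse = ", "), call. = FALSE)
    shared <- setdiff(shared, bad)
  }
  if (length(shared) < 3L) {
    stop(sprintf("need >= 3 shared compounds with positive E/E0, have %d",
                 length(shared)), call. = FALSE)
  }
  tab <- data.frame(compound_id = shared,
                    x = unname(reactivities[shared]),
                    log_ee0 = log10(unname(activities[shared])),
                    stringsAsFactors = FALSE)
  m <- fit_univariate(tab, descriptor = "x", response = "log_ee0")
  m$descriptor_name <- x_kind
  m$response_name <- "log10_E_over_E0"
  m
}

#' Read progress curves from CSV
#'
#' Expected columns: `sample_id`, `inhibitor_id`, `time_min`, and either
#' `signal` or the `a400`/`a790` pair.
#'
#' @param path CSV file path.
#' @return A list of [progress_curve()] objects.
#' @export
read_progress_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "inhibitor_id", "time_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("progress-curve CSV missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  has_signal <- "signal" %in% names(df)
  if (!has_signal && !all(c("a400", "a790") %in% names(df))) {
    stop("progress-curve CSV needs `signal` or `a400` + `a790`",
         call. = FALSE)
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    if (has_signal) {
      progress_curve(d$sample_id[1], d$time_min, signal = d$signal,
                     inhibitor_id = d$inhibitor_id[1])
    } else {
      progress_curve(d$sample_id[1], d$time_min, a400 = d$a400,
                     a790 = d$a790, inhibitor_id = d$inhibitor_id[1])
    }
  })
  out[order(names(out))]
}
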