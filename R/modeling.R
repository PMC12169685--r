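#' Fit a univariate descriptor-to-barrier linear model
#'
#' Ordinary least squares of a response (usually the experimental or
#' computed activation free energy, or log10 k_GSH) on a single
#' descriptor column. This is the workhorse of the linear free-energy
#' relationship screen and of the single-parameter electron-affinity
#' model.
#'
#' @param table A descriptor table ([as_descriptor_table()]).
#' @param descriptor Descriptor column name, e.g. `"EA_eV"`.
#' @param response Response column name, e.g. `"dG_exp_kcal_mol"` or
#'   `"log_k_gsh"`.
#' @param exclude Character vector of compound ids to leave out (outlier
#'   handling is explicit: compounds are never dropped automatically).
#' @param min_n Minimum number of complete pairs (default 3; tests may
#'   relax to 2 to compare against the closed-form two-point line).
#' @return An object of class `crg_linear_model`: list with
#'   `descriptor_name`, `response_name`, `slope`, `intercept`,
#'   `r_squared`, `residual_sd`, `slope_stderr`, `n_train`,
#'   `training_ids`, `excluded`.
#' @export
fit_univariate <- function(table, descriptor, response = "dG_exp_kcal_mol",
                           exclude = character(), min_n = 3L) {
  stopifnot(is.data.frame(table))
  for (col in c(descriptor, response)) {
    if (!col %in% names(table)) {
      stop(sprintf("column `%s` not present in table", col), call. = FALSE)
    }
  }
  keep <- !(table$compound_id %in% exclude)
  x <- table[[descriptor]][keep]
  y <- table[[response]][keep]
  ids <- table$compound_id[keep]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_n) {
    stop(sprintf("descriptor `%s`: only %d complete pairs (need >= %d)",
                 descriptor, sum(ok), min_n), call. = FALSE)
  }
  fit <- stats::lm(y[ok] ~ x[ok])
  sm <- summary(fit)
  structure(
    list(descriptor_name = descriptor,
         response_name = response,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         residual_sd = sm$sigma,
         slope_stderr = unname(sm$coefficients[2, 2]),
         n_train = sum(ok),
         training_ids = ids[ok],
         excluded = exclude),
    class = "crg_linear_model")
}

#' @export
print.crg_linear_model <- function(x, ...) {
  cat(sprintf(
    "<crg_linear_model> %s = %.4g * %s + %.4g  (R2 = %.3f, s = %.3g, n = %d)\n",
    x$response_name, x$slope, x$descriptor_name, x$intercept,
    x$r_squared, x$residual_sd, x$n_train))
  invisible(x)
}

#' Screen every registered descriptor against a response
#'
#' One [fit_univariate()] per registered descriptor with complete data,
#' ranked by decreasing R-squared (ties broken alphabetically by
#' descriptor name for reproducibility). Descriptors with too few
#' complete pairs are reported as skipped, not errors.
#'
#' @inheritParams fit_univariate
#' @param descriptors Descriptor names to screen; default every
#'   registered name (see [descriptor_vocabulary()]) present in the table.
#' @return A list of class `screen_report`: `results` (data.frame with
#'   `descriptor`, `slope`, `intercept`, `r_squared`, `residual_sd`,
#'   `n`), `models` (named list of fitted models), `skipped`
#'   (named character vector of reasons), `response`, `excluded`.
#' @export
screen_descriptors <- function(table, response = "dG_exp_kcal_mol",
                               exclude = character(), descriptors = NULL) {
  if (is.null(descriptors)) {
    descriptors <- intersect(descriptor_vocabulary()$name, names(table))
  }
  if (!length(descriptors)) {
    stop("no registered descriptor columns in table", call. = FALSE)
  }
  models <- list()
  skipped <- character()
  for (d in descriptors) {
    m <- tryCatch(fit_univariate(table, d, response, exclude = exclude),
                  error = function(e) conditionMessage(e))
    if (inherits(m, "crg_linear_model")) models[[d]] <- m else skipped[d] <- m
  }
  res <- do.call(rbind, lapply(models, function(m) {
    data.frame(descriptor = m$descriptor_name, slope = m$slope,
               intercept = m$intercept, r_squared = m$r_squared,
               residual_sd = m$residual_sd, n = m$n_train,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!is.null(res)) {
    res <- res[order(-res$r_squared, res$descriptor), , drop = FALSE]
    rownames(res) <- NULL
  }
  structure(list(results = res, models = models, skipped = skipped,
                 response = response, excluded = exclude),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> response = %s, %d descriptor(s) fitted",
              x$response, length(x$models)))
  if (length(x$excluded)) cat(", excluding", paste(x$excluded, collapse = ", "))
  cat("\n")
  if (!is.null(x$results)) {
    print(format(x$results, digits = 3), row.names = FALSE)
  }
  if (length(x$skipped)) {
    cat("skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict an activation free energy for one compound
#'
#' Plain path: `slope * descriptor + intercept`. When the compound has a
#' conjugate-acid pKa and a protonated-species descriptor value
#' (`<descriptor>_protonated_*` column, e.g. `EA_protonated_eV` for
#' `EA_eV`), both species are predicted and combined with
#' [weighted_prediction()] at the protonated fraction implied by the pH.
#'
#' @param model A `crg_linear_model` (typically the EA model).
#' @param record One-row data.frame (a row of a descriptor table).
#' @param ph Assay pH (default 7.4); only used on the weighted path.
#' @param weighting `"dg_space"` (default) or `"rate_space"`.
#' @param temperature Kelvin for rate-space weighting.
#' @return Predicted barrier, kcal/mol.
#' @export
predict_dg <- function(model, record, ph = 7.4,
                       weighting = c("dg_space", "rate_space"),
                       temperature = crg_constants()$T_default) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(model, "crg_linear_model"), is.data.frame(record),
            nrow(record) == 1L)
  d <- model$descriptor_name
  if (!d %in% names(record) || !is.finite(record[[d]])) {
    stop(sprintf("compound `%s` has no value for descriptor `%s`",
                 record$compound_id, d), call. = FALSE)
  }
  plain <- model$slope * record[[d]] + model$intercept
  prot_col <- .protonated_column(d)
  has_weighted <- "pKa_conjugate_acid" %in% names(record) &&
    is.finite(record[["pKa_conjugate_acid"]]) &&
    prot_col %in% names(record) && is.finite(record[[prot_col]])
  if (!has_weighted) return(plain)
  dg_prot <- model$slope * record[[prot_col]] + model$intercept
  f <- protonated_fraction(record[["pKa_conjugate_acid"]], ph)
  weighted_prediction(dg_prot, plain, f, mode = weighting,
                      temperature = temperature)
}

.protonated_column <- function(descriptor) {
  # EA_eV -> EA_protonated_eV; fall back to "<name>_protonated"
  parts <- strsplit(descriptor, "_")[[1]]
  if (length(parts) > 1) {
    paste(c(parts[-length(parts)], "protonated", parts[length(parts)]),
          collapse = "_")
  } else {
    paste0(descriptor, "_protonated")
  }
}

#' Predict barriers for every compound in a table
#'
#' @inheritParams predict_dg
#' @param table Descriptor table.
#' @return Numeric vector of predictions, named by compound id.
#' @export
predict_dg_table <- function(model, table, ph = 7.4,
                             weighting = "dg_space",
                             temperature = crg_constants()$T_default) {
  out <- vapply(seq_len(nrow(table)), function(i) {
    predict_dg(model, table[i, , drop = FALSE], ph = ph,
               weighting = weighting, temperature = temperature)
  }, numeric(1))
  stats::setNames(out, table$compound_id)
}

#' Validate a model on a test set
#'
#' Predicts every test compound, compares with its experimental barrier
#' and reports the mean unsigned error (MUE, unweighted arithmetic mean
#' of absolute errors) together with the R-squared of predicted versus
#' experimental.
#'
#' @inheritParams predict_dg_table
#' @param response Experimental response column (default
#'   `"dG_exp_kcal_mol"`).
#' @return A list of class `validation_report`: `per_compound`
#'   (data.frame with `compound_id`, observed, predicted, `signed_error`),
#'   `mue`, `r_squared`, `n`.
#' @export
validate <- function(model, table, ph = 7.4, weighting = "dg_space",
                     response = "dG_exp_kcal_mol",
                     temperature = crg_constants()$T_default) {
  if (!nrow(table)) stop("empty test set", call. = FALSE)
  obs <- table[[response]]
  if (is.null(obs) || any(!is.finite(obs))) {
    stop("every test compound needs a finite `", response, "`", call. = FALSE)
  }
  pred <- predict_dg_table(model, table, ph = ph, weighting = weighting,
                           temperature = temperature)
  err <- pred - obs
  per <- data.frame(compound_id = table$compound_id, observed = obs,
                    predicted = unname(pred), signed_error = unname(err),
                    stringsAsFactors = FALSE)
  r2 <- if (nrow(per) >= 3 && stats::sd(pred) > 0 && stats::sd(obs) > 0) {
    stats::cor(pred, obs)^2
  } else {
    NA_real_
  }
  structure(list(per_compound = per, mue = mean(abs(err)), r_squared = r2,
                 n = nrow(per)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d, MUE = %.3f kcal/mol, R2 = %s\n",
              x$n, x$mue,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared)))
  invisible(x)
}

#' Multivariate linear model with optional leave-one-out Q-squared
#'
#' Ordinary least squares on a set of named descriptors. The single-
#' descriptor call reproduces [fit_univariate()] exactly. Leave-one-out
#' cross-validation reports the predictive R-squared
#' `Q2 = 1 - PRESS / SS_tot`; it is reported as computed, negative values
#' are not clamped.
#'
#' @inheritParams fit_univariate
#' @param descriptors Character vector of descriptor column names.
#' @param cv `"none"` (default) or `"leave_one_out"`.
#' @return A list of class `crg_mlr_model`: `descriptors`,
#'   `coefficients` (named, includes `(Intercept)`), `r_squared`,
#'   `residual_sd`, `q_squared` (NA unless requested), `n_train`,
#'   `training_ids`.
#' @export
fit_multivariate <- function(table, descriptors,
                             response = "dG_exp_kcal_mol",
                             exclude = character(),
                             cv = c("none", "leave_one_out")) {
  cv <- match.arg(cv)
  keep <- !(table$compound_id %in% exclude)
  cols <- c(descriptors, response)
  miss <- setdiff(cols, names(table))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- table[keep, , drop = FALSE]
  ok <- rowSums(!is.finite(as.matrix(d[cols]))) == 0
  d <- d[ok, , drop = FALSE]
  if (nrow(d) <= length(descriptors) + 1L) {
    stop(sprintf("need n > p + 1 (n = %d, p = %d)", nrow(d),
                 length(descriptors)), call. = FALSE)
  }
  X <- as.matrix(d[descriptors])
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    stop("rank-deficient design; collinear descriptors among: ",
         paste(descriptors, collapse = ", "), call. = FALSE)
  }
  y <- d[[response]]
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  co <- stats::coef(fit)
  names(co) <- c("(Intercept)", descriptors)
  q2 <- NA_real_
  if (cv == "leave_one_out") {
    # PRESS via the hat-matrix shortcut: e_i / (1 - h_ii)
    h <- stats::lm.influence(fit, do.coef = FALSE)$hat
    press <- sum((stats::residuals(fit) / (1 - h))^2)
    q2 <- 1 - press / sum((y - mean(y))^2)
  }
  structure(
    list(descriptors = descriptors, coefficients = co,
         r_squared = sm$r.squared, residual_sd = sm$sigma, q_squared = q2,
         n_train = nrow(d), training_ids = d$compound_id),
    class = "crg_mlr_model")
}

#' @export
print.crg_mlr_model <- function(x, ...) {
  cat(sprintf("<crg_mlr_model> %d descriptor(s), n = %d, R2 = %.3f, Q2 = %s\n",
              length(x$descriptors), x$n_train, x$r_squared,
              if (is.na(x$q_squared)) "NA" else sprintf("%.3f", x$q_squared)))
  invisible(x)
}

#' Serialize a fitted univariate model to JSON
#'
#' @param model A `crg_linear_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "crg_linear_model"))
  out <- unclass(model)
  out$package_version <- as.character(utils::packageVersion("crgreact"))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized univariate model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return A `crg_linear_model`.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- c("descriptor_name", "response_name", "slope", "intercept",
            "r_squared", "residual_sd", "slope_stderr", "n_train",
            "training_ids", "excluded")
  m <- x[keep]
  m$excluded <- as.character(m$excluded %||% character())
  structure(m, class = "crg_linear_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
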