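# Write a complete synthetic input bundle (kinetics, descriptors, test
# set, assay) into `dir` and return the file paths. Everything is seeded
# and the planted truth is returned alongside.
make_bundle <- function(dir, seed = 101) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- 6
  ids <- sprintf("c%02d", seq_len(n))
  set.seed(seed)
  ea <- seq(0.1, 1.0, length.out = n)
  dg <- -3.8 * ea + 25 + stats::rnorm(n, 0, 0.1)
  k <- crgreact::dg_to_rate(dg)

  # kinetics time series from the implied rate constants
  spec <- crgreact::sim_spec(seed = seed, k_true = stats::setNames(k, ids),
                             n_replicates = 2, noise_sd = 0.01)
  series <- crgreact::gen_decay(spec)
  ts_csv <- file.path(dir, "timeseries.csv")
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(compound_id = s$compound_id, replicate_id = s$replicate_id,
               time = s$time / 60, integral = s$fraction_remaining)
  }))
  utils::write.csv(df, ts_csv, row.names = FALSE)

  # descriptor table: EA is the real driver, one pure-noise descriptor
  set.seed(seed + 1)
  desc <- data.frame(compound_id = ids, EA_eV = ea,
                     dG_exp_kcal_mol = dg,
                     nics0zz_ppm = stats::rnorm(n, -25, 3))
  desc_csv <- file.path(dir, "descriptors.csv")
  utils::write.csv(desc, desc_csv, row.names = FALSE)

  # test set drawn from the same relationship
  set.seed(seed + 2)
  ea_t <- stats::runif(4, 0.1, 1.0)
  test <- data.frame(compound_id = sprintf("v%02d", 1:4), EA_eV = ea_t,
                     dG_exp_kcal_mol = -3.8 * ea_t + 25 +
                       stats::rnorm(4, 0, 0.1))
  test_csv <- file.path(dir, "test.csv")
  utils::write.csv(test, test_csv, row.names = FALSE)

  # papain assay: residual activity tied to the planted rates
  ratios <- stats::setNames(
    pmin(0.95, pmax(0.05, 0.3 - 0.25 * (log10(k) - mean(log10(k))))), ids)
  curves <- crgreact::gen_progress_curves(
    crgreact::sim_spec(seed = seed + 3, assay_noise_sd = 0), ratios = ratios)
  assay_csv <- file.path(dir, "assay.csv")
  adf <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(sample_id = cv$sample_id, inhibitor_id = cv$inhibitor_id,
               time_min = cv$time, signal = cv$signal)
  }))
  utils::write.csv(adf, assay_csv, row.names = FALSE)

  list(timeseries = ts_csv, descriptors = desc_csv, test = test_csv,
       assay = assay_csv,
       truth = list(ids = ids, ea = ea, dg = dg, k = k, ratios = ratios))
}
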