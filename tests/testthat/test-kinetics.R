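test_that("noiseless exponential decay is recovered exactly", {
  for (k in c(1e-5, 1e-4, 5e-4)) {
    s <- make_exact_series(k)
    f <- suppressWarnings(fit_pseudo_first_order(s))
    expect_equal(f$k, k, tolerance = 1e-10)
    expect_equal(f$r_squared, 1, tolerance = 1e-10)
    expect_equal(f$t_half, log(2) / k, tolerance = 1e-12)
    expect_true(f$decaying)
  }
})

test_that("a constant series is flagged as non-decaying", {
  s <- decay_series("flat", 0:10, rep(1, 11), time_unit = "min")
  f <- suppressWarnings(fit_pseudo_first_order(s))
  expect_false(f$decaying)
  expect_lte(f$k, 0)
  expect_true(is.na(f$t_half))
  expect_true(is.na(f$dg_exp))
})

test_that("noisy decay fit agrees with an independent OLS oracle", {
  spec <- sim_spec(seed = 42, k_true = c(x = 5e-4), n_replicates = 1,
                   noise_sd = 0.02)
  s <- gen_decay(spec)[[1]]
  f <- fit_pseudo_first_order(s)
  oracle <- ols_oracle(s$time, log(s$fraction_remaining))
  expect_equal(f$k, -oracle$slope, tolerance = 1e-10)
  expect_equal(f$k_stderr, oracle$se_slope, tolerance = 1e-10)
  expect_equal(f$r_squared, oracle$r2, tolerance = 1e-10)
  # recovery of the generating constant
  expect_lt(abs(f$k - 5e-4), 3 * f$k_stderr)
})

test_that("series construction enforces its invariants", {
  # normalization to the first observation
  s <- decay_series("1a", c(0, 10, 20), c(100, 90, 81), time_unit = "min")
  expect_equal(s$fraction_remaining[1], 1)
  expect_equal(s$time, c(0, 600, 1200))  # minutes converted to seconds
  # non-positive integrals dropped with a warning
  expect_warning(
    s2 <- decay_series("1a", c(0, 10, 20, 30), c(100, 90, -1, 70),
                       time_unit = "min"),
    "non-positive")
  expect_equal(length(s2$time), 3L)
  expect_equal(s2$n_dropped, 1L)
  # non-monotone time rejected
  expect_error(decay_series("1a", c(0, 20, 10), c(1, .9, .8)),
               "strictly increasing")
  # too few points for a fit
  expect_error(
    fit_pseudo_first_order(decay_series("1a", c(0, 10), c(1, 0.9))),
    "at least 3")
})

test_that("max_conversion restricts the fit to the early window", {
  k <- 1e-4
  t <- (0:45) * 600
  f_clean <- exp(-k * t)
  # corrupt the late (high-conversion) points; an early-window fit must
  # be unaffected by them (the corrupted values stay below the cutoff)
  f_corrupt <- f_clean
  f_corrupt[f_clean < 0.5] <- f_corrupt[f_clean < 0.5] * 0.2
  s <- decay_series("x", t, f_corrupt, time_unit = "s", normalize = FALSE)
  fit <- suppressWarnings(
    fit_pseudo_first_order(s, max_conversion = 0.5))
  expect_equal(fit$k, k, tolerance = 1e-8)
})

test_that("half-life conversions are exact", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(2 * log(2)), 0.5)
  expect_equal(half_life(log(2) / 1320), 1320)  # the 22-min round trip
  expect_error(half_life(0), "positive")
  expect_error(half_life(-1), "positive")
})

test_that("Eyring conversions invert each other and match direct arithmetic", {
  cc <- crg_constants()
  T <- cc$T_default
  # transmission-limit identity
  expect_equal(rate_to_dg(cc$k_B * T / cc$h, T), 0, tolerance = 1e-12)
  expect_equal(dg_to_rate(0, T), cc$k_B * T / cc$h)
  # round trip across the experimental k range
  for (k in 10^seq(-6, -2)) {
    expect_equal(dg_to_rate(rate_to_dg(k, T), T), k, tolerance = 1e-10)
  }
  # 22-minute half-life against the independent arithmetic oracle
  k22 <- log(2) / (22 * 60)
  expect_equal(rate_to_dg(k22, T), eyring_dg_oracle(k22), tolerance = 1e-12)
  expect_equal(rate_to_dg(k22, T), 22.83442, tolerance = 1e-6)
  # +1 kcal/mol divides the rate by exp(1/(R T))
  expect_equal(dg_to_rate(21, T) / dg_to_rate(20, T),
               exp(-1 / (cc$R * T)), tolerance = 1e-12)
  expect_error(rate_to_dg(-1), "positive")
  expect_error(dg_to_rate(20, temperature = -5), "positive")
})

test_that("replicate aggregation follows the mean-half-life convention", {
  mk_fit <- function(t_half_min, rep) {
    suppressWarnings(fit_pseudo_first_order(
      make_exact_series(log(2) / (t_half_min * 60), id = "c1", rep = rep)))
  }
  fits <- list(mk_fit(60, "r1"), mk_fit(80, "r2"), mk_fit(100, "r3"))
  agg <- aggregate_replicates(fits)
  expect_equal(agg$t_half / 60, 80, tolerance = 1e-8)
  expect_equal(agg$k_mean, mean(vapply(fits, `[[`, numeric(1), "k")))
  expect_equal(agg$dg_exp, rate_to_dg(agg$k_mean))
  # the alternative convention uses the mean rate constant
  agg2 <- aggregate_replicates(fits, t_half_method = "from_mean_k")
  expect_equal(agg2$t_half, log(2) / agg2$k_mean)
  expect_lt(agg2$t_half, agg$t_half)  # harmonic-type vs arithmetic mean
  # single replicate: summary equals the replicate
  one <- aggregate_replicates(fits[1])
  expect_equal(one$k_mean, fits[[1]]$k)
  expect_equal(one$t_half, fits[[1]]$t_half)
  # mixed compounds rejected
  other <- suppressWarnings(
    fit_pseudo_first_order(make_exact_series(1e-4, id = "c2")))
  expect_error(aggregate_replicates(list(fits[[1]], other)), "multiple")
})

test_that("triplicate simulated fits recover the true rate constant", {
  k_true <- 2e-4
  spec <- sim_spec(seed = 11, k_true = c(c1 = k_true), n_replicates = 3,
                   noise_sd = 0.02)
  fits <- lapply(gen_decay(spec), fit_pseudo_first_order)
  agg <- aggregate_replicates(fits)
  expect_lt(abs(agg$k_mean - k_true), 3 * agg$k_sd / sqrt(3) + 1e-12)
})

test_that("k, half-life and barrier orderings are mutually consistent", {
  set.seed(5)
  ks <- 10^stats::runif(12, -6, -2)
  th <- half_life(ks)
  dg <- rate_to_dg(ks)
  expect_equal(order(-ks), order(th))
  expect_equal(order(-ks), order(dg))
})

test_that("time-series CSV round trip reproduces the fits", {
  spec <- sim_spec(seed = 9, k_true = c(a = 1e-4, b = 5e-4),
                   n_replicates = 2, noise_sd = 0.01)
  series <- gen_decay(spec)
  csv <- tempfile(fileext = ".csv")
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(compound_id = s$compound_id, replicate_id = s$replicate_id,
               time = s$time / 60, integral = s$fraction_remaining)
  }))
  utils::write.csv(df, csv, row.names = FALSE)
  back <- read_timeseries_csv(csv, time_unit = "min")
  expect_setequal(names(back), names(series))
  fits1 <- fit_kinetics_table(series)
  fits2 <- fit_kinetics_table(back[names(series)])
  expect_equal(fits2$k_per_s, fits1$k_per_s, tolerance = 1e-10)
  summ <- summarise_kinetics(back)
  expect_equal(nrow(summ), 2L)
  expect_equal(summ$n_replicates, c(2L, 2L))
})
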