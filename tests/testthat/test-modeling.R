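make_table <- function(n, slope, intercept, sd, seed, ea = NULL) {
  set.seed(seed)
  if (is.null(ea)) ea <- stats::runif(n, 0, 1.1)
  as_descriptor_table(data.frame(
    compound_id = sprintf("t%02d", seq_len(n)),
    EA_eV = ea,
    dG_exp_kcal_mol = slope * ea + intercept + stats::rnorm(n, 0, sd)))
}

test_that("exactly collinear data give R2 = 1 and exact coefficients", {
  tab <- make_table(8, slope = -3.8, intercept = 25, sd = 0, seed = 1)
  m <- suppressWarnings(fit_univariate(tab, "EA_eV"))
  expect_equal(m$slope, -3.8, tolerance = 1e-10)
  expect_equal(m$intercept, 25, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("fit_univariate agrees with independent correlation arithmetic", {
  tab <- make_table(10, -3.8, 25, 0.3, seed = 2)
  m <- fit_univariate(tab, "EA_eV")
  oracle <- ols_oracle(tab$EA_eV, tab$dG_exp_kcal_mol)
  expect_equal(m$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(m$intercept, oracle$intercept, tolerance = 1e-12)
  expect_equal(m$slope_stderr, oracle$se_slope, tolerance = 1e-12)
  expect_equal(m$r_squared, cor(tab$EA_eV, tab$dG_exp_kcal_mol)^2,
               tolerance = 1e-12)
  # permuting the response destroys the correlation
  set.seed(3)
  tab$dG_exp_kcal_mol <- sample(tab$dG_exp_kcal_mol)
  m0 <- fit_univariate(tab, "EA_eV")
  expect_equal(m0$r_squared, cor(tab$EA_eV, tab$dG_exp_kcal_mol)^2,
               tolerance = 1e-12)
  expect_lt(m0$r_squared, 0.3)
})

test_that("n = 2 fits reproduce the closed-form two-point line", {
  tab <- as_descriptor_table(data.frame(
    compound_id = c("a", "b"), EA_eV = c(0.2, 0.8),
    dG_exp_kcal_mol = c(24, 21)))
  m <- suppressWarnings(fit_univariate(tab, "EA_eV", min_n = 2))
  expect_equal(m$slope, (21 - 24) / (0.8 - 0.2))
  expect_equal(m$intercept, 24 - m$slope * 0.2)
})

test_that("slope and intercept are recovered within their 95% CIs", {
  tab <- make_table(8, -3.8, 25, 0.3, seed = 4)
  m <- fit_univariate(tab, "EA_eV")
  tq <- stats::qt(0.975, m$n_train - 2)
  expect_lt(abs(m$slope - (-3.8)), tq * m$slope_stderr)
})

test_that("R2 is invariant and the slope rescales under affine descriptor maps", {
  tab <- make_table(9, -3.8, 25, 0.3, seed = 6)
  m <- fit_univariate(tab, "EA_eV")
  tab2 <- tab
  tab2$EA_eV <- 3.2 * tab$EA_eV - 1.5
  m2 <- fit_univariate(tab2, "EA_eV")
  expect_equal(m2$r_squared, m$r_squared, tolerance = 1e-12)
  expect_equal(m2$slope, m$slope / 3.2, tolerance = 1e-12)
})

test_that("screening ranks by R2 with alphabetical tie-breaks", {
  tab <- make_table(8, -3.8, 25, 0.2, seed = 7)
  # a second registered descriptor identical to the first: identical R2
  tab$LUMO_eV <- tab$EA_eV
  rep <- screen_descriptors(tab)
  expect_equal(nrow(rep$results), 2L)
  expect_equal(rep$results$r_squared[1], rep$results$r_squared[2])
  expect_equal(rep$results$descriptor, c("EA_eV", "LUMO_eV"))  # name tie-break
  # single-descriptor table gives a length-1 report
  rep1 <- screen_descriptors(tab[setdiff(names(tab), "LUMO_eV")])
  expect_equal(nrow(rep1$results), 1L)
  # a descriptor with no data is skipped, not an error
  tab$sigma_het <- NA_real_
  rep2 <- screen_descriptors(tab)
  expect_true("sigma_het" %in% names(rep2$skipped))
  expect_equal(nrow(rep2$results), 2L)
  # excluded compounds are left out of every fit
  rep3 <- screen_descriptors(tab, exclude = "t01")
  expect_true(all(rep3$results$n == 7))
})

test_that("predictions honour OLS identities and the weighted path", {
  tab <- make_table(8, -3.8, 25, 0.3, seed = 8)
  m <- fit_univariate(tab, "EA_eV")
  # prediction at the training-mean descriptor equals the mean response
  rec <- tab[1, , drop = FALSE]
  rec$EA_eV <- mean(tab$EA_eV)
  expect_equal(predict_dg(m, rec), mean(tab$dG_exp_kcal_mol),
               tolerance = 1e-10)
  # without a pKa the prediction is independent of pH
  expect_equal(predict_dg(m, tab[2, ], ph = 5), predict_dg(m, tab[2, ], ph = 9))
  # with pKa = pH the two species are weighted half-and-half (dg space)
  rec2 <- tab[3, , drop = FALSE]
  rec2$pKa_conjugate_acid <- 7.4
  rec2$EA_protonated_eV <- rec2$EA_eV + 0.5
  plain <- m$slope * rec2$EA_eV + m$intercept
  prot <- m$slope * rec2$EA_protonated_eV + m$intercept
  expect_equal(predict_dg(m, rec2, ph = 7.4), 0.5 * (plain + prot))
  # rate-space weighting sits at or below dg-space weighting
  expect_lte(predict_dg(m, rec2, ph = 7.4, weighting = "rate_space"),
             predict_dg(m, rec2, ph = 7.4))
  # missing descriptor is an error
  rec3 <- tab[4, , drop = FALSE]
  rec3$EA_eV <- NA_real_
  expect_error(predict_dg(m, rec3), "no value")
})

test_that("validation reports MUE and R2 with the expected identities", {
  tab <- make_table(8, -3.8, 25, 0, seed = 9)
  m <- suppressWarnings(fit_univariate(tab, "EA_eV"))
  # perfect model on its own training set: MUE = 0
  v <- validate(m, tab)
  expect_equal(v$mue, 0, tolerance = 1e-10)
  # constant offset c shifts MUE to exactly c
  m_off <- m
  m_off$intercept <- m$intercept + 0.7
  v_off <- validate(m_off, tab)
  expect_equal(v_off$mue, 0.7, tolerance = 1e-10)
  expect_equal(v_off$per_compound$signed_error, rep(0.7, 8),
               tolerance = 1e-10)
  # on noisy training data: MUE <= residual sd, R2 equals training R2
  tabn <- make_table(10, -3.8, 25, 0.3, seed = 10)
  mn <- fit_univariate(tabn, "EA_eV")
  vn <- validate(mn, tabn)
  expect_lte(vn$mue, mn$residual_sd)
  expect_equal(vn$r_squared, mn$r_squared, tolerance = 1e-10)
  expect_error(validate(mn, tabn[0, ]), "empty")
})

test_that("test-set MUE matches the half-normal closed form", {
  # predictions from the exact generating model leave N(0, sigma) errors,
  # whose absolute mean is sigma * sqrt(2/pi)
  sigma <- 0.3
  truth <- structure(list(descriptor_name = "EA_eV",
                          response_name = "dG_exp_kcal_mol",
                          slope = -3.8, intercept = 25),
                     class = "crg_linear_model")
  mues <- vapply(1:60, function(i) {
    validate(truth, make_table(8, -3.8, 25, sigma, seed = 100 + i))$mue
  }, numeric(1))
  expected <- sigma * sqrt(2 / pi)
  mc_se <- sigma * sqrt(1 - 2 / pi) / sqrt(60 * 8)
  expect_lt(abs(mean(mues) - expected), 4 * mc_se)
})

test_that("multivariate fits generalize the univariate model", {
  tab <- make_table(10, -3.8, 25, 0.3, seed = 12)
  m1 <- fit_univariate(tab, "EA_eV")
  mm <- fit_multivariate(tab, "EA_eV")
  expect_equal(unname(mm$coefficients["EA_eV"]), m1$slope, tolerance = 1e-12)
  expect_equal(unname(mm$coefficients["(Intercept)"]), m1$intercept,
               tolerance = 1e-12)
  expect_equal(mm$r_squared, m1$r_squared, tolerance = 1e-12)
  # exact two-descriptor response: coefficients recovered, Q2 = 1
  set.seed(13)
  tab$LUMO_eV <- stats::runif(10, -0.5, 1)
  tab$dG_exp_kcal_mol <- 2 * tab$EA_eV - 1.5 * tab$LUMO_eV + 20
  mm2 <- suppressWarnings(
    fit_multivariate(tab, c("EA_eV", "LUMO_eV"), cv = "leave_one_out"))
  expect_equal(unname(mm2$coefficients[c("EA_eV", "LUMO_eV")]), c(2, -1.5),
               tolerance = 1e-8)
  expect_equal(mm2$q_squared, 1, tolerance = 1e-8)
  # noise-only responses typically give negative Q2, reported unclamped
  q2s <- vapply(1:20, function(i) {
    set.seed(200 + i)
    tab$dG_exp_kcal_mol <- stats::rnorm(10)
    fit_multivariate(tab, c("EA_eV", "LUMO_eV"),
                     cv = "leave_one_out")$q_squared
  }, numeric(1))
  expect_lt(stats::median(q2s), 0)
  expect_true(any(q2s < 0))  # negatives really are reported, not clamped
  # rank deficiency names the collinear descriptors
  tab$dup <- tab$EA_eV
  names(tab)[names(tab) == "dup"] <- "sigma_het"
  tab$sigma_het <- tab$EA_eV
  expect_error(fit_multivariate(tab, c("EA_eV", "sigma_het")),
               "collinear")
  expect_error(fit_multivariate(tab[1:3, ], c("EA_eV", "LUMO_eV")),
               "n > p")
})

test_that("models serialize to JSON and back without loss", {
  tab <- make_table(8, -3.8, 25, 0.3, seed = 15)
  m <- fit_univariate(tab, "EA_eV", exclude = character())
  path <- tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(m2$slope, m$slope)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$r_squared, m$r_squared)
  expect_equal(m2$training_ids, m$training_ids)
  # predictions from the round-tripped model are identical
  expect_equal(predict_dg_table(m2, tab), predict_dg_table(m, tab))
})
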