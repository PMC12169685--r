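# Independent closed-form OLS oracle (textbook formulas, no lm()).
ols_oracle <- function(x, y) {
  n <- length(x)
  xm <- mean(x)
  ym <- mean(y)
  sxx <- sum((x - xm)^2)
  slope <- sum((x - xm) * (y - ym)) / sxx
  intercept <- ym - slope * xm
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       r2 = 1 - sum(res^2) / sum((y - ym)^2))
}

# Direct Eyring arithmetic with CODATA constants, independent of the
# package's conversion functions.
eyring_dg_oracle <- function(k, T = 310.15) {
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  R <- 1.987204e-3
  R * T * log(kB * T / (h * k))
}

# Build a noiseless decay series with a known rate constant.
make_exact_series <- function(k, n = 46, dt = 600, id = "x", rep = "r1") {
  t <- (seq_len(n) - 1) * dt
  decay_series(id, t, exp(-k * t), replicate_id = rep, time_unit = "s")
}
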