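test_that("identical series give P(0) = P_max = 1 at zero lag", {
  x <- 100 + 10 * ar1(200, 0.8)
  r <- lag_correlation(x, x, tau_min = -24, tau_max = 24, min_overlap = 10)
  expect_equal(r$P_max, 1)
  expect_equal(r$T_delay, 0)
  expect_equal(r$P[r$tau == 0], 1)
  expect_true(r$significant)   # significant at lag zero, no direction
  expect_true(is.na(r$p_fisher))
})

test_that("an exact delayed copy is located at T_delay = -k for k = 1..24", {
  set.seed(7)
  x <- 100 + 10 * ar1(600, 0.9)
  for (k in c(1, 2, 6, 12, 24)) {
    x2 <- c(rep(NA, k), x)[seq_along(x)]   # x2(t) = x1(t - k)
    r <- suppressWarnings(
      lag_correlation(x, x2, tau_min = -30, tau_max = 30, min_overlap = 10))
    expect_equal(r$T_delay, -k)
    expect_equal(r$P_max, 1, tolerance = 1e-12)
  }
})

test_that("swapping the pair reverses the profile: T_delay negates, P_max invariant", {
  set.seed(8)
  for (i in 1:5) {
    x1 <- 100 + 10 * ar1(300, 0.7)
    x2 <- 100 + 10 * ar1(300, 0.7)
    a <- lag_correlation(x1, x2, tau_min = -20, tau_max = 20, min_overlap = 10)
    b <- lag_correlation(x2, x1, tau_min = -20, tau_max = 20, min_overlap = 10)
    expect_equal(a$P, rev(b$P), tolerance = 1e-12)
    expect_equal(a$n, rev(b$n))
    expect_equal(a$P_max, b$P_max, tolerance = 1e-12)
    expect_equal(a$T_delay, -b$T_delay)
  }
})

test_that("profile matches the definitional brute-force oracle with missing data", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(20:50, 1)
    v1 <- rnorm(n); v2 <- rnorm(n)
    v1[sample(n, round(0.15 * n))] <- NA
    v2[sample(n, round(0.15 * n))] <- NA
    taus <- -5:5
    oracle <- brute_lag_profile(v1, v2, taus, min_overlap = 3)
    got <- lag_correlation(v1, v2, tau_min = -5, tau_max = 5, min_overlap = 3)
    expect_equal(got$n, oracle$n)
    expect_equal(got$P, oracle$P, tolerance = 1e-12)
  }
})

test_that("the profile is invariant to positive affine transforms of either series", {
  set.seed(10)
  x1 <- ar1(250, 0.6); x2 <- ar1(250, 0.6)
  base <- lag_correlation(x1, x2, tau_min = -10, tau_max = 10, min_overlap = 10)
  tr <- lag_correlation(3.2 * x1 + 40, x2, tau_min = -10, tau_max = 10,
                        min_overlap = 10)
  tr2 <- lag_correlation(x1, 0.05 * x2 + 7, tau_min = -10, tau_max = 10,
                         min_overlap = 10)
  expect_equal(base$P, tr$P, tolerance = 1e-10)
  expect_equal(base$P, tr2$P, tolerance = 1e-10)
  expect_equal(base$T_delay, tr$T_delay)
})

test_that("site_series inputs align by instant across different record spans", {
  set.seed(12)
  x <- 100 + 10 * ar1(400, 0.9)
  t0 <- as.POSIXct("2018-01-01 00:00:00", tz = "UTC")
  s1 <- site_series("up", t0, x[1:300], 8L)
  # downstream series starts 50 h later and lags by 12 h
  s2 <- site_series("down", t0 + 50 * 3600, x[(50 - 12 + 1):(350 - 12)], 8L)
  r <- suppressWarnings(
    lag_correlation(s1, s2, tau_min = -24, tau_max = 24, min_overlap = 20))
  expect_equal(r$T_delay, -12)
  expect_equal(r$P_max, 1, tolerance = 1e-12)
  expect_error(lag_correlation(s1, align_timezone(s2, 9L)), "same timezone")
})

test_that("lags with thin overlap or zero variance are undefined, not errors", {
  set.seed(14)
  v1 <- c(rnorm(10), rep(NA, 30))
  v2 <- c(rnorm(10), rep(NA, 30))
  r <- lag_correlation(v1, v2, tau_min = -8, tau_max = 8, min_overlap = 5)
  expect_true(any(is.na(r$P)))              # large |tau|: too little overlap
  expect_true(all(r$n[!is.na(r$P)] >= 5))   # defined lags meet the minimum
  # no lag with enough overlap -> explicit error
  expect_error(
    lag_correlation(rep(NA_real_, 20), rnorm(20), tau_min = -2, tau_max = 2,
                    min_overlap = 3),
    "insufficient overlap")
  # a zero-variance slice leaves that lag undefined while others are fine
  v3 <- c(rep(5, 20), rnorm(20))
  v4 <- rnorm(40)
  r2 <- lag_correlation(v3, v4, tau_min = -20, tau_max = 20, min_overlap = 20)
  expect_true(is.na(r2$P[r2$tau == -20]))   # constant stretch of v3
  expect_false(is.na(r2$P[r2$tau == 20]))
})

test_that("argmax ties resolve to the smallest |tau|, then the negative lag", {
  # symmetric two-point series: profile equal at +/- lags by construction
  v <- rep(c(1, 2), 30)
  r <- suppressWarnings(
    lag_correlation(v, v, tau_min = -4, tau_max = 4, min_overlap = 5))
  expect_equal(r$T_delay, 0)        # P = 1 at all even lags; 0 is smallest
  v2 <- c(v[-1], 1)
  r2 <- suppressWarnings(
    lag_correlation(v, v2, tau_min = -4, tau_max = 4, min_overlap = 5))
  expect_equal(abs(r2$T_delay), 1)
  expect_equal(r2$T_delay, -1)      # tie between -1 and +1 goes negative
})

test_that("correlation t-test matches its closed form and is monotone in |r|", {
  # frozen case: r = 0.5, n = 30 -> t = 0.5 sqrt(28)/sqrt(0.75) = 3.0551
  res <- test_r_nonzero(0.5, 30)
  t_exp <- 0.5 * sqrt(28) / sqrt(1 - 0.25)
  expect_equal(res$statistic, t_exp, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(t_exp, 28, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_true(res$significant)

  z <- test_r_nonzero(0, 25)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  expect_false(z$significant)

  ps <- sapply(seq(0.05, 0.95, by = 0.05),
               function(r) test_r_nonzero(r, 40)$p_value)
  expect_true(all(diff(ps) < 0))

  res1 <- test_r_nonzero(1, 10)
  expect_true(res1$significant)
  expect_true(res1$p_value > 0)     # underflow floor, not zero or crash
})

test_that("Fisher r-to-z comparison matches its closed form and is antisymmetric", {
  # frozen case: r_max = 0.8, r_zero = 0.5, n = 103 each
  res <- fisher_compare(0.8, 0.5, 103, 103)
  z_exp <- (atanh(0.8) - atanh(0.5)) / sqrt(2 / 100)
  expect_equal(res$statistic, z_exp, tolerance = 1e-10)
  expect_equal(res$p_value, pnorm(z_exp, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(res$significant)

  eq <- fisher_compare(0.4, 0.4, 50, 50)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 0.5)
  expect_false(eq$significant)

  a <- fisher_compare(0.7, 0.3, 60, 80)
  b <- fisher_compare(0.3, 0.7, 80, 60)
  expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)

  expect_warning(fisher_compare(1, 0.5, 50, 50), "saturated")
})

test_that("the two-test gate passes true lagged signals and the Fisher gate prunes", {
  set.seed(13)
  # shifted copy plus mild noise: should be significant with a lagged peak
  x <- 100 + 10 * ar1(744, 0.95)
  x2 <- c(rep(NA, 12), x)[1:744] + rnorm(744, 0, 2)
  r <- lag_correlation(x, x2, tau_min = -48, tau_max = 48)
  expect_true(r$significant)
  expect_equal(r$T_delay, -12)

  # independent white noise: the Fisher gate removes part of what the
  # t-test alone (inflated by max-over-lags selection) would pass
  n_pairs <- 60
  gate_t <- logical(n_pairs); gate_full <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- rnorm(300); b <- rnorm(300)
    r <- lag_correlation(a, b, tau_min = -48, tau_max = 48)
    gate_t[i] <- r$p_r < 0.05
    gate_full[i] <- r$significant
  }
  expect_lt(sum(gate_full), sum(gate_t))
  expect_lt(mean(gate_full), 1)
})
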