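# Independent brute-force oracles, kept deliberately definitional (explicit
# loops and sum formulas) so they share no code path with the package.

# Pearson r from its definitional sums
brute_pearson <- function(a, b) {
  n <- length(a)
  sx <- sum(a); sy <- sum(b)
  sxx <- sum(a^2); syy <- sum(b^2); sxy <- sum(a * b)
  num <- n * sxy - sx * sy
  den <- sqrt(n * sxx - sx^2) * sqrt(n * syy - sy^2)
  num / den
}

# profile of Corr(x1(t), x2(t - tau)) by explicit slicing, pairwise-complete
brute_lag_profile <- function(v1, v2, taus, min_overlap = 3) {
  out <- rep(NA_real_, length(taus))
  ns <- integer(length(taus))
  for (k in seq_along(taus)) {
    tau <- taus[k]
    pairs_a <- c(); pairs_b <- c()
    for (t in seq_along(v1)) {
      j <- t - tau            # x2 index aligned with x1[t]
      if (j >= 1 && j <= length(v2) && !is.na(v1[t]) && !is.na(v2[j])) {
        pairs_a <- c(pairs_a, v1[t]); pairs_b <- c(pairs_b, v2[j])
      }
    }
    ns[k] <- length(pairs_a)
    if (ns[k] >= min_overlap &&
        length(unique(pairs_a)) > 1 && length(unique(pairs_b)) > 1)
      out[k] <- brute_pearson(pairs_a, pairs_b)
  }
  list(P = out, n = ns)
}

# Benjamini-Hochberg step-up, hand-coded
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# convenience: wrap a numeric vector as a site_series starting Jan 1 2018 CST
make_series <- function(values, city = "x", tz = 8,
                        start = as.POSIXct("2017-12-31 16:00:00", tz = "UTC")) {
  site_series(city, start, values, tz)
}

# stationary AR(1), marginal sd 1
ar1 <- function(n, phi = 0.5) as.numeric(arima.sim(list(ar = phi), n))
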