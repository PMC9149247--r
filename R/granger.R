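#' Bivariate Granger-causality F-test
#'
#' Tests whether the source city's past concentrations improve an
#' autoregressive prediction of the target city's concentrations. The
#' restricted model regresses the target on p of its own lags (plus
#' intercept); the unrestricted model adds p lags of the source. The
#' SSR-based statistic is
#' F = ((RSS_r - RSS_u) / p) / (RSS_u / (T - 2p - 1)),
#' compared to F(p, T - 2p - 1). The lag order p is chosen by an
#' information criterion (default AIC) on the restricted model — the
#' target's own autoregression — over 1..`max_lag`, evaluated on a common
#' sample so candidate orders are comparable; the final models are refit on
#' all rows available at the chosen order. Selecting p without looking at
#' the source terms keeps the F-test's null distribution intact; selecting
#' on the model that already includes the source lags picks the order that
#' most flatters them and inflates the type-I error (see the methods
#' vignette). Rows containing any missing lagged value are deleted
#' listwise — nothing is imputed.
#'
#' @param x_source,x_target `site_series` objects (aligned by instant) or
#'   plain numeric vectors taken as already aligned.
#' @param max_lag Largest lag order considered, hours (default 24).
#' @param min_lag Smallest lag order considered (default 1). Direction
#'   confirmation raises this to the identified |T_delay| so the
#'   unrestricted model always spans the candidate transport delay —
#'   an order below it could not see the relationship under test.
#' @param alpha Significance level.
#' @param criterion `"aic"`, `"bic"`, or `"fixed"` (then `fixed_lag` is used).
#' @param fixed_lag Lag order when `criterion = "fixed"`.
#' @param difference If `TRUE`, first-difference both series before testing
#'   (a stationarity guard; recorded in the result).
#' @return Object of class `granger_test`: `source`, `target`, `p_order`,
#'   `F`, `df1`, `df2`, `p_value`, `reject`, `criterion`, `differenced`,
#'   `n` (rows used in the final fit), `rss_r`, `rss_u`.
#' @export
granger_test <- function(x_source, x_target, max_lag = 24, alpha = 0.05,
                         criterion = c("aic", "bic", "fixed"),
                         fixed_lag = NULL, difference = FALSE, min_lag = 1) {
  criterion <- match.arg(criterion)
  stopifnot(max_lag >= 1, min_lag >= 1, min_lag <= max_lag)
  src_id <- if (inherits(x_source, "site_series")) x_source$city_id else "source"
  tgt_id <- if (inherits(x_target, "site_series")) x_target$city_id else "target"
  al <- align_pair(x_source, x_target)
  s <- al$v1; y <- al$v2
  if (difference) { s <- diff(s); y <- diff(y) }
  if (stats::sd(s, na.rm = TRUE) == 0 || all(is.na(s)))
    stop("degenerate input: source series '", src_id, "' has zero variance")
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y)))
    stop("degenerate input: target series '", tgt_id, "' has zero variance")

  # full design at max_lag; column j of Ly is y lagged j hours
  Tn <- length(y)
  if (Tn <= max_lag + 1) stop("series too short for max_lag = ", max_lag)
  idx <- (max_lag + 1):Tn
  Y <- y[idx]
  Ly <- sapply(seq_len(max_lag), function(j) y[idx - j])
  Ls <- sapply(seq_len(max_lag), function(j) s[idx - j])
  sel_ok <- stats::complete.cases(cbind(Y, Ly, Ls))
  if (sum(sel_ok) < 10 * max_lag)
    stop("insufficient data: ", sum(sel_ok), " complete rows after listwise ",
         "deletion; need >= ", 10 * max_lag)

  if (criterion == "fixed") {
    if (is.null(fixed_lag) || fixed_lag < 1 || fixed_lag > max_lag)
      stop("criterion 'fixed' requires fixed_lag in 1..max_lag")
    p <- as.integer(fixed_lag)
  } else {
    n_sel <- sum(sel_ok)
    Ys <- Y[sel_ok]
    cand <- min_lag:max_lag
    crit <- vapply(cand, function(pp) {
      X <- cbind(1, Ly[sel_ok, seq_len(pp), drop = FALSE])
      rss <- fit_rss(X, Ys)
      k <- pp + 1
      n_sel * log(rss / n_sel) +
        if (criterion == "aic") 2 * k else log(n_sel) * k
    }, numeric(1))
    p <- cand[which.min(crit)]
  }

  # final fit at order p on all rows available at that order
  idx_p <- (p + 1):Tn
  Yp <- y[idx_p]
  Lyp <- sapply(seq_len(p), function(j) y[idx_p - j])
  Lsp <- sapply(seq_len(p), function(j) s[idx_p - j])
  Xu <- cbind(1, Lyp, Lsp)
  ok <- stats::complete.cases(cbind(Yp, Xu))
  Yp <- Yp[ok]; Xu <- Xu[ok, , drop = FALSE]
  n <- length(Yp)
  if (n <= 2 * p + 1) stop("insufficient data for F-test at lag order ", p)
  if (qr(Xu)$rank < ncol(Xu))
    stop("rank-deficient design at lag order ", p,
         " (collinear regressors after deletion)")
  rss_u <- fit_rss(Xu, Yp)
  rss_r <- fit_rss(Xu[, 1:(p + 1), drop = FALSE], Yp)
  df2 <- n - 2 * p - 1
  Fstat <- ((rss_r - rss_u) / p) / (rss_u / df2)
  pval <- stats::pf(Fstat, p, df2, lower.tail = FALSE)
  structure(
    list(source = src_id, target = tgt_id, p_order = p,
         F = Fstat, df1 = p, df2 = df2, p_value = pval, alpha = alpha,
         reject = pval < alpha, criterion = criterion,
         differenced = difference, n = n, rss_r = rss_r, rss_u = rss_u),
    class = "granger_test")
}

fit_rss <- function(X, y) {
  sum(stats::lm.fit(X, y)$residuals^2)
}

# put two series on a common hourly index; plain vectors are taken aligned
align_pair <- function(x1, x2) {
  if (inherits(x1, "site_series") && inherits(x2, "site_series")) {
    h1 <- series_hours(x1); h2 <- series_hours(x2)
    h0 <- min(h1[1], h2[1]); hN <- max(h1[length(h1)], h2[length(h2)])
    grid <- h0:hN
    v1 <- rep(NA_real_, length(grid)); v2 <- v1
    v1[h1 - h0 + 1] <- x1$values
    v2[h2 - h0 + 1] <- x2$values
    list(v1 = v1, v2 = v2)
  } else {
    v1 <- if (inherits(x1, "site_series")) x1$values else as.numeric(x1)
    v2 <- if (inherits(x2, "site_series")) x2$values else as.numeric(x2)
    if (length(v1) != length(v2))
      stop("plain numeric series must have equal length (assumed aligned)")
    list(v1 = v1, v2 = v2)
  }
}

#' @export
print.granger_test <- function(x, ...) {
  cat(sprintf("<granger_test> %s -> %s\n", x$source, x$target))
  cat(sprintf("  lag order p = %d (%s), F(%d, %d) = %.4g, p = %.4g -> %s\n",
              x$p_order, x$criterion, x$df1, x$df2, x$F, x$p_value,
              if (x$reject) "reject (Granger-causal)" else "no evidence"))
  if (x$differenced) cat("  series first-differenced before testing\n")
  invisible(x)
}

#' Confirm the lag-derived direction of a significant pair
#'
#' The sign of `T_delay` nominates a direction (negative: X1 -> X2;
#' positive: X2 -> X1). Granger tests run in both directions; the edge is
#' confirmed only when the candidate direction rejects. A rejection only in
#' the reverse direction yields no edge and is recorded as an anomaly;
#' rejection in both directions sets a bidirectional flag (the candidate
#' still gives the edge its arrow). The Granger lag order is selected over
#' |T_delay|..`max_lag`, never below the identified transport delay: an
#' autoregression too short to reach the candidate lag could not detect the
#' very relationship the test is confirming.
#'
#' @param result `lagcorr` result for the pair; must be significant with a
#'   nonzero `T_delay`.
#' @param x1,x2 The two series, in the same order as in the correlation.
#' @param max_lag,alpha,criterion,fixed_lag,difference Passed to
#'   [granger_test()].
#' @return Object of class `direction_decision`.
#' @export
confirm_direction <- function(result, x1, x2, max_lag = 24, alpha = 0.05,
                              criterion = "aic", fixed_lag = NULL,
                              difference = FALSE) {
  stopifnot(inherits(result, "lagcorr"))
  if (!result$significant)
    stop("pair is not significant; nothing to confirm")
  if (result$T_delay == 0)
    stop("T_delay = 0: contemporaneous alignment has no direction to confirm")
  if (result$T_delay < 0) { src <- x1; tgt <- x2; ids <- result$pair }
  else { src <- x2; tgt <- x1; ids <- rev(result$pair) }
  floor_lag <- min(abs(result$T_delay), max_lag)
  fwd <- granger_test(src, tgt, max_lag, alpha, criterion, fixed_lag,
                      difference, min_lag = floor_lag)
  rev_ <- granger_test(tgt, src, max_lag, alpha, criterion, fixed_lag,
                       difference, min_lag = floor_lag)
  structure(
    list(source = ids[1], target = ids[2],
         confirmed = fwd$reject,
         bidirectional = fwd$reject && rev_$reject,
         anomaly = !fwd$reject && rev_$reject,
         forward = fwd, reverse = rev_,
         lag_hours = abs(result$T_delay), strength = result$P_max),
    class = "direction_decision")
}

#' @export
print.direction_decision <- function(x, ...) {
  verdict <- if (x$confirmed) "CONFIRMED" else if (x$anomaly)
    "not confirmed (reverse-only rejection: anomaly)" else "not confirmed"
  cat(sprintf("<direction_decision> %s -> %s: %s%s\n", x$source, x$target,
              verdict, if (x$bidirectional) " [bidirectional]" else ""))
  cat(sprintf("  strength P_max = %.4f, |lag| = %d h; forward p = %.4g, reverse p = %.4g\n",
              x$strength, x$lag_hours, x$forward$p_value, x$reverse$p_value))
  invisible(x)
}
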