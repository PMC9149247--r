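#' Lag-scanned Pearson cross-correlation for a city pair
#'
#' Computes the profile P(tau) = Corr(X1(t), X2(t - tau)) over an hourly
#' lag grid, typically +/- 168 h (one synoptic week). The maximum of the
#' profile, `P_max`, measures the strength of a potential transport
#' relationship; the lag at which it occurs, `T_delay`, its temporal order.
#' A negative `T_delay` means X2 lags X1 — the candidate direction is
#' X1 -> X2 (an upwind city leading a downwind one by |T_delay| hours).
#'
#' Correlations use pairwise-complete overlap at each lag; lags whose
#' overlap falls below `min_overlap`, or where either slice has zero
#' variance, are undefined (`NA`) and ignored by the argmax. Two gates are
#' attached: a t-test that `P_max` differs from zero
#' ([test_r_nonzero()]) and a one-sided Fisher r-to-z comparison of `P_max`
#' against the contemporaneous P(0) ([fisher_compare()]). Ties in the
#' argmax resolve to the smallest |tau|, then to the negative lag; a
#' maximum sitting on the grid edge is flagged `boundary` (an argmax at the
#' edge is not a located peak).
#'
#' @param x1,x2 `site_series` objects on the same timezone, or plain
#'   numeric vectors (taken as already aligned hourly series).
#' @param tau_min,tau_max Lag grid bounds in hours (must bracket 0).
#' @param step Grid step in hours (>= 1).
#' @param min_overlap Minimum pairwise-complete overlap for a lag to be
#'   defined (>= 3; default 30).
#' @param alpha Significance level for both gates.
#' @return An object of class `lagcorr`: the grid `tau`, profile `P`,
#'   overlap counts `n`, `P_max`, `T_delay`, `P_zero`, the two p-values
#'   (`p_r`, `p_fisher`), `significant` and `boundary` flags.
#' @seealso [significant_pair()], [confirm_direction()]
#' @export
lag_correlation <- function(x1, x2, tau_min = -168, tau_max = 168, step = 1,
                            min_overlap = 30, alpha = 0.05) {
  stopifnot(tau_min <= 0, tau_max >= 0, step >= 1, min_overlap >= 3)
  if (inherits(x1, "site_series") && inherits(x2, "site_series") &&
      x1$tz_offset_hours != x2$tz_offset_hours)
    stop("series must be expressed in the same timezone; use align_timezone()")
  pair <- c(if (inherits(x1, "site_series")) x1$city_id else "x1",
            if (inherits(x2, "site_series")) x2$city_id else "x2")
  v1 <- if (inherits(x1, "site_series")) x1$values else as.numeric(x1)
  v2 <- if (inherits(x2, "site_series")) x2$values else as.numeric(x2)
  # hour offset between the two grids (0 when plain vectors)
  d <- if (inherits(x1, "site_series") && inherits(x2, "site_series"))
    as.numeric(x1$start - x2$start, units = "hours") else 0
  if (d != round(d)) stop("series are not on a common hourly grid")

  taus <- seq(tau_min, tau_max, by = step)
  if (all(taus == round(taus))) taus <- as.integer(taus)
  if (!any(taus == 0)) stop("lag grid must include tau = 0")
  P <- rep(NA_real_, length(taus))
  n <- integer(length(taus))
  n1 <- length(v1); n2 <- length(v2)
  for (k in seq_along(taus)) {
    s <- d - taus[k]               # x1[i] pairs with x2[i + s]
    i0 <- max(1, 1 - s); i1 <- min(n1, n2 - s)
    if (i1 < i0) next
    a <- v1[i0:i1]; b <- v2[(i0 + s):(i1 + s)]
    ok <- !is.na(a) & !is.na(b)
    n[k] <- sum(ok)
    if (n[k] < min_overlap) next
    a <- a[ok]; b <- b[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next  # undefined, not an error
    P[k] <- stats::cor(a, b)
  }
  defined <- !is.na(P)
  if (!any(defined)) stop("insufficient overlap: no lag has >= ", min_overlap,
                          " complete pairs")
  P_max <- max(P[defined])
  cand <- which(defined & P == P_max)
  cand <- cand[order(abs(taus[cand]), taus[cand])]   # smallest |tau|, then negative
  imax <- cand[1]
  T_delay <- taus[imax]
  n_max <- n[imax]
  izero <- which(taus == 0)
  P_zero <- P[izero]
  n_zero <- n[izero]

  p_r <- test_r_nonzero(P_max, n_max, alpha)$p_value
  p_fisher <- if (T_delay == 0 || is.na(P_zero)) NA_real_ else
    fisher_compare(P_max, P_zero, n_max, n_zero, alpha)$p_value

  res <- structure(
    list(pair = pair, tau = taus, P = P, n = n,
         P_max = P_max, T_delay = T_delay, n_max = n_max,
         P_zero = P_zero, n_zero = n_zero,
         p_r = p_r, p_fisher = p_fisher,
         boundary = T_delay %in% c(tau_min, tau_max),
         alpha = alpha, min_overlap = min_overlap),
    class = "lagcorr")
  res$significant <- significant_pair(res, alpha)
  res
}

#' @export
print.lagcorr <- function(x, ...) {
  cat(sprintf("<lagcorr> %s ~ %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  P_max = %.4f at T_delay = %d h (n = %d); P(0) = %s (n = %d)\n",
              x$P_max, x$T_delay, x$n_max,
              ifelse(is.na(x$P_zero), "NA", sprintf("%.4f", x$P_zero)), x$n_zero))
  cat(sprintf("  p_r = %.3g; p_fisher = %s; significant: %s%s\n",
              x$p_r, ifelse(is.na(x$p_fisher), "NA (lag zero)",
                            sprintf("%.3g", x$p_fisher)),
              x$significant, if (x$boundary) " [boundary maximum]" else ""))
  if (x$significant && x$T_delay != 0)
    cat(sprintf("  candidate direction: %s -> %s (|lag| = %d h)\n",
                x$pair[(x$T_delay > 0) + 1L], x$pair[(x$T_delay < 0) + 1L],
                abs(x$T_delay)))
  invisible(x)
}

#' @export
plot.lagcorr <- function(x, ...) {
  graphics::plot(x$tau, x$P, type = "l", xlab = "lag tau (h)",
                 ylab = "P(tau)",
                 main = sprintf("%s ~ %s", x$pair[1], x$pair[2]), ...)
  graphics::abline(v = 0, lty = 3)
  graphics::points(x$T_delay, x$P_max, pch = 19, col = "red3")
  graphics::mtext(sprintf("P_max = %.3f at %d h", x$P_max, x$T_delay),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' t-test that a correlation coefficient differs from zero
#'
#' Two-sided test based on t = r sqrt(n - 2) / sqrt(1 - r^2) with n - 2
#' degrees of freedom. At |r| = 1 the statistic is infinite; the p-value is
#' reported as the smallest representable double rather than crashing.
#'
#' @param r Pearson correlation, |r| <= 1.
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @return A `driftnet_sigtest` list: `test`, `statistic`, `df`, `p_value`,
#'   `alpha`, `significant`.
#' @export
test_r_nonzero <- function(r, n, alpha = 0.05) {
  stopifnot(abs(r) <= 1, n >= 4)
  if (abs(r) == 1) {
    t_stat <- Inf
    p <- .Machine$double.xmin
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  }
  sigtest("correlation t-test", t_stat, df = n - 2, p_value = p, alpha = alpha)
}

#' Fisher r-to-z comparison of two correlation coefficients
#'
#' One-sided test that `r_max` exceeds `r_zero`, using
#' z = (atanh(r_max) - atanh(r_zero)) / sqrt(1/(n_max - 3) + 1/(n_zero - 3)).
#' This is the independent-samples form; the lagged and contemporaneous
#' coefficients actually share data, a dependence deliberately not
#' corrected for (see the methods vignette). Correlations at |r| = 1 are
#' saturated at atanh(1 - 1e-15) with a warning.
#'
#' @param r_max,r_zero The two correlations being compared.
#' @param n_max,n_zero Their sample sizes (>= 4).
#' @param alpha Significance level.
#' @return A `driftnet_sigtest` list (statistic is z; df is `NA`).
#' @export
fisher_compare <- function(r_max, r_zero, n_max, n_zero, alpha = 0.05) {
  stopifnot(n_max >= 4, n_zero >= 4, abs(r_max) <= 1, abs(r_zero) <= 1)
  cap <- 1 - 1e-15
  if (abs(r_max) >= 1 || abs(r_zero) >= 1) {
    warning("correlation at +/-1: Fisher transform saturated at atanh(1 - 1e-15)")
    r_max <- sign(r_max) * min(abs(r_max), cap)
    r_zero <- sign(r_zero) * min(abs(r_zero), cap)
  }
  z <- (atanh(r_max) - atanh(r_zero)) /
    sqrt(1 / (n_max - 3) + 1 / (n_zero - 3))
  p <- stats::pnorm(z, lower.tail = FALSE)
  sigtest("Fisher r-to-z (one-sided)", z, df = NA_real_, p_value = p,
          alpha = alpha)
}

sigtest <- function(test, statistic, df, p_value, alpha) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, alpha = alpha,
                 significant = p_value < alpha),
            class = "driftnet_sigtest")
}

#' @export
print.driftnet_sigtest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (alpha = %g) -> %s\n",
              x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p_value, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Two-test significance gate for a city pair
#'
#' A pair is significant when `P_max` differs from zero (t-test) and, for a
#' lagged maximum, `P_max` is significantly larger than P(0) (Fisher
#' r-to-z). At `T_delay = 0` the Fisher comparison is vacuous (it would
#' compare `P_max` with itself), so the pair can be significant at lag zero
#' — but such pairs yield no directed edge downstream.
#'
#' @param result A `lagcorr` object.
#' @param alpha Significance level (defaults to the one used in the fit).
#' @return Logical.
#' @export
significant_pair <- function(result, alpha = result$alpha) {
  stopifnot(inherits(result, "lagcorr"))
  if (!(result$p_r < alpha)) return(FALSE)
  if (result$T_delay == 0) return(TRUE)
  !is.na(result$p_fisher) && result$p_fisher < alpha
}

#' Export a lag-correlation profile as a long-format data frame
#'
#' @param x A `lagcorr` object.
#' @param ... Unused.
#' @return Data frame with columns `city_1`, `city_2`, `tau`, `P_tau`, `n_tau`.
#' @export
as.data.frame.lagcorr <- function(x, ...) {
  data.frame(city_1 = x$pair[1], city_2 = x$pair[2],
             tau = x$tau, P_tau = x$P, n_tau = x$n,
             stringsAsFactors = FALSE)
}
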