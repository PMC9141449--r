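# Time-domain features computed per channel: basic signal statistics,
# Hjorth parameters, the non-stationary index, the Higuchi fractal
# dimension and higher-order crossings.

#' Basic time-domain statistics of a signal
#'
#' Power (mean squared amplitude), mean, standard deviation (n - 1
#' denominator), mean absolute first and second differences and their
#' standard-deviation-normalized versions. When the standard deviation is
#' zero the normalized differences are defined as 0.
#'
#' @param x Numeric signal vector, length >= 3.
#' @return List with `power`, `mean`, `sd`, `first_diff`,
#'   `norm_first_diff`, `second_diff`, `norm_second_diff`.
#' @export
time_stats <- function(x) {
  T <- length(x)
  if (T < 3) stopf("signal too short (%d); need length >= 3", T)
  mu <- mean(x)
  sdv <- stats::sd(x)
  d1 <- sum(abs(diff(x))) / (T - 1)
  d2 <- sum(abs(x[3:T] - x[1:(T - 2)])) / (T - 2)
  list(power = mean(x^2), mean = mu, sd = sdv,
       first_diff = d1,
       norm_first_diff = if (sdv > 0) d1 / sdv else 0,
       second_diff = d2,
       norm_second_diff = if (sdv > 0) d2 / sdv else 0)
}

#' Hjorth parameters
#'
#' Activity is the population variance (T denominator). Mobility is the
#' rooted ratio of the variance of the first forward difference to the
#' variance of the signal; complexity is the mobility of the differenced
#' signal divided by the mobility of the signal.
#'
#' @param x Numeric signal vector, length >= 3, non-constant.
#' @return List with `activity`, `mobility`, `complexity`.
#' @export
hjorth <- function(x) {
  if (length(x) < 3) stopf("signal too short; need length >= 3")
  v0 <- stats::var(x)
  if (!is.finite(v0) || v0 == 0) stopf("degenerate signal: zero variance")
  d1 <- diff(x)
  d2 <- diff(d1)
  mob <- sqrt(stats::var(d1) / v0)
  mob_d <- sqrt(stats::var(d2) / stats::var(d1))
  list(activity = mean((x - mean(x))^2), mobility = mob,
       complexity = mob_d / mob)
}

#' Non-stationary index
#'
#' The signal is z-normalized, divided into `n_segments` equal parts
#' (a trailing remainder is truncated) and the variance of the segment
#' means is returned. Stationary signals give values near zero.
#'
#' @param x Numeric signal vector.
#' @param n_segments Number of segments (default 32; 120-sample segments on
#'   a 3840-sample window).
#' @return List with `value`, `n_segments`, `local_means`.
#' @export
nsi <- function(x, n_segments = 32) {
  if (n_segments < 2) stopf("`n_segments` must be >= 2")
  T <- length(x)
  seg_len <- T %/% n_segments
  if (seg_len < 1) stopf("signal too short for %d segments", n_segments)
  sdv <- stats::sd(x)
  z <- if (sdv > 0) (x - mean(x)) / sdv else x * 0
  z <- z[seq_len(seg_len * n_segments)]
  means <- colMeans(matrix(z, seg_len, n_segments))
  list(value = stats::var(means), n_segments = n_segments,
       local_means = means)
}

#' Higuchi fractal dimension
#'
#' Builds the k sub-sampled curves for each time interval k = 1..kmax,
#' averages their normalized lengths and estimates the dimension as the
#' negative least-squares slope of log mean length versus log k. Estimates
#' are clipped into \[1, 2\], the admissible range for a planar curve.
#'
#' @param x Numeric signal vector.
#' @param kmax Largest time interval (default 8).
#' @return List with `dimension`, `kmax`, `curve_lengths` (mean L(k)).
#' @export
higuchi_fd <- function(x, kmax = 8) {
  T <- length(x)
  if (kmax < 2) stopf("`kmax` must be >= 2")
  if (T < 2 * kmax) stopf("signal too short (%d) for kmax = %d", T, kmax)
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      n_steps <- (T - m) %/% k
      if (n_steps < 1) { Lm[m] <- NA; next }
      idx <- m + (0:n_steps) * k
      Lm[m] <- (T - 1) / (k^2 * n_steps) * sum(abs(diff(x[idx])))
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  if (any(Lk <= 0)) stopf("degenerate signal: zero curve length")
  fit <- stats::lm.fit(cbind(1, log(seq_len(kmax))), log(Lk))
  d <- -fit$coefficients[2]
  list(dimension = min(2, max(1, unname(d))), kmax = kmax,
       curve_lengths = Lk)
}

#' Higher-order crossing counts
#'
#' The signal is demeaned, then for each order k = 1..`max_order` the
#' backward difference operator is applied k - 1 times and the number of
#' strict sign changes is counted (exact zeros are removed before
#' counting).
#'
#' @param x Numeric signal vector, length > `max_order`.
#' @param max_order Number of filter orders (default 10).
#' @return Integer vector of length `max_order` of zero-crossing counts.
#' @export
hoc_features <- function(x, max_order = 10) {
  if (max_order < 1) stopf("`max_order` must be >= 1")
  if (length(x) <= max_order)
    stopf("signal too short (%d) for max_order = %d", length(x), max_order)
  y <- x - mean(x)
  counts <- integer(max_order)
  for (k in seq_len(max_order)) {
    s <- sign(y)
    s <- s[s != 0]
    counts[k] <- if (length(s) > 1) sum(s[-1] != s[-length(s)]) else 0L
    y <- diff(y)
  }
  counts
}
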