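# Time-frequency features: empirical mode decomposition with the
# Hilbert-Huang spectrum, and 4-level db4 discrete-wavelet features.

# ---- Empirical mode decomposition ------------------------------------------

# Locate extrema of a signal. mode "all": every strict local max/min
# (plateaus use their first sample). mode "segment": one max and one min per
# `seg_len`-sample block, the detector printed in the sifting algorithm.
find_extrema <- function(x, mode = "all", seg_len = 128) {
  T <- length(x)
  if (mode == "all") {
    d <- diff(x)
    s <- sign(d)
    nz <- which(s != 0)
    if (length(nz) < 2)
      return(list(max_idx = integer(), max_val = numeric(),
                  min_idx = integer(), min_val = numeric()))
    # Carry signs over flat runs so plateau edges register once.
    sf <- s
    for (i in seq_len(T - 1)[-1]) if (sf[i] == 0) sf[i] <- sf[i - 1]
    turns <- which(sf[-1] != sf[-(T - 1)] & sf[-(T - 1)] != 0) + 1
    mx <- turns[sf[turns - 1] > 0]
    mn <- turns[sf[turns - 1] < 0]
    list(max_idx = mx, max_val = x[mx], min_idx = mn, min_val = x[mn])
  } else {
    starts <- seq(1, T, by = seg_len)
    mx_i <- integer(); mn_i <- integer()
    for (s0 in starts) {
      s1 <- min(s0 + seg_len - 1, T)
      if (s1 - s0 < 1) next
      blk <- x[s0:s1]
      mx_i <- c(mx_i, s0 - 1 + which.max(blk))
      mn_i <- c(mn_i, s0 - 1 + which.min(blk))
    }
    list(max_idx = mx_i, max_val = x[mx_i], min_idx = mn_i, min_val = x[mn_i])
  }
}

# Cubic-spline envelope through extrema, with one mirrored extremum beyond
# each end so the spline does not diverge at the boundaries.
spline_envelope <- function(idx, val, T) {
  if (idx[1] > 1) { idx <- c(2 - idx[1], idx); val <- c(val[1], val) }
  nl <- length(idx)
  if (idx[nl] < T) { idx <- c(idx, 2 * T - idx[nl]); val <- c(val, val[nl]) }
  stats::spline(idx, val, xout = seq_len(T), method = "fmm")$y
}

#' Empirical mode decomposition by sifting
#'
#' Iteratively extracts intrinsic mode functions: upper and lower
#' cubic-spline envelopes through the local maxima/minima are averaged and
#' subtracted until the normalized squared change between consecutive
#' sifts falls below `sd_threshold`; the extracted component becomes an
#' IMF and sifting restarts on the remainder. Extraction stops when the
#' mean absolute residue falls below `residue_threshold`, the residue has
#' fewer than 4 extrema, or `max_imfs` is reached. By construction the
#' IMFs plus the residue reconstruct the input exactly.
#'
#' @param x Numeric signal vector.
#' @param seg_len Block length for the segment-wise extrema detector
#'   (default 128; only used when `extrema = "segment"`).
#' @param residue_threshold Stop when mean(|residue|) falls below this
#'   (default 1e-3).
#' @param sd_threshold Sift stopping threshold (default 0.25, in the
#'   classic 0.2-0.3 range).
#' @param max_imfs Maximum number of IMFs (default 10).
#' @param extrema "all" (every local extremum, default) or "segment" (one
#'   max/min per block, as printed in the sifting algorithm).
#' @param max_sift Hard cap on sift iterations per IMF (default 200); on
#'   hitting it the current component is kept and a warning flag recorded.
#' @return An `imf_set`: list with `imfs` (list of vectors), `residue`,
#'   `non_convergent` (logical per IMF).
#' @export
emd_decompose <- function(x, seg_len = 128, residue_threshold = 1e-3,
                          sd_threshold = 0.25, max_imfs = 10,
                          extrema = c("all", "segment"), max_sift = 200) {
  extrema <- match.arg(extrema)
  if (seg_len < 4) stopf("`seg_len` must be >= 4")
  if (sd_threshold <= 0 || sd_threshold >= 1)
    stopf("`sd_threshold` must be in (0, 1)")
  if (max_imfs < 1) stopf("`max_imfs` must be >= 1")
  T <- length(x)
  if (T < 2 * seg_len) stopf("signal too short (%d) for seg_len %d", T, seg_len)
  imfs <- list()
  flags <- logical()
  r <- x
  repeat {
    h <- r
    it <- 0
    converged <- FALSE
    repeat {
      ex <- find_extrema(h, extrema, seg_len)
      if (length(ex$max_idx) < 2 || length(ex$min_idx) < 2) {
        converged <- TRUE  # too few extrema: component cannot be sifted further
        break
      }
      upper <- spline_envelope(ex$max_idx, ex$max_val, T)
      lower <- spline_envelope(ex$min_idx, ex$min_val, T)
      m <- (upper + lower) / 2
      hn <- h - m
      # Cauchy-type sift criterion: normalized squared change between
      # consecutive sifts (ratio-of-sums form, which is well-behaved where
      # the component passes through zero).
      sd_val <- sum((h - hn)^2) / max(sum(h^2), 1e-300)
      h <- hn
      it <- it + 1
      if (sd_val <= sd_threshold) { converged <- TRUE; break }
      if (it >= max_sift) break
    }
    if (!converged)
      warning(sprintf("sift %d did not converge within %d iterations",
                      length(imfs) + 1, max_sift))
    imfs[[length(imfs) + 1]] <- h
    flags <- c(flags, !converged)
    r <- r - h
    if (length(imfs) >= max_imfs) break
    if (mean(abs(r)) <= residue_threshold) break
    ex <- find_extrema(r, "all")
    if (length(ex$max_idx) + length(ex$min_idx) < 4) break
  }
  structure(list(imfs = imfs, residue = r, non_convergent = flags,
                 input_length = T),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) of length %d; mean |residue| %.3g\n",
              length(x$imfs), x$input_length, mean(abs(x$residue))))
  invisible(x)
}

# Analytic signal via the one-sided-spectrum construction.
analytic_signal <- function(x) {
  N <- length(x)
  X <- stats::fft(x)
  h <- numeric(N)
  if (N %% 2 == 0) {
    h[c(1, N / 2 + 1)] <- 1
    h[2:(N / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((N + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / N
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Hilbert-Huang spectrum of an IMF set
#'
#' Per IMF the analytic signal gives instantaneous energy (squared
#' magnitude) and instantaneous frequency (unwrapped phase difference
#' times fs / 2 pi, clipped to \[0, fs/2\]). Band energies aggregate
#' energy over all samples of all IMFs whose instantaneous frequency falls
#' in the band, normalized by the number of time samples.
#'
#' @param imfs An `imf_set` (or plain list of numeric vectors).
#' @param fs Sampling rate in Hz.
#' @return List with `energy` and `frequency` (matrices IMFs x samples)
#'   and `band_energy` (named length-4 vector: theta, alpha, beta, gamma).
#' @export
hilbert_spectrum <- function(imfs, fs) {
  il <- if (inherits(imfs, "imf_set")) imfs$imfs else imfs
  if (!length(il)) stopf("empty IMF list")
  T <- length(il[[1]])
  E <- matrix(0, length(il), T)
  Fq <- matrix(0, length(il), T)
  for (i in seq_along(il)) {
    z <- analytic_signal(il[[i]])
    E[i, ] <- Mod(z)^2
    ph <- unwrap_phase(Arg(z))
    f <- c(diff(ph), 0) * fs / (2 * pi)
    f[T] <- f[T - 1]
    Fq[i, ] <- pmin(pmax(f, 0), fs / 2)
  }
  bands <- band_edges()
  be <- vapply(bands, function(b)
    sum(E[Fq >= b[1] & Fq <= b[2]]) / T, numeric(1))
  list(energy = E, frequency = Fq, band_energy = be)
}

# ---- Discrete wavelet transform (db4, periodized) --------------------------

# Daubechies-4 (8-tap) decomposition/reconstruction filters.
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157,
                -0.6308807679298589, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)
DB4_REC_LO <- rev(DB4_DEC_LO)
DB4_REC_HI <- rev(DB4_DEC_HI)

# One periodized analysis step: x (even length N) -> list(a, d), each N/2.
# a[i] = sum_k dec_lo[k] x[(2(i-1) + k - 1) mod N + 1]; likewise d with
# dec_hi. The shifted filter rows are orthonormal, so the synthesis step is
# the transpose (exact inverse for N >= 16).
dwt_step <- function(x) {
  N <- length(x)
  half <- N / 2
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (k in seq_along(DB4_DEC_LO)) {
    xi <- x[(base + k - 1) %% N + 1]
    a <- a + DB4_DEC_LO[k] * xi
    d <- d + DB4_DEC_HI[k] * xi
  }
  list(a = a, d = d)
}

# Transpose of dwt_step: scatter each coefficient back through its filter.
# Filter taps land on distinct positions for N >= 16 (no wrap collision),
# which dwt_db4's length precondition guarantees at every level.
idwt_step <- function(a, d) {
  half <- length(a)
  N <- 2 * half
  x <- numeric(N)
  base <- 2 * (seq_len(half) - 1)
  for (k in seq_along(DB4_DEC_LO)) {
    pos <- (base + k - 1) %% N + 1
    contrib <- DB4_DEC_LO[k] * a + DB4_DEC_HI[k] * d
    if (anyDuplicated(pos)) {
      for (i in seq_along(pos)) x[pos[i]] <- x[pos[i]] + contrib[i]
    } else {
      x[pos] <- x[pos] + contrib
    }
  }
  x
}

#' 4-level db4 wavelet decomposition
#'
#' Periodized pyramid transform with the 8-tap fourth-order Daubechies
#' filters. The input length must be a multiple of 16.
#'
#' @param x Numeric signal vector (length a multiple of 16, >= 16).
#' @return List of coefficient vectors `A4`, `D4`, `D3`, `D2`, `D1`.
#' @export
dwt_db4 <- function(x) {
  if (length(x) < 16 || length(x) %% 16 != 0)
    stopf("signal length %d must be a positive multiple of 16", length(x))
  a <- x
  det <- list()
  for (lev in 1:4) {
    s <- dwt_step(a)
    a <- s$a
    det[[lev]] <- s$d
  }
  list(A4 = a, D4 = det[[4]], D3 = det[[3]], D2 = det[[2]], D1 = det[[1]])
}

#' Inverse 4-level db4 wavelet transform
#'
#' @param coeffs List as returned by [dwt_db4()].
#' @return The reconstructed signal (machine-precision reconstruction).
#' @export
idwt_db4 <- function(coeffs) {
  a <- coeffs$A4
  for (d in list(coeffs$D4, coeffs$D3, coeffs$D2, coeffs$D1))
    a <- idwt_step(a, d)
  a
}

#' Wavelet-domain features
#'
#' Decomposes the signal with [dwt_db4()] and maps detail levels to the
#' analysis bands by their frequency ranges at 128 Hz (D4 = theta, D3 =
#' alpha, D2 = beta, D1 = gamma). Per band: Shannon entropy (natural log)
#' of the normalized squared coefficients, the RMS of the coefficients,
#' and |ln REE| where REE is the band's share of the total energy over all
#' five sub-bands (A4, D4..D1). The REE values over the five sub-bands sum
#' to 1.
#'
#' @param x Numeric signal vector (length a multiple of 16).
#' @return List with `coeffs`, per-band matrices in `features` (rows
#'   theta/alpha/beta/gamma; columns entropy, rms, abs_log_ree) and `ree`
#'   (all five sub-bands).
#' @export
dwt_features <- function(x) {
  if (all(x == 0)) stopf("degenerate signal: all zeros")
  co <- dwt_db4(x)
  energies <- vapply(co, function(cf) sum(cf^2), numeric(1))
  total <- sum(energies)
  ree <- energies / total
  bands <- c(theta = "D4", alpha = "D3", beta = "D2", gamma = "D1")
  feat <- matrix(NA_real_, 4, 3,
                 dimnames = list(names(bands), c("entropy", "rms", "abs_log_ree")))
  for (i in seq_along(bands)) {
    cf <- co[[bands[[i]]]]
    e2 <- cf^2
    p <- e2 / sum(e2)
    p <- p[p > 0]
    feat[i, ] <- c(-sum(p * log(p)), sqrt(mean(cf^2)),
                   abs(log(ree[[bands[[i]]]])))
  }
  list(coeffs = co, features = feat, ree = ree)
}
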