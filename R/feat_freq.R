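# Frequency-domain features: Welch spectra, power-law index, short-time
# band power, the bispectrum with its scalar summaries, magnitude-squared
# coherence and hemispheric asymmetry.

# Segment a signal for Welch-type averaging: demean each segment, apply the
# taper, return the matrix of one-sided FFT columns (nfft odd -> bins
# 0..(nfft-1)/2, no Nyquist bin).
welch_segments_fft <- function(x, nfft, overlap) {
  T <- length(x)
  if (T < nfft) stopf("signal length %d < segment length %d", T, nfft)
  step <- nfft - overlap
  starts <- seq(1, T - nfft + 1, by = step)
  w <- hamming_window(nfft)
  n_keep <- (nfft + 1) %/% 2
  out <- matrix(0i, n_keep, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nfft - 1)]
    seg <- (seg - mean(seg)) * w
    out[, i] <- stats::fft(seg)[seq_len(n_keep)]
  }
  out
}

#' Welch averaged modified periodogram
#'
#' Power spectral density with an 853-point Hamming window and 426-sample
#' (half-window) overlap; each segment is demeaned before tapering. The
#' density normalization satisfies Parseval: sum(power) * df approximates
#' the signal variance.
#'
#' @param x Numeric signal vector (length >= `nfft`; a 3840-sample window
#'   yields 7 averaged segments).
#' @param fs Sampling rate in Hz.
#' @param nfft Window/FFT length (default 853).
#' @param overlap Overlap in samples (default 426).
#' @return A `psd_estimate`: list with `freqs` (Hz), `power` (density,
#'   units^2/Hz), `nfft`, `overlap`, `n_segments`.
#' @export
welch_psd <- function(x, fs, nfft = 853, overlap = 426) {
  ff <- welch_segments_fft(x, nfft, overlap)
  w <- hamming_window(nfft)
  scale <- 1 / (fs * sum(w^2))
  p <- rowMeans(Mod(ff)^2) * scale
  p[-1] <- 2 * p[-1]  # one-sided (odd nfft: no Nyquist bin)
  structure(list(freqs = (seq_len(nrow(ff)) - 1) * fs / nfft, power = p,
                 nfft = nfft, overlap = overlap, n_segments = ncol(ff),
                 fs = fs),
            class = "psd_estimate")
}

#' Power-law index of a spectrum
#'
#' Fits log10 power against log10 frequency by least squares over
#' `fit_range` and returns the negated slope: the exponent eta of
#' P(f) ~ f^-eta. Non-positive power bins are excluded from the fit.
#'
#' @param psd A `psd_estimate` from [welch_psd()].
#' @param fit_range Frequency range in Hz (default 3-47, the analyzed band).
#' @return List with `eta`, `fit_range`, `r_squared`.
#' @export
power_law_index <- function(psd, fit_range = c(3, 47)) {
  keep <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2] & psd$power > 0
  if (sum(keep) < 5) stopf("fewer than 5 usable bins in fit range")
  lf <- log10(psd$freqs[keep]); lp <- log10(psd$power[keep])
  fit <- stats::lm.fit(cbind(1, lf), lp)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lp - mean(lp))^2)
  list(eta = -unname(fit$coefficients[2]), fit_range = fit_range,
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0)
}

# Per-frame band energies of the short-time Fourier transform: 128-sample
# (1000 ms) Hamming frames, no overlap; band energy is the sum of squared
# magnitudes over the band's frequency bins. Returns frames x bands.
stft_band_energy <- function(x, fs, frame_len = 128) {
  n_frames <- length(x) %/% frame_len
  if (n_frames < 1) stopf("signal shorter than one %d-sample frame", frame_len)
  w <- hamming_window(frame_len)
  freqs <- (0:(frame_len %/% 2)) * fs / frame_len
  bands <- band_edges()
  bins <- lapply(bands, function(b) which(freqs >= b[1] & freqs <= b[2]))
  if (any(vapply(bins, length, 1L) == 0))
    stopf("sampling rate %g Hz leaves an empty analysis band", fs)
  out <- matrix(0, n_frames, length(bands),
                dimnames = list(NULL, names(bands)))
  for (i in seq_len(n_frames)) {
    seg <- x[((i - 1) * frame_len + 1):(i * frame_len)] * w
    mag2 <- Mod(stats::fft(seg)[seq_along(freqs)])^2
    for (b in seq_along(bins)) out[i, b] <- sum(mag2[bins[[b]]])
  }
  out
}

#' Short-time band-power features
#'
#' 128-sample (1000 ms at 128 Hz) Hamming frames with no overlap (30 frames
#' on a 3840-sample window). Per band (theta 3-7, alpha 8-13, beta 14-29,
#' gamma 30-47 Hz): natural log of the frame-averaged, maximum and minimum
#' band energy; plus the variance of the four average band powers and the
#' average beta/alpha power ratio — 14 values.
#'
#' @param x Numeric signal vector (length >= 128).
#' @param fs Sampling rate in Hz.
#' @return List with `per_band` (matrix 4 x 3: log_avg/log_max/log_min),
#'   `power_variance`, `ratio_beta_alpha`, `band_avg` (linear scale),
#'   `n_frames`.
#' @export
band_power_features <- function(x, fs) {
  en <- stft_band_energy(x, fs)
  avg <- colMeans(en)
  per_band <- cbind(log_avg = log(avg),
                    log_max = log(apply(en, 2, max)),
                    log_min = log(apply(en, 2, min)))
  list(per_band = per_band,
       power_variance = stats::var(avg),
       ratio_beta_alpha = avg[["beta"]] / avg[["alpha"]],
       band_avg = avg, n_frames = nrow(en))
}

# Parzen (de la Valle-Poussin) 1-D lag window on |m| <= M.
parzen_lag <- function(m, M) {
  r <- abs(m) / M
  ifelse(r <= 0.5, 1 - 6 * r^2 + 6 * r^3,
         ifelse(r <= 1, 2 * (1 - r)^3, 0))
}

#' Bispectrum estimate (indirect method)
#'
#' The signal is cut into 30 non-overlapping 128-sample segments; each is
#' demeaned and its third-order cumulant sequence C3(k, l) is computed for
#' |k|, |l| <= 63 (biased estimate). Cumulants are averaged over segments,
#' optionally tapered by a product Parzen lag window, and transformed by a
#' two-dimensional 128-point FFT with quadrant shifting so that frequency
#' runs from -fs/2 to fs/2 on both axes.
#'
#' @param x Numeric signal vector, length >= 3840.
#' @param fs Sampling rate in Hz (sets the frequency grid).
#' @param lag_window "none" (default) or "parzen".
#' @param n_segments,segment_len Segmentation (defaults 30 x 128).
#' @return A `bispectrum_estimate`: complex 128 x 128 matrix `B`, frequency
#'   grid `freqs`, logical principal-region mask `omega` (the triangle
#'   0 <= f2 <= f1, f1 + f2 <= fs/2), `n_segments`, `segment_len`.
#' @export
bispectrum_estimate <- function(x, fs = 128, lag_window = c("none", "parzen"),
                                n_segments = 30, segment_len = 128) {
  lag_window <- match.arg(lag_window)
  need <- n_segments * segment_len
  if (length(x) < need) stopf("signal length %d < %d", length(x), need)
  M <- segment_len %/% 2 - 1  # max lag 63
  lags <- -M:M
  nlag <- length(lags)
  C3 <- matrix(0, nlag, nlag)
  for (s in seq_len(n_segments)) {
    seg <- x[((s - 1) * segment_len + 1):(s * segment_len)]
    seg <- seg - mean(seg)
    N <- segment_len
    # Rows: y_k[n] = x[n] * x[n+k] on the valid range, zero elsewhere.
    Y <- matrix(0, nlag, N)
    Xs <- matrix(0, nlag, N)
    for (i in seq_along(lags)) {
      k <- lags[i]
      n0 <- max(1, 1 - k); n1 <- min(N, N - k)
      Y[i, n0:n1] <- seg[n0:n1] * seg[(n0 + k):(n1 + k)]
      Xs[i, n0:n1] <- seg[(n0 + k):(n1 + k)]
    }
    C3 <- C3 + (Y %*% t(Xs)) / N
  }
  C3 <- C3 / n_segments
  if (lag_window == "parzen") {
    d <- parzen_lag(lags, M + 1)
    W <- outer(d, d) * outer(lags, lags, function(k, l) parzen_lag(k - l, M + 1))
    C3 <- C3 * W
  }
  # Embed lags into the FFT grid (index = lag mod segment_len) and transform.
  G <- matrix(0, segment_len, segment_len)
  pos <- (lags %% segment_len) + 1
  G[pos, pos] <- C3
  B <- stats::mvfft(t(stats::mvfft(G)))
  # Quadrant shift so bin 1 corresponds to -fs/2.
  half <- segment_len / 2
  shift <- c((half + 1):segment_len, 1:half)
  B <- B[shift, shift]
  freqs <- ((-half):(half - 1)) * fs / segment_len
  omega <- outer(freqs, freqs, function(f1, f2)
    f2 >= 0 & f2 <= f1 & (f1 + f2) <= fs / 2)
  structure(list(B = B, freqs = freqs, omega = omega,
                 n_segments = n_segments, segment_len = segment_len),
            class = "bispectrum_estimate")
}

#' Scalar summaries of a bispectrum
#'
#' Over the principal region Omega: the normalized bispectral entropy BE1
#' (entropy of |B| normalized to a distribution), the squared-magnitude
#' entropy BE2, and the mean magnitude MMOB. Over the whole matrix: the
#' first-order spectral moment FOSM, the sum of log magnitudes (exact zeros
#' are skipped). Natural logarithms throughout.
#'
#' @param bisp A `bispectrum_estimate`.
#' @return List with `BE1`, `BE2`, `MMOB`, `FOSM`, `pn`, `qn`.
#' @export
bispectral_summaries <- function(bisp) {
  mag <- Mod(bisp$B)[bisp$omega]
  if (all(mag == 0)) stopf("degenerate bispectrum: all-zero magnitude")
  pn <- mag / sum(mag)
  qn <- mag^2 / sum(mag^2)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  allmag <- Mod(bisp$B)
  nz <- allmag[allmag > 0]
  list(BE1 = ent(pn), BE2 = ent(qn), MMOB = mean(mag), FOSM = sum(log(nz)),
       pn = pn, qn = qn)
}

#' Magnitude-squared coherence features over electrode pairs
#'
#' Welch-style coherence |Pij|^2 / (Pi Pj) on the 853-point Hamming /
#' 426-overlap grid, averaged within each analysis band, for each channel
#' pair. With 14 symmetric pairs and 4 bands this yields 56 features.
#'
#' @param trial A `trial_recording` (trimmed or full).
#' @param pairs Integer matrix n x 2 of channel indices (defaults to the 14
#'   symmetric electrode pairs).
#' @return List with `band_coherence` (pairs x bands matrix in \[0, 1\]) and
#'   `coherence` (list of full per-bin coherence vectors).
#' @export
msce_features <- function(trial, pairs = symmetric_pairs()) {
  if (any(pairs[, 1] == pairs[, 2]))
    stopf("a coherence pair must use two distinct channels")
  fs <- trial$fs
  nfft <- 853; overlap <- 426
  chans <- sort(unique(as.vector(pairs)))
  ffts <- lapply(chans, function(ch)
    welch_segments_fft(trial$signal[ch, ], nfft, overlap))
  names(ffts) <- as.character(chans)
  freqs <- (0:((nfft - 1) %/% 2)) * fs / nfft
  bands <- band_edges()
  bmask <- lapply(bands, function(b) freqs >= b[1] & freqs <= b[2])
  bc <- matrix(NA_real_, nrow(pairs), length(bands),
               dimnames = list(NULL, names(bands)))
  coh_full <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    Fi <- ffts[[as.character(pairs[p, 1])]]
    Fj <- ffts[[as.character(pairs[p, 2])]]
    Pij <- rowMeans(Fi * Conj(Fj))
    Pi <- rowMeans(Mod(Fi)^2)
    Pj <- rowMeans(Mod(Fj)^2)
    coh <- Mod(Pij)^2 / (Pi * Pj)
    coh[!is.finite(coh)] <- 0
    coh_full[[p]] <- coh
    for (b in seq_along(bands)) bc[p, b] <- mean(coh[bmask[[b]]])
  }
  list(band_coherence = bc, coherence = coh_full, pairs = pairs)
}

#' Differential and rational hemispheric asymmetry
#'
#' For each symmetric electrode pair and band, the difference (left -
#' right) and ratio (left / right) of the frame-averaged band powers:
#' 56 DASM and 56 RASM values for the standard 14 pairs. A zero
#' right-channel band power yields a missing RASM value.
#'
#' @param trial A `trial_recording`.
#' @param pairs Integer matrix n x 2 (defaults to the 14 symmetric pairs).
#' @return List with matrices `dasm` and `rasm` (pairs x bands).
#' @export
asymmetry_features <- function(trial, pairs = symmetric_pairs()) {
  fs <- trial$fs
  chans <- sort(unique(as.vector(pairs)))
  bp <- lapply(chans, function(ch)
    band_power_features(trial$signal[ch, ], fs)$band_avg)
  names(bp) <- as.character(chans)
  nb <- length(band_names())
  dasm <- matrix(NA_real_, nrow(pairs), nb,
                 dimnames = list(NULL, band_names()))
  rasm <- dasm
  for (p in seq_len(nrow(pairs))) {
    xl <- bp[[as.character(pairs[p, 1])]]
    xr <- bp[[as.character(pairs[p, 2])]]
    dasm[p, ] <- xl - xr
    rasm[p, ] <- ifelse(xr > 0, xl / xr, NA_real_)
  }
  list(dasm = dasm, rasm = rasm, pairs = pairs)
}
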