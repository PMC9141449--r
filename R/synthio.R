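# Synthetic dataset generation and on-disk container I/O.
#
# The generator emulates the geometry of a preprocessed 32-subject affective
# study: per trial a 40 x 8064 signal matrix (32 EEG + 8 peripheral channels,
# 128 Hz, 63 s including a 3 s baseline) with continuous valence / arousal /
# dominance / liking ratings in (0, 9). Emotion structure is injected as
# band-power shifts (alpha power decreasing with arousal, beta increasing
# with valence) so that every downstream feature family can detect it.

EEG_CHANNELS <- c(
  "Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7", "CP5", "CP1",
  "P3", "P7", "PO3", "O1", "Oz", "Pz", "Fp2", "AF4", "Fz", "F4",
  "F8", "FC6", "FC2", "Cz", "C4", "T8", "CP6", "CP2", "P4", "P8",
  "PO4", "O2"
)

PERIPHERAL_CHANNELS <- c(
  "hEOG", "vEOG", "zEMG", "tEMG", "GSR", "Resp", "Plethysmograph", "Temp"
)

# The 14 left/right symmetric electrode pairs of the 32-channel montage
# (the 4 midline electrodes Fz, Cz, Pz, Oz have no partner).
SYMMETRIC_PAIRS <- matrix(c(
  "Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8", "FC1", "FC2",
  "FC5", "FC6", "C3", "C4", "T7", "T8", "CP1", "CP2", "CP5", "CP6",
  "P3", "P4", "P7", "P8", "PO3", "PO4", "O1", "O2"
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("left", "right")))

#' Ordered channel labels of the combined modality
#'
#' @return Character vector of length 40: the 32 EEG electrodes in montage
#'   order followed by the 8 peripheral channels.
#' @export
channel_labels <- function() c(EEG_CHANNELS, PERIPHERAL_CHANNELS)

#' Symmetric electrode pairs
#'
#' The 14 left/right electrode pairs used for coherence and asymmetry
#' features, as channel indices into the 32 EEG channels.
#'
#' @return Integer matrix 14 x 2 with columns `left`, `right`.
#' @export
symmetric_pairs <- function() {
  cbind(left = match(SYMMETRIC_PAIRS[, 1], EEG_CHANNELS),
        right = match(SYMMETRIC_PAIRS[, 2], EEG_CHANNELS))
}

new_trial_recording <- function(subject_id, trial_id, signal, fs, ratings) {
  stopifnot(is.matrix(signal))
  structure(
    list(subject_id = as.integer(subject_id), trial_id = as.integer(trial_id),
         signal = signal, fs = fs, channel_labels = channel_labels()[seq_len(nrow(signal))],
         ratings = ratings),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> subject %d trial %d: %d x %d @ %g Hz\n",
              x$subject_id, x$trial_id, nrow(x$signal), ncol(x$signal), x$fs))
  cat(sprintf("  ratings: V=%.2f A=%.2f D=%.2f L=%.2f\n",
              x$ratings[1], x$ratings[2], x$ratings[3], x$ratings[4]))
  invisible(x)
}

#' @export
print.physio_dataset <- function(x, ...) {
  cat(sprintf("<physio_dataset> %d subjects x %d trials (%d total), seed %d\n",
              x$n_subjects, x$n_trials_per_subject, length(x$trials), x$seed))
  invisible(x)
}

# A band-limited oscillation around given characteristic frequencies:
# random phases and a small frequency jitter per call, unit total power.
# Real scalp rhythms concentrate at stable, subject-characteristic peak
# frequencies (e.g. the individual alpha frequency) rather than spreading
# uniformly over their band.
band_oscillation <- function(t, freqs, jitter = 0.15) {
  freqs <- freqs + stats::runif(length(freqs), -jitter, jitter)
  phases <- stats::runif(length(freqs), 0, 2 * pi)
  x <- numeric(length(t))
  for (i in seq_along(freqs)) x <- x + sin(2 * pi * freqs[i] * t + phases[i])
  x * sqrt(2 / length(freqs))  # unit variance
}

# Band-limited white noise (FFT masking), emulating the 4-45 Hz band-pass
# applied to preprocessed scalp recordings; unit variance before `sd`.
bandpassed_noise <- function(n, fs, sd = 1, band = c(4, 45)) {
  f <- (0:(n - 1)) * fs / n
  fmir <- pmin(f, fs - f)
  keep <- fmir >= band[1] & fmir <= band[2]
  X <- stats::fft(stats::rnorm(n))
  X[!keep] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Generate a synthetic multimodal physiological dataset
#'
#' Each trial is a 40 x `n_samples` matrix (32 EEG + 8 peripheral channels at
#' `fs` Hz). Latent valence/arousal/dominance/liking ratings are drawn
#' uniformly on (1, 9). EEG channels are sums of theta, alpha, beta and
#' gamma oscillations at per-subject characteristic peak frequencies plus
#' 4-45 Hz band-limited noise; the alpha amplitude decreases linearly with
#' arousal and the beta amplitude increases with valence, both scaled by
#' `effect_size`. Peripheral channels carry slow drifts with
#' rating-modulated noise variance. A per-subject lognormal gain emulates
#' inter-subject amplitude variability.
#'
#' @param n_subjects,n_trials Positive counts.
#' @param seed Integer seed; regeneration with equal arguments is
#'   bit-for-bit identical.
#' @param effect_size Non-negative scaling of the rating-dependent structure;
#'   0 makes signals statistically independent of the ratings, 1 gives
#'   moderate class separability, 2 strong separability.
#' @param n_samples Samples per trial (default 8064 = 63 s at 128 Hz).
#' @param fs Sampling rate in Hz.
#' @return A `physio_dataset`: list of `trial_recording`s plus metadata.
#' @export
generate_dataset <- function(n_subjects, n_trials, seed, effect_size = 1,
                             n_samples = 8064, fs = 128) {
  assert_scalar_int(n_subjects, "n_subjects", min = 1)
  assert_scalar_int(n_trials, "n_trials", min = 1)
  assert_scalar_int(seed, "seed")
  if (!is.numeric(effect_size) || effect_size < 0)
    stopf("`effect_size` must be a non-negative number")

  bands <- band_edges()
  # Baseline band amplitudes (alpha-dominant, 1/f-like decline).
  base_amp <- c(theta = 0.9, alpha = 1.0, beta = 0.55, gamma = 0.3)
  tt <- (seq_len(n_samples) - 1) / fs

  trials <- vector("list", n_subjects * n_trials)
  idx <- 0
  for (s in seq_len(n_subjects)) {
    subj <- with_seed(derive_seed(seed, s, 0), {
      # per-subject gain and characteristic peak frequency per band: the
      # canonical band center plus ~0.5 Hz of between-subject variation
      # (cf. the individual alpha frequency), truncated into the band
      list(gain = exp(stats::rnorm(1, 0, 0.2)),
           peaks = lapply(bands, function(b)
             min(max(mean(b) + stats::rnorm(1, 0, 0.5), b[1] + 0.5),
                 b[2] - 0.5)))
    })
    gain <- subj$gain
    for (tr in seq_len(n_trials)) {
      idx <- idx + 1
      trials[[idx]] <- with_seed(derive_seed(seed, s, tr), {
        ratings <- stats::runif(4, 1, 9)  # valence, arousal, dominance, liking
        valence <- ratings[1]; arousal <- ratings[2]
        # Rating-modulated band amplitudes, floored away from zero.
        amp <- base_amp
        amp["alpha"] <- max(0.05, amp["alpha"] * (1 - 0.45 * effect_size * (arousal - 5) / 4))
        amp["beta"]  <- max(0.05, amp["beta"]  * (1 + 0.40 * effect_size * (valence - 5) / 4))
        sig <- matrix(0, 40, n_samples)
        for (ch in 1:32) {
          x <- numeric(n_samples)
          for (b in band_names())
            x <- x + amp[[b]] * band_oscillation(tt, subj$peaks[[b]],
                                                 jitter = 0.05)
          sig[ch, ] <- gain * (x + bandpassed_noise(n_samples, fs, sd = 0.5))
        }
        for (ch in 33:40) {
          drift <- 0.8 * band_oscillation(tt, c(0.1, 0.25), jitter = 0.05)
          nsd <- 0.5 * (1 + 0.25 * effect_size * (arousal - 5) / 4) +
                 0.1 * effect_size * (valence - 5) / 8
          noise <- stats::rnorm(n_samples, sd = max(0.05, nsd))
          sig[ch, ] <- gain * (drift + noise)
        }
        new_trial_recording(s, tr, sig, fs, ratings)
      })
    }
  }
  structure(list(trials = trials, n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials),
                 seed = as.integer(seed), effect_size = effect_size, fs = fs),
            class = "physio_dataset")
}

#' Keep only the last 30 s of the stimulus window
#'
#' Drops the 3 s pre-stimulus baseline and the first half of the 60 s
#' stimulus, keeping the final 3840 samples of every channel.
#'
#' @param rec A `trial_recording` with at least 3840 samples.
#' @return The trimmed `trial_recording` (idempotent on exact length).
#' @export
trim_stimulus_segment <- function(rec) {
  n <- ncol(rec$signal)
  if (n < 3840) stopf("trial has %d samples; >= 3840 required", n)
  if (n > 3840) rec$signal <- rec$signal[, (n - 3840 + 1):n, drop = FALSE]
  rec
}

#' Trim every trial of a dataset
#' @param dataset A `physio_dataset`.
#' @return The dataset with each trial reduced to its last 3840 samples.
#' @export
trim_dataset <- function(dataset) {
  dataset$trials <- lapply(dataset$trials, trim_stimulus_segment)
  dataset
}

#' Ratings matrix of a dataset
#' @param dataset A `physio_dataset`.
#' @return Data frame with columns subject, trial, valence, arousal,
#'   dominance, liking (one row per trial, in dataset order).
#' @export
dataset_ratings <- function(dataset) {
  r <- t(vapply(dataset$trials, function(tr) tr$ratings, numeric(4)))
  data.frame(subject = vapply(dataset$trials, `[[`, 1L, "subject_id"),
             trial = vapply(dataset$trials, `[[`, 1L, "trial_id"),
             valence = r[, 1], arousal = r[, 2], dominance = r[, 3],
             liking = r[, 4])
}

#' Binarize continuous ratings into high/low labels
#'
#' A trial is labelled high (1) iff its rating is strictly greater than the
#' threshold of 4.5, the midpoint of the (0, 9) rating range; a rating of
#' exactly 4.5 maps to low.
#'
#' @param dataset A `physio_dataset` (or a data frame from
#'   [dataset_ratings()]).
#' @param scale One of "valence", "arousal", "dominance".
#' @param threshold Split point (default 4.5).
#' @return A `label_set`: list with `scale`, integer `labels` (0/1),
#'   `threshold`.
#' @export
binarize_ratings <- function(dataset, scale, threshold = 4.5) {
  scale <- match.arg(scale, c("valence", "arousal", "dominance"))
  ratings <- if (is.data.frame(dataset)) dataset else dataset_ratings(dataset)
  labels <- as.integer(ratings[[scale]] > threshold)
  structure(list(scale = scale, labels = labels, threshold = threshold),
            class = "label_set")
}

# ---- On-disk container -----------------------------------------------------
# Directory layout: manifest.json (geometry, seed), ratings.csv, and
# signals/s{SS}.bin holding each subject's trials as raw little-endian
# float64 in trial-major, channel-major order. Lossless and streamable.

#' Write a dataset container to disk
#'
#' @param dataset A `physio_dataset`.
#' @param path Directory to create (overwritten if it exists).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(file.path(path, "signals"), recursive = TRUE, showWarnings = FALSE)
  n_ch <- nrow(dataset$trials[[1]]$signal)
  n_sa <- ncol(dataset$trials[[1]]$signal)
  manifest <- list(format = "affectsda-dataset", version = 1L,
                   n_subjects = dataset$n_subjects,
                   n_trials_per_subject = dataset$n_trials_per_subject,
                   n_channels = n_ch, n_samples = n_sa,
                   fs = dataset$fs, seed = dataset$seed,
                   effect_size = dataset$effect_size)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(dataset_ratings(dataset), file.path(path, "ratings.csv"),
                   row.names = FALSE)
  for (s in seq_len(dataset$n_subjects)) {
    con <- file(file.path(path, "signals", sprintf("s%02d.bin", s)), "wb")
    for (tr in dataset$trials) {
      if (tr$subject_id == s)
        writeBin(as.numeric(t(tr$signal)), con, size = 8, endian = "little")
    }
    close(con)
  }
  invisible(path)
}

#' Read a dataset container from disk
#'
#' @param path Directory written by [write_dataset()].
#' @return A `physio_dataset` identical (bit-for-bit in all signal values,
#'   ids and ratings) to the one written.
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stopf("not a dataset container: missing manifest.json in '%s'", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rf <- file.path(path, "ratings.csv")
  if (!file.exists(rf)) stopf("malformed container: missing ratings table in '%s'", path)
  ratings <- utils::read.csv(rf)
  n_ch <- manifest$n_channels; n_sa <- manifest$n_samples
  trials <- vector("list", manifest$n_subjects * manifest$n_trials_per_subject)
  idx <- 0
  for (s in seq_len(manifest$n_subjects)) {
    f <- file.path(path, "signals", sprintf("s%02d.bin", s))
    if (!file.exists(f)) stopf("malformed container: missing signals for subject %d", s)
    con <- file(f, "rb")
    on.exit(close(con), add = TRUE)
    for (tr in seq_len(manifest$n_trials_per_subject)) {
      vals <- readBin(con, "numeric", n_ch * n_sa, size = 8, endian = "little")
      if (length(vals) < n_ch * n_sa)
        stopf("malformed container: truncated signals at subject %d trial %d", s, tr)
      row <- ratings[ratings$subject == s & ratings$trial == tr, ]
      if (nrow(row) != 1)
        stopf("malformed container: ratings missing for subject %d trial %d", s, tr)
      idx <- idx + 1
      trials[[idx]] <- new_trial_recording(
        s, tr, matrix(vals, n_ch, n_sa, byrow = TRUE), manifest$fs,
        c(row$valence, row$arousal, row$dominance, row$liking))
    }
    close(con)
    on.exit()
  }
  structure(list(trials = trials, n_subjects = manifest$n_subjects,
                 n_trials_per_subject = manifest$n_trials_per_subject,
                 seed = manifest$seed, effect_size = manifest$effect_size,
                 fs = manifest$fs),
            class = "physio_dataset")
}

# ---- Preprocessed per-subject adapter --------------------------------------
# Dialect for one subject of a preprocessed study export: a flat float64
# array of shape 40 trials x 40 channels x 8064 samples (C order) plus a
# 40 x 4 ratings CSV.

#' Write one subject in the preprocessed per-subject dialect
#'
#' @param dataset A `physio_dataset` containing the subject.
#' @param subject Subject id to export.
#' @param path Basename; writes `<path>.dat` (signals) and
#'   `<path>_ratings.csv`.
#' @return `path`, invisibly.
#' @export
write_subject_array <- function(dataset, subject, path) {
  trs <- Filter(function(tr) tr$subject_id == subject, dataset$trials)
  if (!length(trs)) stopf("subject %d not present in dataset", subject)
  con <- file(paste0(path, ".dat"), "wb")
  for (tr in trs)
    writeBin(as.numeric(t(tr$signal)), con, size = 8, endian = "little")
  close(con)
  r <- t(vapply(trs, function(tr) tr$ratings, numeric(4)))
  colnames(r) <- c("valence", "arousal", "dominance", "liking")
  utils::write.csv(as.data.frame(r), paste0(path, "_ratings.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read one subject in the preprocessed per-subject dialect
#'
#' @param path Basename used by [write_subject_array()].
#' @param subject Subject id to assign (default 1).
#' @param n_channels,n_samples Expected geometry (default 40 x 8064).
#' @param fs Sampling rate in Hz.
#' @return List of `trial_recording`s (one per trial).
#' @export
read_subject_array <- function(path, subject = 1, n_channels = 40,
                               n_samples = 8064, fs = 128) {
  dat <- paste0(path, ".dat")
  if (!file.exists(dat)) stopf("missing signal array '%s'", dat)
  rcsv <- paste0(path, "_ratings.csv")
  if (!file.exists(rcsv)) stopf("missing ratings table '%s'", rcsv)
  ratings <- as.matrix(utils::read.csv(rcsv))
  vals <- readBin(dat, "numeric", file.size(dat) / 8, size = 8,
                  endian = "little")
  per_trial <- n_channels * n_samples
  n_trials <- length(vals) / per_trial
  if (n_trials != round(n_trials) || n_trials != nrow(ratings))
    stopf("array size inconsistent with %d ratings rows", nrow(ratings))
  lapply(seq_len(n_trials), function(tr) {
    block <- vals[((tr - 1) * per_trial + 1):(tr * per_trial)]
    new_trial_recording(subject, tr,
                        matrix(block, n_channels, n_samples, byrow = TRUE),
                        fs, as.numeric(ratings[tr, ]))
  })
}
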