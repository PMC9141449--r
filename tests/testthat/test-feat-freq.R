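# Frequency-domain features: spectral estimators, bispectrum, coherence
# and asymmetry against constructions with known answers.

test_that("Welch PSD finds a tone, satisfies Parseval, averages 7 segments", {
  t <- (0:3839) / 128
  p <- welch_psd(sin(2 * pi * 10 * t), 128)
  expect_equal(p$freqs[which.max(p$power)], 10, tolerance = 128 / 853)
  expect_equal(p$n_segments, 7)

  df <- p$freqs[2] - p$freqs[1]
  for (i in 1:5) {
    x <- with_seed_test(200 + i, rnorm(3840))
    pw <- welch_psd(x, 128)
    expect_equal(sum(pw$power) * df, var(x), tolerance = 0.05)
  }
  expect_error(welch_psd(rnorm(500), 128), "length")
})

test_that("power-law index: flat, 1/f-shaped, and scale-invariant", {
  x <- with_seed_test(8, rnorm(3840))
  expect_equal(power_law_index(welch_psd(x, 128))$eta, 0, tolerance = 0.15)

  # shape white noise to a 1/f amplitude spectrum by inverse FFT
  one_over_f <- with_seed_test(9, {
    N <- 3840
    f <- (0:(N - 1)) * 128 / N
    fmir <- pmin(f, 128 - f)
    amp <- ifelse(fmir > 0, 1 / sqrt(fmir), 0)
    ph <- runif(N, 0, 2 * pi)
    Re(fft(amp * exp(1i * ph), inverse = TRUE))
  })
  expect_equal(power_law_index(welch_psd(one_over_f, 128))$eta, 1,
               tolerance = 0.2)

  expect_equal(power_law_index(welch_psd(x, 128))$eta,
               power_law_index(welch_psd(7 * x, 128))$eta, tolerance = 1e-10)
})

test_that("band power: tone location, equal-energy ratio, frame count", {
  t <- (0:3839) / 128
  bp <- band_power_features(sin(2 * pi * 10 * t), 128)
  la <- bp$per_band[, "log_avg"]
  expect_true(la[["alpha"]] > max(la[c("theta", "beta", "gamma")]))
  expect_equal(bp$n_frames, 30)

  bp2 <- band_power_features(sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t), 128)
  expect_equal(bp2$ratio_beta_alpha, 1, tolerance = 0.2)

  # per-band ordering invariant
  x <- with_seed_test(10, rnorm(3840))
  pb <- band_power_features(x, 128)$per_band
  expect_true(all(pb[, "log_max"] >= pb[, "log_avg"]))
  expect_true(all(pb[, "log_avg"] >= pb[, "log_min"]))
})

test_that("bispectrum is symmetric, sign-invariant in magnitude, localizes QPC", {
  x <- with_seed_test(11, rnorm(3840))
  b <- bispectrum_estimate(x)
  m <- Mod(b$B)
  expect_lt(max(abs(m - t(m))) / max(m), 1e-8)

  bneg <- bispectrum_estimate(-x)
  expect_equal(Mod(bneg$B), m, tolerance = 1e-10)

  bq <- bispectrum_estimate(qpc_signal(seed = 5))
  mq <- Mod(bq$B); mq[!bq$omega] <- 0
  peak <- which(mq == max(mq), arr.ind = TRUE)[1, ]
  expect_equal(sort(c(bq$freqs[peak[1]], bq$freqs[peak[2]])), c(10, 15))

  expect_error(bispectrum_estimate(rnorm(1000)), "length")
})

test_that("coupled tones raise the mean bispectral magnitude 10x over noise", {
  ratio <- vapply(1:3, function(i) {
    xn <- with_seed_test(300 + i, rnorm(3840))
    bq <- bispectrum_estimate(qpc_signal(seed = 400 + i))
    bn <- bispectrum_estimate(xn)
    mean(Mod(bq$B)[bq$omega]) / mean(Mod(bn$B)[bn$omega])
  }, numeric(1))
  expect_true(all(ratio >= 10))
})

test_that("bispectral summaries match direct transcription", {
  # uniform magnitude over the principal region: maximum entropy ln L
  b <- bispectrum_estimate(with_seed_test(12, rnorm(3840)))
  L <- sum(b$omega)
  bu <- b
  bu$B <- matrix(0i, 128, 128)
  bu$B[bu$omega] <- 1 + 0i
  s <- bispectral_summaries(bu)
  expect_equal(s$BE1, log(L))
  expect_equal(s$MMOB, L / L)

  bp <- b
  bp$B <- matrix(0i, 128, 128)
  bp$B[which(bp$omega)[3]] <- 2 + 0i
  s <- bispectral_summaries(bp)
  expect_equal(s$BE1, 0)
  expect_equal(s$BE2, 0)

  s <- bispectral_summaries(b)
  mag <- Mod(b$B)[b$omega]
  pn <- mag / sum(mag); qn <- mag^2 / sum(mag^2)
  expect_equal(s$BE1, -sum(pn[pn > 0] * log(pn[pn > 0])))
  expect_equal(s$BE2, -sum(qn[qn > 0] * log(qn[qn > 0])))
  expect_equal(s$MMOB, mean(mag))
  allm <- Mod(b$B)
  expect_equal(s$FOSM, sum(log(allm[allm > 0])))
})

test_that("coherence: self-coherence 1, bounded, symmetric, low for noise", {
  tr <- full_trial()
  tr <- trim_stimulus_segment(tr)
  tr$signal[2, ] <- tr$signal[1, ]  # identical pair
  res <- msce_features(tr, pairs = cbind(1, 2))
  expect_equal(max(abs(res$coherence[[1]] - 1)), 0, tolerance = 1e-6)

  noise <- with_seed_test(13, matrix(rnorm(2 * 3840), 2))
  trn <- tr; trn$signal[1:2, ] <- noise
  resn <- msce_features(trn, pairs = cbind(1, 2))
  expect_true(all(resn$band_coherence < 0.5))
  expect_true(all(resn$coherence[[1]] >= 0 & resn$coherence[[1]] <= 1))

  # symmetry in the pair
  r12 <- msce_features(trn, pairs = cbind(1, 2))$band_coherence
  r21 <- msce_features(trn, pairs = cbind(2, 1))$band_coherence
  expect_equal(r12, r21)

  expect_error(msce_features(tr, pairs = cbind(3, 3)), "distinct")
})

test_that("asymmetry features: symmetric input, amplitude ratio, counts", {
  tr <- trim_stimulus_segment(full_trial())
  pr <- symmetric_pairs()
  trs <- tr
  for (p in seq_len(nrow(pr))) trs$signal[pr[p, 2], ] <- trs$signal[pr[p, 1], ]
  af <- asymmetry_features(trs, pr)
  expect_equal(max(abs(af$dasm)), 0)
  expect_equal(max(abs(af$rasm - 1)), 0)
  expect_equal(length(af$dasm), 56)
  expect_equal(length(af$rasm), 56)

  tr2 <- tr
  tr2$signal[pr[1, 1], ] <- sqrt(2) * tr2$signal[pr[1, 2], ]
  af2 <- asymmetry_features(tr2, pr)
  expect_equal(unname(af2$rasm[1, ]), rep(2, 4), tolerance = 0.05)
})

test_that("PSD is invariant to time reversal", {
  # length chosen so the 7 segments tile the signal exactly; reversal then
  # maps the segment set onto itself and per-segment magnitudes are equal
  x <- with_seed_test(14, rnorm(853 + 6 * 427))
  p1 <- welch_psd(x, 128)$power
  p2 <- welch_psd(rev(x), 128)$power
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("band features stay finite across the effect-size range", {
  for (es in c(0, 1, 2)) {
    ds <- trim_dataset(generate_dataset(1, 2, seed = 77, effect_size = es,
                                        n_samples = 4096))
    for (tr in ds$trials) {
      for (ch in c(1, 16, 32)) {
        bp <- band_power_features(tr$signal[ch, ], 128)
        expect_true(all(is.finite(bp$per_band)))
        expect_true(is.finite(bp$ratio_beta_alpha))
      }
    }
  }
})
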