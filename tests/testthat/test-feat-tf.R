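# Time-frequency features: sifting decomposition, Hilbert spectrum and
# db4 wavelet features.

test_that("sifting is complete and orders components high-frequency first", {
  t <- (0:3839) / 128
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 40 * t)
  e <- emd_decompose(x)
  recon <- Reduce(`+`, e$imfs) + e$residue
  expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)
  expect_true(length(e$imfs) >= 2 && length(e$imfs) <= 10)

  domfreq <- function(v) {
    p <- Mod(fft(v))[1:1920]
    ((0:1919) * 128 / 3840)[which.max(p)]
  }
  expect_equal(domfreq(e$imfs[[1]]), 40, tolerance = 1)
  expect_equal(domfreq(e$imfs[[2]]), 5, tolerance = 1)

  # a pure tone is essentially a single mode
  e2 <- emd_decompose(sin(2 * pi * 10 * t))
  en <- vapply(e2$imfs, function(v) sum(v^2), numeric(1))
  expect_gt(en[1] / (sum(en) + sum(e2$residue^2)), 0.95)
})

test_that("completeness holds for arbitrary signals in both extrema modes", {
  for (i in 1:3) {
    x <- with_seed_test(500 + i,
                        as.numeric(stats::filter(rnorm(3840), 0.9,
                                                 method = "recursive")))
    for (mode in c("all", "segment")) {
      e <- suppressWarnings(emd_decompose(x, extrema = mode))
      recon <- Reduce(`+`, e$imfs) + e$residue
      expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-6)
      expect_lte(length(e$imfs), 10)
    }
  }
})

test_that("Hilbert spectrum recovers tone amplitude and frequency", {
  t <- (0:3839) / 128
  hs <- hilbert_spectrum(list(cos(2 * pi * 10 * t)), 128)
  mid <- 200:3600
  expect_equal(sqrt(hs$energy[1, mid]), rep(1, length(mid)), tolerance = 0.02)
  expect_equal(hs$frequency[1, mid], rep(10, length(mid)), tolerance = 0.5)
  expect_length(hs$band_energy, 4)
  expect_gt(hs$band_energy[["alpha"]], 0.9)

  hs0 <- hilbert_spectrum(list(numeric(512)), 128)
  expect_equal(max(hs0$energy), 0)

  # energy is conserved between the analytic and spectral views
  x <- with_seed_test(15, rnorm(1024))
  e <- emd_decompose(x, seg_len = 64)
  hs2 <- hilbert_spectrum(e, 128)
  direct <- sum(vapply(e$imfs, function(v)
    sum(Mod(affectsda:::analytic_signal(v))^2), numeric(1)))
  expect_equal(sum(hs2$energy), direct)

  expect_error(hilbert_spectrum(list(), 128), "empty")
})

test_that("db4 transform reconstructs perfectly and partitions energy", {
  for (i in 1:100) {
    n <- sample(c(256, 512, 3840), 1)
    x <- with_seed_test(600 + i, rnorm(n))
    co <- dwt_db4(x)
    expect_lt(max(abs(idwt_db4(co) - x)) / max(abs(x)), 1e-8)
  }
  x <- with_seed_test(16, rnorm(3840))
  f <- dwt_features(x)
  expect_equal(sum(f$ree), 1, tolerance = 1e-9)
})

test_that("a 10 Hz tone concentrates in the alpha-band detail level", {
  t <- (0:3839) / 128
  f <- dwt_features(sin(2 * pi * 10 * t))
  rms <- f$features[, "rms"]
  expect_equal(names(which.max(rms)), "alpha")
})

test_that("band energies match a brute-force filter-cascade oracle", {
  # oracle: circulant-matrix filtering + explicit decimation, one level at
  # a time, written independently of the production pyramid
  brute_step <- function(x, h) {
    N <- length(x)
    y <- numeric(N / 2)
    for (i in seq_len(N / 2)) {
      acc <- 0
      for (k in seq_along(h))
        acc <- acc + h[k] * x[(2 * (i - 1) + k - 1) %% N + 1]
      y[i] <- acc
    }
    y
  }
  lo <- affectsda:::DB4_DEC_LO; hi <- affectsda:::DB4_DEC_HI
  x <- with_seed_test(17, rnorm(512))
  a <- x; details <- list()
  for (lev in 1:4) {
    d <- brute_step(a, hi)
    a <- brute_step(a, lo)
    details[[lev]] <- d
  }
  co <- dwt_db4(x)
  for (lev in 1:4) {
    nm <- paste0("D", lev)
    expect_equal(sum(co[[nm]]^2), sum(details[[lev]]^2), tolerance = 0.01)
  }
  expect_equal(sum(co$A4^2), sum(a^2), tolerance = 0.01)
})

test_that("degenerate and malformed wavelet inputs are rejected", {
  expect_error(dwt_features(numeric(512)), "degenerate")
  expect_error(dwt_db4(rnorm(100)), "multiple of 16")
})
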