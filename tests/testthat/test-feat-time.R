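# Time-domain features: hand-computed values, closed forms and brute-force
# oracles.

test_that("time statistics match hand evaluation and a brute-force oracle", {
  s <- time_stats(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 0)
  expect_equal(s$power, 25)
  expect_equal(s$first_diff, 0)
  expect_equal(s$norm_first_diff, 0)

  s <- time_stats(c(0, 1, 0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$power, 0.5)
  expect_equal(s$first_diff, 1)
  expect_equal(s$sd, sqrt(1 / 3))
  expect_equal(s$norm_first_diff, sqrt(3))

  # independent transcription of the defining sums
  x <- with_seed_test(1, rnorm(100))
  T <- 100
  mu <- sum(x) / T
  sdv <- sqrt(sum((x - mu)^2) / (T - 1))
  d1 <- 0; for (t in 1:(T - 1)) d1 <- d1 + abs(x[t + 1] - x[t])
  d1 <- d1 / (T - 1)
  d2 <- 0; for (t in 1:(T - 2)) d2 <- d2 + abs(x[t + 2] - x[t])
  d2 <- d2 / (T - 2)
  s <- time_stats(x)
  expect_equal(s$power, sum(x^2) / T)
  expect_equal(s$mean, mu)
  expect_equal(s$sd, sdv)
  expect_equal(s$first_diff, d1)
  expect_equal(s$norm_first_diff, d1 / sdv)
  expect_equal(s$second_diff, d2)
  expect_equal(s$norm_second_diff, d2 / sdv)

  expect_error(time_stats(c(1, 2)), "too short")
})

test_that("Hjorth parameters: scale invariance and sinusoid closed forms", {
  x <- with_seed_test(2, rnorm(500))
  h1 <- hjorth(x)
  h2 <- hjorth(3.7 * x)
  expect_equal(h1$mobility, h2$mobility)
  expect_equal(h1$complexity, h2$complexity)
  expect_equal(h2$activity, 3.7^2 * h1$activity)

  # discrete differencing of sin(2 pi f t / fs) scales the std by
  # 2 sin(pi f / fs), so mobility has that closed form
  t <- 0:3839
  x <- sin(2 * pi * 8 * t / 128)
  h <- hjorth(x)
  expect_equal(h$mobility, 2 * sin(pi * 8 / 128), tolerance = 0.01)
  expect_equal(h$complexity, 1, tolerance = 0.02)

  expect_error(hjorth(rep(2, 10)), "degenerate")
})

test_that("non-stationary index equals the segment-mean variance oracle", {
  expect_equal(nsi(rep(1, 320))$value, 0)

  # staircase: the signal is its own segment-mean sequence
  levels <- c(-2, 0, 1, 5)
  x <- rep(levels, each = 80)
  z <- (x - mean(x)) / sd(x)
  expect_equal(nsi(x, 4)$value, var((unique(z))))

  x <- with_seed_test(3, rnorm(3840))
  res <- nsi(x, 32)
  z <- (x - mean(x)) / sd(x)
  oracle <- var(colMeans(matrix(z, 120, 32)))
  expect_equal(res$value, oracle)
  expect_length(res$local_means, 32)

  expect_error(nsi(x, 1), "n_segments")
})

test_that("Higuchi dimension: line, white noise, affine invariance", {
  line <- higuchi_fd(as.numeric(1:2000))
  expect_equal(line$dimension, 1, tolerance = 0.05)

  dims <- vapply(1:5, function(i)
    higuchi_fd(with_seed_test(100 + i, rnorm(3840)))$dimension, numeric(1))
  expect_true(all(abs(dims - 2) < 0.15))

  x <- with_seed_test(4, cumsum(rnorm(1000)))
  expect_equal(higuchi_fd(x)$dimension, higuchi_fd(5 * x - 3)$dimension,
               tolerance = 1e-8)

  expect_error(higuchi_fd(rnorm(10), kmax = 8), "too short")
})

test_that("higher-order crossings count strict sign changes per order", {
  x <- rep(c(1, -1), 50)
  expect_equal(hoc_features(x)[1], 99)

  expect_equal(hoc_features(numeric(50)), rep(0L, 10))

  x <- with_seed_test(5, sample(c(-1, 1), 200, replace = TRUE))
  d1 <- 0
  y <- x - mean(x)
  s <- sign(y); s <- s[s != 0]
  for (i in 2:length(s)) if (s[i] != s[i - 1]) d1 <- d1 + 1
  expect_equal(hoc_features(x)[1], d1)
  expect_length(hoc_features(x), 10)

  expect_error(hoc_features(rnorm(5), max_order = 10), "too short")
})

test_that("symmetric statistics are invariant to time reversal", {
  x <- with_seed_test(6, rnorm(3200))
  xr <- rev(x)
  expect_equal(time_stats(x)$power, time_stats(xr)$power)
  expect_equal(time_stats(x)$sd, time_stats(xr)$sd)
  expect_equal(hjorth(x)$activity, hjorth(xr)$activity)
  expect_equal(nsi(x, 32)$value, nsi(xr, 32)$value, tolerance = 1e-12)
})

test_that("statistics of a z-normalized signal are exactly standardized", {
  x <- with_seed_test(7, rnorm(1000, mean = 3, sd = 10))
  z <- (x - mean(x)) / sd(x)
  s <- time_stats(z)
  expect_equal(s$mean, 0, tolerance = 1e-10)
  expect_equal(s$sd, 1, tolerance = 1e-10)
})
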