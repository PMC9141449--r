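# Feature selection: variance filter, univariate scorers against textbook
# oracles, top-k unions and the greedy forward wrapper.

make_table <- function(values, family = "unknown") feature_table(values, family = family)

test_that("the variance filter removes strictly-below-threshold features", {
  v <- cbind(const = rep(2, 50),
             tiny = with_seed_test(20, rnorm(50, sd = 0.01)),
             wide = with_seed_test(21, rnorm(50, sd = 2)))
  res <- rflv(make_table(v), threshold = 0.01)
  expect_false(res$mask[1])
  expect_false(res$mask[2])
  expect_true(res$mask[3])

  # boundary: variance exactly equal to the threshold is kept
  thr <- var(v[, "tiny"])
  expect_true(rflv(make_table(v), threshold = thr)$mask[2])

  # brute-force variance scan agrees on a random table
  m <- with_seed_test(22, matrix(rnorm(600, sd = rep(c(0.05, 1), each = 300)),
                                 30, 20))
  res <- rflv(make_table(m), 0.01)
  oracle <- vapply(seq_len(20), function(j) {
    mu <- mean(m[, j]); sum((m[, j] - mu)^2) / (nrow(m) - 1)
  }, numeric(1)) >= 0.01
  expect_equal(unname(res$mask), unname(oracle))

  # idempotence
  kept <- subset_features(make_table(m), res$mask)
  expect_true(all(rflv(kept, 0.01)$mask))
})

test_that("all scorers rank a label-identical feature first", {
  y <- rep(c(0, 1), 100)
  v <- cbind(with_seed_test(23, matrix(rnorm(200 * 5), 200)), exact = y)
  tab <- make_table(v)
  for (m in c("chi2", "mutual_info", "fisher")) {
    r <- score_features(tab, y, m)
    expect_equal(r$ranking[1], 6)
  }
  expect_error(score_features(tab, rep(1, 200), "chi2"), "single class")
})

test_that("chi-square equals the hand-computed contingency statistic", {
  y <- c(rep(0, 60), rep(1, 40))
  x <- with_seed_test(24, rbinom(100, 1, ifelse(y == 1, 0.7, 0.3)))
  s <- score_features(make_table(cbind(f = x)), y, "chi2")$scores
  tab <- table(x, y)
  oracle <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / sum(tab)
    oracle <- oracle + (tab[i, j] - e)^2 / e
  }
  expect_equal(unname(s), oracle)
})

test_that("mutual information is near zero for independent features", {
  y <- with_seed_test(25, rbinom(2000, 1, 0.5))
  x <- with_seed_test(26, rnorm(2000))
  s <- score_features(make_table(cbind(f = x)), y, "mutual_info")$scores
  expect_lt(s[[1]], 0.02)
  # and recovers dependence
  x2 <- y + with_seed_test(27, rnorm(2000, sd = 0.5))
  s2 <- score_features(make_table(cbind(f = x2)), y, "mutual_info")$scores
  expect_gt(s2[[1]], 0.2)
})

test_that("scorers follow their features under column permutation", {
  y <- rep(c(0, 1), 50)
  m <- with_seed_test(28, matrix(rnorm(100 * 6), 100))
  m[, 3] <- y + rnorm(100, sd = 0.3)
  perm <- c(5, 3, 1, 6, 2, 4)
  for (meth in c("chi2", "mutual_info", "fisher")) {
    s1 <- score_features(feature_table(m, paste0("f", 1:6)), y, meth)$scores
    s2 <- score_features(feature_table(m[, perm], paste0("f", perm)), y,
                         meth)$scores
    expect_equal(unname(s2), unname(s1[perm]))
  }
})

test_that("top-k union obeys set arithmetic and commutes", {
  n <- 500
  mk <- function(scores) affectsda:::selection_result(
    scores, rep(TRUE, n), "x", paste0("f", 1:n))
  s <- runif(n)
  expect_equal(sum(union_topk(mk(s), mk(s), k = 200)$mask), 200)

  s2 <- s; s2[order(s, decreasing = TRUE)] <- sort(s)  # reversed ranking
  a <- mk(s); b <- mk(s2)
  expect_equal(sum(union_topk(a, b, k = 200)$mask), 400)

  # construct 50-feature overlap between the two top-200 sets
  sa <- numeric(n); sb <- numeric(n)
  sa[1:200] <- 2; sb[151:350] <- 2
  u <- union_topk(mk(sa), mk(sb), k = 200)
  expect_equal(sum(u$mask), 2 * 200 - 50)

  expect_equal(union_topk(a, b, 100)$mask, union_topk(b, a, 100)$mask)
  bad <- affectsda:::selection_result(s, rep(TRUE, n), "x", paste0("g", 1:n))
  expect_error(union_topk(a, bad), "different feature sets")
})

test_that("the forward wrapper finds separating structure and terminates", {
  # one perfect feature among noise
  y <- rep(c(0, 1), each = 30)
  v <- with_seed_test(29, cbind(matrix(rnorm(60 * 4), 60),
                                sep = y * 2 - 1 + rnorm(60, sd = 0.05)))
  res <- forward_wrapper(make_table(v), y, "lda", folds = 5, seed = 3)
  expect_equal(res$selected[1], 5)
  expect_equal(res$cv_accuracy, 1)

  # pure noise: terminates with at most 2 features
  vn <- with_seed_test(30, matrix(rnorm(60 * 6), 60))
  resn <- forward_wrapper(make_table(vn), y, "lda", folds = 5, seed = 3)
  expect_lte(length(resn$selected), 2)

  # XOR pair: neither feature is informative alone, both needed
  xor_y <- with_seed_test(31, {
    a <- rbinom(200, 1, 0.5); b <- rbinom(200, 1, 0.5)
    list(x = cbind(a = a + rnorm(200, sd = 0.05),
                   b = b + rnorm(200, sd = 0.05)),
         y = as.integer(xor(a, b)))
  })
  resx <- forward_wrapper(make_table(xor_y$x), xor_y$y, "dt", folds = 5,
                          seed = 3)
  expect_setequal(resx$selected, c(1, 2))
  expect_gt(resx$cv_accuracy, 0.9)

  expect_error(forward_wrapper(make_table(vn), y, "lda", folds = 100),
               "folds")
})

test_that("median imputation fills missing values and respects given medians", {
  v <- cbind(a = c(1, NA, 3, 5), b = c(NA, 2, 2, 2))
  imp <- impute_missing(make_table(v))
  expect_false(anyNA(imp$table$values))
  expect_equal(unname(imp$table$values[2, "a"]), 3)
  imp2 <- impute_missing(make_table(v), medians = c(a = 10, b = 20))
  expect_equal(unname(imp2$table$values[1, "b"]), 20)
})

test_that("selection results serialize to a readable CSV", {
  m <- with_seed_test(60, matrix(rnorm(40 * 6), 40))
  tab <- feature_table(m, paste0("f", 1:6), family = "stats")
  res <- rflv(tab, 0.5)
  path <- file.path(tempdir(), "sel.csv")
  write_selection(res, tab, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$name, paste0("f", 1:6))
  expect_equal(back$kept, unname(res$mask))
})
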