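# Denoising autoencoders, stacking, RBM and the reference baselines, on
# small synthetic problems with known answers.

test_that("corruption zeroes exactly round(q d) coordinates, others intact", {
  x <- with_seed_test(40, rnorm(100)) + 10
  expect_identical(corrupt_input(x, 0, seed = 1), x)
  expect_equal(corrupt_input(x, 1, seed = 1), numeric(100))
  for (q in c(0.1, 0.2, 0.33)) {
    for (d in c(50, 100, 3840)) {
      xx <- rep(1, d)
      xc <- corrupt_input(xx, q, seed = 7)
      expect_equal(sum(xc == 0), round(q * d))
      expect_true(all(xc[xc != 0] == 1))
    }
  }
  # deterministic under the seed
  expect_identical(corrupt_input(x, 0.2, seed = 3), corrupt_input(x, 0.2, seed = 3))
})

test_that("an uncorrupted full-width code can represent the identity", {
  X <- with_seed_test(41, matrix(rnorm(200 * 10), 200))
  layer <- dae_layer(10, 10, corruption = 0, activation = "linear", seed = 2)
  layer <- dae_pretrain_layer(layer, X, epochs = 300, seed = 2, lr = 5e-3)
  expect_lt(tail(layer$loss_trace, 1), 1e-3 * mean(apply(X, 2, var)))
})

test_that("pre-training is deterministic and its smoothed loss non-increasing", {
  X <- with_seed_test(42, matrix(rnorm(256 * 20), 256))
  l1 <- dae_pretrain_layer(dae_layer(20, 8, seed = 5), X, epochs = 60, seed = 9)
  l2 <- dae_pretrain_layer(dae_layer(20, 8, seed = 5), X, epochs = 60, seed = 9)
  expect_identical(l1$loss_trace, l2$loss_trace)
  expect_identical(l1$W, l2$W)
  sm <- stats::filter(l1$loss_trace, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-4))
})

test_that("a one-layer stack reduces to single-layer pre-training", {
  X <- with_seed_test(43, matrix(rnorm(128 * 12), 128))
  st <- sda_stack(c(12, 5), seed = 4)
  st <- sda_pretrain(st, X, epochs_per_layer = 15, seed = 21)
  single <- dae_pretrain_layer(dae_layer(12, 5, seed = affectsda:::derive_seed(4, 1)),
                               X, 15, seed = affectsda:::derive_seed(21, 1))
  expect_equal(st$layers[[1]]$W, single$W)
  codes <- encode_features(st, X)
  expect_equal(ncol(codes$values), 5)
})

test_that("fine-tuning under a bare cross-entropy loss matches a hand check", {
  X <- with_seed_test(44, matrix(rnorm(4 * 6), 4))
  y <- c(0, 1, 0, 1)
  st <- sda_stack(c(6, 3), seed = 8)
  bare <- loss_spec(lambda0 = 1, lambda1 = 0, lambda2 = 0, lambda3 = 0)
  # lr = 0 leaves parameters untouched, so the recorded loss is the plain
  # cross-entropy of the initial network, computable independently
  st0 <- fine_tune(st, X, y, loss = bare, epochs = 1, seed = 1, lr = 0)
  P <- affectsda:::sda_forward_full(st, X)$prob
  ce <- -mean(log(P[cbind(1:4, y + 1)]))
  expect_equal(st0$fine_tune_trace$loss[1], ce)
  expect_error(fine_tune(st, X, c(0, 1), epochs = 1), "mismatch")
})

test_that("the cost term vanishes when all predictions are correct", {
  # strongly separated 2-class Gaussians: training converges to zero error,
  # after which the recorded loss equals CE + weight penalties exactly
  d <- 8
  X <- with_seed_test(45, rbind(matrix(rnorm(200 * d, -2), 200),
                                matrix(rnorm(200 * d, 2), 200)))
  y <- rep(c(0, 1), each = 200)
  st <- sda_stack(c(d, 4), seed = 6)
  ls <- loss_spec(lambda3 = 0.7)
  st <- fine_tune(st, X, y, loss = ls, epochs = 30, seed = 2, lr = 1e-2)
  tr <- tail(st$fine_tune_trace, 1)
  expect_equal(tr$train_accuracy, 1)
  P <- sda_predict(st, X)
  pen <- affectsda:::sda_penalties(st)
  expect_equal(tr$loss,
               -mean(log(P[cbind(seq_along(y), y + 1)])) +
                 ls$lambda1 * pen[["l1"]] + ls$lambda2 * pen[["l2"]])
})

test_that("pretraining plus fine-tuning separates an easy held-out problem", {
  d <- 10
  mk <- function(seed, n) with_seed_test(seed, {
    y <- rbinom(n, 1, 0.5)
    x <- matrix(rnorm(n * d), n) + outer(y * 4 - 2, rep(1, d))
    list(x = x, y = y)
  })
  tr <- mk(46, 300); te <- mk(47, 150)
  st <- sda_stack(c(d, 6, 3), seed = 9)
  st <- sda_pretrain(st, tr$x, epochs_per_layer = 30, seed = 9)
  st <- fine_tune(st, tr$x, tr$y, epochs = 40, seed = 9, lr = 1e-2)
  pred <- max.col(sda_predict(st, te$x)) - 1
  expect_gt(mean(pred == te$y), 0.9)

  # codes are deterministic and shaped by the top width
  codes1 <- encode_features(st, te$x)
  codes2 <- encode_features(st, te$x)
  expect_identical(codes1$values, codes2$values)
  expect_equal(ncol(codes1$values), 3)
  expect_error(encode_features(sda_stack(c(d, 3)), te$x), "untrained")
})

test_that("RBM: hidden probabilities, energy transcription, learning trend", {
  rbm <- rbm_layer(6, 4, seed = 3)
  rbm$W[] <- 0
  rbm$b <- c(-1, 0, 0.5, 2)
  V <- matrix(rbinom(30, 1, 0.5), 5)
  expect_equal(rbm_hidden_prob(rbm, V),
               matrix(rep(1 / (1 + exp(-rbm$b)), each = 5), 5))

  # energy on a 3-visible / 2-hidden configuration, by direct transcription
  r2 <- rbm_layer(3, 2, seed = 4)
  v <- c(1, 0, 1); h <- c(1, 1)
  oracle <- 0
  for (i in 1:3) for (j in 1:2) oracle <- oracle - v[i] * r2$W[i, j] * h[j]
  oracle <- oracle - sum(r2$b * h) - sum(r2$c * v)
  expect_equal(rbm_energy(r2, v, h), oracle)

  # reconstruction error decreases on structured binary data
  X <- with_seed_test(48, {
    proto <- matrix(rbinom(3 * 12, 1, 0.5), 3)
    flips <- matrix(rbinom(240 * 12, 1, 0.05), 240)
    abs(proto[sample(1:3, 240, TRUE), ] - flips)
  })
  r3 <- rbm_train(rbm_layer(12, 6, seed = 5), X, epochs = 50, lr = 0.1, seed = 5)
  sm <- stats::filter(r3$error_trace, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(tail(sm, 1), sm[1])

  # CD update is deterministic under the seed
  u1 <- rbm_cd_update(r2, matrix(c(1, 0, 1), 1), lr = 0.1, seed = 11)
  u2 <- rbm_cd_update(r2, matrix(c(1, 0, 1), 1), lr = 0.1, seed = 11)
  expect_identical(u1$W, u2$W)
})

test_that("baseline architectures have the stated shapes", {
  dnn <- build_baseline("dnn")
  expect_equal(dnn$widths, c(3840, 800, 200, 20, 2))
  expect_equal(vapply(dnn$layers, `[[`, numeric(1), "dropout"),
               c(0.45, 0.5, 0.25))

  cnn <- build_baseline("cnn")
  expect_equal(cnn$image, c(60, 64))
  X <- with_seed_test(49, matrix(rnorm(3 * 3840), 3))
  out <- predict_baseline(cnn, X)  # untrained forward pass: shape contract
  expect_equal(dim(out$prob), c(3, 2))
  expect_equal(rowSums(out$prob), rep(1, 3))
  out2 <- predict_baseline(dnn, X)
  expect_equal(dim(out2$prob), c(3, 2))

  expect_error(build_baseline("dnn", input_dim = 100), "3840")
})

test_that("both discriminative baselines beat chance on strong effects", {
  a <- augmented_study(2)
  x_tr <- a$x[!a$test, , drop = FALSE]; y_tr <- a$y[!a$test]
  x_te <- a$x[a$test, , drop = FALSE]; y_te <- a$y[a$test]
  dnn <- train_baseline(build_baseline("dnn", seed = 5), x_tr, y_tr,
                        epochs = 10, seed = 5)
  expect_gt(mean(predict_baseline(dnn, x_te)$class == y_te), 0.6)
  cnn <- train_baseline(build_baseline("cnn", seed = 5), x_tr, y_tr,
                        epochs = 10, seed = 5)
  expect_gt(mean(predict_baseline(cnn, x_te)$class == y_te), 0.6)
})

test_that("the deeper stack fine-tunes to no worse a final loss", {
  # 3840-1000-200-40-2 versus 3840-1000-200-2 on the same data and seeds
  a <- augmented_study(1)
  idx <- which(!a$test)[1:320]
  x <- a$x[idx, , drop = FALSE]; y <- a$y[idx]
  final_loss <- function(dims) {
    st <- sda_stack(dims, seed = 71)
    st <- sda_pretrain(st, x, epochs_per_layer = 10, seed = 71)
    st <- fine_tune(st, x, y, epochs = 10, seed = 71)
    tail(st$fine_tune_trace$loss, 1)
  }
  expect_lte(final_loss(c(3840, 1000, 200, 40)),
             final_loss(c(3840, 1000, 200)) + 1e-9)
})

test_that("training is bit-reproducible under a fixed seed", {
  X <- with_seed_test(61, matrix(rnorm(96 * 15), 96))
  y <- rep(c(0, 1), 48)
  run <- function() {
    st <- sda_stack(c(15, 8, 4), seed = 13)
    st <- sda_pretrain(st, X, epochs_per_layer = 5, seed = 13)
    st <- fine_tune(st, X, y, epochs = 5, seed = 13)
    encode_features(st, X)$values
  }
  expect_identical(run(), run())
})
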