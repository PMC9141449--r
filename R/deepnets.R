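# Denoising autoencoders, their greedy stacking with supervised
# fine-tuning, and the restricted Boltzmann machine reference.

#' Corrupt an input vector by zero-masking
#'
#' Exactly `round(q * d)` positions, chosen uniformly at random under
#' `seed`, are set to zero; all other coordinates are untouched. Using a
#' fixed count (rather than i.i.d. masking) makes the corruption volume
#' deterministic.
#'
#' @param x Numeric vector.
#' @param q Corruption proportion in \[0, 1\] (0.2 in the reference
#'   configuration).
#' @param seed Integer seed.
#' @return The corrupted vector.
#' @export
corrupt_input <- function(x, q, seed) {
  if (q < 0 || q > 1) stopf("`q` must be in [0, 1]")
  k <- round(q * length(x))
  if (k == 0) return(x)
  idx <- with_seed(seed, sample.int(length(x), k))
  x[idx] <- 0
  x
}

# Matrix version: every row corrupted with its own derived seed.
corrupt_rows <- function(m, q, seed) {
  if (q <= 0) return(m)
  k <- round(q * ncol(m))
  if (k == 0) return(m)
  with_seed(seed, {
    for (i in seq_len(nrow(m))) m[i, sample.int(ncol(m), k)] <- 0
  })
  m
}

#' Create a denoising-autoencoder layer
#'
#' Encoder h = sf(W x~ + b) over the corrupted input x~, linear decoder
#' z = W' h + b' with untied weights, trained to reconstruct the clean
#' input under squared error.
#'
#' @param d Input dimension.
#' @param d_hidden Code dimension.
#' @param corruption Zero-masking proportion q (default 0.2).
#' @param activation Encoder activation: "sigmoid" (default) or "linear".
#' @param seed Seed for weight initialization.
#' @return A `dae_layer`.
#' @export
dae_layer <- function(d, d_hidden, corruption = 0.2,
                      activation = c("sigmoid", "linear"), seed = 1) {
  activation <- match.arg(activation)
  structure(list(
    W = xavier_init(d_hidden, d, derive_seed(seed, 1)),
    b = numeric(d_hidden),
    Wp = xavier_init(d, d_hidden, derive_seed(seed, 2)),
    bp = numeric(d),
    d = d, d_hidden = d_hidden, corruption = corruption,
    activation = activation, trained = FALSE, loss_trace = numeric()),
    class = "dae_layer")
}

dae_encode <- function(layer, X) {
  a <- X %*% t(layer$W) + matrix(layer$b, nrow(X), layer$d_hidden, byrow = TRUE)
  if (layer$activation == "sigmoid") sigmoid(a) else a
}

dae_decode <- function(layer, H) {
  H %*% t(layer$Wp) + matrix(layer$bp, nrow(H), layer$d, byrow = TRUE)
}

#' Pre-train one denoising-autoencoder layer
#'
#' Mini-batch Adam on the mean squared reconstruction error between the
#' clean input and the decode of the encoded corrupted input. The
#' per-epoch training loss is recorded in `loss_trace`.
#'
#' @param layer A `dae_layer`.
#' @param X Numeric matrix, instances x d.
#' @param epochs Training epochs.
#' @param seed Seed controlling batching and corruption (same seed, same
#'   data: identical loss trace).
#' @param lr Learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 128).
#' @return The trained `dae_layer`.
#' @export
dae_pretrain_layer <- function(layer, X, epochs, seed = 1, lr = 1e-3,
                               batch_size = 128) {
  if (ncol(X) != layer$d) stopf("input dimension %d != layer dimension %d",
                                ncol(X), layer$d)
  st <- list(W = adam_state(layer$W), b = adam_state(layer$b),
             Wp = adam_state(layer$Wp), bp = adam_state(layer$bp))
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      Xc <- corrupt_rows(Xb, layer$corruption, derive_seed(seed, ep, start))
      H <- dae_encode(layer, Xc)
      Z <- dae_decode(layer, H)
      err <- Z - Xb
      loss <- mean(err^2)
      if (!is.finite(loss)) stopf("training diverged (NaN loss) at epoch %d", ep)
      ep_loss <- ep_loss + loss; nb <- nb + 1
      m <- length(err)
      dZ <- 2 * err / m
      dWp <- t(dZ) %*% H
      dbp <- colSums(dZ)
      dH <- dZ %*% layer$Wp
      dA <- if (layer$activation == "sigmoid") dH * H * (1 - H) else dH
      dW <- t(dA) %*% Xc
      db <- colSums(dA)
      for (p in c("W", "b", "Wp", "bp")) {
        g <- switch(p, W = dW, b = db, Wp = dWp, bp = dbp)
        u <- adam_update(layer[[p]], g, st[[p]], lr)
        layer[[p]] <- u$param; st[[p]] <- u$state
      }
    }
    layer$loss_trace <- c(layer$loss_trace, ep_loss / nb)
  }
  layer$trained <- TRUE
  layer
}

#' Create a stacked denoising autoencoder
#'
#' @param dims Layer widths from input to top code, e.g.
#'   `c(3840, 1000, 200, 40)` (the reference architecture, with a 2-way
#'   head making it 3840-1000-200-40-2).
#' @param n_classes Output classes of the supervised head (default 2).
#' @param corruption Zero-masking proportion applied at each layer's input
#'   during pre-training (default 0.2).
#' @param seed Seed for weight initialization.
#' @return An `sda_stack`.
#' @export
sda_stack <- function(dims = c(3840, 1000, 200, 40), n_classes = 2,
                      corruption = 0.2, seed = 1) {
  if (length(dims) < 2) stopf("`dims` needs an input and at least one hidden width")
  layers <- lapply(seq_len(length(dims) - 1), function(i)
    dae_layer(dims[i], dims[i + 1], corruption, seed = derive_seed(seed, i)))
  structure(list(
    layers = layers, dims = dims, n_classes = n_classes,
    head = list(W = xavier_init(n_classes, dims[length(dims)],
                                derive_seed(seed, 99)),
                b = numeric(n_classes)),
    pretrained = FALSE, fine_tuned = FALSE,
    fine_tune_trace = NULL),
    class = "sda_stack")
}

#' @export
print.sda_stack <- function(x, ...) {
  cat(sprintf("<sda_stack> %s-%d (pretrained: %s, fine-tuned: %s)\n",
              paste(x$dims, collapse = "-"), x$n_classes,
              x$pretrained, x$fine_tuned))
  invisible(x)
}

sda_encode <- function(stack, X) {
  for (l in stack$layers) X <- dae_encode(l, X)
  X
}

#' Stack reconstruction error
#'
#' Encodes through every layer and decodes back down through the linear
#' decoders; returns the mean squared error against the input. This is the
#' quantity whose trajectory distinguishes pre-trained from randomly
#' initialized stacks at the start of fine-tuning.
#'
#' @param stack An `sda_stack`.
#' @param X Numeric matrix.
#' @return Mean squared reconstruction error (scalar).
#' @export
sda_reconstruction_error <- function(stack, X) {
  H <- X
  codes <- list()
  for (l in stack$layers) { H <- dae_encode(l, H); codes[[length(codes) + 1]] <- H }
  Z <- H
  for (i in rev(seq_along(stack$layers))) Z <- dae_decode(stack$layers[[i]], Z)
  mean((Z - X)^2)
}

#' Greedy layer-wise pre-training
#'
#' Trains the denoising layers bottom-up: each layer is pre-trained on the
#' clean codes of the layer below and applies its own corruption to its
#' input.
#'
#' @param stack An `sda_stack`.
#' @param X Training matrix matching the input width.
#' @param epochs_per_layer Epochs per layer (200 in the reference
#'   configuration; reduce for quick runs).
#' @param seed Seed (same seed, same data: identical result).
#' @param lr,batch_size Optimizer settings.
#' @return The pre-trained `sda_stack`.
#' @export
sda_pretrain <- function(stack, X, epochs_per_layer = 200, seed = 1,
                         lr = 1e-3, batch_size = 128) {
  if (ncol(X) != stack$dims[1]) stopf("data width %d != input width %d",
                                      ncol(X), stack$dims[1])
  H <- X
  for (i in seq_along(stack$layers)) {
    stack$layers[[i]] <- dae_pretrain_layer(stack$layers[[i]], H,
                                            epochs_per_layer,
                                            seed = derive_seed(seed, i),
                                            lr = lr, batch_size = batch_size)
    H <- dae_encode(stack$layers[[i]], H)
  }
  stack$pretrained <- TRUE
  stack
}

#' Regularized supervised loss specification
#'
#' Total loss = lambda0 * cross-entropy + lambda1 * L1 + lambda2 * L2 +
#' lambda3 * C, where C is the cost of misclassification under class
#' imbalance: C = C01 + C10 weighted by the respective error counts. When
#' `c01`/`c10` are NULL they default to the inverse training-class
#' frequencies.
#'
#' @param lambda0,lambda1,lambda2,lambda3 Non-negative coefficients
#'   (defaults 1, 1e-4, 1e-4, 0.5).
#' @param c01 Cost of predicting 1 for a true 0; `c10` the reverse.
#' @return A `loss_spec`.
#' @export
loss_spec <- function(lambda0 = 1, lambda1 = 1e-4, lambda2 = 1e-4,
                      lambda3 = 0.5, c01 = NULL, c10 = NULL) {
  structure(list(lambda0 = lambda0, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, c01 = c01, c10 = c10),
            class = "loss_spec")
}

sda_forward_full <- function(stack, X) {
  Hs <- list(X)
  for (l in stack$layers) Hs[[length(Hs) + 1]] <- dae_encode(l, Hs[[length(Hs)]])
  top <- Hs[[length(Hs)]]
  logits <- top %*% t(stack$head$W) +
    matrix(stack$head$b, nrow(top), stack$n_classes, byrow = TRUE)
  list(Hs = Hs, prob = softmax(logits))
}

sda_penalties <- function(stack) {
  l1 <- sum(abs(stack$head$W)); l2 <- sum(stack$head$W^2)
  for (l in stack$layers) {
    l1 <- l1 + sum(abs(l$W)); l2 <- l2 + sum(l$W^2)
  }
  c(l1 = l1, l2 = l2)
}

#' Supervised fine-tuning of the whole stack
#'
#' End-to-end mini-batch gradient descent (Adam) of the encoder weights
#' and the softmax head under the regularized loss. The head takes input
#' only from the top hidden layer. The cost term C is a misclassification
#' count weighted by `c01`/`c10`; since the count is piecewise constant it
#' enters the gradient through a cost-weighted cross-entropy surrogate
#' while the recorded loss uses the count itself.
#'
#' @param stack An `sda_stack` (pre-trained or randomly initialized).
#' @param X,y Training data and 0/1 labels.
#' @param loss A `loss_spec`.
#' @param epochs Training epochs.
#' @param seed Seed for batching.
#' @param lr,batch_size Optimizer settings (default lr 0.1 under plain
#'   gradient descent).
#' @param val_x,val_y Optional held-out data; per-epoch validation accuracy
#'   is then recorded alongside training loss/accuracy.
#' @param optimizer "sgd" (plain mini-batch gradient descent, default:
#'   fine-tuning should adjust rather than overwrite the pre-trained
#'   weights, and scale-free adaptive steps move every parameter by ~lr
#'   per update regardless of its gradient) or "adam".
#' @return The fine-tuned `sda_stack` with `fine_tune_trace` (data frame:
#'   epoch, loss, train_accuracy, recon_error, val_accuracy).
#' @export
fine_tune <- function(stack, X, y, loss = loss_spec(), epochs = 20, seed = 1,
                      lr = 0.1, batch_size = 128, val_x = NULL, val_y = NULL,
                      optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  if (nrow(X) != length(y)) stopf("labels/instances mismatch (%d vs %d)",
                                  length(y), nrow(X))
  n <- nrow(X)
  c01 <- loss$c01; c10 <- loss$c10
  if (is.null(c01)) c01 <- n / max(1, 2 * sum(y == 0))
  if (is.null(c10)) c10 <- n / max(1, 2 * sum(y == 1))
  # per-instance surrogate weight: cost incurred if this instance is missed
  wts <- ifelse(y == 0, c01, c10)
  st <- list()
  for (i in seq_along(stack$layers))
    st[[i]] <- list(W = adam_state(stack$layers[[i]]$W),
                    b = adam_state(stack$layers[[i]]$b))
  st_head <- list(W = adam_state(stack$head$W), b = adam_state(stack$head$b))
  trace <- NULL
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 7, ep), sample.int(n))
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]; wb <- wts[idx]
      fwd <- sda_forward_full(stack, Xb)
      P <- fwd$prob
      m <- nrow(Xb)
      Yb <- matrix(0, m, stack$n_classes); Yb[cbind(seq_len(m), yb + 1)] <- 1
      # lambda0 * CE + lambda3 * cost-weighted CE surrogate
      dlogits <- ((loss$lambda0 + loss$lambda3 * wb) / m) * (P - Yb)
      top <- fwd$Hs[[length(fwd$Hs)]]
      gW <- t(dlogits) %*% top + loss$lambda1 * sign(stack$head$W) +
        2 * loss$lambda2 * stack$head$W
      gb <- colSums(dlogits)
      if (optimizer == "adam") {
        u <- adam_update(stack$head$W, gW, st_head$W, lr)
        stack$head$W <- u$param; st_head$W <- u$state
        u <- adam_update(stack$head$b, gb, st_head$b, lr)
        stack$head$b <- u$param; st_head$b <- u$state
      } else {
        stack$head$W <- stack$head$W - lr * gW
        stack$head$b <- stack$head$b - lr * gb
      }
      dH <- dlogits %*% stack$head$W
      for (i in rev(seq_along(stack$layers))) {
        l <- stack$layers[[i]]
        Hi <- fwd$Hs[[i + 1]]
        dA <- if (l$activation == "sigmoid") dH * Hi * (1 - Hi) else dH
        gW <- t(dA) %*% fwd$Hs[[i]] + loss$lambda1 * sign(l$W) +
          2 * loss$lambda2 * l$W
        gb <- colSums(dA)
        dH <- dA %*% l$W
        if (optimizer == "adam") {
          u <- adam_update(l$W, gW, st[[i]]$W, lr)
          stack$layers[[i]]$W <- u$param; st[[i]]$W <- u$state
          u <- adam_update(l$b, gb, st[[i]]$b, lr)
          stack$layers[[i]]$b <- u$param; st[[i]]$b <- u$state
        } else {
          stack$layers[[i]]$W <- l$W - lr * gW
          stack$layers[[i]]$b <- l$b - lr * gb
        }
      }
    }
    fwd <- sda_forward_full(stack, X)
    pred <- max.col(fwd$prob) - 1
    pen <- sda_penalties(stack)
    C <- (c01 * sum(pred == 1 & y == 0) + c10 * sum(pred == 0 & y == 1)) / n
    ep_loss <- loss$lambda0 * cross_entropy(fwd$prob, y) +
      loss$lambda1 * pen["l1"] + loss$lambda2 * pen["l2"] + loss$lambda3 * C
    row <- data.frame(epoch = ep, loss = unname(ep_loss),
                      train_accuracy = mean(pred == y),
                      recon_error = sda_reconstruction_error(stack, X),
                      val_accuracy = NA_real_)
    if (!is.null(val_x)) {
      vp <- max.col(sda_forward_full(stack, val_x)$prob) - 1
      row$val_accuracy <- mean(vp == val_y)
    }
    trace <- rbind(trace, row)
  }
  stack$fine_tuned <- TRUE
  stack$fine_tune_trace <- trace
  stack
}

#' Predict class probabilities with a fine-tuned stack
#' @param stack A fine-tuned `sda_stack`.
#' @param X Numeric matrix.
#' @return Matrix n x classes of probabilities.
#' @export
sda_predict <- function(stack, X) {
  if (!stack$fine_tuned) stopf("stack has no trained head; fine-tune first")
  sda_forward_full(stack, X)$prob
}

#' Top-layer codes as a feature table
#'
#' The highest-level representations, intended as input for a stand-alone
#' classifier (e.g. KNN or an RBF-kernel SVM).
#'
#' @param stack A trained (pre-trained and/or fine-tuned) `sda_stack`.
#' @param X Numeric matrix matching the input width.
#' @return A `feature_table` with one column per top-layer unit.
#' @export
encode_features <- function(stack, X) {
  if (!stack$pretrained && !stack$fine_tuned)
    stopf("stack is untrained; pre-train or fine-tune before encoding")
  codes <- sda_encode(stack, X)
  feature_table(codes, paste0("sda.code", seq_len(ncol(codes))), "sda")
}

# ---- Restricted Boltzmann machine ------------------------------------------

#' Create a restricted Boltzmann machine layer
#'
#' @param n_visible,n_hidden Unit counts.
#' @param visible_kind "binary" or "gaussian" (for real-valued inputs).
#' @param seed Seed for weight initialization.
#' @return An `rbm_layer` with weights `W` (visible x hidden), hidden
#'   biases `b`, visible biases `c`.
#' @export
rbm_layer <- function(n_visible, n_hidden, visible_kind = c("binary", "gaussian"),
                      seed = 1) {
  visible_kind <- match.arg(visible_kind)
  structure(list(W = xavier_init(n_visible, n_hidden, seed) * 0.1,
                 b = numeric(n_hidden), c = numeric(n_visible),
                 visible_kind = visible_kind),
            class = "rbm_layer")
}

#' Energy of a joint configuration
#'
#' E(v, h) = - v' W h - b' h - c' v (binary form; for Gaussian visibles the
#' quadratic self-term (v - c)^2 / 2 replaces the linear visible term).
#'
#' @param rbm An `rbm_layer`.
#' @param v,h Visible and hidden state vectors.
#' @return Scalar energy.
#' @export
rbm_energy <- function(rbm, v, h) {
  inter <- -as.numeric(t(v) %*% rbm$W %*% h) - sum(rbm$b * h)
  if (rbm$visible_kind == "binary") inter - sum(rbm$c * v)
  else inter + sum((v - rbm$c)^2) / 2
}

#' Hidden activation probabilities given visibles
#' @param rbm An `rbm_layer`.
#' @param V Matrix n x visible.
#' @return Matrix n x hidden of P(h = 1 | v).
#' @export
rbm_hidden_prob <- function(rbm, V) {
  sigmoid(V %*% rbm$W + matrix(rbm$b, nrow(V), length(rbm$b), byrow = TRUE))
}

#' One CD-1 update of a restricted Boltzmann machine
#'
#' Samples h | v, reconstructs v | h (mean-field; Gaussian mean for
#' real-valued visibles), recomputes the hidden probabilities and updates
#' the parameters by the contrastive statistics.
#'
#' @param rbm An `rbm_layer`.
#' @param batch Matrix n x visible.
#' @param lr Learning rate.
#' @param seed Seed for the hidden sampling.
#' @return The updated `rbm_layer`; `recon_error` holds the batch mean
#'   squared reconstruction error.
#' @export
rbm_cd_update <- function(rbm, batch, lr = 0.01, seed = 1) {
  if (ncol(batch) != nrow(rbm$W)) stopf("batch width %d != visible units %d",
                                        ncol(batch), nrow(rbm$W))
  n <- nrow(batch)
  h0p <- rbm_hidden_prob(rbm, batch)
  h0 <- with_seed(seed, matrix(stats::rbinom(length(h0p), 1, h0p), n))
  v1 <- h0 %*% t(rbm$W) + matrix(rbm$c, n, nrow(rbm$W), byrow = TRUE)
  if (rbm$visible_kind == "binary") v1 <- sigmoid(v1)
  h1p <- rbm_hidden_prob(rbm, v1)
  rbm$W <- rbm$W + lr * (t(batch) %*% h0p - t(v1) %*% h1p) / n
  rbm$b <- rbm$b + lr * (colMeans(h0p) - colMeans(h1p))
  rbm$c <- rbm$c + lr * (colMeans(batch) - colMeans(v1))
  rbm$recon_error <- mean((v1 - batch)^2)
  rbm
}

#' Train an RBM by repeated CD-1 sweeps
#'
#' @param rbm An `rbm_layer`.
#' @param X Training matrix.
#' @param epochs Full passes over the data.
#' @param lr Learning rate.
#' @param seed Seed.
#' @param batch_size Mini-batch size.
#' @return The trained `rbm_layer` with `error_trace` (per-epoch mean
#'   reconstruction error).
#' @export
rbm_train <- function(rbm, X, epochs = 20, lr = 0.01, seed = 1,
                      batch_size = 128) {
  n <- nrow(X)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, ep), sample.int(n))
    errs <- c()
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      rbm <- rbm_cd_update(rbm, X[idx, , drop = FALSE], lr,
                           derive_seed(seed, ep, start))
      errs <- c(errs, rbm$recon_error)
    }
    trace[ep] <- mean(errs)
  }
  rbm$error_trace <- trace
  rbm
}
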