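# Reference discriminative baselines: a feed-forward network with batch
# normalization and dropout (3840-800-200-20-2) and a small convolutional
# network over the 60 x 64 image view of a channel instance.

#' Build a reference baseline network
#'
#' `dnn`: affine - batchnorm - ReLU blocks of widths 800, 200, 20 with
#' dropout probabilities 0.45, 0.5, 0.25, then a 2-way softmax.
#' `cnn`: the 3840-sample instance reshaped to a 60 x 64 single-channel
#' image; four convolution modules (kernel 3, stride 2, no padding, each
#' conv followed by batch normalization and ReLU; the last two modules add
#' 2 x 2 max-pooling), then a fully connected head with dropout 0.85.
#'
#' @param model "dnn" or "cnn".
#' @param input_dim Input width; must be 3840.
#' @param seed Seed for weight initialization.
#' @return A `baseline_net` ready for [train_baseline()].
#' @export
build_baseline <- function(model = c("dnn", "cnn"), input_dim = 3840, seed = 1) {
  model <- match.arg(model)
  if (input_dim != 3840)
    stopf("baseline networks expect input_dim 3840, got %d", input_dim)
  if (model == "dnn") {
    widths <- c(input_dim, 800, 200, 20)
    layers <- lapply(seq_len(3), function(i) list(
      W = xavier_init(widths[i + 1], widths[i], derive_seed(seed, i)),
      b = numeric(widths[i + 1]),
      gamma = rep(1, widths[i + 1]), beta = numeric(widths[i + 1]),
      running = list(mean = numeric(widths[i + 1]),
                     var = rep(1, widths[i + 1])),
      dropout = c(0.45, 0.5, 0.25)[i]))
    head <- list(W = xavier_init(2, 20, derive_seed(seed, 9)), b = numeric(2))
    structure(list(kind = "dnn", layers = layers, head = head,
                   widths = c(widths, 2), trained = FALSE),
              class = "baseline_net")
  } else {
    chans <- c(1, 8, 16, 32, 32)
    convs <- lapply(seq_len(4), function(i) list(
      K = xavier_init(chans[i + 1], 9 * chans[i], derive_seed(seed, 10 + i)),
      b = numeric(chans[i + 1]),
      gamma = rep(1, chans[i + 1]), beta = numeric(chans[i + 1]),
      running = list(mean = numeric(chans[i + 1]),
                     var = rep(1, chans[i + 1])),
      pool = i >= 3))
    head <- list(W = xavier_init(2, chans[5], derive_seed(seed, 19)),
                 b = numeric(2), dropout = 0.85)
    structure(list(kind = "cnn", convs = convs, head = head,
                   image = c(60, 64), trained = FALSE),
              class = "baseline_net")
  }
}

relu <- function(x) pmax(x, 0)

# ---- convolution helpers (NHWC arrays) -------------------------------------

conv_out_dim <- function(d, k = 3, stride = 2) (d - k) %/% stride + 1

# im2col for kernel 3, stride 2, valid padding: returns a matrix
# (n * outH * outW) x (9 * C) whose product with the kernel matrix gives
# the convolution.
im2col3 <- function(x, stride = 2) {
  dm <- dim(x)  # n, H, W, C
  oh <- conv_out_dim(dm[2]); ow <- conv_out_dim(dm[3])
  cols <- matrix(0, dm[1] * oh * ow, 9 * dm[4])
  ys <- (seq_len(oh) - 1) * stride
  xs <- (seq_len(ow) - 1) * stride
  j <- 0
  for (dx in 1:3) for (dy in 1:3) {
    patch <- x[, ys + dy, xs + dx, , drop = FALSE]
    cols[, j + seq_len(dm[4])] <- matrix(patch, dm[1] * oh * ow, dm[4])
    j <- j + dm[4]
  }
  attr(cols, "geom") <- c(dm, oh, ow)
  cols
}

col2im3 <- function(dcols, geom, stride = 2) {
  n <- geom[1]; H <- geom[2]; W <- geom[3]; C <- geom[4]
  oh <- geom[5]; ow <- geom[6]
  dx_in <- array(0, c(n, H, W, C))
  ys <- (seq_len(oh) - 1) * stride
  xs <- (seq_len(ow) - 1) * stride
  j <- 0
  for (dx in 1:3) for (dy in 1:3) {
    patch <- array(dcols[, j + seq_len(C)], c(n, oh, ow, C))
    dx_in[, ys + dy, xs + dx, ] <- dx_in[, ys + dy, xs + dx, , drop = FALSE] + patch
    j <- j + C
  }
  dx_in
}

maxpool2 <- function(x) {
  dm <- dim(x)
  oh <- dm[2] %/% 2; ow <- dm[3] %/% 2
  ys <- (seq_len(oh) - 1) * 2
  xs <- (seq_len(ow) - 1) * 2
  slices <- list(x[, ys + 1, xs + 1, , drop = FALSE],
                 x[, ys + 2, xs + 1, , drop = FALSE],
                 x[, ys + 1, xs + 2, , drop = FALSE],
                 x[, ys + 2, xs + 2, , drop = FALSE])
  out <- slices[[1]]; arg <- array(1L, dim(out))
  for (s in 2:4) {
    upd <- slices[[s]] > out
    out[upd] <- slices[[s]][upd]
    arg[upd] <- s
  }
  list(out = out, arg = arg, in_dim = dm)
}

maxpool2_backward <- function(dout, cache) {
  dm <- cache$in_dim
  dx <- array(0, dm)
  oh <- dim(dout)[2]; ow <- dim(dout)[3]
  ys <- (seq_len(oh) - 1) * 2
  xs <- (seq_len(ow) - 1) * 2
  offs <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (s in 1:4) {
    mask <- cache$arg == s
    g <- dout * mask
    dx[, ys + offs[[s]][1], xs + offs[[s]][2], ] <-
      dx[, ys + offs[[s]][1], xs + offs[[s]][2], , drop = FALSE] + g
  }
  dx
}

# ---- forward/backward ------------------------------------------------------

dnn_forward <- function(net, X, train, seed = 0) {
  caches <- list()
  H <- X
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    A <- H %*% t(l$W) + matrix(l$b, nrow(H), length(l$b), byrow = TRUE)
    bn <- bn_forward(A, l$gamma, l$beta, l$running, train = train)
    if (train) net$layers[[i]]$running <- bn$running
    R <- relu(bn$out)
    mask <- if (train) dropout_mask(nrow(R), ncol(R), l$dropout,
                                    derive_seed(seed, 31, i)) else NULL
    O <- if (is.null(mask)) R else R * mask
    caches[[i]] <- list(input = H, bn = bn, pre_relu = bn$out, mask = mask)
    H <- O
  }
  logits <- H %*% t(net$head$W) + matrix(net$head$b, nrow(H), 2, byrow = TRUE)
  list(net = net, prob = softmax(logits), top = H, caches = caches)
}

cnn_forward <- function(net, X, train, seed = 0) {
  n <- nrow(X)
  H <- array(X, c(n, net$image[1], net$image[2], 1))
  caches <- list()
  for (i in seq_along(net$convs)) {
    cv <- net$convs[[i]]
    cols <- im2col3(H)
    A <- cols %*% t(cv$K)
    A <- sweep(A, 2, cv$b, "+")
    bn <- bn_forward(A, cv$gamma, cv$beta, cv$running, train = train)
    if (train) net$convs[[i]]$running <- bn$running
    R <- relu(bn$out)
    geom <- attr(cols, "geom")
    out <- array(R, c(geom[1], geom[5], geom[6], ncol(A)))
    pool <- NULL
    if (cv$pool && dim(out)[2] >= 2 && dim(out)[3] >= 2) {
      pool <- maxpool2(out)
      out2 <- pool$out
    } else out2 <- out
    caches[[i]] <- list(cols = cols, geom = geom, bn = bn, pre_relu = bn$out,
                        pre_pool_dim = dim(out), pool = pool)
    H <- out2
  }
  flat <- matrix(H, n, prod(dim(H)[-1]))
  mask <- if (train) dropout_mask(n, ncol(flat), net$head$dropout,
                                  derive_seed(seed, 41)) else NULL
  top <- if (is.null(mask)) flat else flat * mask
  logits <- top %*% t(net$head$W) + matrix(net$head$b, n, 2, byrow = TRUE)
  list(net = net, prob = softmax(logits), top = top, flat_mask = mask,
       top_dim = dim(H), caches = caches)
}

#' Train a baseline network
#'
#' Mini-batch Adam on softmax cross-entropy.
#'
#' @param net A `baseline_net` from [build_baseline()].
#' @param X,y Training matrix (n x 3840) and 0/1 labels.
#' @param epochs Training epochs.
#' @param seed Seed for batching/dropout.
#' @param lr,batch_size Optimizer settings.
#' @return The trained `baseline_net` with a per-epoch `loss_trace`.
#' @export
train_baseline <- function(net, X, y, epochs = 20, seed = 1, lr = 1e-3,
                           batch_size = 128) {
  n <- nrow(X)
  states <- NULL
  init_state <- function() {
    if (net$kind == "dnn") {
      s <- lapply(net$layers, function(l)
        list(W = adam_state(l$W), b = adam_state(l$b),
             gamma = adam_state(l$gamma), beta = adam_state(l$beta)))
      c(s, list(head = list(W = adam_state(net$head$W),
                            b = adam_state(net$head$b))))
    } else {
      s <- lapply(net$convs, function(cv)
        list(K = adam_state(cv$K), b = adam_state(cv$b),
             gamma = adam_state(cv$gamma), beta = adam_state(cv$beta)))
      c(s, list(head = list(W = adam_state(net$head$W),
                            b = adam_state(net$head$b))))
    }
  }
  states <- init_state()
  upd <- function(param, grad, slot, name) {
    u <- adam_update(param, grad, states[[slot]][[name]], lr)
    states[[slot]][[name]] <<- u$state
    u$param
  }
  head_slot <- length(states)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 51, ep), sample.int(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      m <- length(idx)
      bs <- derive_seed(seed, ep, start)
      fwd <- if (net$kind == "dnn") dnn_forward(net, Xb, TRUE, bs)
             else cnn_forward(net, Xb, TRUE, bs)
      net <- fwd$net
      P <- fwd$prob
      ep_loss <- ep_loss + cross_entropy(P, yb); nb <- nb + 1
      Yb <- matrix(0, m, 2); Yb[cbind(seq_len(m), yb + 1)] <- 1
      dlogits <- (P - Yb) / m
      net$head$W <- upd(net$head$W, t(dlogits) %*% fwd$top, head_slot, "W")
      net$head$b <- upd(net$head$b, colSums(dlogits), head_slot, "b")
      dtop <- dlogits %*% net$head$W
      if (net$kind == "dnn") {
        dH <- dtop
        for (i in rev(seq_along(net$layers))) {
          ca <- fwd$caches[[i]]
          if (!is.null(ca$mask)) dH <- dH * ca$mask
          dH <- dH * (ca$pre_relu > 0)
          bb <- bn_backward(dH, ca$bn, net$layers[[i]]$gamma)
          net$layers[[i]]$gamma <- upd(net$layers[[i]]$gamma, bb$dgamma, i, "gamma")
          net$layers[[i]]$beta <- upd(net$layers[[i]]$beta, bb$dbeta, i, "beta")
          dA <- bb$dx
          net$layers[[i]]$W <- upd(net$layers[[i]]$W, t(dA) %*% ca$input, i, "W")
          net$layers[[i]]$b <- upd(net$layers[[i]]$b, colSums(dA), i, "b")
          dH <- dA %*% net$layers[[i]]$W
        }
      } else {
        if (!is.null(fwd$flat_mask)) dtop <- dtop * fwd$flat_mask
        dH <- array(dtop, fwd$top_dim)
        for (i in rev(seq_along(net$convs))) {
          ca <- fwd$caches[[i]]
          if (!is.null(ca$pool)) dH <- maxpool2_backward(dH, ca$pool)
          dR <- matrix(dH, prod(ca$pre_pool_dim[1:3]), ca$pre_pool_dim[4])
          dR <- dR * (ca$pre_relu > 0)
          bb <- bn_backward(dR, ca$bn, net$convs[[i]]$gamma)
          net$convs[[i]]$gamma <- upd(net$convs[[i]]$gamma, bb$dgamma, i, "gamma")
          net$convs[[i]]$beta <- upd(net$convs[[i]]$beta, bb$dbeta, i, "beta")
          dA <- bb$dx
          net$convs[[i]]$K <- upd(net$convs[[i]]$K, t(dA) %*% ca$cols, i, "K")
          net$convs[[i]]$b <- upd(net$convs[[i]]$b, colSums(dA), i, "b")
          dcols <- dA %*% net$convs[[i]]$K
          dH <- col2im3(dcols, ca$geom)
        }
      }
    }
    trace[ep] <- ep_loss / nb
  }
  net$trained <- TRUE
  net$loss_trace <- trace
  net
}

#' Predict with a baseline network
#' @param net A trained `baseline_net`.
#' @param X Numeric matrix n x 3840.
#' @return List with `class` (0/1) and `prob` (n x 2).
#' @export
predict_baseline <- function(net, X) {
  fwd <- if (net$kind == "dnn") dnn_forward(net, X, FALSE)
         else cnn_forward(net, X, FALSE)
  prob <- fwd$prob
  colnames(prob) <- c("p0", "p1")
  list(class = as.integer(prob[, 2] > prob[, 1]), prob = prob)
}
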