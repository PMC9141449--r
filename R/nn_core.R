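# Minimal neural-network primitives shared by the autoencoder stack, the
# restricted Boltzmann machine and the feed-forward / convolutional
# baselines: parameter initialization, Adam updates, batch normalization,
# dropout and the softmax cross-entropy head.

sigmoid <- function(x) 1 / (1 + exp(-x))

xavier_init <- function(d_out, d_in, seed) {
  lim <- sqrt(6 / (d_in + d_out))
  with_seed(seed, matrix(stats::runif(d_out * d_in, -lim, lim), d_out, d_in))
}

adam_state <- function(param) list(m = param * 0, v = param * 0, t = 0)

adam_update <- function(param, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Inverted dropout mask for a matrix; NULL when p == 0.
dropout_mask <- function(n, d, p, seed) {
  if (p <= 0) return(NULL)
  with_seed(seed, matrix(stats::rbinom(n * d, 1, 1 - p), n, d) / (1 - p))
}

softmax <- function(a) {
  e <- exp(a - apply(a, 1, max))
  e / rowSums(e)
}

cross_entropy <- function(p, y) {
  -mean(log(pmax(p[cbind(seq_along(y), y + 1)], 1e-12)))
}

# Batch normalization over columns of a (n x d) activation matrix.
# Returns normalized output plus the cache needed for the backward pass.
bn_forward <- function(a, gamma, beta, running, momentum = 0.9,
                       train = TRUE, eps = 1e-5) {
  if (train) {
    mu <- colMeans(a)
    v <- colMeans(a^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean; v <- running$var
  }
  xhat <- sweep(sweep(a, 2, mu), 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, inv_sd = 1 / sqrt(v + eps), running = running)
}

bn_backward <- function(dout, cache, gamma) {
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  m <- nrow(dout)
  dxhat <- sweep(dout, 2, gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dout), byrow = TRUE) -
                cache$xhat * matrix(colMeans(dxhat * cache$xhat), m,
                                    ncol(dout), byrow = TRUE),
              2, cache$inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}
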