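# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and integer tags, staying inside the
# 32-bit signed range required by set.seed().
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 1000003 + as.numeric(t)) %% 2147483629
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_int <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x))
    stopf("`%s` must be a single integer", name)
  if (x < min) stopf("`%s` must be >= %s", name, min)
  invisible(as.integer(x))
}

# Symmetric Hamming taper (0.54 - 0.46 cos), the conventional analysis window.
hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Row-wise z-score of a matrix; zero-variance rows become all-zero.
zscore_rows <- function(m, warn = FALSE) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  bad <- sdv <= 0 | !is.finite(sdv)
  if (any(bad)) {
    if (warn) warning(sprintf("%d zero-variance instance(s) replaced by zeros", sum(bad)))
    sdv[bad] <- 1
  }
  out <- (m - mu) / sdv
  out[bad, ] <- 0
  out
}

# EEG band edges in Hz used throughout the package.
band_edges <- function() {
  list(theta = c(3, 7), alpha = c(8, 13), beta = c(14, 29), gamma = c(30, 47))
}

band_names <- function() c("theta", "alpha", "beta", "gamma")
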