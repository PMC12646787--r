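# Internal numerical helpers shared across modules.

#' Derive a deterministic cascade of sub-seeds from a master seed
#'
#' All stochastic stages draw their own seed from a single master seed so
#' that a whole pipeline run is reproducible while stages stay independent.
#'
#' @param master integer master seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, .Machine$integer.max]`.
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max, n)
}

# Run an expression under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# 1-D convolution of the rows dimension of a matrix with kernel k using
# replicate (edge-clamp) padding; implemented as a band-matrix product so
# large truncated kernels stay fast.
.conv_dim1 <- function(x, k) {
  n <- nrow(x)
  K <- length(k)
  h <- (K - 1L) %/% 2L
  idx <- pmin(pmax(seq_len(n + 2L * h) - h, 1L), n)
  xp <- x[idx, , drop = FALSE]
  C <- matrix(0, n, n + 2L * h)
  rows <- rep(seq_len(n), each = K)
  cols <- rep(seq_len(n), each = K) + rep(seq_len(K) - 1L, times = n)
  C[cbind(rows, cols)] <- rep(k, n)
  C %*% xp
}

# Truncated Gaussian kernel; half-width capped at cap (kernel truncated to
# the image extent for very large sigmas) and renormalised to sum 1.
.gauss_kernel <- function(sigma, cap) {
  h <- min(ceiling(3 * sigma), cap)
  z <- seq(-h, h)
  k <- exp(-z^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate boundary handling. A flat field is
# preserved exactly because every (truncated) kernel is normalised.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  kx <- .gauss_kernel(sigma, nrow(x) - 1L)
  ky <- .gauss_kernel(sigma, ncol(x) - 1L)
  t(.conv_dim1(t(.conv_dim1(x, kx)), ky))
}

# Third standardised moment; 0 for (near-)constant input.
skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s < 1e-12) return(0)
  mean((x - m)^3) / s^3
}

# Population standard deviation (divisor n).
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
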