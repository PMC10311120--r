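# Small internal image/RNG utilities shared across modules.

# Evaluate code with a temporarily fixed RNG seed, restoring the caller's
# RNG state afterwards. All stochastic stages go through this so a single
# integer seed makes the whole pipeline reproducible.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive n child seeds from a master seed (all < 2^31).
derive_seeds <- function(seed, n) with_seed(seed, sample.int(2^31 - 2, n))

# 1D Gaussian kernel, radius 3 sigma, normalized.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Pad a matrix by r rows/cols on each side, replicating the border.
pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur with replicate border handling.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  p <- pad_replicate(m, r)
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W + 2L * r)
  for (i in seq_along(k))          # along rows (y)
    tmp <- tmp + k[i] * p[i:(i + H - 1L), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k))          # along columns (x)
    out <- out + k[i] * tmp[, i:(i + W - 1L), drop = FALSE]
  out
}

# Coordinate grids in the 0-based pixel-center convention:
# xg[i, j] = j - 1, yg[i, j] = i - 1.
coord_grids <- function(H, W) {
  list(x = matrix(rep(0:(W - 1), each = H), H, W),
       y = matrix(rep(0:(H - 1), W), H, W))
}

# Zero-normalized cross-correlation of two numeric vectors/matrices over an
# optional logical mask. Shared by the scorer and the exhaustive search.
ncc_values <- function(a, b, mask = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  if (length(a) == 0L) stop("ncc: empty overlap")
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("ncc: constant image over the overlap")
  sum(a * b) / (na * nb)
}
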