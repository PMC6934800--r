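# Low-level numeric helpers shared by the tracking and freezing pipelines.

#' Gaussian convolution kernel
#'
#' One-dimensional normalized Gaussian kernel, truncated at
#' `ceiling(4 * sigma)` taps on each side.
#'
#' @param sigma Standard deviation in pixels (> 0).
#' @return Numeric vector of length `2 * ceiling(4 * sigma) + 1` summing to 1.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  r <- ceiling(4 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Reflect an out-of-range 1-based index back into [1, n]
# (half-sample symmetric: ... 2 1 | 1 2 ... n | n n-1 ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  # period of the reflected sequence is 2n
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j + 1L, 2L * n - j))
}

# Band matrix applying the kernel along a dimension of size n with reflect
# boundary handling. Returns n x n matrix A such that A %*% v convolves v.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (d in -r:r) {
    src <- reflect_index(seq_len(n) + d, n)
    A[cbind(seq_len(n), src)] <- A[cbind(seq_len(n), src)] + kernel[d + r + 1L]
  }
  A
}

# cache of band matrices keyed by "n:sigma"
.conv_cache <- new.env(parent = emptyenv())

conv_matrix_cached <- function(n, sigma) {
  key <- paste0(n, ":", sigma)
  A <- .conv_cache[[key]]
  if (is.null(A)) {
    A <- conv_band_matrix(n, gaussian_kernel(sigma))
    .conv_cache[[key]] <- A
  }
  A
}

#' Gaussian-filter an image
#'
#' Separable Gaussian smoothing with reflect boundary handling, the filter
#' applied to every frame before changed-pixel motion counting.
#'
#' @param m Numeric matrix (grayscale image, rows = y, columns = x).
#' @param sigma Standard deviation of the Gaussian in pixels.
#' @return Matrix of the same dimensions.
#' @export
gaussian_blur <- function(m, sigma = 1) {
  stopifnot(is.matrix(m))
  if (sigma <= 0) return(m)
  A <- conv_matrix_cached(nrow(m), sigma)
  B <- conv_matrix_cached(ncol(m), sigma)
  A %*% m %*% t(B)
}

# Linear-interpolation percentile (quantile type 7) of all matrix entries.
percentile_of <- function(x, p) {
  stats::quantile(x, p / 100, names = FALSE, type = 7)
}

# Bilinear resampling of a matrix by a positive real scale factor.
resize_bilinear <- function(m, factor) {
  stopifnot(is.matrix(m), factor > 0)
  h <- nrow(m); w <- ncol(m)
  nh <- max(1L, as.integer(round(h * factor)))
  nw <- max(1L, as.integer(round(w * factor)))
  if (nh == h && nw == w) return(m)
  # map output pixel centers onto input pixel-center coordinates
  ys <- (seq_len(nh) - 0.5) * h / nh + 0.5 - 0.5
  xs <- (seq_len(nw) - 0.5) * w / nw + 0.5 - 0.5
  y0 <- pmin(pmax(floor(ys), 1), h); y1 <- pmin(y0 + 1, h)
  x0 <- pmin(pmax(floor(xs), 1), w); x1 <- pmin(x0 + 1, w)
  fy <- pmin(pmax(ys - y0, 0), 1);   fx <- pmin(pmax(xs - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx)
  bot <- m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
  top + bot
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# derive a per-frame seed below 2^31 from a base seed and frame index
frame_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 97003 * (index + 1)) %% 2147483629)
}
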