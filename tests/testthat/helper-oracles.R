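# Independent brute-force oracles used to pin down the numerical behavior of
# the pipeline operations. These deliberately avoid the code paths they check.

# pixel-wise median of a list of matrices by explicit sort-and-middle
oracle_median_stack <- function(frames) {
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    v <- sort(vapply(frames, function(f) f[i, j], numeric(1)))
    n <- length(v)
    out[i, j] <- if (n %% 2 == 1) v[(n + 1) / 2] else
      (v[n / 2] + v[n / 2 + 1]) / 2
  }
  out
}

# linear-interpolation percentile by explicit sort
oracle_percentile <- function(x, p) {
  v <- sort(as.vector(x))
  h <- (length(v) - 1) * p / 100
  lo <- floor(h)
  if (lo + 1 >= length(v)) return(v[length(v)])
  v[lo + 1] + (h - lo) * (v[lo + 2] - v[lo + 1])
}

# percentile threshold by double loop, strict survival
oracle_threshold <- function(m, p) {
  cutoff <- oracle_percentile(m, p)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (m[i, j] <= cutoff) out[i, j] <- 0
  }
  out
}

# center of mass by double loop over 0-based (x, y)
oracle_com <- function(m) {
  tot <- 0; sx <- 0; sy <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- m[i, j]
    tot <- tot + v
    sx <- sx + v * (j - 1)
    sy <- sy + v * (i - 1)
  }
  c(sx / tot, sy / tot)
}

# dense 2-D Gaussian convolution with reflect boundary, by quadruple loop
oracle_gaussian <- function(m, sigma) {
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + k2[di + r + 1, dj + r + 1] *
        m[refl(i + di, h), refl(j + dj, w)]
    }
    out[i, j] <- acc
  }
  out
}

# freezing by checking every candidate window of length >= mf
oracle_freezing <- function(motion, ft, mf) {
  n <- length(motion)
  cand <- motion < ft
  out <- logical(n)
  for (s in seq_len(n)) {
    e <- s + mf - 1
    if (e > n) break
    if (all(cand[s:e])) out[s:e] <- TRUE
  }
  as.integer(out) * 100L
}

# tiny in-memory stream from a list of matrices
mat_stream <- function(frames, fps = 30) as_frame_stream(frames, fps = fps)

# per-frame tracking error against a fixture's ground-truth trajectory
tracking_error <- function(result, bundle) {
  sqrt((result$x - bundle$trajectory$x)^2 +
         (result$y - bundle$trajectory$y)^2)
}
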