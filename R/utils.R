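#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.  All seeded generator code funnels through here so that the
# determinism contract (same seed + same specs => identical output) holds.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Trapezoidal integral of y over x (uniform or not).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Robust noise scale of a 1D signal: MAD of first differences / sqrt(2),
# insensitive to the slowly varying structural profile underneath.
robust_noise <- function(x) {
  d <- diff(x[is.finite(x)])
  if (length(d) < 2L) return(0)
  stats::mad(d) / sqrt(2)
}

# Separable Gaussian smoothing of a matrix (reflective boundaries).
gauss_smooth_mat <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  m <- apply_kernel_rows(m, k)
  t(apply_kernel_rows(t(m), k))
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  ifelse(j < n, j + 1L, 2L * n - 1L - j)
}

# Convolve each column of m with kernel k along the row index (dim 1),
# reflecting at the boundaries.
apply_kernel_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- m[reflect_idx(seq.int(1L - r, n + r), n), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

gauss_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  drop(gauss_smooth_mat(matrix(x, ncol = 1L), sigma))
}

# Bilinear sampling of matrix `m` at fractional (row, col) positions
# (1-based, R matrix convention).  Out-of-range samples return `fill`.
bilinear_sample <- function(m, row, col, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp exact upper edge
  edge_r <- row == nr & c0 >= 1 & c0 <= nc - 1
  edge_c <- col == nc & r0 >= 1 & r0 <= nr - 1
  corner <- row == nr & col == nc
  out <- rep(fill, length(row))
  g <- function(r, c) m[cbind(r, c)]
  i <- which(ok)
  if (length(i)) {
    out[i] <- (1 - fr[i]) * (1 - fc[i]) * g(r0[i], c0[i]) +
      (1 - fr[i]) * fc[i] * g(r0[i], c0[i] + 1L) +
      fr[i] * (1 - fc[i]) * g(r0[i] + 1L, c0[i]) +
      fr[i] * fc[i] * g(r0[i] + 1L, c0[i] + 1L)
  }
  i <- which(edge_r & !ok)
  if (length(i)) out[i] <- (1 - fc[i]) * g(rep(nr, length(i)), c0[i]) +
    fc[i] * g(rep(nr, length(i)), c0[i] + 1L)
  i <- which(edge_c & !ok & !edge_r)
  if (length(i)) out[i] <- (1 - fr[i]) * g(r0[i], rep(nc, length(i))) +
    fr[i] * g(r0[i] + 1L, rep(nc, length(i)))
  if (any(corner)) out[corner] <- m[nr, nc]
  out
}

# Quadratic (parabolic) sub-sample refinement of a local maximum at index i
# of series y; returns fractional index offset in (-0.5, 0.5).
parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom == 0) return(0)
  off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  max(min(off, 0.5), -0.5)
}
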