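#' Prominence-filtered peak detection
#'
#' Locates local maxima of a 1D series and computes their topographic
#' prominence: the height of a peak above the highest of the two saddle
#' levels separating it from higher terrain.  Works on open (linear)
#' series and on circular series such as rotational correlation curves,
#' where the index wraps around.
#'
#' @param x numeric series.
#' @param min_prominence keep only peaks with prominence at or above this
#'   value.
#' @param circular logical; treat \code{x} as periodic (last sample
#'   adjacent to the first).
#' @return data frame with columns \code{index} (integer sample index of
#'   each peak), \code{value}, and \code{prominence}, ordered by index.
#' @export
find_peaks <- function(x, min_prominence = 0, circular = FALSE) {
  n <- length(x)
  empty <- data.frame(index = integer(), value = numeric(),
                      prominence = numeric())
  if (n < 3L || !any(is.finite(x))) return(empty)
  xs <- x
  get <- function(i) {
    if (circular) xs[((i - 1L) %% n) + 1L]
    else if (i < 1L || i > n) -Inf
    else xs[i]
  }
  # local maxima (plateaus: keep first sample strictly above what follows)
  cand <- integer()
  for (i in seq_len(n)) {
    if (!circular && (i == 1L || i == n)) next
    l <- get(i - 1L); r <- get(i + 1L)
    if (xs[i] > l && xs[i] >= r) {
      # skip plateau continuation
      if (xs[i] == r) {
        j <- i + 1L
        while (get(j) == xs[i]) j <- j + 1L
        if (get(j) > xs[i]) next
      }
      cand <- c(cand, i)
    }
  }
  if (!length(cand)) return(empty)
  prom <- vapply(cand, function(i) peak_prominence(xs, i, circular), 0)
  keep <- prom >= min_prominence & prom > 0
  data.frame(index = cand[keep], value = xs[cand[keep]],
             prominence = prom[keep])
}

peak_prominence <- function(x, i, circular = FALSE) {
  n <- length(x)
  v <- x[i]
  side_min <- function(step) {
    lo <- v
    j <- i
    travelled <- 0L
    repeat {
      j <- j + step
      travelled <- travelled + 1L
      if (circular) {
        jj <- ((j - 1L) %% n) + 1L
        if (travelled >= n) return(lo)  # full wrap: global max
        if (x[jj] > v) return(lo)
        lo <- min(lo, x[jj])
      } else {
        if (j < 1L || j > n) return(lo)  # reached edge: base is min so far
        if (x[j] > v) return(lo)
        lo <- min(lo, x[j])
      }
    }
  }
  v - max(side_min(-1L), side_min(1L))
}

# Full width at half prominence of the peak at index i, in samples.
# Interpolates the half-level crossings linearly on each side; with
# circular = TRUE the walk wraps around the series.
peak_fwhm <- function(x, i, prominence = NULL, circular = FALSE) {
  if (is.null(prominence)) prominence <- peak_prominence(x, i, circular)
  half <- x[i] - prominence / 2
  n <- length(x)
  # each side's walk ends at the half level or at the first substantial
  # valley (running minimum followed by a clear rise), so the width of
  # one peak never bleeds across a saddle into its neighbor
  cross <- function(step) {
    j <- i
    travelled <- 0L
    minval <- x[i]; minpos <- 0L
    repeat {
      j2 <- j + step
      if (circular) {
        if (travelled >= n) return(travelled + 0.5)
        j2 <- ((j2 - 1L) %% n) + 1L
      } else if (j2 < 1L || j2 > n) {
        return(travelled + 0.5)
      }
      travelled <- travelled + 1L
      if (x[j2] <= half) {
        frac <- (x[j] - half) / (x[j] - x[j2])
        return(travelled - 1L + frac)
      }
      if (x[j2] < minval) { minval <- x[j2]; minpos <- travelled }
      if (x[j2] > minval + 0.25 * prominence || x[j2] > x[i])
        return(minpos)
      j <- j2
    }
  }
  cross(-1L) + cross(1L)
}

# Sub-sample refined peak positions (fractional indices) for a set of
# detected peaks.
refine_peaks <- function(x, idx) {
  idx + vapply(idx, function(i) parabolic_offset(x, i), 0)
}
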