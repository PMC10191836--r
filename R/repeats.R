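#' Extract repeat windows from a straightened filament
#'
#' Detects bead peaks on the axial mean profile and cuts one 2D window
#' per repeat, bead-to-bead with half-open boundaries (a filament with
#' b detected beads yields b - 1 windows).  Windows are resampled to a
#' common axial length (the median repeat length in pixels) so that the
#' whole stack shares one grid.  Explicit boundaries or a fixed period
#' may be supplied instead of peak detection.
#'
#' @param straightened a \code{straightened_filament}.
#' @param boundaries_nm optional vector of repeat boundaries (arc nm).
#' @param period_nm optional fixed period; boundaries are then laid out
#'   from the first detected bead (or from 0).
#' @return object of class \code{"repeat_stack"}: list with
#'   \code{windows} (list of axial x transverse matrices on one grid),
#'   \code{shifts_nm} (zeros until alignment), \code{pixel_size_nm},
#'   \code{window_len}.
#' @export
extract_repeats <- function(straightened, boundaries_nm = NULL,
                            period_nm = NULL) {
  stopifnot(inherits(straightened, "straightened_filament"))
  px <- straightened$pixel_size_nm
  v <- straightened$values
  n_ax <- nrow(v)
  if (is.null(boundaries_nm)) {
    prof <- axial_mean_profile(straightened)
    pos_nm <- (detect_bead_peaks(prof$value) - 1) * px
    if (!is.null(period_nm)) {
      start <- if (length(pos_nm)) pos_nm[1] else 0
      boundaries_nm <- seq(start, n_ax * px, by = period_nm)
    } else {
      boundaries_nm <- pos_nm
    }
  }
  boundaries_nm <- sort(boundaries_nm)
  if (length(boundaries_nm) < 2L)
    return(empty_repeat_stack(px))
  win_nm <- diff(boundaries_nm)
  len <- max(2L, round(stats::median(win_nm) / px))
  windows <- vector("list", length(win_nm))
  cols <- seq_len(ncol(v))
  for (k in seq_along(win_nm)) {
    # half-open [b_k, b_{k+1}): rows sampled at len points across the repeat
    pos_px <- boundaries_nm[k] / px + (seq_len(len) - 1L) * (win_nm[k] / px) / len
    rows <- pmin(pmax(pos_px + 1, 1), n_ax)
    windows[[k]] <- matrix(bilinear_sample(v, rep(rows, length(cols)),
                                           rep(cols, each = len)),
                           nrow = len)
  }
  structure(list(windows = windows, shifts_nm = rep(0, length(windows)),
                 pixel_size_nm = px, window_len = len),
            class = "repeat_stack")
}

empty_repeat_stack <- function(px) {
  structure(list(windows = list(), shifts_nm = numeric(),
                 pixel_size_nm = px, window_len = 0L),
            class = "repeat_stack")
}

#' Combine repeat stacks from several filaments
#'
#' Stacks must share pixel size; windows are resampled to the first
#' stack's axial length if they differ.
#'
#' @param ... \code{repeat_stack} objects.
#' @return one combined \code{repeat_stack}.
#' @export
bind_repeat_stacks <- function(...) {
  stacks <- Filter(function(s) length(s$windows) > 0, list(...))
  if (!length(stacks)) stopf("no non-empty stacks to combine")
  px <- stacks[[1]]$pixel_size_nm
  len <- stacks[[1]]$window_len
  if (any(abs(vapply(stacks, `[[`, 0, "pixel_size_nm") - px) > 1e-9))
    stopf("stacks have different pixel sizes")
  windows <- list()
  for (s in stacks) {
    w <- s$windows
    if (s$window_len != len) {
      w <- lapply(w, function(m) {
        rows <- 1 + (seq_len(len) - 1L) * (nrow(m) - 1L) / (len - 1L)
        matrix(bilinear_sample(m, rep(rows, ncol(m)),
                               rep(seq_len(ncol(m)), each = len)),
               nrow = len)
      })
    }
    windows <- c(windows, w)
  }
  structure(list(windows = windows, shifts_nm = rep(0, length(windows)),
                 pixel_size_nm = px, window_len = len),
            class = "repeat_stack")
}

#' @export
print.repeat_stack <- function(x, ...) {
  cat(sprintf("Repeat stack: %d windows of %d axial px (%.2f nm)\n",
              length(x$windows), x$window_len,
              x$window_len * x$pixel_size_nm))
  invisible(x)
}

# Circular sub-sample shift of a vector by `delta` samples (positive
# delta moves content toward higher indices), linear interpolation.
shift_circular <- function(v, delta) {
  n <- length(v)
  idx <- (seq_len(n) - 1 - delta) %% n
  i0 <- floor(idx); fr <- idx - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  (1 - fr) * v[i0] + fr * v[i1]
}

# Best circular lag aligning p to ref (lag to apply to p), sub-sample.
# max_lag (samples) restricts the search to small shifts.
best_circular_lag <- function(ref, p, max_lag = Inf) {
  n <- length(ref)
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(p)), inverse = TRUE)) / n
  if (is.finite(max_lag)) {
    lags <- c(0:(n - 1))
    lags[lags > n / 2] <- lags[lags > n / 2] - n
    cc[abs(lags) > max_lag] <- -Inf
  }
  i <- which.max(cc)
  lag <- i - 1L
  off <- parabolic_offset(c(cc[((i - 2) %% n) + 1L], cc[i],
                            cc[(i %% n) + 1L]), 2L)
  lag <- lag + off
  if (lag > n / 2) lag <- lag - n
  lag
}

# Iterative translational alignment of the rows of a profile matrix
# (columns = repeats) to the running average.  Returns cumulative
# shifts in samples and the aligned matrix.
align_1d_stack <- function(mat, max_iter = 25L, tol_samples = 0.02) {
  n_rep <- ncol(mat)
  shifts <- rep(0, n_rep)
  aligned <- mat
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ref <- rowMeans(aligned)
    upd <- vapply(seq_len(n_rep),
                  function(j) best_circular_lag(ref, aligned[, j]), 0)
    for (j in seq_len(n_rep)) aligned[, j] <- shift_circular(aligned[, j], upd[j])
    shifts <- shifts + upd
    if (mean(abs(upd)) < tol_samples) { converged <- TRUE; break }
  }
  list(aligned = aligned, shifts = shifts, converged = converged,
       iterations = it)
}

#' Align and average a repeat stack
#'
#' Iterative translational alignment of each repeat to the running
#' average by circular 1D cross-correlation of the axial mean profiles
#' (sub-pixel, parabolic interpolation of the correlation peak),
#' followed by averaging.  Rotational alignment is unnecessary because
#' straightening already removes in-plane rotation.  The averaged
#' window is returned together with its axial mean profile, re-centered
#' so the bead peak sits at position 0 on a grid covering one period.
#'
#' @param stack a \code{repeat_stack} with at least 2 windows.
#' @param max_iter maximum alignment iterations.
#' @param tol_nm convergence tolerance on the mean shift update (nm).
#' @param center \code{"peak"} re-centers the averaged profile on its
#'   global maximum (the bead, when the bead dominates);
#'   \code{"boundary"} keeps the window cut position (the detected or
#'   supplied bead boundary) at position 0 -- use this when heavy
#'   decoration could outweigh the bead peak.
#' @return list with \code{average} (2D window), \code{profile}
#'   (\code{\link{axial_profile}}, bead at 0), \code{shifts_nm}
#'   (per-repeat cumulative shift), \code{converged}, \code{iterations}.
#' @export
align_average <- function(stack, max_iter = 25L, tol_nm = 0.01,
                          center = c("peak", "boundary")) {
  center <- match.arg(center)
  stopifnot(inherits(stack, "repeat_stack"))
  n_rep <- length(stack$windows)
  if (n_rep < 2L) stopf("alignment needs at least 2 repeats")
  px <- stack$pixel_size_nm
  profs <- vapply(stack$windows, rowMeans, numeric(stack$window_len))
  res <- align_1d_stack(profs, max_iter = max_iter,
                        tol_samples = tol_nm / px)
  if (!res$converged)
    warning("alignment did not converge in max_iter iterations; returning best")
  # apply the 1D shifts to the 2D windows, column by column
  avg <- matrix(0, stack$window_len, ncol(stack$windows[[1]]))
  for (j in seq_len(n_rep)) {
    w <- stack$windows[[j]]
    for (cc in seq_len(ncol(w))) w[, cc] <- shift_circular(w[, cc], res$shifts[j])
    avg <- avg + w / n_rep
  }
  prof_v <- rowMeans(avg)
  prof <- center_profile_on_peak(prof_v, px,
                                 at = if (center == "peak") NULL else 1L)
  list(average = avg, profile = prof, shifts_nm = res$shifts * px,
       converged = res$converged, iterations = res$iterations)
}

# Rotate a periodic profile so its global maximum (the bead) -- or the
# supplied index `at` -- sits at position 0, grid spanning [-P/2, P/2).
center_profile_on_peak <- function(v, step_nm, at = NULL) {
  n <- length(v)
  half <- floor(n / 2)
  at <- at %||% which.max(v)
  out <- v[((at - 1L) + (seq_len(n) - 1L - half)) %% n + 1L]
  axial_profile((seq_len(n) - 1L - half) * step_nm, out,
                unit = "intensity", period_nm = n * step_nm)
}
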