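#' Construct a filament trace
#'
#' An ordered polyline of sub-pixel (x, y) positions (0-based pixel
#' coordinates) following one filament axis.
#'
#' @param x,y numeric coordinate vectors (>= 2 points, no zero-length
#'   segments).
#' @return object of class \code{"filament_trace"}.
#' @export
filament_trace <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stopf("a trace needs at least two (x, y) points")
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg <= 0)) stopf("trace arc length must be strictly increasing")
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "filament_trace")
}

#' Arc length of a trace in pixels
#' @param trace a \code{\link{filament_trace}}.
#' @return total arc length (px).
#' @export
trace_length_px <- function(trace) {
  sum(sqrt(diff(trace$x)^2 + diff(trace$y)^2))
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("Filament trace: %d points, arc length %.1f px\n",
              length(x$x), trace_length_px(x)))
  invisible(x)
}

# Normalize polarity so filaments are bright: stain exclusion appears
# bright in negative stain; dark-on-bright images are sign-flipped.
normalize_polarity <- function(v) {
  med <- stats::median(v)
  hi <- stats::quantile(v, 0.999) - med
  lo <- med - stats::quantile(v, 0.001)
  if (lo > hi) med - v else v - med
}

#' Trace filaments by ridge following
#'
#' Finds intensity ridges in a micrograph and follows them to produce
#' filament traces.  The image is polarity-normalized (filaments
#' bright), then smoothed heavily (sigma = 2 x expected width) so that
#' the beaded axial modulation does not break the ridge; the follower
#' steps along the ridge, re-centering transversely on the smoothed
#' intensity at every step, and each finished trace is trimmed back to
#' its outermost axial intensity peaks (the terminal beads) measured on
#' a lightly smoothed image.  Without seed points, seeds are taken
#' iteratively at the brightest unclaimed pixel.
#'
#' @param mg a \code{\link{micrograph}}.
#' @param expected_width_px approximate transverse sigma of a filament
#'   in pixels (>= 2).
#' @param seed_points optional data frame of starting points (columns
#'   \code{x}, \code{y}, 0-based px); one trace is attempted per seed.
#' @param min_length_nm traces shorter than this are discarded (default
#'   two repeats of a ~58 nm period).
#' @param max_traces cap on the number of auto-seeded traces.
#' @return list of \code{\link{filament_trace}} objects (possibly
#'   empty).
#' @export
trace_filaments <- function(mg, expected_width_px = 8, seed_points = NULL,
                            min_length_nm = 116, max_traces = 50L) {
  stopifnot(inherits(mg, "micrograph"))
  if (expected_width_px < 2) stopf("expected_width_px must be >= 2 px")
  v <- normalize_polarity(mg$values)
  # three scales: heavy bridges the beaded axial modulation (seed/stop
  # decisions), medium keeps the transverse ridge sharp (re-centering),
  # light preserves the bead peaks (end trimming)
  sigma_heavy <- 2 * expected_width_px
  sm <- gauss_smooth_mat(v, sigma_heavy)
  smm <- gauss_smooth_mat(v, expected_width_px)
  sml <- gauss_smooth_mat(v, max(1, expected_width_px / 4))
  ny <- nrow(v); nx <- ncol(v)
  # noise floor of the heavily smoothed field: pixel noise attenuated by
  # the 2D Gaussian kernel norm
  sigma_n <- stats::mad(v - sml)
  sm_noise <- sigma_n / (2 * sqrt(pi) * sigma_heavy)
  bg <- stats::quantile(sm, 0.25, names = FALSE)
  peak_amp <- max(sm) - bg
  if (peak_amp <= max(10 * sm_noise, .Machine$double.eps * 100)) return(list())

  sample_sm <- function(x, y) bilinear_sample(sm, y + 1, x + 1, fill = -Inf)
  sample_smm <- function(x, y) bilinear_sample(smm, y + 1, x + 1, fill = -Inf)

  # Local line fit for re-centering: transverse intensity slices are
  # taken at several offsets along the current direction; each slice
  # with appreciable signal yields an intensity-weighted centroid, and
  # a weighted straight-line fit of centroid against axial offset gives
  # both the transverse correction (intercept) and the local direction
  # mismatch (slope).  Averaging over the axial window makes the beaded
  # modulation irrelevant, and measuring the slope directly avoids the
  # unstable feedback of displacement-based direction updates near the
  # filament ends, where the window holds signal on one side only.
  axial_avg_px <- 7 * expected_width_px
  recentre <- function(x, y, dxv, dyv, halfw) {
    nxv <- -dyv; nyv <- dxv
    toff <- seq(-halfw, halfw, by = 0.5)
    uoff <- seq(-axial_avg_px, axial_avg_px, by = 2)
    xs <- outer(toff * nxv, uoff * dxv, `+`) + x
    ys <- outer(toff * nyv, uoff * dyv, `+`) + y
    vals <- matrix(bilinear_sample(smm, ys + 1, xs + 1, fill = NA_real_),
                   nrow = length(toff))
    mins <- suppressWarnings(apply(vals, 2L, min, na.rm = TRUE))
    w <- sweep(vals, 2L, mins)
    w[!is.finite(w)] <- 0
    mass <- colSums(w)
    keep <- mass >= 0.3 * max(mass) & mass > 0
    if (sum(keep) < 5L) return(NULL)          # too little signal: stop
    cent <- colSums(w * toff)[keep] / mass[keep]
    u <- uoff[keep]; mw <- mass[keep]
    ubar <- sum(mw * u) / sum(mw)
    cbar <- sum(mw * cent) / sum(mw)
    denom <- sum(mw * (u - ubar)^2)
    slope <- if (denom > 0) sum(mw * (u - ubar) * (cent - cbar)) / denom else 0
    a <- cbar - slope * ubar                  # offset at the window center
    a <- max(min(a, 0.75), -0.75)
    slope <- max(min(slope, 0.3), -0.3)
    list(p = c(x + a * nxv, y + a * nyv), slope = slope)
  }

  init_direction <- function(x, y) {
    th <- seq(0, pi, length.out = 13L)[-13L]
    ray <- seq(1, 4 * expected_width_px, by = 1)
    score <- vapply(th, function(a) {
      dx <- cos(a); dy <- sin(a)
      mean(c(sample_sm(x + ray * dx, y + ray * dy),
             sample_sm(x - ray * dx, y - ray * dy)), na.rm = TRUE)
    }, 0)
    a <- th[which.max(score)]
    c(cos(a), sin(a))
  }

  follow <- function(x0, y0, dir, thr_stop) {
    xs <- x0; ys <- y0
    d <- dir
    for (step in seq_len(ceiling(3 * (nx + ny)))) {
      x <- xs[length(xs)] + d[1]
      y <- ys[length(ys)] + d[2]
      rc <- recentre(x, y, d[1], d[2], 2 * expected_width_px)
      if (is.null(rc)) break
      p <- rc$p
      if (p[1] < 0 || p[1] > nx - 1 || p[2] < 0 || p[2] > ny - 1) break
      if (sample_sm(p[1], p[2]) < thr_stop) break
      # blend the measured local direction (d + slope * normal) in
      dt <- d + rc$slope * c(-d[2], d[1])
      dt <- dt / sqrt(sum(dt^2))
      d <- 0.8 * d + 0.2 * dt
      d <- d / sqrt(sum(d^2))
      xs <- c(xs, p[1]); ys <- c(ys, p[2])
    }
    list(x = xs, y = ys)
  }

  trace_from <- function(sx, sy) {
    # climb to the local ridge before starting
    win_x <- round(max(0, sx - 2 * expected_width_px)):round(min(nx - 1, sx + 2 * expected_width_px))
    win_y <- round(max(0, sy - 2 * expected_width_px)):round(min(ny - 1, sy + 2 * expected_width_px))
    sub <- sm[win_y + 1, win_x + 1, drop = FALSE]
    k <- arrayInd(which.max(sub), dim(sub))
    sx <- win_x[k[2]]; sy <- win_y[k[1]]
    seed_val <- sm[win_y[k[1]] + 1, win_x[k[2]] + 1]
    if (seed_val - bg <= max(10 * sm_noise, .Machine$double.eps * 100))
      return(NULL)
    thr_stop <- bg + max(0.12 * (seed_val - bg), 6 * sm_noise)
    d0 <- init_direction(sx, sy)
    fwd <- follow(sx, sy, d0, thr_stop)
    bwd <- follow(sx, sy, -d0, thr_stop)
    x <- c(rev(bwd$x[-1]), fwd$x)
    y <- c(rev(bwd$y[-1]), fwd$y)
    if (length(x) < 3L) return(NULL)
    # light smoothing of the polyline: removes step-level jitter that
    # would otherwise inflate the local curvature estimate (done before
    # end trimming so boundary effects fall outside the kept range)
    x <- gauss_smooth_1d(x, expected_width_px / 2)
    y <- gauss_smooth_1d(y, expected_width_px / 2)
    keep <- c(TRUE, sqrt(diff(x)^2 + diff(y)^2) > 1e-6)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) return(NULL)
    # trim to outermost axial peaks on the lightly smoothed image
    cv <- bilinear_sample(sml, y + 1, x + 1, fill = 0)
    pk <- find_peaks(cv, min_prominence = 0.2 * (max(cv) - min(cv)))
    if (nrow(pk) >= 2L) {
      sel <- seq.int(min(pk$index), max(pk$index))
      x <- x[sel]; y <- y[sel]
    }
    if (length(x) < 2L) return(NULL)
    tr <- filament_trace(x, y)
    if (trace_length_px(tr) * mg$pixel_size_nm < min_length_nm) return(NULL)
    tr
  }

  traces <- list()
  if (!is.null(seed_points)) {
    for (i in seq_len(nrow(seed_points))) {
      tr <- trace_from(seed_points$x[i], seed_points$y[i])
      if (!is.null(tr)) traces[[length(traces) + 1L]] <- tr
    }
    return(traces)
  }
  claimed <- matrix(FALSE, ny, nx)
  thr_seed <- bg + max(10 * sm_noise, 0.15 * peak_amp)
  for (it in seq_len(max_traces)) {
    avail <- sm
    avail[claimed] <- -Inf
    i <- which.max(avail)
    if (!is.finite(avail[i]) || avail[i] <= thr_seed) break
    k <- arrayInd(i, dim(sm))
    tr <- trace_from(k[2] - 1L, k[1] - 1L)
    # claim the full smoothing halo so one filament seeds only once
    r <- ceiling(3 * expected_width_px + 2 * sigma_heavy)
    if (!is.null(tr)) {
      # drop re-traces of an already claimed filament
      hit <- claimed[cbind(pmin(pmax(round(tr$y) + 1L, 1L), ny),
                           pmin(pmax(round(tr$x) + 1L, 1L), nx))]
      if (mean(hit) > 0.5) tr <- NULL
    }
    if (is.null(tr)) {
      # claim a block around the failed seed so we do not loop
      rows <- max(1, k[1] - r):min(ny, k[1] + r)
      cols <- max(1, k[2] - r):min(nx, k[2] + r)
      claimed[rows, cols] <- TRUE
      next
    }
    for (j in seq_along(tr$x)) {
      rows <- max(1, round(tr$y[j]) + 1 - r):min(ny, round(tr$y[j]) + 1 + r)
      cols <- max(1, round(tr$x[j]) + 1 - r):min(nx, round(tr$x[j]) + 1 + r)
      claimed[rows, cols] <- TRUE
    }
    traces[[length(traces) + 1L]] <- tr
  }
  traces
}
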