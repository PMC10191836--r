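#' Straighten a filament into an axis-aligned lane
#'
#' Resamples the micrograph along the trace at one-pixel arc steps: row
#' i of the output is the bilinear resampling of the normal
#' cross-section at arc length i pixels, so the filament axis runs along
#' the first dimension and arc length is preserved.  Mirrors the
#' "straighten" preprocessing used before repeat-length measurement.
#'
#' @param mg a \code{\link{micrograph}}.
#' @param trace a \code{\link{filament_trace}}.
#' @param lane_width_px transverse lane width in pixels (odd values keep
#'   the axis on the central column).
#' @return object of class \code{"straightened_filament"}: list with
#'   \code{values} (rows = axial samples), \code{pixel_size_nm} and
#'   \code{trace}.
#' @export
straighten <- function(mg, trace, lane_width_px = 21) {
  stopifnot(inherits(mg, "micrograph"), inherits(trace, "filament_trace"))
  if (lane_width_px < 1) stopf("lane_width_px must be >= 1")
  rp <- resample_polyline(trace$x, trace$y, step_px = 1)
  tg <- polyline_tangent(rp$x, rp$y)
  # curvature: turning angle per unit arc; reject if normals cross
  ang <- atan2(tg$ty, tg$tx)
  dang <- diff(ang)
  dang <- atan2(sin(dang), cos(dang))
  curv <- max(abs(dang))                      # rad per px
  if (curv > 0 && (1 / curv) < lane_width_px / 2)
    stopf("trace curvature radius %.1f px < lane_width/2: normals cross",
          1 / curv)
  half <- (lane_width_px - 1) / 2
  toff <- seq(-half, half, by = 1)
  np <- length(rp$x); nt <- length(toff)
  xs <- rep(rp$x, nt) + rep(-tg$ty, nt) * rep(toff, each = np)
  ys <- rep(rp$y, nt) + rep(tg$tx, nt) * rep(toff, each = np)
  if (any(xs < 0 | xs > ncol(mg$values) - 1 | ys < 0 | ys > nrow(mg$values) - 1))
    stopf("lane leaves the image along the trace")
  vals <- bilinear_sample(mg$values, ys + 1, xs + 1)
  out <- matrix(vals, nrow = np, ncol = nt)
  structure(list(values = out, pixel_size_nm = mg$pixel_size_nm,
                 trace = trace, arc_length_px = rp$length),
            class = "straightened_filament")
}

#' @export
print.straightened_filament <- function(x, ...) {
  cat(sprintf("Straightened filament: %d axial x %d transverse px (%.1f nm)\n",
              nrow(x$values), ncol(x$values),
              nrow(x$values) * x$pixel_size_nm))
  invisible(x)
}

#' Axial mean profile of a straightened filament
#'
#' @param sf a \code{straightened_filament}.
#' @return an \code{\link{axial_profile}} (unit \code{"intensity"});
#'   positions start at 0 at the trace start.
#' @export
axial_mean_profile <- function(sf) {
  stopifnot(inherits(sf, "straightened_filament"))
  v <- rowMeans(sf$values)
  axial_profile(seq(0, by = sf$pixel_size_nm, length.out = length(v)), v,
                unit = "intensity",
                period_nm = length(v) * sf$pixel_size_nm)
}
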