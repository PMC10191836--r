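# Subparticle recentering: shift particle records aligned to the full
# repeat so that a sub-region (bead or arm) sits at the particle
# center.  The 3D offset, expressed in the reference (reconstruction)
# frame, is rotated by each particle's orientation, projected onto the
# image plane and applied to the centered coordinate; origins are reset
# to the sub-pixel remainder so extraction boxes land on integer
# pixels.  The Euler convention (ZYZ intrinsic, rot-tilt-psi in
# degrees) is shared with the particle generator and locked by
# round-trip tests.

#' ZYZ Euler rotation matrix
#'
#' \code{R = Rz(psi) Ry(tilt) Rz(rot)}, angles in degrees.
#'
#' @param rot,tilt,psi Euler angles (degrees).
#' @return 3x3 rotation matrix.
#' @export
euler_matrix <- function(rot, tilt, psi) {
  rz <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
  }
  ry <- function(a) {
    a <- a * pi / 180
    matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, byrow = TRUE)
  }
  rz(psi) %*% ry(tilt) %*% rz(rot)
}

particle_required_cols <- c("coordinate_x", "coordinate_y",
                            "euler_rot", "euler_tilt", "euler_psi",
                            "origin_x", "origin_y", "pixel_size_A")

#' Recenter particle records on a sub-region
#'
#' For each record the reference-frame offset \code{v} (Angstrom) is
#' rotated by the particle orientation, its in-plane components are
#' converted to pixels and added to the centered position (coordinate
#' minus origin); the new coordinate is the nearest integer pixel and
#' the new origin the sub-pixel remainder, so the centered position is
#' exact.  Angles and all other columns pass through unchanged.
#' Records whose recentered coordinate falls outside the micrograph (if
#' dimensions are given) are excluded and counted.
#'
#' @param records data frame with columns \code{coordinate_x},
#'   \code{coordinate_y} (px), \code{euler_rot}, \code{euler_tilt},
#'   \code{euler_psi} (degrees, ZYZ), \code{origin_x}, \code{origin_y}
#'   (px) and \code{pixel_size_A}.
#' @param v offset 3-vector (Angstrom) from the full-repeat center to
#'   the sub-region center, in the reference frame.
#' @param micrograph_px optional c(nx, ny) bounds for exclusion.
#' @return the recentered records; excluded rows are dropped and their
#'   count stored in attribute \code{"n_excluded"}.
#' @export
recenter_particles <- function(records, v, micrograph_px = NULL) {
  if (!all(particle_required_cols %in% names(records)))
    stopf("records must have columns %s",
          paste(particle_required_cols, collapse = ", "))
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v)))
    stopf("v must be a finite 3-vector (Angstrom)")
  px <- unique(records$pixel_size_A)
  if (length(px) != 1L) stopf("all records must share one pixel size")
  n <- nrow(records)
  dxy <- t(vapply(seq_len(n), function(i) {
    R <- euler_matrix(records$euler_rot[i], records$euler_tilt[i],
                      records$euler_psi[i])
    (R %*% v)[1:2] / px        # drop the beam-axis component, A -> px
  }, numeric(2)))
  cx <- records$coordinate_x - records$origin_x + dxy[, 1]
  cy <- records$coordinate_y - records$origin_y + dxy[, 2]
  out <- records
  out$coordinate_x <- round(cx)
  out$coordinate_y <- round(cy)
  out$origin_x <- round(cx) - cx
  out$origin_y <- round(cy) - cy
  excluded <- rep(FALSE, n)
  if (!is.null(micrograph_px)) {
    excluded <- cx < 0 | cx > micrograph_px[1] - 1 |
      cy < 0 | cy > micrograph_px[2] - 1
    out <- out[!excluded, , drop = FALSE]
  }
  attr(out, "n_excluded") <- sum(excluded)
  out
}

#' Centered particle positions
#'
#' The position each extraction box is centered on: coordinate minus
#' origin, in pixels.
#'
#' @param records particle record data frame.
#' @return two-column matrix (x, y) in px.
#' @export
particle_centers <- function(records) {
  cbind(x = records$coordinate_x - records$origin_x,
        y = records$coordinate_y - records$origin_y)
}
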