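#' Generate a Cn-symmetric test volume
#'
#' Places \code{n_fold} Gaussian blobs at equal angles on a ring about
#' the z axis in the central plane of a cubic box.  The construction is
#' analytic, so the volume is exactly Cn-symmetric up to grid
#' discretization.  Unequal \code{blob_amplitudes} produce a
#' pseudo-symmetric arrangement; optional seeded Gaussian noise can be
#' added on top.
#'
#' @param n_fold symmetry order (positive integer).
#' @param blob_radius_A Gaussian sigma of each blob (Angstrom).
#' @param ring_radius_A distance of blob centers from the axis
#'   (Angstrom); the ring plus 3 sigma must fit inside the box.
#' @param box_size_vox cubic box edge (voxels).
#' @param voxel_size_A voxel size (Angstrom).
#' @param blob_amplitudes optional numeric vector of length
#'   \code{n_fold} (default all 1).
#' @param noise_sd additive Gaussian noise s.d. (default 0).
#' @param seed RNG seed for the noise.
#' @param phase_deg angular offset of the first blob.
#' @return a \code{\link{density_volume}}.
#' @export
generate_symmetric_volume <- function(n_fold, blob_radius_A = 8,
                                      ring_radius_A = 40,
                                      box_size_vox = 64, voxel_size_A = 2,
                                      blob_amplitudes = NULL,
                                      noise_sd = 0, seed = 1L,
                                      phase_deg = 0) {
  if (n_fold < 1) stopf("n_fold must be a positive integer")
  half_A <- (box_size_vox / 2) * voxel_size_A
  if (ring_radius_A + 3 * blob_radius_A >= half_A)
    stopf("ring plus blob support does not fit inside the box")
  amps <- blob_amplitudes %||% rep(1, n_fold)
  if (length(amps) != n_fold) stopf("need one amplitude per blob")
  ctr <- (box_size_vox + 1) / 2
  ax <- (seq_len(box_size_vox) - ctr) * voxel_size_A
  xg <- rep(ax, times = box_size_vox)
  yg <- rep(ax, each = box_size_vox)
  plane_r2 <- function(cx, cy) (xg - cx)^2 + (yg - cy)^2
  vol <- array(0, dim = rep(box_size_vox, 3L))
  zg <- ax
  s2 <- 2 * blob_radius_A^2
  for (k in seq_len(n_fold)) {
    a <- 2 * pi * (k - 1) / n_fold + phase_deg * pi / 180
    cx <- ring_radius_A * cos(a)
    cy <- ring_radius_A * sin(a)
    plane <- amps[k] * exp(-plane_r2(cx, cy) / s2)
    for (iz in seq_len(box_size_vox)) {
      w <- exp(-zg[iz]^2 / s2)
      if (w > 1e-12)
        vol[, , iz] <- vol[, , iz] + matrix(plane * w, box_size_vox)
    }
  }
  if (noise_sd > 0) {
    vol <- vol + with_seed(seed, array(stats::rnorm(length(vol), 0, noise_sd),
                                       dim = dim(vol)))
  }
  density_volume(vol, voxel_size_A)
}

#' Annular mask around the blob ring of a synthetic volume
#'
#' Convenience mask for correlation analysis: a torus-like annulus
#' covering radius \code{ring_radius_A +/- width_A} within
#' \code{+/- width_A} of the central plane.
#'
#' @param box_size_vox,voxel_size_A lattice description.
#' @param ring_radius_A annulus center radius (Angstrom).
#' @param width_A annulus half-thickness (Angstrom).
#' @return binary \code{\link{density_volume}}.
#' @export
ring_mask <- function(box_size_vox, voxel_size_A, ring_radius_A,
                      width_A = 30) {
  ctr <- (box_size_vox + 1) / 2
  ax <- (seq_len(box_size_vox) - ctr) * voxel_size_A
  xg <- rep(ax, times = box_size_vox)
  yg <- rep(ax, each = box_size_vox)
  r <- sqrt(xg^2 + yg^2)
  ring <- abs(r - ring_radius_A) <= width_A
  vol <- array(0, dim = rep(box_size_vox, 3L))
  for (iz in seq_len(box_size_vox)) {
    if (abs(ax[iz]) <= width_A)
      vol[, , iz] <- matrix(as.numeric(ring), box_size_vox)
  }
  density_volume(vol, voxel_size_A)
}
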