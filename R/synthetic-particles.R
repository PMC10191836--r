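#' Generate a ground-truthed particle table
#'
#' Draws particle records (coordinates, ZYZ Euler angles, origin
#' shifts) from simple distributions and computes, from the same
#' generative model used by \code{\link{recenter_particles}}, the true
#' sub-region center of every particle for a given reference-frame
#' offset.
#'
#' @param n_particles number of records (>= 1).
#' @param true_offset_A reference-frame offset 3-vector (Angstrom).
#' @param angle_distribution \code{"uniform"} (rot and psi uniform on
#'   (-180, 180], tilt with uniform cos) or \code{"zero"} (all angles
#'   0).
#' @param seed RNG seed.
#' @param pixel_size_A pixel size (Angstrom).
#' @param box_size_px extraction box (px).
#' @param micrograph_px c(nx, ny) micrograph size (px).
#' @param origin_range_px origins drawn uniformly in +/- this range.
#' @return data frame of particle records with extra ground-truth
#'   columns \code{true_center_x}, \code{true_center_y} (px).
#' @export
generate_particle_set <- function(n_particles, true_offset_A = c(0, 0, 0),
                                  angle_distribution = c("uniform", "zero"),
                                  seed = 1L, pixel_size_A = 2.2,
                                  box_size_px = 256L,
                                  micrograph_px = c(4096L, 4096L),
                                  origin_range_px = 5) {
  if (n_particles < 1L) stopf("n_particles must be >= 1")
  angle_distribution <- match.arg(angle_distribution)
  v <- as.numeric(true_offset_A)
  if (length(v) != 3L) stopf("true_offset_A must be a 3-vector")
  df <- with_seed(seed, {
    margin <- box_size_px / 2
    cx <- round(stats::runif(n_particles, margin, micrograph_px[1] - margin))
    cy <- round(stats::runif(n_particles, margin, micrograph_px[2] - margin))
    ox <- stats::runif(n_particles, -origin_range_px, origin_range_px)
    oy <- stats::runif(n_particles, -origin_range_px, origin_range_px)
    if (angle_distribution == "uniform") {
      rot <- stats::runif(n_particles, -180, 180)
      psi <- stats::runif(n_particles, -180, 180)
      tilt <- acos(stats::runif(n_particles, -1, 1)) * 180 / pi
    } else {
      rot <- psi <- tilt <- rep(0, n_particles)
    }
    data.frame(micrograph_id = sprintf("mic%04d", ((seq_len(n_particles) - 1L) %/% 50L) + 1L),
               coordinate_x = cx, coordinate_y = cy,
               euler_rot = rot, euler_tilt = tilt, euler_psi = psi,
               origin_x = ox, origin_y = oy,
               box_size = as.integer(box_size_px),
               pixel_size_A = pixel_size_A)
  })
  dxy <- t(vapply(seq_len(n_particles), function(i) {
    R <- euler_matrix(df$euler_rot[i], df$euler_tilt[i], df$euler_psi[i])
    (R %*% v)[1:2] / pixel_size_A
  }, numeric(2)))
  df$true_center_x <- df$coordinate_x - df$origin_x + dxy[, 1]
  df$true_center_y <- df$coordinate_y - df$origin_y + dxy[, 2]
  df
}
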