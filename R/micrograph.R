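#' Construct a micrograph
#'
#' A micrograph is a 2D intensity grid with a physical pixel size.  The
#' value matrix is indexed \code{values[y + 1, x + 1]} for the 0-based
#' pixel coordinate (x, y), with x rightward and y downward.
#'
#' @param values numeric matrix of finite intensities.
#' @param pixel_size_nm pixel size in nm (> 0).
#' @return object of class \code{"micrograph"}.
#' @export
micrograph <- function(values, pixel_size_nm) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stopf("micrograph values must be a finite numeric matrix")
  if (pixel_size_nm <= 0) stopf("pixel_size_nm must be positive")
  structure(list(values = values, pixel_size_nm = pixel_size_nm),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("Micrograph: %d x %d px at %.4g nm/px (%.3g x %.3g nm)\n",
              ncol(x$values), nrow(x$values), x$pixel_size_nm,
              ncol(x$values) * x$pixel_size_nm,
              nrow(x$values) * x$pixel_size_nm))
  invisible(x)
}

#' @export
plot.micrograph <- function(x, ...) {
  v <- t(x$values)[, rev(seq_len(nrow(x$values))), drop = FALSE]
  graphics::image(z = v, col = grDevices::gray.colors(256), asp = nrow(x$values) / ncol(x$values),
                  axes = FALSE, ...)
  invisible(x)
}

#' Construct a density volume
#'
#' A 3D density map with cubic voxels.  Values are indexed
#' \code{values[x, y, z]} (1-based), matching the storage order of MRC
#' maps (x fastest).
#'
#' @param values numeric 3D array.
#' @param voxel_size_A voxel edge length in Angstrom (> 0).
#' @param origin optional origin offset in voxels (length-3 numeric).
#' @return object of class \code{"density_volume"}.
#' @export
density_volume <- function(values, voxel_size_A, origin = c(0, 0, 0)) {
  if (!(is.array(values) && length(dim(values)) == 3L))
    stopf("volume values must be a 3D array")
  if (!all(is.finite(values))) stopf("volume values must be finite")
  if (voxel_size_A <= 0) stopf("voxel_size_A must be positive")
  structure(list(values = values, voxel_size_A = voxel_size_A,
                 origin = origin),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Density volume: %d x %d x %d voxels at %.3g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size_A))
  invisible(x)
}
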