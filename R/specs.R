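#' Describe a beaded filament for the synthetic generator
#'
#' A fibril specification lists the axial mass features of one repeat
#' (bead, arms, interbead, shoulder, or custom components), the repeat
#' period, and how many repeats to render.  Each feature is rendered as a
#' truncated Gaussian (support limited to +/- 3 sigma) normalized so that
#' its integral over one period equals its mass in kDa; the sum of
#' feature masses is the repeat mass.
#'
#' @param period_nm repeat period in nm (> 0).
#' @param features data frame with columns \code{name} (one of
#'   \code{"bead"}, \code{"arm"}, \code{"interbead"}, \code{"shoulder"},
#'   \code{"custom"}), \code{center_nm} in [0, period), \code{width_nm}
#'   (Gaussian sigma, > 0) and \code{mass_kDa} (>= 0).
#' @param n_repeats number of repeats rendered along the filament.
#' @param path optional polyline, a data frame / list with \code{x} and
#'   \code{y} in pixel coordinates (0-based); when \code{NULL} the
#'   renderer lays the filament out as a horizontal line.
#' @return object of class \code{"fibril_spec"}; the derived repeat mass
#'   is available as \code{$repeat_mass_kDa}.
#' @export
fibril_spec <- function(period_nm, features, n_repeats = 10L, path = NULL) {
  if (!is.numeric(period_nm) || length(period_nm) != 1L || period_nm <= 0)
    stopf("period_nm must be a single positive length")
  features <- as.data.frame(features)
  need <- c("name", "center_nm", "width_nm", "mass_kDa")
  if (!all(need %in% names(features)))
    stopf("features must have columns %s", paste(need, collapse = ", "))
  ok_names <- c("bead", "arm", "interbead", "shoulder", "custom")
  if (!all(features$name %in% ok_names))
    stopf("feature names must be one of %s", paste(ok_names, collapse = ", "))
  if (any(features$center_nm < 0 | features$center_nm >= period_nm))
    stopf("every feature center_nm must lie in [0, period_nm)")
  if (any(features$width_nm <= 0))
    stopf("zero- or negative-width features are not allowed")
  if (any(features$mass_kDa < 0))
    stopf("feature masses must be nonnegative")
  if (n_repeats < 1L) stopf("n_repeats must be a positive integer")
  structure(list(period_nm = period_nm, features = features,
                 n_repeats = as.integer(n_repeats), path = path,
                 repeat_mass_kDa = sum(features$mass_kDa)),
            class = "fibril_spec")
}

#' Describe ligand decoration of a fibril repeat
#'
#' Decoration adds ligand mass at a fixed axial position in every repeat.
#' The mass added per repeat is \code{occupancy * (copies_per_repeat *
#' ligand_mass_kDa + associated_mass_kDa)}; the optional associated mass
#' models co-bound material that rides along with the ligand.
#'
#' @param ligand_mass_kDa mass of one ligand molecule (kDa, > 0).
#' @param copies_per_repeat integer number of ligand copies per repeat.
#' @param axial_center_nm axial position of the added mass within the
#'   repeat, in [0, period).
#' @param occupancy fraction of repeats (equivalently, of sites) occupied,
#'   in [0, 1].
#' @param width_nm Gaussian sigma of the added axial density (nm).
#' @param associated_mass_kDa extra co-bound mass per fully occupied
#'   repeat (kDa, default 0).
#' @return object of class \code{"decoration_spec"}.
#' @export
decoration_spec <- function(ligand_mass_kDa, copies_per_repeat = 1L,
                            axial_center_nm = 0, occupancy = 1,
                            width_nm = 3, associated_mass_kDa = 0) {
  if (ligand_mass_kDa <= 0) stopf("ligand_mass_kDa must be positive")
  if (copies_per_repeat < 0) stopf("copies_per_repeat must be nonnegative")
  if (occupancy < 0 || occupancy > 1) stopf("occupancy must lie in [0, 1]")
  if (width_nm <= 0) stopf("width_nm must be positive")
  if (associated_mass_kDa < 0) stopf("associated_mass_kDa must be nonnegative")
  structure(list(ligand_mass_kDa = ligand_mass_kDa,
                 copies_per_repeat = as.integer(copies_per_repeat),
                 axial_center_nm = axial_center_nm,
                 occupancy = occupancy, width_nm = width_nm,
                 associated_mass_kDa = associated_mass_kDa),
            class = "decoration_spec")
}

decoration_mass_kDa <- function(decoration) {
  if (is.null(decoration)) return(0)
  with(decoration,
       occupancy * (copies_per_repeat * ligand_mass_kDa + associated_mass_kDa))
}

#' Imaging conditions for the synthetic renderers
#'
#' @param pixel_size_nm physical pixel size (nm, > 0).
#' @param noise_sd standard deviation of additive Gaussian noise, in
#'   intensity units (>= 0).
#' @param background_level constant background intensity.
#' @param contrast_polarity \code{"bright_on_dark"} (stain exclusion /
#'   dark-field) or \code{"dark_on_bright"}.
#' @param seed integer RNG seed; identical seed and specs give
#'   bit-identical images.
#' @return object of class \code{"imaging_spec"}.
#' @export
imaging_spec <- function(pixel_size_nm = 0.5, noise_sd = 0,
                         background_level = 0,
                         contrast_polarity = c("bright_on_dark",
                                               "dark_on_bright"),
                         seed = 1L) {
  if (pixel_size_nm <= 0) stopf("pixel_size_nm must be positive")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  contrast_polarity <- match.arg(contrast_polarity)
  structure(list(pixel_size_nm = pixel_size_nm, noise_sd = noise_sd,
                 background_level = background_level,
                 contrast_polarity = contrast_polarity,
                 seed = as.integer(seed)),
            class = "imaging_spec")
}

#' Calibration rod for STEM mass mapping
#'
#' Describes a straight rod of known, constant mass per unit length used
#' as the internal calibration standard in dark-field mass mapping, such
#' as tobacco mosaic virus (131.4 kDa/nm).
#'
#' @param mul_kDa_per_nm nominal mass per unit length (kDa/nm, > 0).
#' @param length_nm rod length (nm).
#' @param width_nm apparent rod width (nm); the transverse intensity
#'   envelope uses sigma = width/4 so the rendered rod spans about one
#'   width.
#' @return object of class \code{"calibration_rod_spec"}.
#' @export
calibration_rod_spec <- function(mul_kDa_per_nm = 131.4, length_nm = 300,
                                 width_nm = 18) {
  if (mul_kDa_per_nm <= 0) stopf("mul_kDa_per_nm must be positive")
  if (length_nm <= 0 || width_nm <= 0)
    stopf("length_nm and width_nm must be positive")
  structure(list(mul_kDa_per_nm = mul_kDa_per_nm, length_nm = length_nm,
                 width_nm = width_nm),
            class = "calibration_rod_spec")
}

# -------------------------------------------------------------------------
# Presets.  These are data: the repeat geometries and masses of the study
# conditions (control, delta-H1 and WMS fibrillin microfibrils, LTBP-1
# decoration, TMV calibration rod).  Axial layout within the repeat (bead
# at 0, arms ~18 nm, interbead ~27 nm, shoulder ~35 nm) follows the
# negative-stain banding pattern, with the bead carrying ~1.1 MDa of the
# 3,055-kDa repeat and the remaining mass split uniformly over the other
# features.

.fibril_presets <- list(
  control = list(period_nm = 57.95, repeat_mass_kDa = 3055,
                 bead_mass_kDa = 1100, shoulder = TRUE),
  dh1     = list(period_nm = 57.14, repeat_mass_kDa = 3055,
                 bead_mass_kDa = 1100, shoulder = FALSE),
  wms     = list(period_nm = 55.21, repeat_mass_kDa = 3055,
                 bead_mass_kDa = 1100, shoulder = FALSE)
)

#' Built-in fibril condition presets
#'
#' Returns the generator specification for one of the study conditions:
#' \describe{
#'   \item{\code{"control"}}{wild-type repeat, period 57.95 nm, repeat
#'     mass 3,055 kDa with ~1.1 MDa in the bead and a distinct shoulder
#'     feature at ~35 nm from the bead center.}
#'   \item{\code{"dh1"}}{first-hybrid-domain deletion, period 57.14 nm;
#'     the shoulder feature is absent.}
#'   \item{\code{"wms"}}{TB1-PRR-EGF4 three-domain deletion
#'     (Weill-Marchesani syndrome), period 55.21 nm; shoulder absent.}
#' }
#'
#' @param name preset name.
#' @param n_repeats repeats per rendered filament.
#' @return a \code{fibril_spec}.
#' @seealso \code{\link{ltbp1_decoration}}, \code{\link{tmv_rod}}
#' @export
fibril_preset <- function(name = c("control", "dh1", "wms"),
                          n_repeats = 10L) {
  name <- match.arg(name)
  p <- .fibril_presets[[name]]
  non_bead <- p$repeat_mass_kDa - p$bead_mass_kDa
  # mutants keep the shoulder mass but as a diffuse component: the
  # feature is disordered (no longer a distinct peak), not removed
  feats <- data.frame(
    name = c("bead", "arm", "interbead", "shoulder"),
    center_nm = c(0, 18, 27, 35),
    width_nm = c(3.5, 3, 4, if (p$shoulder) 2.5 else 8),
    mass_kDa = c(p$bead_mass_kDa, rep(non_bead / 3, 3)))
  fibril_spec(p$period_nm, feats, n_repeats = n_repeats)
}

#' LTBP-1 decoration preset
#'
#' Two copies of the 151-kDa short splice form of LTBP-1 bound at the
#' bead.  With \code{measured_gain = TRUE} (default) the decoration also
#' carries 48.2 kDa of associated co-bound mass so that the total gain
#' per repeat is 350.2 kDa (the decorated repeat mass preset, 3,405 kDa);
#' with \code{measured_gain = FALSE} the decoration is the bare two-copy
#' stoichiometry (302 kDa).
#'
#' @param measured_gain logical, see Description.
#' @param occupancy site occupancy in [0, 1].
#' @return a \code{decoration_spec} centered on the bead.
#' @export
ltbp1_decoration <- function(measured_gain = TRUE, occupancy = 1) {
  decoration_spec(ligand_mass_kDa = 151, copies_per_repeat = 2L,
                  axial_center_nm = 0, occupancy = occupancy,
                  width_nm = 3,
                  associated_mass_kDa = if (measured_gain) 48.2 else 0)
}

#' Tobacco mosaic virus calibration rod preset
#'
#' @param length_nm rod length in nm.
#' @return a \code{calibration_rod_spec} at 131.4 kDa/nm, 18 nm width.
#' @export
tmv_rod <- function(length_nm = 300) {
  calibration_rod_spec(mul_kDa_per_nm = 131.4, length_nm = length_nm,
                       width_nm = 18)
}

#' Default analysis windows and constants
#'
#' Central place for tunable constants: the axial half-width of the bead
#' window used for mass-localization statements (11 nm, covering the
#' truncated bead Gaussian), and the protein density used to convert
#' thresholded map volume to mass (0.813 Da per cubic Angstrom,
#' equivalent to 1.35 g/cm^3).
#'
#' @return named list of defaults.
#' @export
fibrilkit_defaults <- function() {
  list(bead_window_half_nm = 11,
       protein_density_Da_per_A3 = 0.813,
       tmv_mul_kDa_per_nm = 131.4)
}
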