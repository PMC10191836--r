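# STEM dark-field mass mapping: net intensity extraction with local
# flanking-band background subtraction, calibration against a rod of
# known mass per unit length, integration to mass per repeat, and
# ligand-decoration analysis.

#' Net intensity-per-nm trace along a filament or rod
#'
#' Straightens a lane around the trace plus two flanking background
#' bands, and returns the per-axial-step lane sum minus the local
#' background (mean of the two bands times the lane width), divided by
#' the axial step in nm.  Axial steps whose background bands deviate
#' grossly from the global band level (another object entering the
#' band) are set to NA and excluded downstream.
#'
#' @param mg a \code{\link{micrograph}}.
#' @param trace a \code{\link{filament_trace}} along the object axis.
#' @param lane_width_px signal lane width (px).
#' @param band_gap_px gap between the lane edge and each background
#'   band (px).
#' @param band_width_px width of each background band (px).
#' @param band_outlier_mads reject axial steps whose band mean deviates
#'   from the median band level by more than this many MADs.
#' @return data frame of class \code{"intensity_trace"} with columns
#'   \code{position_nm} and \code{intensity_per_nm} (NA where
#'   rejected); pixel size kept as an attribute.
#' @export
net_intensity_profile <- function(mg, trace, lane_width_px = 25,
                                  band_gap_px = 6, band_width_px = 8,
                                  band_outlier_mads = 6) {
  stopifnot(inherits(mg, "micrograph"))
  total_w <- lane_width_px + 2 * (band_gap_px + band_width_px)
  if (total_w %% 2 == 0) total_w <- total_w + 1L
  sf <- straighten(mg, trace, lane_width_px = total_w)
  v <- sf$values
  mid <- (ncol(v) + 1) / 2
  half_lane <- (lane_width_px - 1) / 2
  lane_cols <- which(abs(seq_len(ncol(v)) - mid) <= half_lane)
  band_cols <- which(abs(seq_len(ncol(v)) - mid) > half_lane + band_gap_px)
  lane_sum <- rowSums(v[, lane_cols, drop = FALSE])
  band_mean <- rowMeans(v[, band_cols, drop = FALSE])
  bm_med <- stats::median(band_mean)
  bm_mad <- stats::mad(band_mean)
  bad <- bm_mad > 0 & abs(band_mean - bm_med) > band_outlier_mads * bm_mad
  net <- (lane_sum - band_mean * length(lane_cols)) / sf$pixel_size_nm
  net[bad] <- NA_real_
  structure(data.frame(position_nm = (seq_along(net) - 1) * sf$pixel_size_nm,
                       intensity_per_nm = net),
            pixel_size_nm = sf$pixel_size_nm,
            n_rejected = sum(bad),
            class = c("intensity_trace", "data.frame"))
}

#' Calibrate intensity to mass per unit length
#'
#' Computes the calibration constant k (kDa/nm per net-intensity unit)
#' from the trace of a rod of known mass per unit length:
#' k = nominal MUL / mean(net intensity per nm).
#'
#' @param rod_trace an \code{intensity_trace} measured on the rod.
#' @param rod_spec the \code{\link{calibration_rod_spec}} (nominal MUL).
#' @param trim fraction of the rod trace trimmed at each end before
#'   averaging (rod ends taper).
#' @return object of class \code{"calibration_result"}: list with
#'   \code{k}, \code{rod_mean_intensity_per_nm}, \code{rod_cv},
#'   \code{rod_spec}.
#' @export
calibrate <- function(rod_trace, rod_spec, trim = 0.1) {
  stopifnot(inherits(rod_spec, "calibration_rod_spec"))
  y <- rod_trace$intensity_per_nm
  pos <- rod_trace$position_nm
  keep <- is.finite(y)
  y <- y[keep]; pos <- pos[keep]
  if (length(pos) < 2L || diff(range(pos)) < 50)
    stopf("rod trace must span at least 50 nm")
  n <- length(y)
  cut <- floor(trim * n)
  if (cut > 0) y <- y[(cut + 1):(n - cut)]
  m <- mean(y)
  if (!is.finite(m) || m <= 0)
    stopf("rod mean net intensity must be positive")
  structure(list(k = rod_spec$mul_kDa_per_nm / m,
                 rod_mean_intensity_per_nm = m,
                 rod_cv = stats::sd(y) / m,
                 rod_spec = rod_spec),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration: k = %.5g kDa/nm per intensity unit (rod CV %.2f%%)\n",
              x$k, 100 * x$rod_cv))
  invisible(x)
}

#' Write a calibration result as JSON
#' @param calib a \code{calibration_result}.
#' @param path output path.
#' @export
write_calibration_json <- function(calib, path) {
  jsonlite::write_json(list(k_kDa_per_nm_per_intensity = calib$k,
                            rod_mean_intensity_per_nm = calib$rod_mean_intensity_per_nm,
                            rod_cv = calib$rod_cv,
                            rod_mul_kDa_per_nm = calib$rod_spec$mul_kDa_per_nm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a net intensity trace to calibrated MUL
#'
#' @param trace an \code{intensity_trace}.
#' @param calib a \code{calibration_result}.
#' @return data frame of class \code{"mul_profile"} with columns
#'   \code{position_nm}, \code{mul_kDa_per_nm}.
#' @export
apply_calibration <- function(trace, calib) {
  stopifnot(inherits(calib, "calibration_result"))
  structure(data.frame(position_nm = trace$position_nm,
                       mul_kDa_per_nm = trace$intensity_per_nm * calib$k),
            pixel_size_nm = attr(trace, "pixel_size_nm"),
            class = c("mul_profile", "data.frame"))
}

# Bead positions (nm) detected on a MUL profile, for bead-to-bead
# integration when ground truth is not supplied.
detect_bead_positions <- function(mul_profile) {
  y <- mul_profile$mul_kDa_per_nm
  y[!is.finite(y)] <- stats::median(y, na.rm = TRUE)
  step <- mul_profile$position_nm[2] - mul_profile$position_nm[1]
  ys <- gauss_smooth_1d(y, sigma = 2 / step)   # ~2 nm smoothing
  pos <- detect_bead_peaks(ys)
  if (!length(pos)) return(numeric())
  mul_profile$position_nm[1] + (pos - 1) * step
}

#' Integrate MUL to mass per repeat
#'
#' Trapezoidal integral of the calibrated mass-per-unit-length trace
#' over each bead-to-bead interval.  Boundaries may be supplied (e.g.
#' generator ground truth) or detected from the MUL trace itself.
#' Repeats whose mass deviates from the set median by more than 3
#' robust standard deviations are flagged, not dropped.
#'
#' @param mul_profile a \code{mul_profile}.
#' @param bead_positions_nm optional boundary positions (nm); when
#'   NULL, bead peaks are detected on the trace.
#' @param period_nm optional fixed period laid out from the first bead.
#' @param condition label for the resulting set.
#' @return object of class \code{"mass_per_repeat_set"}: list with
#'   \code{condition}, \code{masses_kDa}, \code{n}, \code{flagged}.
#' @export
mass_per_repeat <- function(mul_profile, bead_positions_nm = NULL,
                            period_nm = NULL, condition = "") {
  stopifnot(inherits(mul_profile, "mul_profile"))
  if (is.null(bead_positions_nm)) {
    bead_positions_nm <- detect_bead_positions(mul_profile)
    if (!is.null(period_nm) && length(bead_positions_nm) >= 1L) {
      bead_positions_nm <- seq(bead_positions_nm[1],
                               max(mul_profile$position_nm), by = period_nm)
    }
  }
  bead_positions_nm <- sort(bead_positions_nm)
  if (length(bead_positions_nm) < 2L)
    return(structure(list(condition = condition, masses_kDa = numeric(),
                          n = 0L, flagged = logical()),
                     class = "mass_per_repeat_set"))
  pos <- mul_profile$position_nm
  y <- mul_profile$mul_kDa_per_nm
  masses <- vapply(seq_len(length(bead_positions_nm) - 1L), function(k) {
    a <- bead_positions_nm[k]; b <- bead_positions_nm[k + 1L]
    sel <- pos >= a & pos <= b
    if (sum(sel) < 2L || anyNA(y[sel])) return(NA_real_)
    xs <- pos[sel]; ys <- y[sel]
    # extend to the exact interval ends by linear interpolation
    if (xs[1] > a) { ys <- c(stats::approx(pos, y, a)$y, ys); xs <- c(a, xs) }
    if (xs[length(xs)] < b) { ys <- c(ys, stats::approx(pos, y, b)$y); xs <- c(xs, b) }
    trapz(xs, ys)
  }, 0)
  keep <- is.finite(masses)
  masses <- masses[keep]
  med <- stats::median(masses)
  rsd <- stats::mad(masses)
  flagged <- if (rsd > 0) abs(masses - med) > 3 * rsd else rep(FALSE, length(masses))
  structure(list(condition = condition, masses_kDa = masses,
                 n = length(masses), flagged = flagged),
            class = "mass_per_repeat_set")
}

#' @export
print.mass_per_repeat_set <- function(x, ...) {
  if (x$n) {
    cat(sprintf("Mass per repeat ('%s'): n = %d, mean %.0f kDa, sd %.1f kDa (%d flagged)\n",
                x$condition, x$n, mean(x$masses_kDa),
                stats::sd(x$masses_kDa), sum(x$flagged)))
  } else cat(sprintf("Mass per repeat ('%s'): empty set\n", x$condition))
  invisible(x)
}

#' Bead-aligned average MUL trace over repeats
#'
#' Cuts the MUL trace at the given boundaries, resamples each repeat to
#' a common grid, aligns the repeats translationally and averages,
#' returning the average re-centered with the bead at position 0 on a
#' grid spanning [-P/2, P/2).
#'
#' @param mul_profile a \code{mul_profile}.
#' @param bead_positions_nm repeat boundaries (nm); detected when NULL.
#' @return an \code{\link{axial_profile}} in kDa/nm, bead at 0.
#' @export
average_mul_per_repeat <- function(mul_profile, bead_positions_nm = NULL) {
  stopifnot(inherits(mul_profile, "mul_profile"))
  if (is.null(bead_positions_nm))
    bead_positions_nm <- detect_bead_positions(mul_profile)
  bead_positions_nm <- sort(bead_positions_nm)
  if (length(bead_positions_nm) < 2L)
    stopf("need at least one full repeat to average")
  pos <- mul_profile$position_nm
  y <- mul_profile$mul_kDa_per_nm
  step <- pos[2] - pos[1]
  P <- stats::median(diff(bead_positions_nm))
  len <- max(4L, round(P / step))
  segs <- list()
  for (k in seq_len(length(bead_positions_nm) - 1L)) {
    a <- bead_positions_nm[k]; b <- bead_positions_nm[k + 1L]
    xs <- a + (seq_len(len) - 1L) * (b - a) / len
    v <- stats::approx(pos, y, xout = xs, rule = 2)$y
    if (!anyNA(v)) segs[[length(segs) + 1L]] <- v
  }
  if (length(segs) < 1L) stopf("no usable repeats")
  mat <- do.call(cbind, segs)
  if (ncol(mat) > 1L) mat <- align_1d_stack(mat)$aligned
  avg <- rowMeans(mat)
  prof <- center_profile_on_peak(avg, P / len)
  attr(prof, "unit") <- "kDa/nm"
  prof
}

#' Quantify ligand-decoration mass gain and its localization
#'
#' Compares mass-per-repeat sets with and without ligand: the increase
#' is the difference of set means (with s.d. combined in quadrature),
#' its significance an unpaired two-tailed pooled t-test, and the
#' localization trace the difference of the bead-aligned average MUL
#' traces.  The axial window containing at least half the added mass is
#' reported against the bead window.
#'
#' @param bare list with \code{mass_set} (a \code{mass_per_repeat_set})
#'   and \code{mul_avg} (bead-centered \code{axial_profile} in kDa/nm).
#' @param decorated same structure for the decorated condition.
#' @param ligand_mass_kDa single-ligand mass used to round the gain to
#'   a copy number.
#' @param bead_window_half_nm half-width of the bead window (nm).
#' @return object of class \code{"decoration_result"}: list with
#'   \code{increase_kDa}, \code{increase_sd_kDa}, \code{t_test},
#'   \code{localization} (difference \code{axial_profile}),
#'   \code{bead_fraction}, \code{copies_per_repeat}.
#' @export
decoration_analysis <- function(bare, decorated, ligand_mass_kDa = 151,
                                bead_window_half_nm =
                                  fibrilkit_defaults()$bead_window_half_nm) {
  ms_b <- bare$mass_set; ms_d <- decorated$mass_set
  stopifnot(inherits(ms_b, "mass_per_repeat_set"),
            inherits(ms_d, "mass_per_repeat_set"))
  if (ms_b$n < 2L || ms_d$n < 2L) stopf("both mass sets need n >= 2")
  pa <- bare$mul_avg; pd <- decorated$mul_avg
  if (nrow(pa) != nrow(pd) ||
      abs(profile_step(pa) - profile_step(pd)) > 0.02 * profile_step(pa))
    stopf("averaged MUL traces are not on a common grid")
  increase <- mean(ms_d$masses_kDa) - mean(ms_b$masses_kDa)
  inc_sd <- sqrt(stats::sd(ms_d$masses_kDa)^2 + stats::sd(ms_b$masses_kDa)^2)
  tt <- unpaired_t_test(ms_d$masses_kDa, ms_b$masses_kDa)
  dv <- pd$value - pa$value
  loc <- axial_profile(pa$position_nm, dv, unit = "kDa/nm",
                       period_nm = attr(pa, "period_nm"))
  total_added <- sum(dv) * profile_step(pa)
  in_bead <- abs(pa$position_nm) <= bead_window_half_nm
  bead_added <- sum(dv[in_bead]) * profile_step(pa)
  bead_fraction <- if (abs(total_added) > 1e-8) bead_added / total_added else NA_real_
  structure(list(increase_kDa = increase, increase_sd_kDa = inc_sd,
                 t_test = tt, localization = loc,
                 bead_fraction = bead_fraction,
                 bead_window_half_nm = bead_window_half_nm,
                 copies_per_repeat = round(increase / ligand_mass_kDa)),
            class = "decoration_result")
}

#' @export
print.decoration_result <- function(x, ...) {
  cat(sprintf("Decoration gain: %.1f +/- %.1f kDa per repeat (p = %.3g)\n",
              x$increase_kDa, x$increase_sd_kDa, x$t_test$p))
  if (is.finite(x$bead_fraction))
    cat(sprintf("  %.0f%% of the added mass lies within +/- %.0f nm of the bead\n",
                100 * x$bead_fraction, x$bead_window_half_nm))
  cat(sprintf("  ~%d ligand copies per repeat\n", x$copies_per_repeat))
  invisible(x)
}
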