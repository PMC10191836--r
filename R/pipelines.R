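# High-level recovery pipelines tying the generator to the measurement
# chain.  These are the workflows a validation study runs: simulate
# filaments under a named condition, push them through tracing,
# straightening and period measurement (or through dark-field mass
# mapping), and return the measured quantities next to the ground
# truth.

#' Simulate filaments and recover their periodicity
#'
#' Renders \code{n_filaments} noisy filaments of the given condition
#' preset, traces each automatically, straightens along the trace and
#' measures bead-to-bead periods, pooling all filaments.
#'
#' @param condition preset name (\code{"control"}, \code{"dh1"},
#'   \code{"wms"}).
#' @param n_filaments number of filaments.
#' @param n_repeats repeats per filament.
#' @param seed base RNG seed; filament i uses seed + i.
#' @param pixel_size_nm,noise_sd imaging conditions.
#' @return a \code{\link{period_set}} with attribute
#'   \code{"true_period_nm"}.
#' @export
run_period_recovery <- function(condition, n_filaments = 6L,
                                n_repeats = 20L, seed = 1L,
                                pixel_size_nm = 0.5, noise_sd = 0.3) {
  spec <- fibril_preset(condition, n_repeats = n_repeats)
  periods <- numeric()
  fibril_id <- integer()
  for (i in seq_len(n_filaments)) {
    im <- imaging_spec(pixel_size_nm = pixel_size_nm, noise_sd = noise_sd,
                       seed = seed + i)
    r <- render_filament_image(spec, im)
    trs <- trace_filaments(r$micrograph,
                           expected_width_px = 4 / pixel_size_nm)
    for (tr in trs) {
      sf <- straighten(r$micrograph, tr,
                       lane_width_px = 2 * floor(5 / pixel_size_nm) + 1)
      p <- measure_periods(sf)
      periods <- c(periods, p)
      fibril_id <- c(fibril_id, rep(i, length(p)))
    }
  }
  ps <- period_set(condition, periods)
  ps$fibril_id <- fibril_id
  attr(ps, "true_period_nm") <- spec$period_nm
  ps
}

#' Simulate STEM fields and recover mass per repeat
#'
#' Renders annular dark-field fields each holding fibrils and a
#' TMV-like calibration rod, extracts net intensity traces along the
#' known lanes, calibrates against the rod, integrates bead-to-bead to
#' mass per repeat (bead boundaries detected on the calibrated trace),
#' and accumulates a bead-aligned average MUL trace.
#'
#' @param decoration optional \code{\link{decoration_spec}} applied to
#'   every fibril.
#' @param n_fibrils fibrils per field.
#' @param n_repeats repeats per fibril.
#' @param n_fields number of independent fields.
#' @param seed base RNG seed.
#' @param pixel_size_nm,noise_sd imaging conditions.
#' @param condition label for the returned mass set.
#' @return list with \code{mass_set} (a \code{mass_per_repeat_set}),
#'   \code{mul_avg} (bead-centered average MUL
#'   \code{\link{axial_profile}}), \code{calibrations} (list of
#'   \code{calibration_result}), \code{true_repeat_mass_kDa}.
#' @export
run_stem_recovery <- function(decoration = NULL, n_fibrils = 5L,
                              n_repeats = 16L, n_fields = 1L, seed = 1L,
                              pixel_size_nm = 1, noise_sd = 0.5,
                              condition = "") {
  spec <- fibril_preset("control", n_repeats = n_repeats)
  masses <- numeric()
  avg_sum <- NULL
  n_avg <- 0L
  calibs <- list()
  for (f in seq_len(n_fields)) {
    im <- imaging_spec(pixel_size_nm = pixel_size_nm, noise_sd = noise_sd,
                       seed = seed + f)
    fld <- render_stem_field(replicate(n_fibrils, spec, simplify = FALSE),
                             im, decoration = decoration,
                             rod = tmv_rod(length_nm = 400),
                             lane_spacing_nm = 80)
    objs <- fld$ground_truth$objects
    rod_obj <- objs[[length(objs)]]
    rod_trace <- net_intensity_profile(fld$micrograph, rod_obj$trace,
                                       lane_width_px = 33 / pixel_size_nm,
                                       band_gap_px = 6, band_width_px = 8)
    cal <- calibrate(rod_trace, tmv_rod(length_nm = 400))
    calibs[[f]] <- cal
    for (k in seq_len(n_fibrils)) {
      nt <- net_intensity_profile(fld$micrograph, objs[[k]]$trace,
                                  lane_width_px = 33 / pixel_size_nm,
                                  band_gap_px = 6, band_width_px = 8)
      mul <- apply_calibration(nt, cal)
      beads <- detect_bead_positions(mul)
      # terminal beads are truncated by the fibril ends and their apex
      # estimates biased inward; keep interior repeats only
      if (length(beads) > 3L) beads <- beads[-c(1L, length(beads))]
      ms <- mass_per_repeat(mul, bead_positions_nm = beads)
      masses <- c(masses, ms$masses_kDa)
      if (length(beads) >= 3L) {
        avg <- average_mul_per_repeat(mul, bead_positions_nm = beads)
        if (is.null(avg_sum)) {
          avg_sum <- avg$value
          avg_grid <- avg$position_nm
          avg_period <- attr(avg, "period_nm")
        } else if (length(avg$value) == length(avg_sum)) {
          avg_sum <- avg_sum + avg$value
        }
        n_avg <- n_avg + 1L
      }
    }
  }
  mass_set <- structure(list(condition = condition, masses_kDa = masses,
                             n = length(masses),
                             flagged = rep(FALSE, length(masses))),
                        class = "mass_per_repeat_set")
  mul_avg <- if (n_avg > 0L)
    axial_profile(avg_grid, avg_sum / n_avg, unit = "kDa/nm",
                  period_nm = avg_period) else NULL
  list(mass_set = mass_set, mul_avg = mul_avg, calibrations = calibs,
       true_repeat_mass_kDa = spec$repeat_mass_kDa +
         decoration_mass_kDa(decoration))
}
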