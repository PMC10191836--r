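#' Measure bead-to-bead periodicities
#'
#' Locates bead peaks on the axial mean profile of a straightened
#' filament (or on a supplied axial profile) by prominence-filtered peak
#' detection with sub-pixel parabolic refinement, and returns the
#' consecutive peak-to-peak distances in nm.  Bead peaks are the
#' dominant axial feature; detected peaks are kept when their prominence
#' reaches both 3x the robust noise of the profile and half the largest
#' prominence, which rejects the weaker arm/interbead/shoulder peaks.
#'
#' @param filament a \code{straightened_filament} or
#'   \code{\link{axial_profile}}.
#' @param min_prominence optional absolute prominence floor overriding
#'   the noise-based default.
#' @return numeric vector of periods (nm); empty if fewer than two bead
#'   peaks are found.
#' @export
measure_periods <- function(filament, min_prominence = NULL) {
  if (inherits(filament, "straightened_filament")) {
    prof <- axial_mean_profile(filament)
  } else if (inherits(filament, "axial_profile")) {
    prof <- filament
  } else stopf("measure_periods needs a straightened filament or axial profile")
  v <- prof$value
  pos <- detect_bead_peaks(v, min_prominence = min_prominence)
  if (length(pos) < 2L) return(numeric())
  # a terminal bead cut by the series boundary has a biased apex: drop
  # the bordering interval when the peak's half-width leaves the series
  touches_edge <- function(p) {
    i <- max(1L, min(length(v), round(p)))
    hw <- peak_fwhm(v, i) / 2
    (p - hw) < 1 || (p + hw) > length(v)
  }
  if (touches_edge(pos[1])) pos <- pos[-1]
  if (length(pos) >= 2L && touches_edge(pos[length(pos)]))
    pos <- pos[-length(pos)]
  if (length(pos) < 2L) return(numeric())
  diff(pos) * profile_step(prof)
}

# Dominant period of a series (samples) from its circular
# autocorrelation; NA when no clear periodicity.
dominant_period_samples <- function(v, min_lag = 5L) {
  n <- length(v)
  if (n < 4L * min_lag) return(NA_real_)
  x <- v - mean(v)
  ac <- Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE))[1:(n %/% 2)]
  ac <- ac / ac[1]
  pk <- find_peaks(ac, min_prominence = 0.05)
  pk <- pk[pk$index > min_lag, , drop = FALSE]
  if (!nrow(pk)) return(NA_real_)
  # first substantial peak = fundamental (global max may sit on a
  # multiple when harmonics interfere)
  cand <- pk[pk$value >= 0.5 * max(pk$value), , drop = FALSE]
  i <- cand$index[1]
  i + parabolic_offset(ac, i)
}

# Bead peak positions (fractional sample index, sorted) of a beaded
# axial profile.  Peaks are prominence-filtered, then the dominant
# periodicity anchors a window walk from the strongest peak so that
# secondary intra-repeat features (arm, interbead, shoulder) are
# skipped; sub-sample parabolic refinement is applied at the end.
detect_bead_peaks <- function(v, min_prominence = NULL) {
  if (length(v) < 3L) return(numeric())
  noise <- robust_noise(v)
  floor_prom <- min_prominence %||% max(3 * noise, 0.02 * (max(v) - min(v)))
  pk <- find_peaks(v, min_prominence = floor_prom)
  if (nrow(pk) < 2L) return(refine_peaks(v, pk$index))
  P <- dominant_period_samples(v)
  n <- length(v)
  if (is.finite(P) && P > 4) {
    # candidate pool: every local maximum, including the series edges,
    # where a terminal bead has truncated prominence
    pool <- find_peaks(v, min_prominence = 0)$index
    if (v[1] >= v[2]) pool <- c(1L, pool)
    if (v[n] >= v[n - 1L]) pool <- c(pool, n)
    anchor <- pk$index[which.max(pk$value)]
    ks <- seq(floor((1 - anchor) / P), ceiling((n - anchor) / P))
    sel <- integer()
    for (ctr in anchor + ks * P) {
      cand <- pool[abs(pool - ctr) <= 0.3 * P]
      if (length(cand)) sel <- c(sel, cand[which.max(v[cand])])
    }
    sel <- sort(unique(sel))
    sel <- sel[v[sel] >= 0.5 * stats::median(v[sel])]   # windows past the ends
    idx <- sel
  } else {
    idx <- pk$index[pk$prominence >= 0.5 * max(pk$prominence)]
  }
  sort(refine_peaks(v, idx))
}

#' Summarize a set of period measurements
#'
#' @param periods_nm numeric vector of periods (>= 2 values).
#' @return list with \code{mean_nm}, \code{sd_nm}, \code{sem_nm} and
#'   \code{n} (standard unbiased estimators).
#' @export
summarize_periods <- function(periods_nm) {
  periods_nm <- periods_nm[is.finite(periods_nm)]
  n <- length(periods_nm)
  if (n < 2L) stopf("need at least two periods to summarize")
  list(mean_nm = mean(periods_nm), sd_nm = stats::sd(periods_nm),
       sem_nm = stats::sd(periods_nm) / sqrt(n), n = n)
}

#' Build a period set
#'
#' @param condition label for the condition.
#' @param periods_nm vector of positive period measurements (nm).
#' @return object of class \code{"period_set"}.
#' @export
period_set <- function(condition, periods_nm) {
  periods_nm <- as.numeric(periods_nm)
  if (any(!is.finite(periods_nm)) || any(periods_nm <= 0))
    stopf("all periods must be positive and finite")
  structure(list(condition = condition, periods_nm = periods_nm,
                 n = length(periods_nm)),
            class = "period_set")
}

#' @export
print.period_set <- function(x, ...) {
  s <- summarize_periods(x$periods_nm)
  cat(sprintf("Period set '%s': n = %d, mean %.2f nm, sd %.2f nm\n",
              x$condition, x$n, s$mean_nm, s$sd_nm))
  invisible(x)
}
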