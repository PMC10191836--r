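#' Compare two axial profiles for lost, gained or broadened peaks
#'
#' Profiles are min-max normalized (stain depth is uncalibrated between
#' grids), profile b is resampled onto a's grid by periodic linear
#' interpolation of the normalized phase, and the difference trace is
#' computed.  Peaks are detected in each profile (circular, prominence
#' at least \code{prominence_factor} x the robust noise, with a small
#' range-based floor) and matched by position; a peak present in a with
#' no counterpart in b is reported as \code{"lost"} (and vice versa as
#' \code{"gained"}), and a matched peak whose full width at half
#' prominence grows by at least \code{fwhm_factor} is reported as
#' \code{"broadened"}.
#'
#' @param a,b \code{\link{axial_profile}} objects covering one period
#'   each; periods may differ by at most \code{max_period_mismatch}
#'   (fractional).
#' @param prominence_factor peak threshold in robust-noise units.
#' @param fwhm_factor width-ratio threshold for "broadened".
#' @param match_tol_nm maximum circular distance for peak matching.
#' @param max_period_mismatch reject when periods differ more than this.
#' @param max_align_shift_nm largest circular shift allowed when
#'   aligning b to a (both profiles are expected to be bead-centered).
#' @return object of class \code{"profile_comparison"}: list with
#'   \code{difference} (\code{axial_profile} on a's grid) and
#'   \code{events} (data frame: position_nm, kind, magnitude).
#' @export
compare_profiles <- function(a, b, prominence_factor = 2,
                             fwhm_factor = 1.5, match_tol_nm = 5,
                             max_period_mismatch = 0.06,
                             max_align_shift_nm = 10) {
  stopifnot(inherits(a, "axial_profile"), inherits(b, "axial_profile"))
  Pa <- attr(a, "period_nm"); Pb <- attr(b, "period_nm")
  if (abs(Pa - Pb) / Pa > max_period_mismatch)
    stopf("profile periods differ by more than %.0f%%",
          100 * max_period_mismatch)
  norm01 <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(v * 0)
    (v - r[1]) / diff(r)
  }
  va <- norm01(a$value)
  # resample b on a's grid via normalized phase
  phase_a <- (a$position_nm - a$position_nm[1]) / Pa
  nb <- length(b$value)
  idx <- phase_a * nb
  i0 <- floor(idx); fr <- idx - i0
  i0 <- (as.integer(i0) %% nb) + 1L
  i1 <- (i0 %% nb) + 1L
  vb_raw <- b$value[i0] * (1 - fr) + b$value[i1] * fr
  vb <- norm01(vb_raw)
  # circularly align b to a on their common structure; the search is
  # restricted to small shifts (both profiles follow the bead-at-0
  # convention) so a dominant decoration hump cannot hijack alignment
  lag <- best_circular_lag(va, vb, max_lag = max_align_shift_nm / profile_step(a))
  vb <- shift_circular(vb, lag)
  diff_v <- va - vb
  step <- profile_step(a)

  describe_peaks <- function(v) {
    # ~1 nm smoothing so noise ripple does not truncate width measures
    v <- gauss_smooth_1d(v, 1 / step)
    thr <- max(prominence_factor * robust_noise(v), 0.05 * diff(range(v)))
    pk <- find_peaks(v, min_prominence = thr, circular = TRUE)
    if (!nrow(pk)) return(pk)
    pk$position_nm <- a$position_nm[pk$index]
    pk$fwhm_nm <- vapply(pk$index,
                         function(i) peak_fwhm(v, i, circular = TRUE) * step, 0)
    pk
  }
  pa <- describe_peaks(va)
  pb <- describe_peaks(vb)
  circ_dist <- function(x, y) {
    d <- abs(x - y) %% Pa
    pmin(d, Pa - d)
  }
  events <- data.frame(position_nm = numeric(), kind = character(),
                       magnitude = numeric())
  used_b <- rep(FALSE, nrow(pb))
  for (i in seq_len(nrow(pa))) {
    if (nrow(pb)) {
      d <- circ_dist(pa$position_nm[i], pb$position_nm)
      j <- which.min(d)
    } else j <- integer()
    if (length(j) && d[j] <= match_tol_nm && !used_b[j]) {
      used_b[j] <- TRUE
      ratio <- pb$fwhm_nm[j] / pa$fwhm_nm[i]
      if (is.finite(ratio) && ratio >= fwhm_factor) {
        events <- rbind(events,
                        data.frame(position_nm = pa$position_nm[i],
                                   kind = "broadened", magnitude = ratio))
      }
    } else {
      events <- rbind(events,
                      data.frame(position_nm = pa$position_nm[i],
                                 kind = "lost",
                                 magnitude = pa$prominence[i]))
    }
  }
  for (j in which(!used_b)) {
    events <- rbind(events,
                    data.frame(position_nm = pb$position_nm[j],
                               kind = "gained",
                               magnitude = pb$prominence[j]))
  }
  structure(list(difference = axial_profile(a$position_nm, diff_v,
                                            unit = "normalized difference",
                                            period_nm = Pa),
                 events = events,
                 peaks_a = pa, peaks_b = pb),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Profile comparison: %d event(s)\n", nrow(x$events)))
  if (nrow(x$events)) print(x$events, row.names = FALSE)
  invisible(x)
}
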