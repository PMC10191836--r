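#' Construct an axial profile object
#'
#' An axial profile is a uniformly sampled 1D trace of intensity, stain
#' exclusion or mass density against axial position over exactly one
#' repeat period, with the bead center at position 0.
#'
#' @param position_nm uniform position grid (nm).
#' @param value profile values.
#' @param unit unit tag, e.g. \code{"kDa/nm"} or \code{"intensity"}.
#' @param period_nm the repeat period covered by the grid.
#' @return data frame of class \code{"axial_profile"} with columns
#'   \code{position_nm} and \code{value}.
#' @export
axial_profile <- function(position_nm, value, unit = "intensity",
                          period_nm = NULL) {
  if (length(position_nm) != length(value))
    stopf("position and value lengths differ")
  if (length(position_nm) > 1L) {
    st <- diff(position_nm)
    if (max(abs(st - st[1])) > 1e-6 * abs(st[1]))
      stopf("axial profile grid must be uniform")
  }
  structure(data.frame(position_nm = position_nm, value = value),
            unit = unit,
            period_nm = period_nm %||%
              (length(position_nm) * (position_nm[2] - position_nm[1])),
            class = c("axial_profile", "data.frame"))
}

profile_step <- function(p) p$position_nm[2] - p$position_nm[1]

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("Axial profile: %d samples over %.2f nm (step %.3f nm, unit %s)\n",
              nrow(x), attr(x, "period_nm"), profile_step(x),
              attr(x, "unit")))
  invisible(x)
}

#' @export
plot.axial_profile <- function(x, ...) {
  graphics::plot(x$position_nm, x$value, type = "l",
                 xlab = "axial position (nm)", ylab = attr(x, "unit"), ...)
  invisible(x)
}

# Wrapped truncated Gaussian on a periodic grid, normalized so that
# sum(values) * step == mass exactly.
wrapped_feature <- function(pos, period, center, sigma, mass, step) {
  g <- numeric(length(pos))
  for (k in -3:3) {
    d <- pos - center + k * period
    sel <- abs(d) <= 3 * sigma
    if (any(sel)) g[sel] <- g[sel] + exp(-0.5 * (d[sel] / sigma)^2)
  }
  tot <- sum(g) * step
  if (tot > 0) g <- g * (mass / tot)
  g
}

#' Generate the axial mass-density profile of one repeat
#'
#' Renders every feature of a fibril specification as a truncated
#' Gaussian (support +/- 3 sigma, wrapped periodically) whose integral
#' over the period equals the feature mass, and optionally adds ligand
#' decoration at its axial center.  The returned profile is in kDa/nm;
#' its integral over one period is the (decorated) repeat mass, exactly.
#'
#' @param spec a \code{\link{fibril_spec}}.
#' @param decoration optional \code{\link{decoration_spec}}.
#' @param grid_step_nm requested sample spacing (> 0 and <=
#'   period/10); the actual spacing is the nearest value that divides
#'   the period exactly, so that the discrete integral and the
#'   continuous integral of the periodic interpolant agree.
#' @return an \code{\link{axial_profile}} in kDa/nm with bead at 0.
#' @export
generate_axial_profile <- function(spec, decoration = NULL,
                                   grid_step_nm = 0.1) {
  stopifnot(inherits(spec, "fibril_spec"))
  if (grid_step_nm <= 0 || grid_step_nm > spec$period_nm / 10)
    stopf("grid_step_nm must be positive and at most period/10")
  if (!is.null(decoration)) stopifnot(inherits(decoration, "decoration_spec"))
  P <- spec$period_nm
  n <- max(10L, round(P / grid_step_nm))
  grid_step_nm <- P / n
  pos <- (seq_len(n) - 1L) * grid_step_nm
  val <- numeric(length(pos))
  for (i in seq_len(nrow(spec$features))) {
    f <- spec$features[i, ]
    val <- val + wrapped_feature(pos, P, f$center_nm, f$width_nm,
                                 f$mass_kDa, grid_step_nm)
  }
  if (!is.null(decoration)) {
    dm <- decoration_mass_kDa(decoration)
    if (decoration$axial_center_nm < 0 || decoration$axial_center_nm >= P)
      stopf("decoration axial_center_nm must lie in [0, period)")
    if (dm > 0)
      val <- val + wrapped_feature(pos, P, decoration$axial_center_nm,
                                   decoration$width_nm, dm, grid_step_nm)
  }
  axial_profile(pos, val, unit = "kDa/nm", period_nm = P)
}

# Evaluate a periodic axial profile at arbitrary arc positions (nm) by
# linear interpolation on the circular grid.
eval_profile_periodic <- function(profile, s_nm) {
  P <- attr(profile, "period_nm")
  step <- profile_step(profile)
  v <- profile$value
  n <- length(v)
  u <- (s_nm %% P) / step          # fractional grid index, 0-based
  i0 <- floor(u)
  fr <- u - i0
  i0 <- (as.integer(i0) %% n) + 1L
  i1 <- (i0 %% n) + 1L
  (1 - fr) * v[i0] + fr * v[i1]
}
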