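# Rendering engine for the synthetic generator.  A filament is drawn by
# walking its path at sub-pixel arc steps, depositing the axial mass
# density (kDa/nm) at each step spread over a normalized transverse
# Gaussian, and splatting each deposit bilinearly onto the pixel grid.
# Pixel values are therefore linear in projected mass: intensity =
# gain * mass-in-pixel (plus background and noise), which is the
# annular dark-field contrast model and, up to polarity, also serves as
# the stain-exclusion model.

# Resample a polyline (0-based px coords) at uniform arc-length steps;
# include_end appends the exact endpoint when the step does not divide
# the total length.
resample_polyline <- function(x, y, step_px, include_end = FALSE) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- seq(0, L, by = step_px)
  if (include_end && s[length(s)] < L - 1e-9) s <- c(s, L)
  list(x = stats::approx(cum, x, xout = s, rule = 2)$y,
       y = stats::approx(cum, y, xout = s, rule = 2)$y,
       s = s, length = L)
}

polyline_tangent <- function(x, y) {
  n <- length(x)
  tx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  ty <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  list(tx = tx / nrm, ty = ty / nrm)
}

# Deposit mass along a path into an (ny x nx) accumulator.  density_fun
# maps arc length (nm, from the path start) to kDa/nm.  Returns a sparse
# triplet accumulation as a dense matrix of deposited kDa per pixel.
splat_path <- function(nx, ny, path_x, path_y, pixel_size_nm, density_fun,
                       sigma_t_nm, arc_step_frac = 0.25,
                       t_step_frac = 0.5) {
  rp <- resample_polyline(path_x, path_y, step_px = arc_step_frac,
                          include_end = TRUE)
  s_nm <- rp$s * pixel_size_nm
  # trapezoidal arc weights conserve the deposited mass at the ends
  dsv <- diff(s_nm)
  ds_nm <- (c(dsv, 0) + c(0, dsv)) / 2
  dens <- density_fun(s_nm)
  tg <- polyline_tangent(rp$x, rp$y)
  nxv <- -tg$ty; nyv <- tg$tx            # unit normal
  sigma_t_px <- sigma_t_nm / pixel_size_nm
  toff <- seq(-3 * sigma_t_px, 3 * sigma_t_px, by = t_step_frac)
  wt <- exp(-0.5 * (toff / sigma_t_px)^2)
  wt <- wt / sum(wt)                      # transverse kernel sums to 1
  np <- length(rp$x); nt <- length(toff)
  px <- rep(rp$x, nt) + rep(nxv, nt) * rep(toff, each = np)
  py <- rep(rp$y, nt) + rep(nyv, nt) * rep(toff, each = np)
  w <- rep(dens * ds_nm, nt) * rep(wt, each = np)   # kDa per deposit
  # bilinear splat onto 1-based matrix indices (row = y+1, col = x+1)
  col <- px + 1; row <- py + 1
  c0 <- floor(col); r0 <- floor(row)
  fc <- col - c0; fr <- row - r0
  ii <- c(r0, r0, r0 + 1, r0 + 1)
  jj <- c(c0, c0 + 1, c0, c0 + 1)
  ww <- c(w * (1 - fr) * (1 - fc), w * (1 - fr) * fc,
          w * fr * (1 - fc), w * fr * fc)
  ok <- ii >= 1 & ii <= ny & jj >= 1 & jj <= nx & ww != 0
  acc <- Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = ww[ok],
                              dims = c(ny, nx))
  as.matrix(acc)
}

path_margin_ok <- function(path_x, path_y, nx, ny, margin_px) {
  all(path_x >= margin_px - 1e-9, path_x <= nx - 1 - margin_px + 1e-9,
      path_y >= margin_px - 1e-9, path_y <= ny - 1 - margin_px + 1e-9)
}

default_path <- function(length_px, margin_px, y_px) {
  list(x = c(margin_px, margin_px + length_px), y = c(y_px, y_px))
}

finish_image <- function(signal, imaging) {
  sgn <- if (imaging$contrast_polarity == "bright_on_dark") 1 else -1
  img <- imaging$background_level + sgn * signal
  if (imaging$noise_sd > 0) {
    img <- img + with_seed(imaging$seed,
                           matrix(stats::rnorm(length(img), 0, imaging$noise_sd),
                                  nrow(img), ncol(img)))
  }
  img
}

#' Render a synthetic beaded filament micrograph
#'
#' Draws one filament whose intensity along the path is the repeat's
#' axial mass-density profile (optionally decorated) convolved with a
#' transverse Gaussian envelope, on a constant background with seeded
#' additive Gaussian noise.  Bead centers sit at arc lengths 0, P, 2P,
#' ... along the path, so a filament of n repeats carries n + 1 bead
#' peaks.  The returned ground truth records the path, the exact bead
#' arc positions, the generative mass-per-unit-length profile and the
#' per-repeat masses.
#'
#' @param spec a \code{\link{fibril_spec}}.
#' @param imaging an \code{\link{imaging_spec}}.
#' @param decoration optional \code{\link{decoration_spec}}.
#' @param sigma_t_nm transverse envelope sigma (nm).
#' @param margin_nm clear margin around the path (nm); must be at least
#'   half the transverse profile width.
#' @param gain intensity units per kDa of projected mass.
#' @return list with elements \code{micrograph} (a
#'   \code{\link{micrograph}}) and \code{ground_truth} (list: trace,
#'   bead_positions_nm, mul_profile, per_repeat_masses_kDa, gain).
#' @export
render_filament_image <- function(spec, imaging, decoration = NULL,
                                  sigma_t_nm = 4, margin_nm = 20,
                                  gain = 1) {
  stopifnot(inherits(spec, "fibril_spec"), inherits(imaging, "imaging_spec"))
  if (margin_nm < 3 * sigma_t_nm)
    stopf("margin_nm must cover the transverse envelope (>= 3 * sigma_t_nm)")
  px <- imaging$pixel_size_nm
  profile <- generate_axial_profile(spec, decoration,
                                    grid_step_nm = min(0.1, spec$period_nm / 20))
  L_nm <- spec$n_repeats * spec$period_nm
  margin_px <- margin_nm / px
  if (is.null(spec$path)) {
    ny <- ceiling(2 * margin_px) + 1L
    nx <- ceiling(L_nm / px + 2 * margin_px) + 1L
    path <- default_path(L_nm / px, margin_px, (ny - 1) / 2)
  } else {
    path <- list(x = spec$path$x, y = spec$path$y)
    seg <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
    nx <- ceiling(max(path$x) + margin_px) + 1L
    ny <- ceiling(max(path$y) + margin_px) + 1L
    if (!path_margin_ok(path$x, path$y, nx, ny, margin_px))
      stopf("path leaves the frame: a margin of %.1f nm is required", margin_nm)
  }
  dens <- function(s_nm) eval_profile_periodic(profile, s_nm)
  signal <- splat_path(nx, ny, path$x, path$y, px, dens, sigma_t_nm)
  img <- finish_image(gain * signal, imaging)
  rp <- resample_polyline(path$x, path$y, step_px = 1)
  arc_len_nm <- rp$length * px
  gt <- list(trace = filament_trace(rp$x, rp$y),
             bead_positions_nm = seq(0, arc_len_nm, by = spec$period_nm),
             mul_profile = profile,
             per_repeat_masses_kDa = rep(spec$repeat_mass_kDa +
                                           decoration_mass_kDa(decoration),
                                         spec$n_repeats),
             gain = gain)
  list(micrograph = micrograph(img, px), ground_truth = gt)
}

#' Render a synthetic STEM annular dark-field field
#'
#' Lays out one or more fibrils and a calibration rod as parallel
#' horizontal lanes and renders them under the linear dark-field
#' contrast model: pixel intensity = gain x projected mass, one shared
#' gain for every object, plus background and seeded noise.  Lanes must
#' not overlap; the layout is rejected if transverse envelopes would
#' touch.
#'
#' @param fibril_specs a \code{\link{fibril_spec}} or list of them.
#' @param imaging an \code{\link{imaging_spec}}.
#' @param decoration optional \code{\link{decoration_spec}} applied to
#'   every fibril.
#' @param rod optional \code{\link{calibration_rod_spec}}; required when
#'   the field is to be used for calibration.
#' @param sigma_t_nm fibril transverse sigma (nm).
#' @param lane_spacing_nm center-to-center lane spacing (nm).
#' @param margin_nm margin around all objects (nm).
#' @param gain intensity units per kDa.
#' @return list with \code{micrograph} and \code{ground_truth}; the
#'   ground truth holds one record per object (type, trace,
#'   bead_positions_nm, mul profile or constant, repeat masses).
#' @export
render_stem_field <- function(fibril_specs, imaging, decoration = NULL,
                              rod = NULL, sigma_t_nm = 4,
                              lane_spacing_nm = 60, margin_nm = 30,
                              gain = 1) {
  if (inherits(fibril_specs, "fibril_spec")) fibril_specs <- list(fibril_specs)
  stopifnot(inherits(imaging, "imaging_spec"))
  px <- imaging$pixel_size_nm
  sig_rod <- if (!is.null(rod)) rod$width_nm / 4 else 0
  widths <- c(rep(sigma_t_nm, length(fibril_specs)),
              if (!is.null(rod)) sig_rod)
  n_obj <- length(widths)
  if (n_obj == 0L) stopf("nothing to render")
  # overlap check: adjacent lanes must be separated by both envelopes
  if (n_obj > 1L) {
    need <- 3 * (widths[-1] + widths[-n_obj]) + 2 * px
    if (any(lane_spacing_nm < need))
      stopf("objects overlap: lane_spacing_nm %.1f < required %.1f nm",
            lane_spacing_nm, max(need))
  }
  lengths_nm <- c(vapply(fibril_specs,
                         function(s) s$n_repeats * s$period_nm, 0),
                  if (!is.null(rod)) rod$length_nm)
  margin_px <- margin_nm / px
  nx <- ceiling(max(lengths_nm) / px + 2 * margin_px) + 1L
  ny <- ceiling((n_obj - 1) * lane_spacing_nm / px + 2 * margin_px) + 1L
  signal <- matrix(0, ny, nx)
  truth <- vector("list", n_obj)
  for (k in seq_len(n_obj)) {
    y_px <- margin_px + (k - 1) * lane_spacing_nm / px
    is_rod <- !is.null(rod) && k == n_obj
    len_px <- lengths_nm[k] / px
    path <- default_path(len_px, margin_px, y_px)
    if (is_rod) {
      dens <- function(s_nm) rep(rod$mul_kDa_per_nm, length(s_nm))
      sig <- sig_rod
    } else {
      spec_k <- fibril_specs[[k]]
      profile_k <- generate_axial_profile(spec_k, decoration,
                                          grid_step_nm = min(0.1, spec_k$period_nm / 20))
      dens <- local({
        p <- profile_k
        function(s_nm) eval_profile_periodic(p, s_nm)
      })
      sig <- sigma_t_nm
    }
    signal <- signal + splat_path(nx, ny, path$x, path$y, px, dens, sig)
    rp <- resample_polyline(path$x, path$y, step_px = 1)
    truth[[k]] <- if (is_rod) {
      list(type = "rod", trace = filament_trace(rp$x, rp$y),
           mul_kDa_per_nm = rod$mul_kDa_per_nm)
    } else {
      list(type = "fibril", trace = filament_trace(rp$x, rp$y),
           bead_positions_nm = seq(0, lengths_nm[k], by = fibril_specs[[k]]$period_nm),
           mul_profile = generate_axial_profile(fibril_specs[[k]], decoration,
                                                grid_step_nm = min(0.1, fibril_specs[[k]]$period_nm / 20)),
           per_repeat_masses_kDa = rep(fibril_specs[[k]]$repeat_mass_kDa +
                                         decoration_mass_kDa(decoration),
                                       fibril_specs[[k]]$n_repeats))
    }
  }
  img <- finish_image(gain * signal, imaging)
  list(micrograph = micrograph(img, px),
       ground_truth = list(objects = truth, gain = gain))
}
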