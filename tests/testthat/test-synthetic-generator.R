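# The synthetic generator is the oracle for every downstream analysis,
# so its own contracts are tested first: exact mass bookkeeping,
# byte-level determinism, and linearity of the dark-field render.

test_that("axial profiles conserve mass exactly for every preset and decoration", {
  for (cond in c("control", "dh1", "wms")) {
    spec <- fibril_preset(cond)
    for (dec in list(NULL, ltbp1_decoration(), ltbp1_decoration(FALSE))) {
      prof <- generate_axial_profile(spec, dec)
      step <- prof$position_nm[2] - prof$position_nm[1]
      expect_equal(sum(prof$value) * step,
                   spec$repeat_mass_kDa +
                     (if (is.null(dec)) 0 else
                        dec$occupancy * (dec$copies_per_repeat * dec$ligand_mass_kDa +
                                           dec$associated_mass_kDa)),
                   tolerance = 1e-9)
    }
  }
})

test_that("the control bead window carries its nominal share of the repeat mass", {
  spec <- fibril_preset("control")
  prof <- generate_axial_profile(spec)
  step <- prof$position_nm[2] - prof$position_nm[1]
  P <- spec$period_nm
  w <- fibrilkit_defaults()$bead_window_half_nm
  d <- pmin(prof$position_nm, P - prof$position_nm)   # circular distance to bead
  frac <- sum(prof$value[d <= w]) / sum(prof$value)
  expect_lt(abs(frac / (1100 / 3055) - 1), 0.01)
})

test_that("decoration adds exactly copies x ligand mass at full occupancy", {
  spec <- fibril_preset("control")
  bare <- generate_axial_profile(spec)
  dec <- decoration_spec(ligand_mass_kDa = 151, copies_per_repeat = 2L,
                         axial_center_nm = 0, occupancy = 1)
  deco <- generate_axial_profile(spec, dec)
  step <- bare$position_nm[2] - bare$position_nm[1]
  expect_equal((sum(deco$value) - sum(bare$value)) * step, 302,
               tolerance = 1e-9)
  # occupancy scales the added mass linearly
  half <- generate_axial_profile(spec, decoration_spec(151, 2L, 0, occupancy = 0.5))
  expect_equal((sum(half$value) - sum(bare$value)) * step, 151,
               tolerance = 1e-9)
})

test_that("profile generation rejects invalid features and steps", {
  feats <- data.frame(name = "bead", center_nm = 60, width_nm = 3,
                      mass_kDa = 100)
  expect_error(fibril_spec(57.95, feats), "center_nm")
  feats$center_nm <- 10; feats$width_nm <- 0
  expect_error(fibril_spec(57.95, feats), "width")
  spec <- fibril_preset("control")
  expect_error(generate_axial_profile(spec, grid_step_nm = 10), "period/10")
})

test_that("identical seeds and specs give bit-identical rendered images", {
  spec <- fibril_preset("control", n_repeats = 4L)
  im <- default_imaging(seed = 11, noise_sd = 0.4)
  r1 <- render_filament_image(spec, im)
  r2 <- render_filament_image(spec, im)
  expect_identical(r1$micrograph$values, r2$micrograph$values)
  f1 <- render_stem_field(spec, im, rod = tmv_rod(200), lane_spacing_nm = 80)
  f2 <- render_stem_field(spec, im, rod = tmv_rod(200), lane_spacing_nm = 80)
  expect_identical(f1$micrograph$values, f2$micrograph$values)
  # a different seed changes the noise
  r3 <- render_filament_image(spec, default_imaging(seed = 12, noise_sd = 0.4))
  expect_false(identical(r1$micrograph$values, r3$micrograph$values))
})

test_that("noiseless column sums reproduce the axial profile up to one scale factor", {
  spec <- fibril_preset("control", n_repeats = 6L)
  r <- render_condition(n_repeats = 6L, seed = 1, noise_sd = 0)
  cs <- colSums(r$micrograph$values)
  prof <- r$ground_truth$mul_profile
  px <- r$micrograph$pixel_size_nm
  # compare over interior repeats (ends hold truncated half-beads)
  x0 <- 20 / px                      # margin in px
  cols <- seq(floor(x0 + 57.95 / px), floor(x0 + 5 * 57.95 / px))
  s_nm <- (cols - x0) * px
  expected <- fibrilkit:::eval_profile_periodic(prof, s_nm)
  expect_gt(stats::cor(cs[cols + 1], expected), 0.999)
})

test_that("dark-field render is exactly linear in mass", {
  spec <- fibril_preset("control", n_repeats = 4L)
  feats2 <- spec$features
  feats2$mass_kDa <- 2 * feats2$mass_kDa
  spec2 <- fibril_spec(spec$period_nm, feats2, n_repeats = 4L)
  im <- default_imaging(seed = 3, noise_sd = 0, pixel_size_nm = 1)
  f1 <- render_stem_field(spec, im, rod = NULL, lane_spacing_nm = 80)
  f2 <- render_stem_field(spec2, im, rod = NULL, lane_spacing_nm = 80)
  expect_equal(f2$micrograph$values, 2 * f1$micrograph$values,
               tolerance = 1e-12)
})

test_that("fibril and rod share one contrast constant in rendered STEM fields", {
  spec <- fibril_preset("control", n_repeats = 8L)
  im <- default_imaging(seed = 5, noise_sd = 0, pixel_size_nm = 1)
  fld <- render_stem_field(spec, im, rod = tmv_rod(300), lane_spacing_nm = 80)
  objs <- fld$ground_truth$objects
  fib <- net_intensity_profile(fld$micrograph, objs[[1]]$trace, 33, 6, 8)
  rod <- net_intensity_profile(fld$micrograph, objs[[2]]$trace, 33, 6, 8)
  # average fibril intensity per nm over interior repeats vs rod level
  sel <- fib$position_nm >= 57.95 & fib$position_nm <= 7 * 57.95
  ratio <- mean(fib$intensity_per_nm[sel]) /
    mean(rod$intensity_per_nm[rod$position_nm >= 50 & rod$position_nm <= 250])
  expect_equal(ratio, (3055 / 57.95) / 131.4, tolerance = 0.01)
})

test_that("rendered STEM fields reject overlapping lane layouts", {
  spec <- fibril_preset("control", n_repeats = 4L)
  im <- default_imaging(seed = 1, noise_sd = 0, pixel_size_nm = 1)
  expect_error(render_stem_field(list(spec, spec), im,
                                 lane_spacing_nm = 10),
               "overlap")
})

test_that("bead spacing along a sinusoidal path equals the period in arc length", {
  spec0 <- fibril_preset("control", n_repeats = 8L)
  px <- 0.5
  margin_px <- 40
  # sinusoidal polyline long enough in arc length for 8 repeats
  xs <- seq(0, 1200, by = 1)
  ys <- 30 * sin(2 * pi * xs / 600)
  arc <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  need_px <- 8 * 57.95 / px
  keep <- arc <= need_px
  path <- list(x = xs[keep] + margin_px, y = ys[keep] + 40 + margin_px)
  spec <- fibril_spec(spec0$period_nm, spec0$features, n_repeats = 8L,
                      path = path)
  r <- render_filament_image(spec, default_imaging(seed = 2, noise_sd = 0))
  sf <- straighten(r$micrograph, r$ground_truth$trace, lane_width_px = 21)
  p <- measure_periods(sf)
  expect_gt(length(p), 4)
  expect_lt(abs(mean(p) - 57.95), 0.5)   # within one grid step
})

test_that("a path leaving the frame is rejected with a bounds error", {
  spec0 <- fibril_preset("control", n_repeats = 4L)
  bad <- fibril_spec(spec0$period_nm, spec0$features, n_repeats = 4L,
                     path = list(x = c(5, 500), y = c(5, 5)))
  expect_error(render_filament_image(bad, default_imaging(1, 0)),
               "frame|margin")
})

test_that("generated particle tables honor the stated trivial geometries", {
  # no rotation: every true center shifts by d / pixel in x only
  ps <- generate_particle_set(50, true_offset_A = c(11, 0, 0),
                              angle_distribution = "zero", seed = 3,
                              pixel_size_A = 2.2)
  expect_equal(ps$true_center_x,
               ps$coordinate_x - ps$origin_x + 11 / 2.2, tolerance = 1e-12)
  expect_equal(ps$true_center_y, ps$coordinate_y - ps$origin_y,
               tolerance = 1e-12)
  # zero offset: true centers equal particle centers
  ps0 <- generate_particle_set(50, true_offset_A = c(0, 0, 0), seed = 4)
  expect_equal(ps0$true_center_x, ps0$coordinate_x - ps0$origin_x,
               tolerance = 1e-12)
})
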