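# Dark-field mass mapping: net intensity extraction, rod calibration,
# per-repeat integration and decoration analysis.

make_field <- function(seed = 1, noise_sd = 0, n_repeats = 8L,
                       decoration = NULL, gain = 1) {
  spec <- fibril_preset("control", n_repeats = n_repeats)
  im <- imaging_spec(pixel_size_nm = 1, noise_sd = noise_sd, seed = seed)
  render_stem_field(spec, im, decoration = decoration,
                    rod = tmv_rod(300), lane_spacing_nm = 80, gain = gain)
}

test_that("a blank image yields a near-zero net trace", {
  set.seed(3)
  mg <- micrograph(matrix(stats::rnorm(120 * 500, 5, 0.5), 120, 500), 1)
  tr <- filament_trace(c(40, 450), c(60, 60))
  nt <- net_intensity_profile(mg, tr, 25, 6, 8)
  expect_lt(abs(mean(nt$intensity_per_nm, na.rm = TRUE)), 1)
})

test_that("a noiseless rod gives a constant net trace and the filament tracks its MUL", {
  fld <- make_field(noise_sd = 0)
  objs <- fld$ground_truth$objects
  rod <- net_intensity_profile(fld$micrograph, objs[[2]]$trace, 33, 6, 8)
  interior <- rod$position_nm > 30 & rod$position_nm < 270
  expect_lt(stats::sd(rod$intensity_per_nm[interior]) /
              mean(rod$intensity_per_nm[interior]), 1e-3)
  fib <- net_intensity_profile(fld$micrograph, objs[[1]]$trace, 33, 6, 8)
  gen <- objs[[1]]$mul_profile
  sel <- fib$position_nm >= 58 & fib$position_nm <= 7 * 58
  expected <- fibrilkit:::eval_profile_periodic(gen, fib$position_nm[sel])
  expect_gt(stats::cor(fib$intensity_per_nm[sel], expected), 0.999)
})

test_that("calibrating the standard against itself returns its nominal MUL exactly", {
  fld <- make_field(noise_sd = 0.3, seed = 5)
  rod_tr <- net_intensity_profile(fld$micrograph,
                                  fld$ground_truth$objects[[2]]$trace,
                                  33, 6, 8)
  cal <- calibrate(rod_tr, tmv_rod(300))
  mul <- apply_calibration(rod_tr, cal)
  n <- length(mul$mul_kDa_per_nm)
  cut <- floor(0.1 * n)
  expect_equal(mean(mul$mul_kDa_per_nm[(cut + 1):(n - cut)], na.rm = TRUE),
               131.4, tolerance = 1e-9)
})

test_that("doubling the image gain halves the calibration constant", {
  f1 <- make_field(noise_sd = 0, gain = 1)
  f2 <- make_field(noise_sd = 0, gain = 2)
  k1 <- calibrate(net_intensity_profile(f1$micrograph,
                                        f1$ground_truth$objects[[2]]$trace,
                                        33, 6, 8), tmv_rod(300))$k
  k2 <- calibrate(net_intensity_profile(f2$micrograph,
                                        f2$ground_truth$objects[[2]]$trace,
                                        33, 6, 8), tmv_rod(300))$k
  expect_equal(k2, k1 / 2, tolerance = 1e-9)
})

test_that("independent noisy fields give calibrations agreeing within the rod CV", {
  ks <- vapply(c(11, 12), function(s) {
    fld <- make_field(noise_sd = 0.5, seed = s)
    calibrate(net_intensity_profile(fld$micrograph,
                                    fld$ground_truth$objects[[2]]$trace,
                                    33, 6, 8), tmv_rod(300))$k
  }, 0)
  fld <- make_field(noise_sd = 0.5, seed = 11)
  cv <- calibrate(net_intensity_profile(fld$micrograph,
                                        fld$ground_truth$objects[[2]]$trace,
                                        33, 6, 8), tmv_rod(300))$rod_cv
  expect_lt(abs(ks[1] - ks[2]) / ks[1], 2 * cv)
})

test_that("short or empty rod traces are rejected", {
  tr <- structure(data.frame(position_nm = seq(0, 30), intensity_per_nm = 1),
                  pixel_size_nm = 1, class = c("intensity_trace", "data.frame"))
  expect_error(calibrate(tr, tmv_rod(300)), "50 nm")
  tr2 <- structure(data.frame(position_nm = seq(0, 100),
                              intensity_per_nm = -1),
                   pixel_size_nm = 1, class = c("intensity_trace", "data.frame"))
  expect_error(calibrate(tr2, tmv_rod(300)), "positive")
})

test_that("integrating a constant MUL over one period gives the product exactly", {
  mul <- structure(data.frame(position_nm = seq(0, 114, 0.5),
                              mul_kDa_per_nm = 53.6),
                   pixel_size_nm = 0.5, class = c("mul_profile", "data.frame"))
  ms <- mass_per_repeat(mul, bead_positions_nm = c(0, 57))
  expect_equal(ms$masses_kDa, 53.6 * 57, tolerance = 1e-3)
  empty <- mass_per_repeat(mul, bead_positions_nm = numeric())
  expect_identical(empty$n, 0L)
})

test_that("calibrated masses are invariant to a global intensity scale", {
  f1 <- make_field(noise_sd = 0, gain = 1)
  f2 <- make_field(noise_sd = 0, gain = 3.7)
  get_masses <- function(fld) {
    objs <- fld$ground_truth$objects
    cal <- calibrate(net_intensity_profile(fld$micrograph, objs[[2]]$trace,
                                           33, 6, 8), tmv_rod(300))
    mul <- apply_calibration(net_intensity_profile(fld$micrograph,
                                                   objs[[1]]$trace, 33, 6, 8),
                             cal)
    mass_per_repeat(mul, bead_positions_nm = objs[[1]]$bead_positions_nm)$masses_kDa
  }
  expect_equal(get_masses(f1), get_masses(f2), tolerance = 1e-9)
})

test_that("per-repeat masses sum to the integral over the spanned interval", {
  fld <- make_field(noise_sd = 0)
  objs <- fld$ground_truth$objects
  cal <- calibrate(net_intensity_profile(fld$micrograph, objs[[2]]$trace,
                                         33, 6, 8), tmv_rod(300))
  mul <- apply_calibration(net_intensity_profile(fld$micrograph,
                                                 objs[[1]]$trace, 33, 6, 8),
                           cal)
  b <- objs[[1]]$bead_positions_nm
  b <- b[b <= max(mul$position_nm)]      # last bead may sit past the trace
  ms <- mass_per_repeat(mul, bead_positions_nm = b)
  sel <- mul$position_nm >= min(b) & mul$position_nm <= max(b)
  xs <- c(min(b), mul$position_nm[sel], max(b))
  ys <- c(stats::approx(mul$position_nm, mul$mul_kDa_per_nm, min(b))$y,
          mul$mul_kDa_per_nm[sel],
          stats::approx(mul$position_nm, mul$mul_kDa_per_nm, max(b))$y)
  whole <- fibrilkit:::trapz(xs, ys)
  expect_lt(abs(sum(ms$masses_kDa) / whole - 1), 1e-3)
})

test_that("decoration analysis is null for identical inputs", {
  set.seed(13)
  ms <- structure(list(condition = "x", masses_kDa = stats::rnorm(20, 3055, 30),
                       n = 20L, flagged = rep(FALSE, 20)),
                  class = "mass_per_repeat_set")
  avg <- axial_profile(seq(-28.5, 28.5, 0.5), stats::runif(115, 40, 60),
                       unit = "kDa/nm", period_nm = 57.5)
  res <- decoration_analysis(list(mass_set = ms, mul_avg = avg),
                             list(mass_set = ms, mul_avg = avg))
  expect_equal(res$increase_kDa, 0)
  expect_lt(max(abs(res$localization$value)), 1e-12)
  expect_true(is.na(res$bead_fraction))
})

test_that("a two-copy ligand decoration is recovered in mass and bead localization", {
  bare <- run_stem_recovery(NULL, n_fibrils = 5L, n_repeats = 16L,
                            seed = 61, condition = "bare")
  dec <- ltbp1_decoration(measured_gain = FALSE)     # exactly 2 x 151 kDa
  deco <- run_stem_recovery(dec, n_fibrils = 5L, n_repeats = 16L,
                            seed = 71, condition = "ltbp1")
  res <- decoration_analysis(list(mass_set = bare$mass_set,
                                  mul_avg = bare$mul_avg),
                             list(mass_set = deco$mass_set,
                                  mul_avg = deco$mul_avg))
  expect_lt(abs(res$increase_kDa / 302 - 1), 0.05)
  expect_gte(res$bead_fraction, 0.5)
  expect_identical(res$copies_per_repeat, 2)
})

test_that("mass sets at the reported group statistics separate decisively", {
  set.seed(17)
  bare <- stats::rnorm(75, 3055, 36.7)
  deco <- stats::rnorm(69, 3405, 54.43)
  expect_lt(unpaired_t_test(deco, bare)$p, 1e-4)
})
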