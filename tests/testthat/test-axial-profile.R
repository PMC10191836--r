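# Repeat extraction, translational alignment/averaging, and the
# comparison of averaged stain-exclusion profiles between conditions.

test_that("a noiseless filament of five periods yields windows matching the generative profile", {
  s <- straightened_condition(n_repeats = 5L, seed = 1, noise_sd = 0)
  st <- extract_repeats(s$sf)
  expect_true(length(st$windows) %in% 4:5)
  gen <- generate_axial_profile(fibril_preset("control"))
  for (w in st$windows) {
    prof <- rowMeans(w)
    ref <- fibrilkit:::eval_profile_periodic(
      gen, seq(0, length.out = length(prof),
               by = 57.95 / length(prof)))
    # windows are cut at bead peaks; allow a small circular lag
    ccs <- vapply(-4:4, function(l)
      stats::cor(prof, fibrilkit:::shift_circular(ref, l)), 0)
    expect_gt(max(ccs), 0.98)
  }
})

test_that("a sub-period fragment yields an empty stack", {
  s <- straightened_condition(n_repeats = 3L, seed = 2, noise_sd = 0)
  frag <- s$sf
  frag$values <- frag$values[1:40, ]     # 20 nm: less than one period
  st <- extract_repeats(frag)
  expect_length(st$windows, 0L)
})

test_that("stacks from many filaments combine to the requested repeat count", {
  stacks <- list()
  for (i in 1:21) {
    r <- render_condition(n_repeats = 24L, seed = 100 + i, noise_sd = 0.3,
                          pixel_size_nm = 1)
    y0 <- mean(r$ground_truth$trace$y)
    tr <- filament_trace(range(r$ground_truth$trace$x), c(y0, y0))
    sf <- straighten(r$micrograph, tr, lane_width_px = 11)
    stacks[[i]] <- extract_repeats(sf)
  }
  all <- do.call(bind_repeat_stacks, stacks)
  expect_gte(length(all$windows), 458L)
  sub <- all
  sub$windows <- sub$windows[1:458]
  sub$shifts_nm <- sub$shifts_nm[1:458]
  expect_length(sub$windows, 458L)
})

test_that("alignment recovers applied shifts and restores the average", {
  base <- averaged_profile(seed = 3, n_repeats = 10L)
  n <- nrow(base)
  applied <- c(0, 3, -5, 8, -2, 6)
  wins <- lapply(applied, function(d)
    matrix(fibrilkit:::shift_circular(base$value, d), ncol = 1))
  stack <- structure(list(windows = wins,
                          shifts_nm = rep(0, length(wins)),
                          pixel_size_nm = fibrilkit:::profile_step(base),
                          window_len = n),
                     class = "repeat_stack")
  aa <- align_average(stack)
  rec <- aa$shifts_nm / fibrilkit:::profile_step(base)
  # shifts are defined up to one common constant (the gauge of the mean)
  resid <- (rec + applied) - stats::median(rec + applied)
  expect_lt(max(abs(resid)), 0.1)
  ccs <- vapply(-3:3, function(l)
    stats::cor(aa$profile$value,
               fibrilkit:::shift_circular(base$value, l)), 0)
  expect_gt(max(ccs), 0.995)
})

test_that("alignment requires at least two repeats", {
  s <- straightened_condition(n_repeats = 4L, seed = 4, noise_sd = 0)
  st <- extract_repeats(s$sf)
  st$windows <- st$windows[1]
  st$shifts_nm <- st$shifts_nm[1]
  expect_error(align_average(st), "at least 2")
})

test_that("averaging a noisy stack recovers the generative profile", {
  prof <- averaged_profile(seed = 5, n_repeats = 16L)
  gen <- generate_axial_profile(fibril_preset("control"))
  n <- nrow(prof)
  ref <- fibrilkit:::eval_profile_periodic(
    gen, seq(0, length.out = n, by = 57.95 / n))
  ccs <- vapply(seq_len(n) - 1L, function(l)
    stats::cor(prof$value, fibrilkit:::shift_circular(ref, l)), 0)
  expect_gt(max(ccs), 0.99)
})

test_that("alignment is translation-equivariant", {
  base <- averaged_profile(seed = 6, n_repeats = 10L)
  n <- nrow(base)
  applied <- c(0, 4, -3, 7)
  wins <- lapply(applied, function(d)
    matrix(fibrilkit:::shift_circular(base$value, d), ncol = 1))
  mk <- function(w) structure(list(windows = w,
                                   shifts_nm = rep(0, length(w)),
                                   pixel_size_nm = fibrilkit:::profile_step(base),
                                   window_len = n),
                              class = "repeat_stack")
  a1 <- align_average(mk(wins))
  delta <- 5
  wins2 <- lapply(wins, function(w)
    matrix(fibrilkit:::shift_circular(w[, 1], delta), ncol = 1))
  a2 <- align_average(mk(wins2))
  d_shift <- (a2$shifts_nm - a1$shifts_nm) / fibrilkit:::profile_step(base)
  expect_lt(max(abs(d_shift - stats::median(d_shift))), 0.1)
  expect_lt(max(abs(a2$profile$value - a1$profile$value)) /
              diff(range(a1$profile$value)), 1e-3)
})

test_that("averaging reduces noise roughly as one over root N", {
  set.seed(21)
  gen <- generate_axial_profile(fibril_preset("control"))
  truth <- gen$value / max(gen$value)
  n <- length(truth)
  sigma <- 0.1
  ratios <- vapply(1:3, function(rep) {
    wins <- lapply(1:25, function(i)
      matrix(truth + stats::rnorm(n, 0, sigma), ncol = 1))
    stack <- structure(list(windows = wins, shifts_nm = rep(0, 25),
                            pixel_size_nm = 57.95 / n, window_len = n),
                       class = "repeat_stack")
    aa <- align_average(stack)
    ccs <- vapply(seq_len(n) - 1L, function(l)
      stats::cor(aa$profile$value, fibrilkit:::shift_circular(truth, l)), 0)
    lag <- which.max(ccs) - 1L
    resid <- aa$profile$value - fibrilkit:::shift_circular(truth, lag)
    stats::sd(resid) / (sigma / sqrt(25))
  }, 0)
  expect_lt(abs(mean(ratios) - 1), 0.3)
})

test_that("identical profiles compare with zero difference and no events", {
  p <- averaged_profile(seed = 7, n_repeats = 10L)
  cmp <- compare_profiles(p, p)
  expect_identical(nrow(cmp$events), 0L)
  expect_lt(max(abs(cmp$difference$value)), 1e-12)
})

test_that("the mutant profile loses the shoulder peak near its generative position", {
  pc <- averaged_profile("control", seed = 9, n_repeats = 16L)
  pw <- averaged_profile("wms", seed = 10, n_repeats = 16L)
  cmp <- compare_profiles(pc, pw)
  lost <- cmp$events[cmp$events$kind == "lost", ]
  expect_identical(nrow(lost), 1L)
  # generative shoulder at 35 nm from the bead; circular distance on the period
  d <- abs(lost$position_nm %% 57.95 - 35)
  expect_lt(min(d, 57.95 - d), 2)
})

test_that("diffuse decoration at the junction is reported as peak broadening", {
  pc <- averaged_profile("control", seed = 9, n_repeats = 16L)
  dec <- decoration_spec(125, 2L, axial_center_nm = 31, width_nm = 3)
  pint <- averaged_profile("control", seed = 11, n_repeats = 16L,
                           decoration = dec, center = "boundary",
                           use_truth_boundaries = TRUE)
  cmp <- compare_profiles(pc, pint)
  broad <- cmp$events[cmp$events$kind == "broadened", ]
  expect_gte(nrow(broad), 1L)
  # event sits in the interbead/shoulder junction region (25-40 nm)
  pos <- broad$position_nm %% 57.95
  expect_true(any(pos > 25 & pos < 40))
})

test_that("profiles with incompatible periods are rejected", {
  p1 <- axial_profile(seq(0, 57.9, 0.1), stats::runif(580), period_nm = 58)
  p2 <- axial_profile(seq(0, 49.9, 0.1), stats::runif(500), period_nm = 50)
  expect_error(compare_profiles(p1, p2), "differ")
})
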