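# Rotational symmetry-correlation analysis of density maps and
# density-threshold mass estimation.

test_that("volume rotation honors the trivial and analytic cases", {
  v <- test_volume(3)
  expect_identical(rotate_volume(v, 0)$values, v$values)
  expect_identical(rotate_volume(v, 360)$values, v$values)
  # impulse at (+10, 0, 0) voxels from center moves to (0, +10, 0) under
  # a 90-degree rotation about z
  box <- 33L
  arr <- array(0, dim = rep(box, 3))
  ctr <- (box + 1) / 2
  arr[ctr + 10, ctr, ctr] <- 1
  imp <- density_volume(arr, 2)
  rot <- rotate_volume(imp, 90)
  hit <- arrayInd(which.max(rot$values), dim(rot$values))
  expect_lte(max(abs(hit - c(ctr, ctr + 10, ctr))), 1)
  expect_error(rotate_volume(v, 45, axis = c(0, 0, 0)), "nonzero")
})

test_that("mask symmetrization fixes symmetric masks and swallows off-axis balls", {
  box <- 40L
  ctr <- (box + 1) / 2
  ax <- seq_len(box) - ctr
  # z-axis cylinder: already rotationally symmetric
  cyl <- array(0, dim = rep(box, 3))
  for (iz in seq_len(box)) {
    if (abs(ax[iz]) <= 10)
      cyl[, , iz] <- outer(ax, ax, function(x, y) as.numeric(x^2 + y^2 <= 100))
  }
  cm <- density_volume(cyl, 2)
  sym <- symmetrize_mask(cm, step_deg = 15)
  expect_lt(mean(sym$values != cm$values), 0.02)
  # off-axis ball: result contains the ball and forms an annulus
  ball <- array(0, dim = rep(box, 3))
  for (iz in seq_len(box)) {
    w <- 36 - ax[iz]^2
    if (w > 0)
      ball[, , iz] <- outer(ax - 10, ax, function(x, y)
        as.numeric(x^2 + y^2 <= w))
  }
  bm <- density_volume(ball, 2)
  symb <- symmetrize_mask(bm, step_deg = 15)
  expect_true(all(symb$values[ball > 0.5] > 0.5))
  expect_gt(sum(symb$values), 3 * sum(ball))
  # rotational closure: rotating the result by one step barely changes it
  rot <- rotate_volume(symb, 15)
  expect_lt(mean((rot$values > 0.5) != (symb$values > 0.5)), 0.01)
  expect_error(symmetrize_mask(cm, step_deg = 7), "divide")
})

test_that("correlation curves are exact at zero rotation and reject tiny masks", {
  v <- test_volume(5)
  msk <- test_ring_mask()
  cur <- rotational_correlation_curve(v, mask = msk)
  expect_equal(cur$ncc[1], 1, tolerance = 1e-6)
  expect_true(all(abs(cur$ncc) <= 1 + 1e-9))
  tiny <- density_volume(array(c(rep(1, 50), rep(0, 48^3 - 50)),
                               dim = rep(48, 3)), 2)
  expect_error(rotational_correlation_curve(v, mask = tiny), "100 voxels")
})

test_that("self-correlation curves are symmetric about 180 degrees", {
  v <- test_volume(3)
  cur <- rotational_correlation_curve(v, mask = test_ring_mask())
  n <- nrow(cur)
  # ncc(theta) = ncc(360 - theta) for real volumes
  expect_lt(max(abs(cur$ncc[-1] - rev(cur$ncc[-1]))), 0.01)
})

test_that("symmetry order is read off the curve for C8, C2 and C1 volumes", {
  msk <- test_ring_mask()
  c8 <- rotational_correlation_curve(test_volume(8), mask = msk)
  expect_true(all(c8$ncc[c8$angle_deg %% 45 == 0] >= 0.99))
  est8 <- count_symmetry_peaks(c8)
  expect_identical(est8$order, 8L)
  expect_false(est8$pseudo)
  expect_true(all(abs(diff(est8$angles_deg) - 45) <= 2.5))
  # invariance of the curve under 360/n shifts
  shift <- 45 / attr(c8, "step_deg")
  expect_lt(max(abs(c8$ncc - c(c8$ncc[-seq_len(shift)],
                               c8$ncc[seq_len(shift)]))), 0.01)
  est2 <- count_symmetry_peaks(
    rotational_correlation_curve(test_volume(2), mask = msk))
  expect_identical(est2$order, 2L)
  c1 <- rotational_correlation_curve(test_volume(1), mask = msk)
  est1 <- count_symmetry_peaks(c1)
  expect_identical(est1$order, 1L)
  # single blob: exactly one contiguous above-midline excursion
  high <- c1$ncc > (max(c1$ncc) + min(c1$ncc)) / 2
  runs <- rle(c(high, high[1]))      # circular closure
  expect_lte(sum(runs$values & runs$lengths > 0) -
               (high[1] && high[length(high)]), 1)
})

test_that("a 10 percent amplitude perturbation flags the symmetry as pseudo", {
  msk <- test_ring_mask()
  cur <- rotational_correlation_curve(
    test_volume(8, amplitudes = c(1.1, rep(1, 7))), mask = msk)
  est <- count_symmetry_peaks(cur)
  expect_identical(est$order, 8L)
  expect_true(est$pseudo)
})

test_that("a flat curve reports order 1 with a warning", {
  flat <- structure(data.frame(angle_deg = seq(0, 355, 5), ncc = 1),
                    step_deg = 5, class = c("symmetry_curve", "data.frame"))
  expect_warning(est <- count_symmetry_peaks(flat), "flat")
  expect_identical(est$order, 1L)
})

test_that("density-to-mass follows the voxel arithmetic and is monotone", {
  box <- 20L
  arr <- array(0, dim = rep(box, 3))
  arr[seq_len(1000)] <- 1
  v <- density_volume(arr, voxel_size_A = 2.2)
  res <- density_to_mass(v, threshold = 0.5)
  expect_equal(res$mass_kDa, 1000 * 2.2^3 * 0.813 / 1000, tolerance = 1e-9)
  expect_equal(res$mass_kDa, 8.66, tolerance = 0.01)
  expect_equal(res$volume_A3, 1000 * 2.2^3)
  # monotone non-increasing in threshold, linear in voxel count
  set.seed(31)
  rnd <- density_volume(array(stats::runif(30^3), dim = rep(30, 3)), 2)
  ms <- vapply(seq(0.1, 0.9, 0.1),
               function(th) density_to_mass(rnd, th)$mass_kDa, 0)
  expect_true(all(diff(ms) <= 0))
  expect_error(density_to_mass(rnd, threshold = 5), "range")
  expect_warning(res0 <- density_to_mass(rnd, threshold = max(rnd$values)),
                 "mass 0")
  expect_equal(res0$mass_kDa, 0)
})

test_that("a hard ball recovers its analytic molecular volume as mass", {
  box <- 64L
  ctr <- (box + 1) / 2
  ax <- seq_len(box) - ctr
  r_vox <- 10
  arr <- array(0, dim = rep(box, 3))
  for (iz in seq_len(box)) {
    w2 <- r_vox^2 - ax[iz]^2
    if (w2 > 0)
      arr[, , iz] <- outer(ax, ax, function(x, y) as.numeric(x^2 + y^2 <= w2))
  }
  v <- density_volume(arr, voxel_size_A = 2)
  res <- density_to_mass(v, threshold = 0.5)
  analytic <- (4 / 3) * pi * (r_vox * 2)^3 * 0.813 / 1000
  expect_lt(abs(res$mass_kDa / analytic - 1), 0.05)
})
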