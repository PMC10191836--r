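# Shared builders for the test suite.  Everything is generated in code;
# no fixture files.

default_imaging <- function(seed, noise_sd = 0.3, pixel_size_nm = 0.5) {
  imaging_spec(pixel_size_nm = pixel_size_nm, noise_sd = noise_sd,
               seed = seed)
}

# Render one filament and return micrograph + ground truth.
render_condition <- function(condition = "control", n_repeats = 8L,
                             seed = 1L, noise_sd = 0.3,
                             pixel_size_nm = 0.5, decoration = NULL) {
  render_filament_image(fibril_preset(condition, n_repeats = n_repeats),
                        default_imaging(seed, noise_sd, pixel_size_nm),
                        decoration = decoration)
}

# Full trace -> straighten chain on a rendered filament.
straightened_condition <- function(condition = "control", n_repeats = 8L,
                                   seed = 1L, noise_sd = 0.3,
                                   decoration = NULL) {
  r <- render_condition(condition, n_repeats, seed, noise_sd,
                        decoration = decoration)
  trs <- trace_filaments(r$micrograph, expected_width_px = 8)
  expect_gte(length(trs), 1L)
  list(sf = straighten(r$micrograph, trs[[1]], lane_width_px = 21),
       render = r)
}

# Bead-centered averaged intensity profile of a rendered condition.
averaged_profile <- function(condition = "control", seed = 1L,
                             n_repeats = 16L, decoration = NULL,
                             center = "peak", use_truth_boundaries = FALSE) {
  s <- straightened_condition(condition, n_repeats, seed,
                              decoration = decoration)
  boundaries <- NULL
  if (use_truth_boundaries) {
    P <- fibril_preset(condition)$period_nm
    boundaries <- seq(0, nrow(s$sf$values) * s$sf$pixel_size_nm, by = P)
  }
  st <- extract_repeats(s$sf, boundaries_nm = boundaries)
  align_average(st, center = center)$profile
}

# Small exactly C8 / C2 / C1 volumes for symmetry tests (48^3 box).
test_volume <- function(n_fold, amplitudes = NULL, box = 48L) {
  generate_symmetric_volume(n_fold, blob_radius_A = 6, ring_radius_A = 28,
                            box_size_vox = box, voxel_size_A = 2,
                            blob_amplitudes = amplitudes)
}

test_ring_mask <- function(box = 48L) {
  ring_mask(box, 2, 28, width_A = 20)
}
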