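# Shared fixtures, generated once per test run and cached. Sizes are kept
# small (32-64 voxels per axis over the standard 288 mm extent) so the whole
# suite stays fast; the production grid is exercised in the acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# standard small phantom pair: 48^3 at 6 mm, default deformation
small_pair <- function() {
  cached("small_pair", function() {
    generate_phantom_pair(phantom_spec(shape = c(48, 48, 48),
                                       spacing_mm = c(6, 6, 6), seed = 42))
  })
}

# quiet pair: no deformation, no pose, no noise (identity checks)
identity_pair <- function() {
  cached("identity_pair", function() {
    generate_phantom_pair(phantom_spec(shape = c(48, 48, 48),
                                       spacing_mm = c(6, 6, 6),
                                       deformation_amplitude_mm = 0,
                                       pose_translation_mm = c(0, 0, 0),
                                       pose_euler_deg = c(0, 0, 0),
                                       pose_scale = 1, noise_sd_hu = 0,
                                       seed = 42))
  })
}

# noise-free pair for segmentation accuracy checks
clean_pair <- function() {
  cached("clean_pair", function() {
    generate_phantom_pair(phantom_spec(shape = c(48, 48, 48),
                                       spacing_mm = c(6, 6, 6),
                                       noise_sd_hu = 0, seed = 7))
  })
}

# a small volume with arbitrary smooth content on an anisotropic grid
toy_volume <- function(shape = c(12, 10, 8), spacing = c(2, 3, 4),
                       origin = c(-5, 4, 20)) {
  g <- grid3d(shape, spacing, origin)
  pos <- pronelung:::voxel_coords(g)
  v <- sin(pos$x / 7) + cos(pos$y / 9) + sin(pos$z / 11) * 100
  volume3d(array(v, shape), g, unit_tag = "HU")
}

expect_grid_equal <- function(a, b, tol = 1e-6) {
  expect_true(grids_equal(a, b, tol))
}
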