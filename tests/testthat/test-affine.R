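test_that("euler angle conversion round-trips and transforms stay shear-free", {
  for (ang in list(c(5, -3, 8), c(0, 0, 0), c(-8, 8, -8))) {
    R <- euler_to_rot(ang)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(rot_to_euler(R), ang, tolerance = 1e-9)
  }
  T <- affine_transform(c(3, -2, 1), c(4, -6, 2), 1.02, c(10, 20, 30))
  M <- T$rotation %*% diag(T$scale)
  dec <- pronelung:::.decompose_linear(M, T$center, T$translation)
  expect_equal(dec$euler_deg, T$euler_deg, tolerance = 1e-8)
  expect_equal(dec$scale, T$scale, tolerance = 1e-10)
})

test_that("composition and inversion are exact on isotropic shear-free transforms", {
  A <- affine_transform(c(3, -2, 1), c(4, -6, 2), 1.02, c(10, 20, 30))
  B <- affine_transform(c(-1, 5, 2), c(-3, 2, 7), 0.97, c(-5, 0, 15))
  AB <- compose_affine(A, B)
  x <- c(12, -7, 40)
  fx <- function(T, x) as.numeric(T$center + T$rotation %*% (T$scale * (x - T$center)) + T$translation)
  expect_equal(fx(AB, x), fx(A, fx(B, x)), tolerance = 1e-9)
  Ainv <- invert_affine(A)
  expect_equal(fx(Ainv, fx(A, x)), x, tolerance = 1e-9)
})

test_that("identity transform on the same grid returns the input unchanged", {
  pair <- small_pair()
  out <- apply_affine(pair$supine_vol, affine_transform())
  expect_equal(out$values, pair$supine_vol$values, tolerance = 1e-10)
})

test_that("a pure translation moves a delta spike by the exact voxel offset", {
  g <- grid3d(c(21, 21, 21), c(1, 1, 1))
  v <- array(0, g$shape)
  v[11, 11, 11] <- 100
  vol <- volume3d(v, g, "HU")
  # T maps target points into the source: +5 mm means the spike lands at 6
  out <- apply_affine(vol, affine_transform(translation = c(5, 0, 0)),
                      fill = 0)
  expect_equal(out$values[6, 11, 11], 100)
  expect_equal(sum(out$values != 0), 1)
})

test_that("estimating a transform between identical masks yields the identity", {
  pair <- small_pair()
  T <- estimate_affine(pair$supine_labels, pair$supine_labels)
  expect_lt(sqrt(sum(T$translation^2)), 0.1)
  expect_lt(max(abs(T$euler_deg)), 0.1)
  expect_lt(max(abs(T$scale - 1)), 1e-3)
})

test_that("pose recovery: translation, rotation and scale come back within tolerance", {
  # pose-only pairs (no deformation) so the affine is the full ground truth
  base <- list(shape = c(48, 48, 48), spacing_mm = c(6, 6, 6),
               deformation_amplitude_mm = 0)
  fx <- function(T, x) as.numeric(T$center + T$rotation %*% (T$scale * (x - T$center)) + T$translation)

  spec_t <- do.call(phantom_spec, c(base, list(
    pose_translation_mm = c(5, -3, 2), pose_euler_deg = c(0, 0, 0),
    pose_scale = 1, seed = 13)))
  p <- generate_phantom_pair(spec_t)
  T <- estimate_affine(p$prone_labels, p$supine_labels)
  err <- abs(fx(T, p$true_pose$center) - fx(p$true_pose, p$true_pose$center))
  # a pure grid-aligned shift is quantised by nearest-neighbour resampling:
  # any translation within half a voxel reproduces the mask exactly, so half
  # a voxel is the attainable (inclusive) bound
  expect_lte(max(err), 0.5 * 6 + 1e-6)

  spec_rs <- do.call(phantom_spec, c(base, list(
    pose_translation_mm = c(0, 0, 0), pose_euler_deg = c(0, 0, 6),
    pose_scale = 1.03, seed = 14)))
  p2 <- generate_phantom_pair(spec_rs)
  T2 <- estimate_affine(p2$prone_labels, p2$supine_labels)
  dR <- T2$rotation %*% t(p2$true_pose$rotation)
  ang <- acos(max(-1, min(1, (sum(diag(dR)) - 1) / 2))) * 180 / pi
  expect_lt(ang, 1)
  expect_lt(max(abs(T2$scale / p2$true_pose$scale - 1)), 0.01)
})

test_that("refinement never does worse than the closed-form initialisation", {
  pair <- small_pair()
  T <- estimate_affine(pair$prone_labels, pair$supine_labels)
  expect_gte(attr(T, "dice"), attr(T, "init_dice"))
})

test_that("applying a transform and then its inverse nearly restores the mask", {
  pair <- small_pair()
  T <- affine_transform(c(6, -4, 3), c(5, -3, 4), 1.02,
                        center = grid_extent(pair$supine_labels$grid) / 2)
  fwd <- apply_affine(pair$supine_labels, T)
  back <- apply_affine(fwd, invert_affine(T))
  expect_gte(dice(lung_mask(back), lung_mask(pair$supine_labels)), 0.98)
})

test_that("affine QC passes good registrations and fails poor or empty ones", {
  pair <- small_pair()
  good <- qc_affine(pair$supine_labels, pair$supine_labels)
  expect_true(good$pass)
  expect_equal(good$dice, 1)

  empty <- labelmap(array(0L, pair$supine_labels$grid$shape),
                    pair$supine_labels$grid)
  bad <- qc_affine(pair$supine_labels, empty)
  expect_false(bad$pass)
  expect_equal(bad$dice, 0)

  shifted <- apply_affine(pair$supine_labels,
                          affine_transform(translation = c(120, 0, 0)))
  mid <- qc_affine(pair$supine_labels, shifted)
  expect_false(mid$pass)
})

test_that("transforms serialise to JSON and back", {
  T <- affine_transform(c(3.5, -2.25, 1), c(4, -6, 2), 1.02, c(10, 20, 30))
  path <- tempfile(fileext = ".json")
  write_affine(T, path)
  back <- read_affine(path)
  expect_equal(back$translation, T$translation)
  expect_equal(back$euler_deg, T$euler_deg)
  expect_equal(back$scale, T$scale)
  expect_equal(back$center, T$center)
})

test_that("estimation rejects empty masks", {
  pair <- small_pair()
  empty <- labelmap(array(0L, pair$supine_labels$grid$shape),
                    pair$supine_labels$grid)
  expect_error(estimate_affine(empty, pair$supine_labels), "empty")
  expect_error(estimate_affine(pair$supine_labels, empty), "empty")
})
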