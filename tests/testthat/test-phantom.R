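test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(shape = c(32, 32, 32), spacing_mm = c(9, 9, 9), seed = 7)
  a <- generate_phantom_pair(spec)
  b <- generate_phantom_pair(spec)
  expect_identical(a$supine_vol$values, b$supine_vol$values)
  expect_identical(a$prone_vol$values, b$prone_vol$values)
  expect_identical(a$true_field$vectors, b$true_field$vectors)
  expect_identical(a$true_pose$translation, b$true_pose$translation)
})

test_that("identity spec (no pose, no deformation, no noise) reproduces supine exactly", {
  pair <- identity_pair()
  expect_equal(pair$prone_vol$values, pair$supine_vol$values, tolerance = 1e-12)
  expect_identical(pair$prone_labels$labels, pair$supine_labels$labels)
})

test_that("both label maps contain all five lobes and only legend labels", {
  pair <- small_pair()
  expect_setequal(unique(as.vector(pair$supine_labels$labels)), 0:5)
  expect_setequal(unique(as.vector(pair$prone_labels$labels)), 0:5)
})

test_that("the ground-truth field is diffeomorphic with peak amplitude over the lung", {
  pair <- small_pair()
  lung <- lung_mask(pair$supine_labels)
  det <- jacobian_determinant(pair$true_field)
  expect_gt(min(det$values[lung]), 0)
  peak <- max(field_magnitude(pair$true_field)[lung])
  expect_equal(peak, pair$spec$deformation_amplitude_mm, tolerance = 0.01)
})

test_that("fibrosis damps the field to (1 - damping) of the undamped phantom", {
  base <- list(shape = c(48, 48, 48), spacing_mm = c(6, 6, 6), seed = 3)
  damped <- generate_phantom_pair(do.call(phantom_spec,
    c(base, list(fibrosis_extent = 0.5, damping = 0.8))))
  undamped <- generate_phantom_pair(do.call(phantom_spec,
    c(base, list(fibrosis_extent = 0))))
  fib <- damped$fibrosis_mask
  expect_gt(sum(fib), 0)
  m_d <- field_magnitude(damped$true_field)
  m_u <- field_magnitude(undamped$true_field)
  expect_lte(max(m_d[fib]), 0.2 * max(m_u[fib]) + 1e-9)
})

test_that("fibrosis occupies the requested lung fraction, dorsal-basal first", {
  pair <- small_pair()  # fibrosis_extent 0 by default
  expect_equal(sum(pair$fibrosis_mask), 0)
  spec <- phantom_spec(shape = c(48, 48, 48), spacing_mm = c(6, 6, 6),
                       fibrosis_extent = 0.3, seed = 3)
  p <- generate_phantom_pair(spec)
  lung <- lung_mask(p$supine_labels)
  expect_equal(sum(p$fibrosis_mask) / sum(lung), 0.3, tolerance = 0.01)
  pos <- pronelung:::voxel_coords(p$supine_labels$grid)
  # fibrotic voxels sit dorsal (larger y) and basal (smaller z) of the rest
  expect_gt(mean(pos$y[p$fibrosis_mask]), mean(pos$y[lung & !p$fibrosis_mask]))
  expect_lt(mean(pos$z[p$fibrosis_mask]), mean(pos$z[lung & !p$fibrosis_mask]))
  expect_error(phantom_spec(fibrosis_extent = 0.99), "infeasible")
})

test_that("apply_deformation matches direct index arithmetic", {
  g <- grid3d(c(21, 21, 21), c(1, 1, 1))
  v <- array(0, g$shape)
  v[11, 11, 11] <- 100  # delta spike
  vol <- volume3d(v, g, "HU")
  # uniform +5 mm x-shift: output at p samples input at p + 5 -> spike moves
  # to smaller x index by 5? no: out(p) = in(p + d), spike appears where
  # p + d hits the spike, i.e. at index 11 - 5 = 6
  vec <- array(0, c(g$shape, 3))
  vec[, , , 1] <- 5
  f <- displacement_field(vec, g)
  out <- apply_deformation(vol, f, fill = 0)
  expect_equal(out$values[6, 11, 11], 100)
  expect_equal(sum(out$values != 0), 1)

  # zero field is the identity
  zf <- displacement_field(array(0, c(g$shape, 3)), g)
  expect_equal(apply_deformation(vol, zf)$values, vol$values)

  # nearest warp of a labelmap yields only legend labels
  pair <- small_pair()
  warped <- apply_deformation(pair$supine_labels, pair$true_field)
  expect_true(all(warped$labels %in% 0:5))

  # grid mismatch is an error
  g2 <- grid3d(c(21, 21, 21), c(2, 1, 1))
  expect_error(apply_deformation(volume3d(v, g2, "HU"), f), "grids differ")
})

test_that("cohort generation is seeded and couples fibrosis, amplitude and FVC", {
  a <- generate_cohort(3, seed = 5, shape = c(32, 32, 32),
                       spacing_mm = c(9, 9, 9))
  b <- generate_cohort(3, seed = 5, shape = c(32, 32, 32),
                       spacing_mm = c(9, 9, 9))
  expect_identical(a$pairs[[2]]$supine_vol$values, b$pairs[[2]]$supine_vol$values)
  expect_identical(subjects_to_df(a$subjects), subjects_to_df(b$subjects))
  expect_error(generate_cohort(1), "n must be >= 2")

  coh <- generate_cohort(30, seed = 11, shape = c(32, 32, 32),
                         spacing_mm = c(9, 9, 9))
  ext <- vapply(coh$subjects, function(s) s$fibrosis_extent, numeric(1))
  amp <- vapply(coh$pairs, function(p) p$spec$deformation_amplitude_mm, numeric(1))
  fvc <- vapply(coh$subjects, function(s) s$fvc_l, numeric(1))
  expect_lt(cor(ext, amp), 0)
  expect_gt(cor(amp, fvc), 0)
  expect_true(all(ext %in% seq(0, 70, by = 10)))
})

test_that("phantom volume targeting hits the requested lower-lobe gain", {
  pair <- small_pair()
  vc <- volume_change(pair$supine_labels, pair$prone_labels)
  lower <- sum(vc$delta_ml[vc$region %in% c("RLL", "LLL")])
  expect_equal(lower, pair$spec$lower_lobe_expansion_ml, tolerance = 0.05 * 80)
})
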