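test_that("regional volumes follow voxel count times voxel volume", {
  g1 <- grid3d(c(20, 20, 20), c(1, 1, 1))
  lab <- array(0L, g1$shape)
  lab[1:10, 1:10, 1:10] <- 3L  # 1000 voxels of RLL
  v1 <- region_volumes(labelmap(lab, g1))
  expect_equal(unname(v1["RLL"]), 1.0)
  expect_equal(unname(v1["whole"]), 1.0)

  g2 <- grid3d(c(20, 20, 20), c(2, 2, 2))
  v2 <- region_volumes(labelmap(lab, g2))
  expect_equal(unname(v2["RLL"]), 8.0)
})

test_that("regional volumes are additive on every phantom output", {
  for (lm in list(small_pair()$supine_labels, small_pair()$prone_labels)) {
    v <- region_volumes(lm)
    expect_equal(unname(v["whole"]), unname(v["right"] + v["left"]),
                 tolerance = 1e-9)
    expect_equal(unname(v["right"]), unname(v["RUL"] + v["RML"] + v["RLL"]),
                 tolerance = 1e-9)
    expect_equal(unname(v["left"]), unname(v["LUL"] + v["LLL"]),
                 tolerance = 1e-9)
  }
})

test_that("volume change uses the prone-minus-supine sign convention", {
  pair <- small_pair()
  same <- volume_change(pair$supine_labels, pair$supine_labels)
  expect_true(all(same$delta_ml == 0))

  vc <- volume_change(pair$supine_labels, pair$prone_labels)
  known <- region_volumes(pair$prone_labels) - region_volumes(pair$supine_labels)
  expect_equal(vc$delta_ml, unname(known[vc$region]), tolerance = 1e-9)

  # a prone map missing a lobe is flagged, not silently reported
  broken <- pair$prone_labels$labels
  broken[broken == 2L] <- 1L
  expect_error(volume_change(pair$supine_labels,
                             labelmap(broken, pair$prone_labels$grid)),
               "missing lobes: RML")
})

test_that("movement summary computes per-axis and 3D maxima in cm", {
  g <- grid3d(c(5, 5, 5), c(1, 1, 1))
  vec <- array(0, c(g$shape, 3))
  vec[3, 3, 3, ] <- c(30, 40, 0)  # a 3-4-5 triangle in mm
  f <- displacement_field(vec, g)
  lab <- array(0L, g$shape)
  lab[3, 3, 3] <- 1L
  m <- movement_summary(f, labelmap(lab, g))
  expect_equal(m$max_abs_x_cm, 3.0)
  expect_equal(m$max_abs_y_cm, 4.0)
  expect_equal(m$max_abs_z_cm, 0.0)
  expect_equal(m$max_3d_cm, 5.0)

  zero <- displacement_field(array(0, c(g$shape, 3)), g)
  mz <- movement_summary(zero, labelmap(lab, g))
  expect_equal(mz$max_3d_cm, 0)

  expect_error(movement_summary(f, labelmap(array(0L, g$shape), g)), "empty")
})

test_that("movement summary respects percentiles and lobe relabelling", {
  pair <- small_pair()
  m100 <- movement_summary(pair$true_field, pair$supine_labels)
  expect_gte(m100$max_3d_cm, max(m100$max_abs_x_cm, m100$max_abs_y_cm,
                                 m100$max_abs_z_cm))
  m95 <- movement_summary(pair$true_field, pair$supine_labels, percentile = 95)
  expect_lte(m95$max_3d_cm, m100$max_3d_cm)
  expect_lte(m95$max_abs_y_cm, m100$max_abs_y_cm)

  # relabelling lobes leaves the whole-lung summary untouched
  relab <- pair$supine_labels$labels
  relab[relab > 0L] <- 1L
  m_flat <- movement_summary(pair$true_field,
                             labelmap(relab, pair$supine_labels$grid))
  expect_equal(m_flat$max_3d_cm, m100$max_3d_cm)

  # ground-truth peak matches the configured deformation amplitude
  expect_equal(m100$max_3d_cm, pair$spec$deformation_amplitude_mm / 10,
               tolerance = 0.1 * pair$spec$deformation_amplitude_mm / 10)
})

test_that("dice follows its formula including the empty convention", {
  a <- array(FALSE, c(4, 4, 4))
  b <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(a, b), 1.0)
  a[1:2, , ] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b[3:4, , ] <- TRUE
  expect_equal(dice(a, b), 0.0)
  # |A| = |B| = 32, overlap 16
  b2 <- array(FALSE, c(4, 4, 4))
  b2[2:3, , ] <- TRUE
  expect_equal(dice(a, b2), 0.5)
  expect_error(dice(a, array(FALSE, c(4, 4, 2))), "dimensions differ")
})

test_that("the single-subject pipeline is deterministic and fully populated", {
  pair <- small_pair()
  r1 <- analyze_subject(pair$supine_vol, pair$prone_vol,
                        fissures = pair$fissures, subject_id = "P1")
  r2 <- analyze_subject(pair$supine_vol, pair$prone_vol,
                        fissures = pair$fissures, subject_id = "P1")
  expect_true(r1$qc$pass)
  expect_identical(r1$volume_report, r2$volume_report)
  expect_identical(r1$movement, r2$movement)
  expect_identical(r1$field$vectors, r2$field$vectors)
  expect_true(all(c("whole", "RLL", "LLL") %in% r1$volume_report$region))
  expect_gt(r1$dice_whole, 0.9)
  expect_false(is.na(r1$movement$max_3d_cm))
})

test_that("an impossible affine QC threshold flags registration failure and skips analytics", {
  pair <- small_pair()
  r <- analyze_subject(pair$supine_vol, pair$prone_vol,
                       fissures = pair$fissures,
                       qc_dice_threshold = 0.9999)
  expect_false(r$qc$pass)
  expect_true(any(grepl("registration_failure", r$qc$reasons)))
  expect_null(r$movement)
})
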