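test_that("grid and image constructors enforce their invariants", {
  expect_error(grid3d(c(1, 4, 4)), "shape")
  expect_error(grid3d(c(4, 4, 4), spacing = c(1, 0, 1)), "spacing")
  g <- grid3d(c(4, 5, 6), c(1, 2, 3), c(-1, 0, 1))
  expect_equal(grid_extent(g), c(4, 10, 18))

  expect_error(volume3d(array(0, c(4, 5, 5)), g), "do not match")
  expect_error(labelmap(array(9L, c(4, 5, 6)), g), "9")
  # empty (all-zero) label map is legal: an empty lung mask
  lm <- labelmap(array(0L, c(4, 5, 6)), g)
  expect_equal(sum(lung_mask(lm)), 0)

  expect_error(subject_record("S1", 110, "normal"), "fibrosis_extent")
  expect_error(subject_record("S1", 50, "normal", fvc_l = -1), "fvc_l")
})

test_that("volumes round-trip through NIfTI with grid metadata intact", {
  vol <- toy_volume(spacing = c(1, 1, 3))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_grid_equal(back$grid, vol$grid)
  expect_equal(back$grid$spacing, c(1, 1, 3))
  expect_equal(back$values, vol$values, tolerance = 1e-6)
})

test_that("files stored in other axis orders read into identical patient-space content", {
  vol <- toy_volume()
  ref_path <- tempfile(fileext = ".nii.gz")
  write_volume(vol, ref_path)
  ref <- read_volume(ref_path)

  sp <- vol$grid$spacing
  or <- vol$grid$origin
  n <- vol$grid$shape
  # same physical content stored with flipped z, flipped x, and both
  variants <- list(
    list(flip = 3), list(flip = 1), list(flip = c(1, 3)))
  for (vr in variants) {
    a <- vol$values
    m <- rbind(c(-sp[1], 0, 0, -or[1]),
               c(0, -sp[2], 0, -or[2]),
               c(0, 0, sp[3], or[3]),
               c(0, 0, 0, 1))
    for (ax in vr$flip) {
      idx <- rep(list(quote(expr = )), 3)
      idx[[ax]] <- n[ax]:1
      a <- do.call(`[`, c(list(a), idx))
      # stored first voxel moves to the other end of the axis
      m[ax, 4] <- m[ax, 4] + m[ax, ax] * (n[ax] - 1)
      m[ax, ax] <- -m[ax, ax]
    }
    img <- RNifti::asNifti(a, pixdim = sp)
    RNifti::sform(img) <- structure(m, code = 2L)
    p <- tempfile(fileext = ".nii.gz")
    RNifti::writeNifti(img, p)
    got <- read_volume(p)
    expect_grid_equal(got$grid, ref$grid)
    expect_equal(got$values, ref$values, tolerance = 1e-6)
  }
})

test_that("degenerate or oblique NIfTI inputs are rejected", {
  # 4D dataset is not a scalar volume
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(read_volume(p4), "3D")
  # oblique direction cosines
  th <- 5 * pi / 180
  m <- rbind(c(-cos(th), -sin(th), 0, 0),
             c(sin(th), -cos(th), 0, 0),
             c(0, 0, 1, 0), c(0, 0, 0, 1))
  img <- RNifti::asNifti(array(0, c(6, 6, 6)))
  RNifti::sform(img) <- structure(m, code = 2L)
  po <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, po)
  expect_error(read_volume(po), "oblique")
})

test_that("label maps round-trip and reject non-legend labels", {
  pair <- small_pair()
  path <- tempfile(fileext = ".nii.gz")
  write_labelmap(pair$supine_labels, path)
  back <- read_labelmap(path)
  expect_identical(back$labels, pair$supine_labels$labels)
  expect_grid_equal(back$grid, pair$supine_labels$grid)

  bad <- RNifti::asNifti(array(9L, c(4, 4, 4)))
  pb <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(bad, pb)
  expect_error(read_labelmap(pb), "9")
})

test_that("subject CSV parsing validates records and tolerates missing FVC", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,fibrosis_extent,pattern_group,fvc_l",
               "S1,30,UIP_or_probable,2.8",
               "S2,0,normal,"), path)
  subs <- read_subjects(path)
  expect_length(subs, 2)
  expect_equal(subs[[1]]$fibrosis_extent, 30)
  expect_equal(subs[[1]]$fvc_l, 2.8)
  expect_true(is.na(subs[[2]]$fvc_l))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,fibrosis_extent,pattern_group,fvc_l",
               "S1,110,normal,2.8"), bad)
  expect_error(read_subjects(bad), "fibrosis_extent")

  nocol <- tempfile(fileext = ".csv")
  writeLines(c("id,extent", "S1,10"), nocol)
  expect_error(read_subjects(nocol), "missing columns")
})

test_that("displacement fields round-trip with unit metadata and validate shape", {
  pair <- small_pair()
  f <- pair$true_field
  path <- tempfile(fileext = ".nii.gz")
  export_field(f, path)
  back <- import_field(path, f$grid)
  expect_equal(back$vectors, f$vectors, tolerance = 1e-5)

  # voxel-unit conversion through spacing
  g <- grid3d(c(6, 6, 6), c(2, 2, 2))
  vec <- array(0, c(6, 6, 6, 3))
  vec[, , , 1] <- 1  # one voxel in x
  fv <- displacement_field(vec, g)
  pv <- tempfile(fileext = ".nii.gz")
  export_field(fv, pv)
  file.remove(paste0(pv, ".json"))
  expect_error(import_field(pv, g), "units")
  got <- import_field(pv, g, units = "voxels")
  expect_equal(unique(as.vector(got$vectors[, , , 1])), 2)

  # 2-component file is malformed
  img <- RNifti::asNifti(array(0, c(6, 6, 6, 2)))
  p2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, p2)
  expect_error(import_field(p2, g), "3 components")
})
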