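test_that("HSV channels encode per-axis movement with clamping at dmax", {
  g <- grid3d(c(10, 10, 10), c(3, 3, 3))
  lab <- array(0L, g$shape)
  lab[3:8, 3:8, 3:8] <- 1L
  lm <- labelmap(lab, g)
  cfg <- viz_config(slice_axis = "z", slice_fraction = 0.5, dmax_mm = 30)

  # zero field: V = 0, i.e. black lung pixels
  zf <- displacement_field(array(0, c(g$shape, 3)), g)
  img <- hsv_movement_map(zf, lm, cfg)
  hsv <- attr(img, "hsv")
  expect_true(all(hsv$v[hsv$lung] == 0))
  expect_true(all(img[, , 1][t(hsv$lung)[rev(seq_len(10)), ]] == 0))

  # pure z-motion at dmax: H = 0, S = 0, V = 1 -> white lung pixels
  vz <- array(0, c(g$shape, 3))
  vz[, , , 3] <- 30
  imgz <- hsv_movement_map(displacement_field(vz, g), lm, cfg)
  hz <- attr(imgz, "hsv")
  expect_true(all(hz$h[hz$lung] == 0))
  expect_true(all(hz$s[hz$lung] == 0))
  expect_true(all(hz$v[hz$lung] == 1))

  # clamping: motion beyond dmax saturates
  vbig <- array(0, c(g$shape, 3))
  vbig[, , , 3] <- 90
  hbig <- attr(hsv_movement_map(displacement_field(vbig, g), lm, cfg), "hsv")
  expect_true(all(hbig$v[hbig$lung] == 1))
})

test_that("per-channel encoding is monotone in the absolute component", {
  g <- grid3d(c(8, 8, 8), c(3, 3, 3))
  lab <- array(1L, g$shape)
  lm <- labelmap(lab, g)
  cfg <- viz_config(slice_axis = "z", dmax_mm = 30)
  vals <- c(0, 5, 12, 29, 30, 50)
  vs <- vapply(vals, function(d) {
    vec <- array(0, c(g$shape, 3))
    vec[, , , 3] <- d
    h <- attr(hsv_movement_map(displacement_field(vec, g), lm, cfg), "hsv")
    h$v[1, 1]
  }, numeric(1))
  expect_true(all(diff(vs) >= 0))
  expect_equal(vs[5], 1)
  expect_equal(vs[6], 1)
})

test_that("damped fibrotic regions render darker under z-dominant motion", {
  base <- list(shape = c(48, 48, 48), spacing_mm = c(6, 6, 6), seed = 3,
               fibrosis_extent = 0.5)
  damped <- generate_phantom_pair(do.call(phantom_spec,
                                          c(base, list(damping = 0.8))))
  undamped <- generate_phantom_pair(do.call(phantom_spec,
                                            c(base, list(damping = 0))))
  fib <- damped$fibrosis_mask
  k <- which(apply(fib, 3, sum) > 0)[1]
  cfg <- viz_config(slice_axis = "z", slice_index = k, dmax_mm = 30)
  hd <- attr(hsv_movement_map(damped$true_field, damped$supine_labels, cfg),
             "hsv")
  hu <- attr(hsv_movement_map(undamped$true_field, undamped$supine_labels, cfg),
             "hsv")
  sel <- fib[, , k] & abs(undamped$true_field$vectors[, , k, 3]) > 1
  expect_gt(sum(sel), 0)
  expect_true(all(hd$v[sel] < hu$v[sel]))
})

test_that("identical inputs render byte-identical PNG colour maps", {
  pair <- small_pair()
  cfg <- viz_config(slice_axis = "z", slice_fraction = 0.45)
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  hsv_movement_map(pair$true_field, pair$supine_labels, cfg,
                   background = pair$supine_vol, path = p1)
  hsv_movement_map(pair$true_field, pair$supine_labels, cfg,
                   background = pair$supine_vol, path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("quiver maps show only in-plane components at the configured stride", {
  g <- grid3d(c(12, 12, 12), c(3, 3, 3))
  lab <- array(1L, g$shape)
  lm <- labelmap(lab, g)
  cfg <- viz_config(slice_axis = "x", slice_fraction = 0.5, quiver_stride = 2)

  zf <- displacement_field(array(0, c(g$shape, 3)), g)
  a0 <- quiver_map(zf, lm, cfg)
  expect_equal(sum(a0$visible), 0)

  # uniform x-motion on an x-normal slice has no in-plane component
  vx <- array(0, c(g$shape, 3))
  vx[, , , 1] <- 10
  ax <- quiver_map(displacement_field(vx, g), lm, cfg)
  expect_equal(sum(ax$visible), 0)

  # uniform y-motion appears as identical parallel arrows
  vy <- array(0, c(g$shape, 3))
  vy[, , , 2] <- 10
  ay <- quiver_map(displacement_field(vy, g), lm, cfg)
  expect_true(all(ay$visible))
  expect_equal(unique(ay$u_mm), 10)
  expect_equal(unique(ay$v_mm), 0)

  # a PNG is actually written
  p <- tempfile(fileext = ".png")
  quiver_map(displacement_field(vy, g), lm, cfg, path = p)
  expect_true(file.size(p) > 0)
})

test_that("slices outside the volume are rejected", {
  g <- grid3d(c(8, 8, 8), c(3, 3, 3))
  lm <- labelmap(array(1L, g$shape), g)
  f <- displacement_field(array(0, c(g$shape, 3)), g)
  expect_error(hsv_movement_map(f, lm, viz_config(slice_index = 20)),
               "outside")
})
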