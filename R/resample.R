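# Shared resampling helpers. All resampling funnels through the trilinear /
# nearest C++ kernel; maps are given as physical positions (mm) in the source
# image's space.

# Sample `values` (array on src_grid) at physical positions px/py/pz (mm).
.sample_at_mm <- function(values, src_grid, px, py, pz, nearest = FALSE,
                          fill = 0, clamp_edge = FALSE) {
  out <- cpp_resample(as.double(values), src_grid$shape,
                      mm_to_voxel(px, src_grid, 1L),
                      mm_to_voxel(py, src_grid, 2L),
                      mm_to_voxel(pz, src_grid, 3L),
                      nearest, fill, clamp_edge)
  dim(out) <- if (is.array(px)) dim(px) else NULL
  out
}

#' Warp an image by a displacement field
#'
#' The output value at voxel `p` is the input sampled at physical position
#' `pos(p) + field(p)` — the resampling convention used throughout the
#' pipeline (fields map fixed-space points into moving-space points).
#' Volumes are interpolated linearly by default; label maps always use
#' nearest-neighbour so only legend labels can appear.
#'
#' @param img A [volume3d()] or [labelmap()] on the same grid as `field`.
#' @param field A [displacement_field()].
#' @param interpolation `"linear"` or `"nearest"` (volumes only; labels are
#'   always nearest).
#' @param fill Fill value for out-of-volume samples; defaults to -1024 for HU
#'   volumes, 0 for scaled volumes and label maps.
#' @return Object of the same class as `img`.
#' @export
apply_deformation <- function(img, field, interpolation = c("linear", "nearest"),
                              fill = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(field, "displacement_field"))
  grid <- if (inherits(img, "volume3d")) img$grid
          else if (inherits(img, "labelmap")) img$grid
          else stop("apply_deformation: 'img' must be a volume3d or labelmap")
  if (!grids_equal(grid, field$grid))
    stop("apply_deformation: image and field grids differ")
  pos <- voxel_coords(grid)
  px <- pos$x + field$vectors[, , , 1]
  py <- pos$y + field$vectors[, , , 2]
  pz <- pos$z + field$vectors[, , , 3]
  if (inherits(img, "labelmap")) {
    if (is.null(fill)) fill <- 0
    out <- .sample_at_mm(img$labels, grid, px, py, pz, nearest = TRUE,
                         fill = fill)
    return(labelmap(array(as.integer(round(out)), grid$shape), grid))
  }
  if (is.null(fill)) fill <- if (img$unit_tag == "HU") -1024 else 0
  out <- .sample_at_mm(img$values, grid, px, py, pz,
                       nearest = interpolation == "nearest", fill = fill)
  volume3d(array(out, grid$shape), grid, unit_tag = img$unit_tag)
}

# Numerically invert a displacement field by fixed-point iteration:
# g(q) = -f(q + g(q)). Valid for diffeomorphic fields (Jacobian > 0).
invert_field <- function(field, iterations = 12) {
  grid <- field$grid
  pos <- voxel_coords(grid)
  gx <- gy <- gz <- array(0, grid$shape)
  for (it in seq_len(iterations)) {
    px <- pos$x + gx; py <- pos$y + gy; pz <- pos$z + gz
    gx <- -.sample_at_mm(field$vectors[, , , 1], grid, px, py, pz, clamp_edge = TRUE)
    gy <- -.sample_at_mm(field$vectors[, , , 2], grid, px, py, pz, clamp_edge = TRUE)
    gz <- -.sample_at_mm(field$vectors[, , , 3], grid, px, py, pz, clamp_edge = TRUE)
  }
  displacement_field(array(c(gx, gy, gz), c(grid$shape, 3)), grid)
}

#' Jacobian determinant map of a displacement field
#'
#' Central-difference Jacobian determinant of the mapping `x -> x + field(x)`
#' at each interior voxel (border voxels are set to 1). Values below zero
#' indicate folding (a non-physical deformation); values above 1 indicate
#' local expansion of the mapped region.
#'
#' @param field A [displacement_field()].
#' @return A [volume3d()] of determinants (`unit_tag = "scaled"`).
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  grid <- field$grid
  det <- cpp_jacobian_det(as.double(field$vectors[, , , 1]),
                          as.double(field$vectors[, , , 2]),
                          as.double(field$vectors[, , , 3]),
                          grid$shape, grid$spacing)
  volume3d(array(det, grid$shape), grid, unit_tag = "scaled")
}
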