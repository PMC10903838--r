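# Preprocessing: resampling to a fixed cubic voxel grid and attenuation
# scaling, the two normalisation steps applied to every scan before
# segmentation and registration.

#' Preprocessing configuration
#'
#' @param cube_side Output voxels per axis (default 192, the production
#'   resolution; tests use smaller cubes).
#' @param attenuation_divisor Divisor applied to clipped HU (default 3000).
#' @param clip_hu Pair of HU clip bounds applied before scaling
#'   (default c(-1024, 600)); bounds interpolation overshoot and covers
#'   lung-window content.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(cube_side = 192, attenuation_divisor = 3000,
                              clip_hu = c(-1024, 600)) {
  cube_side <- as.integer(cube_side)
  if (is.na(cube_side) || cube_side < 16)
    stop("preprocess_config: cube_side must be an integer >= 16")
  if (attenuation_divisor <= 0)
    stop("preprocess_config: attenuation_divisor must be positive")
  if (length(clip_hu) != 2 || clip_hu[1] >= clip_hu[2])
    stop("preprocess_config: clip_hu must be an increasing pair")
  structure(list(cube_side = cube_side,
                 attenuation_divisor = attenuation_divisor,
                 clip_hu = as.numeric(clip_hu),
                 volume_interpolation = "linear",
                 label_interpolation = "nearest"),
            class = "preprocess_config")
}

#' Resample a volume or label map to a cubic voxel grid
#'
#' Produces a `cube_side`^3 image covering the same physical extent as the
#' input: output spacing per axis is `extent / cube_side` (spacing may end up
#' anisotropic; the extent is what is preserved). Volumes are interpolated
#' linearly, label maps nearest-neighbour, so no new labels can appear.
#'
#' @param img A [volume3d()] or [labelmap()].
#' @param cfg A [preprocess_config()].
#' @return Object of the same class on the cubic grid.
#' @export
resample_to_cube <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  grid <- img$grid
  n <- cfg$cube_side
  extent <- grid_extent(grid)
  new_spacing <- extent / n
  # voxel centres of the new grid span the same physical extent: the first
  # centre sits half a new voxel from the edge of the old first voxel
  new_origin <- grid$origin - grid$spacing / 2 + new_spacing / 2
  ng <- grid3d(rep(n, 3), new_spacing, new_origin)
  pos <- voxel_coords(ng)
  if (inherits(img, "labelmap")) {
    out <- .sample_at_mm(img$labels, grid, pos$x, pos$y, pos$z, nearest = TRUE,
                         fill = 0)
    return(labelmap(array(as.integer(round(out)), ng$shape), ng))
  }
  fill <- if (img$unit_tag == "HU") -1024 else 0
  out <- .sample_at_mm(img$values, grid, pos$x, pos$y, pos$z, fill = fill)
  volume3d(array(out, ng$shape), ng, unit_tag = img$unit_tag)
}

#' Scale CT attenuation for registration
#'
#' Clips HU to `cfg$clip_hu` and divides by the attenuation divisor, giving
#' O(1) intensities (and O(1) gradients) for the deformable registration.
#' Refuses already-scaled input to guard against double scaling.
#'
#' @param vol A [volume3d()] with `unit_tag = "HU"`.
#' @param cfg A [preprocess_config()].
#' @return A [volume3d()] with `unit_tag = "scaled"`.
#' @export
scale_attenuation <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "volume3d"), inherits(cfg, "preprocess_config"))
  if (vol$unit_tag != "HU")
    stop("scale_attenuation: input is already scaled")
  v <- pmin(pmax(vol$values, cfg$clip_hu[1]), cfg$clip_hu[2])
  volume3d(array(v / cfg$attenuation_divisor, vol$grid$shape), vol$grid,
           unit_tag = "scaled")
}

#' Undo attenuation scaling
#' @param vol A scaled [volume3d()].
#' @param cfg The [preprocess_config()] used to scale.
#' @return A [volume3d()] in (clipped) HU.
#' @export
unscale_attenuation <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "volume3d"))
  if (vol$unit_tag != "scaled")
    stop("unscale_attenuation: input is not scaled")
  volume3d(vol$values * cfg$attenuation_divisor, vol$grid, unit_tag = "HU")
}
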