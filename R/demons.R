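# Multi-resolution Gaussian-regularised demons deformable registration. The
# result is a dense displacement field on the fixed (supine) grid mapping
# fixed-space points into the (affine-registered) moving image's space.

#' Demons registration configuration
#'
#' @param levels Pyramid levels (default 3), each downsampling by 2.
#' @param iterations_per_level Iteration caps from coarsest to finest
#'   (default c(100, 60, 30); recycled/truncated to `levels`).
#' @param update_sigma_mm Gaussian sigma smoothing each update (default 2 mm).
#' @param field_sigma_mm Gaussian sigma smoothing the accumulated field each
#'   iteration (default 3 mm).
#' @param max_step_mm Per-iteration displacement-update cap (default 2 mm).
#' @param convergence_tol Relative MSE improvement below which a level stops
#'   (default 1e-4).
#' @param image_sigma_vox Gaussian presmoothing (in voxels of each pyramid
#'   level) applied to both images before force computation (default 1.0);
#'   suppresses voxel-scale noise gradients that would otherwise dominate
#'   the demons forces at fine levels.
#' @return A list of class `demons_config`.
#' @export
demons_config <- function(levels = 3, iterations_per_level = c(100, 60, 30),
                          update_sigma_mm = 2.0, field_sigma_mm = 3.0,
                          max_step_mm = 2.0, convergence_tol = 1e-4,
                          image_sigma_vox = 1.0) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 1) stop("demons_config: levels must be >= 1")
  iterations_per_level <- rep(as.integer(iterations_per_level),
                              length.out = levels)
  if (any(iterations_per_level < 1))
    stop("demons_config: iterations_per_level must be positive")
  if (update_sigma_mm <= 0 || field_sigma_mm <= 0 || max_step_mm <= 0 ||
      convergence_tol <= 0)
    stop("demons_config: sigmas, max_step_mm and convergence_tol must be positive")
  if (image_sigma_vox < 0)
    stop("demons_config: image_sigma_vox must be >= 0")
  structure(list(levels = levels,
                 iterations_per_level = iterations_per_level,
                 update_sigma_mm = update_sigma_mm,
                 field_sigma_mm = field_sigma_mm,
                 max_step_mm = max_step_mm,
                 convergence_tol = convergence_tol,
                 image_sigma_vox = image_sigma_vox),
            class = "demons_config")
}

# Downsample a volume array by an integer factor with pre-smoothing.
.pyramid_level <- function(values, grid, factor) {
  if (factor == 1) return(list(values = values, grid = grid))
  sm <- array(cpp_gaussian3d(as.double(values), grid$shape,
                             rep(0.5 * factor, 3)), grid$shape)
  new_shape <- pmax(8L, as.integer(floor(grid$shape / factor)))
  new_spacing <- grid_extent(grid) / new_shape
  ng <- grid3d(new_shape, new_spacing,
               grid$origin + (new_spacing - grid$spacing) / 2)
  pos <- voxel_coords(ng)
  out <- .sample_at_mm(sm, grid, pos$x, pos$y, pos$z, clamp_edge = TRUE)
  list(values = array(out, new_shape), grid = ng)
}

# Resample a field component array from one grid to another (mm values carry
# over unchanged).
.resample_component <- function(comp, from_grid, to_grid) {
  pos <- voxel_coords(to_grid)
  array(.sample_at_mm(comp, from_grid, pos$x, pos$y, pos$z, clamp_edge = TRUE),
        to_grid$shape)
}

#' Demons deformable registration
#'
#' Classic additive demons with dual Gaussian regularisation, run over a
#' multi-resolution pyramid. Per iteration: the moving image is warped by the
#' current field, an optical-flow-like update
#' `u = -(m_warped - f) * grad(m_warped) / (|grad|^2 + (m_warped - f)^2 / kappa)`
#' (with `kappa` the mean voxel spacing squared) is computed, capped at
#' `max_step_mm`, smoothed with `update_sigma_mm`, added to the field, and
#' the field re-smoothed with `field_sigma_mm`. Levels stop on their
#' iteration cap or when the relative MSE improvement falls below
#' `convergence_tol`.
#'
#' Intensities should be on a common scale for both images (e.g. both passed
#' through [scale_attenuation()]), so gradients are O(1).
#'
#' @param fixed,moving [volume3d()]s on the same grid with the same
#'   `unit_tag`.
#' @param cfg A [demons_config()].
#' @param mask Optional [labelmap()]; updates are restricted to a 15 mm
#'   dilation of its non-zero voxels.
#' @return A [displacement_field()] on the fixed grid, with attribute
#'   `mse_trace` (list of per-level MSE traces).
#' @export
register_deformable <- function(fixed, moving, cfg = demons_config(),
                                mask = NULL) {
  stopifnot(inherits(fixed, "volume3d"), inherits(moving, "volume3d"),
            inherits(cfg, "demons_config"))
  if (!grids_equal(fixed$grid, moving$grid))
    stop("register_deformable: fixed and moving grids differ (run the affine ",
         "stage first)")
  if (fixed$unit_tag != moving$unit_tag)
    stop("register_deformable: fixed and moving are on different intensity scales")
  if (!all(is.finite(fixed$values)) || !all(is.finite(moving$values)))
    stop("register_deformable: non-finite intensities")
  grid <- fixed$grid
  mask_arr <- NULL
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "labelmap"))
    if (!grids_equal(mask$grid, grid))
      stop("register_deformable: mask grid differs from the fixed grid")
    mask_arr <- as.double(.dilate(lung_mask(mask), grid, 15))
    dim(mask_arr) <- grid$shape
  }
  factors <- 2^((cfg$levels - 1):0)
  f_grid <- NULL
  fx <- fy <- fz <- NULL
  traces <- vector("list", cfg$levels)
  for (li in seq_len(cfg$levels)) {
    fac <- factors[li]
    fl <- .pyramid_level(fixed$values, grid, fac)
    ml <- .pyramid_level(moving$values, grid, fac)
    if (cfg$image_sigma_vox > 0) {
      sg <- rep(cfg$image_sigma_vox, 3)
      fl$values <- array(cpp_gaussian3d(as.double(fl$values), fl$grid$shape, sg),
                         fl$grid$shape)
      ml$values <- array(cpp_gaussian3d(as.double(ml$values), ml$grid$shape, sg),
                         ml$grid$shape)
    }
    mk <- if (is.null(mask_arr)) numeric(0) else
      as.double(.pyramid_level(mask_arr, grid, fac)$values)
    if (is.null(f_grid)) {
      fx <- fy <- fz <- array(0, fl$grid$shape)
    } else {
      fx <- .resample_component(fx, f_grid, fl$grid)
      fy <- .resample_component(fy, f_grid, fl$grid)
      fz <- .resample_component(fz, f_grid, fl$grid)
    }
    res <- cpp_demons_level(as.double(fl$values), as.double(ml$values),
                            fl$grid$shape, fl$grid$spacing,
                            as.double(fx), as.double(fy), as.double(fz),
                            cfg$iterations_per_level[li],
                            cfg$update_sigma_mm, cfg$field_sigma_mm,
                            cfg$max_step_mm, cfg$convergence_tol, mk)
    fx <- array(res$fx, fl$grid$shape)
    fy <- array(res$fy, fl$grid$shape)
    fz <- array(res$fz, fl$grid$shape)
    traces[[li]] <- res$mse
    f_grid <- fl$grid
  }
  if (!identical(f_grid$shape, grid$shape)) {
    fx <- .resample_component(fx, f_grid, grid)
    fy <- .resample_component(fy, f_grid, grid)
    fz <- .resample_component(fz, f_grid, grid)
  }
  out <- displacement_field(array(c(fx, fy, fz), c(grid$shape, 3)), grid)
  attr(out, "mse_trace") <- traces
  out
}
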