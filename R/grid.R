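#' @useDynLib pronelung, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd
NULL

#' Lobe label legend
#'
#' Integer labels used by every label map in the package: 0 background,
#' 1 right upper lobe (RUL), 2 right middle lobe (RML), 3 right lower lobe
#' (RLL), 4 left upper lobe (LUL), 5 left lower lobe (LLL). Labels 1--3 form
#' the right lung, 4--5 the left lung, and 1--5 the whole lung.
#'
#' @format Named integer vector of length 6.
#' @export
lobe_legend <- c(background = 0L, RUL = 1L, RML = 2L, RLL = 3L,
                 LUL = 4L, LLL = 5L)

#' Construct a 3D sampling grid
#'
#' A `grid3d` fixes the geometry shared by volumes, label maps and
#' displacement fields: voxel counts, voxel spacing in mm, the physical
#' position of the first voxel, and the package axis convention
#' (+x patient right to left, +y anterior to posterior, +z inferior to
#' superior; 0-based voxel indices). The physical position of voxel
#' `(i, j, k)` is `origin + c(i, j, k) * spacing`.
#'
#' @param shape Integer triple of voxels per axis (each >= 2).
#' @param spacing Positive triple, mm per voxel.
#' @param origin Real triple, mm position of voxel (0, 0, 0).
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 2L))
    stop("grid3d: 'shape' must be an integer triple with all entries >= 2")
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("grid3d: 'spacing' must be a positive triple (mm)")
  if (length(origin) != 3L || anyNA(origin))
    stop("grid3d: 'origin' must be a real triple (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 axis_convention = "LPS+"),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("grid3d %dx%dx%d | spacing %.3g x %.3g x %.3g mm | origin (%g, %g, %g) | %s\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3], x$axis_convention))
  invisible(x)
}

#' Physical extent of a grid (mm per axis)
#' @param grid A `grid3d`.
#' @return Numeric triple, `shape * spacing`.
#' @export
grid_extent <- function(grid) grid$shape * grid$spacing

#' Test two grids for equality within tolerance
#' @param a,b `grid3d` objects.
#' @param tol Absolute tolerance on spacing and origin (mm).
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Construct a scalar volume on a grid
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid A `grid3d`.
#' @param unit_tag `"HU"` for raw CT attenuation, `"scaled"` after division by
#'   the attenuation divisor (see [scale_attenuation()]).
#' @return An object of class `volume3d` with fields `grid`, `values`,
#'   `unit_tag`.
#' @export
volume3d <- function(values, grid, unit_tag = c("HU", "scaled")) {
  unit_tag <- match.arg(unit_tag)
  if (!inherits(grid, "grid3d")) stop("volume3d: 'grid' must be a grid3d")
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume3d: 'values' must be a 3D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("volume3d: array dimensions ", paste(dim(values), collapse = "x"),
         " do not match grid shape ", paste(grid$shape, collapse = "x"))
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, unit_tag = unit_tag),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d [%s] range [%.4g, %.4g]\n", x$unit_tag,
              min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Construct a lobe label map on a grid
#'
#' @param labels 3D integer array matching `grid$shape`; only values in
#'   [lobe_legend] are allowed.
#' @param grid A `grid3d`.
#' @return An object of class `labelmap` with fields `grid`, `labels`,
#'   `legend`.
#' @export
labelmap <- function(labels, grid) {
  if (!inherits(grid, "grid3d")) stop("labelmap: 'grid' must be a grid3d")
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labelmap: 'labels' must be a 3D array")
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("labelmap: array dimensions do not match grid shape")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(lobe_legend))
  if (length(bad) > 0)
    stop("labelmap: labels outside the legend: ", paste(sort(bad), collapse = ", "))
  structure(list(grid = grid, labels = labels, legend = lobe_legend),
            class = "labelmap")
}

#' @export
print.labelmap <- function(x, ...) {
  present <- sort(unique(as.vector(x$labels)))
  cat("labelmap labels present:", paste(present, collapse = ", "), "\n")
  print(x$grid)
  invisible(x)
}

#' Binary lung masks from a label map
#'
#' @param lm A `labelmap`.
#' @param region One of `"whole"`, `"right"`, `"left"`, `"RUL"`, `"RML"`,
#'   `"RLL"`, `"LUL"`, `"LLL"`, `"lower"` (RLL + LLL).
#' @return Logical 3D array.
#' @export
lung_mask <- function(lm, region = "whole") {
  labs <- switch(region,
                 whole = 1:5, right = 1:3, left = 4:5,
                 RUL = 1L, RML = 2L, RLL = 3L, LUL = 4L, LLL = 5L,
                 lower = c(3L, 5L),
                 stop("lung_mask: unknown region '", region, "'"))
  array(lm$labels %in% labs, dim = dim(lm$labels))
}

#' Construct a displacement field on a grid
#'
#' The field lives on the fixed (supine) grid and maps fixed-space points to
#' moving-space points: the tissue at fixed voxel `p` is found at physical
#' position `pos(p) + field(p)` in the moving image. Components are mm in the
#' package axis convention, stored as a 4D array with the 4th dimension
#' ordered (x, y, z).
#'
#' @param vectors 4D numeric array, `grid$shape` by 3, finite entries only.
#' @param grid A `grid3d`.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid) {
  if (!inherits(grid, "grid3d")) stop("displacement_field: 'grid' must be a grid3d")
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("displacement_field: 'vectors' must be a shape x 3 4D array")
  if (!identical(as.integer(dim(vectors)[1:3]), grid$shape))
    stop("displacement_field: array dimensions do not match grid shape")
  if (!all(is.finite(vectors)))
    stop("displacement_field: non-finite entries in vectors")
  storage.mode(vectors) <- "double"
  structure(list(grid = grid, vectors = vectors), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("displacement_field | max |v| = %.3g mm\n", max(mag)))
  print(x$grid)
  invisible(x)
}

#' Per-voxel magnitude of a displacement field (mm)
#' @param field A `displacement_field`.
#' @return 3D numeric array of Euclidean norms.
#' @export
field_magnitude <- function(field) {
  sqrt(field$vectors[, , , 1]^2 + field$vectors[, , , 2]^2 +
         field$vectors[, , , 3]^2)
}

# Physical coordinates (mm) of every voxel, as three arrays of grid shape.
voxel_coords <- function(grid) {
  sh <- grid$shape
  xi <- grid$origin[1] + (0:(sh[1] - 1)) * grid$spacing[1]
  yj <- grid$origin[2] + (0:(sh[2] - 1)) * grid$spacing[2]
  zk <- grid$origin[3] + (0:(sh[3] - 1)) * grid$spacing[3]
  list(x = array(rep(xi, times = sh[2] * sh[3]), dim = sh),
       y = array(rep(rep(yj, each = sh[1]), times = sh[3]), dim = sh),
       z = array(rep(zk, each = sh[1] * sh[2]), dim = sh))
}

# mm positions -> 0-based voxel coordinates of `grid`, per axis
mm_to_voxel <- function(pos_mm, grid, axis) {
  (pos_mm - grid$origin[axis]) / grid$spacing[axis]
}

#' Subject metadata record
#'
#' @param subject_id Character scalar.
#' @param fibrosis_extent Percent of whole lung with fibrotic abnormality,
#'   in \[0, 100\] (visual scores come in units of 10%).
#' @param pattern_group One of `"normal"`, `"UIP_or_probable"`,
#'   `"indeterminate_or_alternative"`.
#' @param fvc_l Forced vital capacity in litres (> 0), or `NA` when missing.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, fibrosis_extent, pattern_group, fvc_l = NA_real_) {
  fibrosis_extent <- as.numeric(fibrosis_extent)
  if (is.na(fibrosis_extent) || fibrosis_extent < 0 || fibrosis_extent > 100)
    stop("subject_record: fibrosis_extent must be in [0, 100] (subject ",
         subject_id, ")")
  pattern_group <- match.arg(pattern_group,
                             c("normal", "UIP_or_probable",
                               "indeterminate_or_alternative"))
  fvc_l <- as.numeric(fvc_l)
  if (!is.na(fvc_l) && fvc_l <= 0)
    stop("subject_record: fvc_l must be positive or missing (subject ",
         subject_id, ")")
  structure(list(subject_id = as.character(subject_id),
                 fibrosis_extent = fibrosis_extent,
                 pattern_group = pattern_group, fvc_l = fvc_l),
            class = "subject_record")
}
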