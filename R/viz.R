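# Displacement-field visualisation: HSV movement colour maps and quiver maps
# on a chosen slice, plus the numeric HSV encoding itself (kept separate so
# it can be tested without touching a graphics device).

#' Visualisation configuration
#'
#' @param slice_axis `"x"`, `"y"` or `"z"`; the slice is taken perpendicular
#'   to this axis.
#' @param slice_fraction Position of the slice along the axis in (0, 1);
#'   ignored when `slice_index` is given.
#' @param slice_index 1-based slice index, or `NULL`.
#' @param dmax_mm Displacement magnitude at which each colour channel
#'   saturates (default 30 mm, comfortably above typical whole-lung maxima
#'   of ~2-3 cm).
#' @param quiver_stride Arrow spacing in voxels (default 6).
#' @param output_dpi PNG resolution hint (default 150).
#' @return A list of class `viz_config`.
#' @export
viz_config <- function(slice_axis = c("z", "x", "y"), slice_fraction = 0.5,
                       slice_index = NULL, dmax_mm = 30, quiver_stride = 6,
                       output_dpi = 150) {
  slice_axis <- match.arg(slice_axis)
  if (dmax_mm <= 0) stop("viz_config: dmax_mm must be positive")
  if (quiver_stride < 1) stop("viz_config: quiver_stride must be >= 1")
  structure(list(slice_axis = slice_axis, slice_fraction = slice_fraction,
                 slice_index = slice_index, dmax_mm = dmax_mm,
                 quiver_stride = as.integer(quiver_stride),
                 output_dpi = output_dpi),
            class = "viz_config")
}

.slice_ix <- function(grid, cfg) {
  ax <- match(cfg$slice_axis, c("x", "y", "z"))
  n <- grid$shape[ax]
  ix <- if (!is.null(cfg$slice_index)) as.integer(cfg$slice_index)
        else as.integer(round(cfg$slice_fraction * (n - 1))) + 1L
  if (ix < 1 || ix > n)
    stop("viz: slice index ", ix, " outside volume (axis ", cfg$slice_axis,
         " has ", n, " slices)")
  list(axis = ax, index = ix)
}

.take_slice <- function(arr, axis, index) {
  switch(axis, arr[index, , ], arr[, index, ], arr[, , index])
}

# numeric HSV -> RGB (h, s, v in [0, 1]); vectorised
.hsv_to_rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' HSV movement colour map of a displacement slice
#'
#' Encodes, for every lung voxel of the chosen slice, hue = |dx| / dmax,
#' saturation = |dy| / dmax and value = |dz| / dmax (each clamped at 1), so
#' the three colour channels carry right-left, anterior-posterior and
#' inferior-superior movement respectively; zero motion renders black and
#' pure saturated-channel motion follows the HSV wheel. Non-lung pixels show
#' the anatomical background volume in greyscale when supplied.
#'
#' @param field A [displacement_field()].
#' @param mask A [labelmap()] on the same grid.
#' @param cfg A [viz_config()].
#' @param background Optional [volume3d()] rendered as greyscale outside the
#'   lung (window -1000..200 HU).
#' @param path Optional PNG output path.
#' @return Invisibly, the RGB array (rows x cols x 3, values in \[0, 1\])
#'   with attribute `hsv` (the raw channel arrays).
#' @export
hsv_movement_map <- function(field, mask, cfg = viz_config(),
                             background = NULL, path = NULL) {
  stopifnot(inherits(field, "displacement_field"), inherits(mask, "labelmap"))
  if (!grids_equal(field$grid, mask$grid))
    stop("hsv_movement_map: field and mask grids differ")
  sl <- .slice_ix(field$grid, cfg)
  dx <- abs(.take_slice(field$vectors[, , , 1], sl$axis, sl$index))
  dy <- abs(.take_slice(field$vectors[, , , 2], sl$axis, sl$index))
  dz <- abs(.take_slice(field$vectors[, , , 3], sl$axis, sl$index))
  lung <- .take_slice(mask$labels, sl$axis, sl$index) > 0
  h <- pmin(dx / cfg$dmax_mm, 1)
  s <- pmin(dy / cfg$dmax_mm, 1)
  v <- pmin(dz / cfg$dmax_mm, 1)
  rgb <- .hsv_to_rgb(h, s, v)
  bg <- if (!is.null(background)) {
    bs <- .take_slice(background$values, sl$axis, sl$index)
    pmin(pmax((bs + 1000) / 1200, 0), 1)
  } else {
    array(0, dim(h))
  }
  r <- ifelse(lung, rgb$r, bg)
  g <- ifelse(lung, rgb$g, bg)
  b <- ifelse(lung, rgb$b, bg)
  # image rows run along the second in-plane axis; transpose for writePNG
  img <- array(c(r, g, b), c(dim(h), 3))
  img <- aperm(img, c(2, 1, 3))[rev(seq_len(dim(h)[2])), , , drop = FALSE]
  if (!is.null(path)) png::writePNG(img, path)
  out <- img
  attr(out, "hsv") <- list(h = h, s = s, v = v, lung = lung)
  invisible(out)
}

#' Quiver map of the in-plane displacement components
#'
#' Draws an arrow at every `quiver_stride`-th lung voxel of the chosen slice
#' showing the two in-plane displacement components, with length
#' proportional to mm. The out-of-plane component is not drawn; a uniform
#' field normal to the slice therefore produces no arrows.
#'
#' @param field A [displacement_field()].
#' @param mask A [labelmap()] on the same grid.
#' @param cfg A [viz_config()].
#' @param path Optional PNG output path.
#' @param min_arrow_mm Arrows shorter than this are suppressed
#'   (default 0.1 mm).
#' @return Invisibly, a data.frame of arrows: in-plane positions (mm) and
#'   components `u`, `v` (mm).
#' @export
quiver_map <- function(field, mask, cfg = viz_config(), path = NULL,
                       min_arrow_mm = 0.1) {
  stopifnot(inherits(field, "displacement_field"), inherits(mask, "labelmap"))
  if (!grids_equal(field$grid, mask$grid))
    stop("quiver_map: field and mask grids differ")
  sl <- .slice_ix(field$grid, cfg)
  inplane <- setdiff(1:3, sl$axis)
  u2 <- .take_slice(field$vectors[, , , inplane[1]], sl$axis, sl$index)
  v2 <- .take_slice(field$vectors[, , , inplane[2]], sl$axis, sl$index)
  lung <- .take_slice(mask$labels, sl$axis, sl$index) > 0
  d <- dim(u2)
  grid <- field$grid
  stride <- cfg$quiver_stride
  ii <- seq(1, d[1], by = stride)
  jj <- seq(1, d[2], by = stride)
  pts <- expand.grid(i = ii, j = jj)
  keep <- lung[cbind(pts$i, pts$j)]
  pts <- pts[keep, , drop = FALSE]
  px <- grid$origin[inplane[1]] + (pts$i - 1) * grid$spacing[inplane[1]]
  py <- grid$origin[inplane[2]] + (pts$j - 1) * grid$spacing[inplane[2]]
  uu <- u2[cbind(pts$i, pts$j)]
  vv <- v2[cbind(pts$i, pts$j)]
  len <- sqrt(uu^2 + vv^2)
  visible <- len >= min_arrow_mm
  arrows_df <- data.frame(x_mm = px, y_mm = py, u_mm = uu, v_mm = vv,
                          length_mm = len, visible = visible)
  if (!is.null(path)) {
    ext <- grid_extent(grid)[inplane]
    grDevices::png(path, width = 6 * cfg$output_dpi, height = 6 * cfg$output_dpi,
                   res = cfg$output_dpi)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(4, 4, 2, 1))
    graphics::plot(NA, xlim = c(0, ext[1]), ylim = c(ext[2], 0),
                   xlab = paste0(c("x", "y", "z")[inplane[1]], " (mm)"),
                   ylab = paste0(c("x", "y", "z")[inplane[2]], " (mm)"),
                   main = sprintf("in-plane displacement, %s-slice %d",
                                  cfg$slice_axis, sl$index), asp = 1)
    vis <- arrows_df[arrows_df$visible, , drop = FALSE]
    if (nrow(vis) > 0)
      graphics::arrows(vis$x_mm, vis$y_mm, vis$x_mm + vis$u_mm,
                       vis$y_mm + vis$v_mm, length = 0.04, col = "steelblue4")
    # reference arrow: 10 mm
    graphics::arrows(0.05 * ext[1], 0.95 * ext[2], 0.05 * ext[1] + 10,
                     0.95 * ext[2], length = 0.04, col = "black")
    graphics::text(0.05 * ext[1], 0.92 * ext[2], "10 mm", adj = 0, cex = 0.8)
  }
  invisible(arrows_df)
}
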