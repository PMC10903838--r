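# Classical threshold/morphology lung segmentation with lobar assignment from
# fissure planes or external masks, plus the QC gate that mirrors cohort
# exclusion of imperfect segmentations.

#' Segmentation configuration
#'
#' @param lung_hu_threshold Voxels below this HU are lung candidates
#'   (default -320; must lie in (-1024, 0)).
#' @param min_component_ml Connected components smaller than this are dropped
#'   (default 100 mL).
#' @param closing_radius_mm Morphological closing ball radius (default 3 mm).
#' @param qc_min_lung_ml,qc_max_lung_ml Physiologic whole-lung volume bounds
#'   for QC (defaults 1000 and 9000 mL, spanning plausible total lung
#'   capacities).
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(lung_hu_threshold = -320, min_component_ml = 100,
                                closing_radius_mm = 3, qc_min_lung_ml = 1000,
                                qc_max_lung_ml = 9000) {
  if (lung_hu_threshold <= -1024 || lung_hu_threshold >= 0)
    stop("segmentation_config: lung_hu_threshold must lie in (-1024, 0)")
  if (min_component_ml <= 0) stop("segmentation_config: min_component_ml must be positive")
  if (closing_radius_mm < 0) stop("segmentation_config: closing_radius_mm must be >= 0")
  if (qc_min_lung_ml >= qc_max_lung_ml)
    stop("segmentation_config: qc_min_lung_ml must be below qc_max_lung_ml")
  structure(list(lung_hu_threshold = lung_hu_threshold,
                 min_component_ml = min_component_ml,
                 closing_radius_mm = closing_radius_mm,
                 qc_min_lung_ml = qc_min_lung_ml,
                 qc_max_lung_ml = qc_max_lung_ml),
            class = "segmentation_config")
}

# binary morphology via the chamfer distance transform
.dilate <- function(mask, grid, r_mm) {
  if (r_mm <= 0) return(mask)
  d <- cpp_chamfer_dt(array(as.integer(mask), grid$shape), grid$shape, grid$spacing)
  array(d <= r_mm, grid$shape)
}

.erode <- function(mask, grid, r_mm) {
  if (r_mm <= 0) return(mask)
  d <- cpp_chamfer_dt(array(as.integer(!mask), grid$shape), grid$shape, grid$spacing)
  array(d > r_mm, grid$shape)
}

.close_mask <- function(mask, grid, r_mm) .erode(.dilate(mask, grid, r_mm), grid, r_mm)

#' Threshold/morphology whole-lung segmentation
#'
#' Deterministic classical segmenter standing in for a trained network:
#' (1) binarise below `lung_hu_threshold`; (2) drop components touching the
#' x/y grid border (exterior air); (3) drop components below
#' `min_component_ml`; (4) morphological closing with a ball of
#' `closing_radius_mm`; (5) split left/right lungs by the two largest
#' components, or by a mid-sagittal cut when they are fused. Right-lung
#' voxels get label 1 (lobes unresolved until [assign_lobes()]), left-lung
#' voxels label 4.
#'
#' @param vol A [volume3d()]; HU or scaled (the threshold is divided by the
#'   attenuation divisor when `unit_tag == "scaled"`).
#' @param cfg A [segmentation_config()].
#' @param attenuation_divisor Divisor assumed for scaled input (default 3000).
#' @return A [labelmap()] with labels 0, 1, 4.
#' @export
segment_lungs <- function(vol, cfg = segmentation_config(),
                          attenuation_divisor = 3000) {
  stopifnot(inherits(vol, "volume3d"), inherits(cfg, "segmentation_config"))
  grid <- vol$grid
  thr <- if (vol$unit_tag == "scaled")
    cfg$lung_hu_threshold / attenuation_divisor else cfg$lung_hu_threshold
  bin <- vol$values < thr
  lab <- cpp_label3d(array(as.integer(bin), grid$shape), grid$shape)
  if (max(lab) == 0) stop("segment_lungs: no voxels below threshold; segmentation failure")
  # components touching the x/y border are exterior air
  border_ids <- unique(c(lab[c(1, grid$shape[1]), , ], lab[, c(1, grid$shape[2]), ]))
  border_ids <- setdiff(border_ids, 0L)
  vox_ml <- prod(grid$spacing) / 1000
  counts <- tabulate(lab[lab > 0L])
  keep_ids <- setdiff(which(counts * vox_ml >= cfg$min_component_ml), border_ids)
  if (length(keep_ids) == 0)
    stop("segment_lungs: no lung-sized component after border and size ",
         "filtering; segmentation failure")
  mask <- array(lab %in% keep_ids, grid$shape)
  mask <- .close_mask(mask, grid, cfg$closing_radius_mm)
  if (!any(mask)) stop("segment_lungs: empty mask after closing; segmentation failure")
  # left/right split on the two largest components, mid-sagittal cut if fused
  lab2 <- cpp_label3d(array(as.integer(mask), grid$shape), grid$shape)
  counts2 <- sort(tabulate(lab2[lab2 > 0L]), decreasing = TRUE)
  pos <- voxel_coords(grid)
  out <- array(0L, grid$shape)
  if (max(lab2) >= 2 && length(counts2) >= 2 &&
      counts2[2] * vox_ml >= cfg$min_component_ml / 2) {
    ids <- order(tabulate(lab2[lab2 > 0L]), decreasing = TRUE)[1:2]
    cx <- vapply(ids, function(i) mean(pos$x[lab2 == i]), numeric(1))
    right_id <- ids[which.min(cx)]  # +x runs right -> left
    left_id <- ids[which.max(cx)]
    out[lab2 == right_id] <- 1L
    out[lab2 == left_id] <- 4L
  } else {
    mid <- sum(pos$x * mask) / sum(mask)
    out[mask & pos$x < mid] <- 1L
    out[mask & pos$x >= mid] <- 4L
  }
  labelmap(out, grid)
}

#' Fissure plane description
#'
#' A plane is `list(point = mm triple, normal = mm triple)`; a voxel at
#' physical position `x` lies on the positive side when
#' `dot(x - point, normal) > 0`. The set used by [assign_lobes()] is
#' `list(right_oblique =, right_horizontal =, left_oblique =)`, with lower
#' lobes on the positive side of the oblique planes and RUL on the positive
#' side of the horizontal plane.
#'
#' @name fissure_planes
NULL

#' Map fissure planes through an affine transform
#'
#' Planes transform with the point mapped directly and the normal by the
#' inverse transpose of the linear part; used to carry supine-space fissure
#' planes into the prone scan's coordinates via the estimated pose.
#'
#' @param fissures A [fissure_planes] list.
#' @param T An [affine_transform()] mapping the source space of the planes
#'   into the target space.
#' @return The transformed fissure-plane list.
#' @export
transform_fissures <- function(fissures, T) {
  stopifnot(inherits(T, "affine_transform"))
  M <- T$rotation %*% diag(T$scale)
  Mit <- t(solve(M))
  lapply(fissures, function(pl) {
    p <- pl$point
    point <- as.numeric(T$center + M %*% (p - T$center) + T$translation)
    normal <- as.numeric(Mit %*% pl$normal)
    list(point = point, normal = normal / sqrt(sum(normal^2)))
  })
}

.plane_side <- function(plane, px, py, pz) {
  (px - plane$point[1]) * plane$normal[1] +
    (py - plane$point[2]) * plane$normal[2] +
    (pz - plane$point[3]) * plane$normal[3] > 0
}

#' Assign lobe labels within segmented lungs
#'
#' Either adopts an externally supplied lobe label map (validated to agree
#' with the lung mask on at least 95% of lung voxels) or splits each lung by
#' geometric fissure planes (see [fissure_planes]): the right lung into RLL
#' (positive side of the right oblique plane), then RUL/RML by the horizontal
#' plane; the left lung into LLL/LUL by the left oblique plane.
#'
#' @param lungs A [labelmap()] with right/left labels (1 and 4).
#' @param fissures A fissure-plane list, or an external [labelmap()] with
#'   full lobe labels.
#' @param min_agreement Minimum voxel agreement for adopting an external map
#'   (default 0.95).
#' @return A [labelmap()] with labels 0-5.
#' @export
assign_lobes <- function(lungs, fissures, min_agreement = 0.95) {
  stopifnot(inherits(lungs, "labelmap"))
  whole <- lung_mask(lungs)
  if (inherits(fissures, "labelmap")) {
    ext <- fissures
    if (!grids_equal(ext$grid, lungs$grid))
      stop("assign_lobes: external lobe map grid differs from the lung mask grid")
    ext_whole <- lung_mask(ext)
    agree <- sum(whole & ext_whole) / max(1, sum(whole | ext_whole))
    if (agree < min_agreement)
      stop(sprintf(paste0("assign_lobes: external lobe map agrees with the ",
                          "lung mask on only %.1f%% of lung extent ",
                          "(minimum %.0f%%); QC failure"),
                   100 * agree, 100 * min_agreement))
    return(ext)
  }
  need <- c("right_oblique", "right_horizontal", "left_oblique")
  if (!is.list(fissures) || !all(need %in% names(fissures)))
    stop("assign_lobes: 'fissures' must be an external labelmap or a list ",
         "with planes ", paste(need, collapse = ", "))
  pos <- voxel_coords(lungs$grid)
  out <- array(0L, lungs$grid$shape)
  right <- lungs$labels == 1L | lungs$labels %in% c(2L, 3L)
  left <- lungs$labels %in% c(4L, 5L)
  rll <- right & .plane_side(fissures$right_oblique, pos$x, pos$y, pos$z)
  rul <- right & !rll & .plane_side(fissures$right_horizontal, pos$x, pos$y, pos$z)
  rml <- right & !rll & !rul
  lll <- left & .plane_side(fissures$left_oblique, pos$x, pos$y, pos$z)
  lul <- left & !lll
  out[rul] <- 1L; out[rml] <- 2L; out[rll] <- 3L; out[lul] <- 4L; out[lll] <- 5L
  labelmap(out, lungs$grid)
}

#' Segmentation quality-control gate
#'
#' Fails when the whole-lung volume falls outside the configured physiologic
#' bounds, when any expected lobe label is empty, or when the left/right
#' volume ratio is outside \[0.2, 5\].
#'
#' @param lm A [labelmap()].
#' @param cfg A [segmentation_config()].
#' @param expect_lobes Require all five lobe labels (default `TRUE` when any
#'   lobe-specific label is present).
#' @return A list with `pass` (logical) and `reasons` (character vector).
#' @export
qc_segmentation <- function(lm, cfg = segmentation_config(),
                            expect_lobes = NULL) {
  stopifnot(inherits(lm, "labelmap"))
  reasons <- character(0)
  vox_ml <- prod(lm$grid$spacing) / 1000
  counts <- vapply(1:5, function(l) sum(lm$labels == l), numeric(1))
  whole_ml <- sum(counts) * vox_ml
  if (whole_ml < cfg$qc_min_lung_ml || whole_ml > cfg$qc_max_lung_ml)
    reasons <- c(reasons,
                 sprintf("whole-lung volume %.0f mL outside [%.0f, %.0f] mL",
                         whole_ml, cfg$qc_min_lung_ml, cfg$qc_max_lung_ml))
  if (is.null(expect_lobes))
    expect_lobes <- any(lm$labels %in% c(2L, 3L, 5L))
  if (expect_lobes) {
    for (l in 1:5) {
      if (counts[l] == 0)
        reasons <- c(reasons, paste0("empty lobe: ",
                                     names(lobe_legend)[lobe_legend == l]))
    }
  }
  right_ml <- sum(counts[1:3]) * vox_ml
  left_ml <- sum(counts[4:5]) * vox_ml
  if (right_ml > 0 && left_ml > 0) {
    ratio <- left_ml / right_ml
    if (ratio < 0.2 || ratio > 5)
      reasons <- c(reasons, sprintf("left/right volume ratio %.2f outside [0.2, 5]", ratio))
  } else {
    reasons <- c(reasons, "one lung entirely missing")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}
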