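# Quantification layer: lobar/whole-lung volumes and prone-minus-supine
# changes, per-axis and 3D movement maxima from the displacement field, Dice
# overlap QC, and the per-subject pipeline orchestration.

.regions <- c("whole", "right", "left", "RUL", "RML", "RLL", "LUL", "LLL")

#' Regional lung volumes in mL
#'
#' Volume = voxel count x voxel volume (mm^3) / 1000, per lobe label and per
#' aggregate region (whole, right = RUL+RML+RLL, left = LUL+LLL).
#'
#' @param lm A [labelmap()].
#' @return Named numeric vector over
#'   `whole, right, left, RUL, RML, RLL, LUL, LLL`.
#' @export
region_volumes <- function(lm) {
  stopifnot(inherits(lm, "labelmap"))
  vox_ml <- prod(lm$grid$spacing) / 1000
  lob <- vapply(1:5, function(l) sum(lm$labels == l), numeric(1)) * vox_ml
  c(whole = sum(lob), right = sum(lob[1:3]), left = sum(lob[4:5]),
    RUL = lob[1], RML = lob[2], RLL = lob[3], LUL = lob[4], LLL = lob[5])
}

#' Prone-minus-supine volume change report
#'
#' Volumes are measured on each position's own (pre-registration) masks, so
#' the affine scaling applied during registration cannot distort them. The
#' sign convention is prone minus supine: positive means expansion in the
#' prone position.
#'
#' @param supine_lm,prone_lm [labelmap()]s (grids may differ).
#' @param require_lobes Error when either map is missing a lobe label
#'   (default `TRUE`).
#' @return A data.frame of class `volume_report` with columns `region`,
#'   `supine_ml`, `prone_ml`, `delta_ml`.
#' @export
volume_change <- function(supine_lm, prone_lm, require_lobes = TRUE) {
  s <- region_volumes(supine_lm)
  p <- region_volumes(prone_lm)
  if (require_lobes) {
    for (nm in c("supine", "prone")) {
      v <- if (nm == "supine") s else p
      missing_lobes <- names(v)[4:8][v[4:8] == 0]
      if (length(missing_lobes) > 0)
        stop("volume_change: ", nm, " map is missing lobes: ",
             paste(missing_lobes, collapse = ", "), " (QC failure)")
    }
  }
  out <- data.frame(region = .regions, supine_ml = unname(s),
                    prone_ml = unname(p), delta_ml = unname(p - s),
                    stringsAsFactors = FALSE)
  class(out) <- c("volume_report", class(out))
  out
}

#' Movement summary from a displacement field
#'
#' Over the lung voxels of `mask`, takes the given percentile (default 100,
#' i.e. the maximum) of the absolute x, y, z displacement components and of
#' the 3D Euclidean distance, reported in cm. The per-axis statistics use
#' absolute components (magnitudes per axis, not signed means).
#'
#' @param field A [displacement_field()].
#' @param mask A [labelmap()] on the same grid; the union of its non-zero
#'   labels defines the region.
#' @param percentile Percentile in (0, 100\] of the absolute displacement
#'   distributions (default 100).
#' @return A list of class `movement_summary` with `max_abs_x_cm`,
#'   `max_abs_y_cm`, `max_abs_z_cm`, `max_3d_cm`, `percentile_used`,
#'   `region_labels`.
#' @export
movement_summary <- function(field, mask, percentile = 100) {
  stopifnot(inherits(field, "displacement_field"), inherits(mask, "labelmap"))
  if (!grids_equal(field$grid, mask$grid))
    stop("movement_summary: field and mask grids differ")
  if (percentile <= 0 || percentile > 100)
    stop("movement_summary: percentile must lie in (0, 100]")
  sel <- mask$labels > 0L
  if (!any(sel)) stop("movement_summary: empty mask")
  dx <- abs(field$vectors[, , , 1][sel])
  dy <- abs(field$vectors[, , , 2][sel])
  dz <- abs(field$vectors[, , , 3][sel])
  d3 <- sqrt(dx^2 + dy^2 + dz^2)
  q <- function(v) if (percentile == 100) max(v) else
    unname(quantile(v, percentile / 100, type = 7))
  structure(list(max_abs_x_cm = q(dx) / 10, max_abs_y_cm = q(dy) / 10,
                 max_abs_z_cm = q(dz) / 10, max_3d_cm = q(d3) / 10,
                 percentile_used = percentile,
                 region_labels = sort(unique(as.vector(mask$labels[sel])))),
            class = "movement_summary")
}

#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined to have Dice 1
#' (identical emptiness).
#'
#' @param a,b Logical/integer 3D arrays of equal dimensions.
#' @return Numeric scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("dice: mask dimensions differ")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Run the full single-subject pipeline
#'
#' Orchestrates preprocessing (cube resampling + attenuation scaling),
#' segmentation (or adoption of supplied lobe masks), shear-free affine
#' registration of the prone lung mask onto the supine one with its Dice QC
#' gate, demons deformable registration of the scaled volumes, and the
#' quantification layer. QC failures are recorded, not thrown: a failed
#' subject comes back with `qc$pass = FALSE` and analytics skipped, matching
#' a cohort design where such subjects are excluded rather than aborting the
#' run.
#'
#' @param supine_vol,prone_vol [volume3d()]s in HU.
#' @param supine_labels,prone_labels Optional [labelmap()]s adopted as
#'   external lobe masks (validated against the internal segmentation).
#' @param fissures Optional [fissure_planes] list for lobar assignment when
#'   no external labels are given; without either, analysis proceeds with
#'   unlobed left/right masks (volume report restricted to whole/right/left).
#' @param subject_id Identifier carried into the result.
#' @param preprocess_cfg,segmentation_cfg,demons_cfg Module configurations.
#' @param qc_dice_threshold Affine QC gate (default 0.80).
#' @param movement_percentile Percentile for [movement_summary()]
#'   (default 100).
#' @return A list of class `subject_result`: `subject_id`, `qc`
#'   (`pass`, `reasons`), `volume_report`, `movement`, `dice_whole`,
#'   `dice_right`, `dice_left`, `affine`, `field`, `masks`.
#' @export
analyze_subject <- function(supine_vol, prone_vol, supine_labels = NULL,
                            prone_labels = NULL, fissures = NULL,
                            subject_id = "subject",
                            preprocess_cfg = NULL,
                            segmentation_cfg = segmentation_config(),
                            demons_cfg = demons_config(),
                            qc_dice_threshold = 0.80,
                            movement_percentile = 100) {
  if (is.null(preprocess_cfg))
    preprocess_cfg <- preprocess_config(cube_side = max(supine_vol$grid$shape))
  qc_reasons <- character(0)
  fail <- function(reasons) {
    structure(list(subject_id = subject_id,
                   qc = list(pass = FALSE, reasons = reasons),
                   volume_report = NULL, movement = NULL,
                   dice_whole = NA_real_, dice_right = NA_real_,
                   dice_left = NA_real_, affine = NULL, field = NULL,
                   masks = NULL),
              class = "subject_result")
  }

  sup <- resample_to_cube(supine_vol, preprocess_cfg)
  pro <- resample_to_cube(prone_vol, preprocess_cfg)

  seg_or_fail <- function(vol, external, fiss, what) {
    seg <- tryCatch(segment_lungs(vol, segmentation_cfg),
                    error = function(e) e)
    if (inherits(seg, "error"))
      return(list(error = paste0("segmentation_failure (", what, "): ",
                                 conditionMessage(seg))))
    lm <- seg
    if (!is.null(external)) {
      ext <- if (grids_equal(external$grid, vol$grid)) external
             else resample_to_cube(external, preprocess_cfg)
      adopted <- tryCatch(assign_lobes(lm, ext), error = function(e) e)
      if (inherits(adopted, "error"))
        return(list(error = paste0("segmentation_failure (", what, "): ",
                                   conditionMessage(adopted))))
      lm <- adopted
    } else if (!is.null(fiss)) {
      lm <- assign_lobes(lm, fiss)
    }
    qc <- qc_segmentation(lm, segmentation_cfg)
    if (!qc$pass)
      return(list(error = paste0("segmentation_failure (", what, "): ",
                                 paste(qc$reasons, collapse = "; "))))
    list(lm = lm)
  }
  s_seg <- seg_or_fail(sup, supine_labels, fissures, "supine")
  if (!is.null(s_seg$error)) return(fail(s_seg$error))
  # prone lobes from fissure planes are assigned after the affine estimate,
  # since the planes are defined in supine space and must follow the pose
  p_seg <- seg_or_fail(pro, prone_labels, NULL, "prone")
  if (!is.null(p_seg$error)) return(fail(p_seg$error))

  # affine: prone (moving) onto supine (fixed)
  T <- estimate_affine(p_seg$lm, s_seg$lm)
  prone_mask_reg <- apply_affine(p_seg$lm, T, sup$grid)
  aqc <- qc_affine(s_seg$lm, prone_mask_reg, qc_dice_threshold)
  if (!aqc$pass) return(fail(aqc$reasons))

  if (is.null(prone_labels) && !is.null(fissures)) {
    p_lm <- assign_lobes(p_seg$lm, transform_fissures(fissures, T))
    pqc <- qc_segmentation(p_lm, segmentation_cfg)
    if (!pqc$pass)
      return(fail(paste0("segmentation_failure (prone): ",
                         paste(pqc$reasons, collapse = "; "))))
    p_seg$lm <- p_lm
    prone_mask_reg <- apply_affine(p_lm, T, sup$grid)
  }

  # volumes on each position's own (pre-registration) masks
  have_lobes <- any(s_seg$lm$labels %in% c(2L, 3L, 5L)) &&
    any(p_seg$lm$labels %in% c(2L, 3L, 5L))
  vol_report <- volume_change(s_seg$lm, p_seg$lm, require_lobes = have_lobes)

  # deformable on scaled intensities
  sup_s <- scale_attenuation(sup, preprocess_cfg)
  pro_s <- scale_attenuation(pro, preprocess_cfg)
  pro_reg <- apply_affine(pro_s, T, sup$grid, fill = pro_s$values[1])
  field <- register_deformable(sup_s, pro_reg, demons_cfg)

  warped_prone_mask <- apply_deformation(prone_mask_reg, field)
  d_whole <- dice(lung_mask(s_seg$lm), lung_mask(warped_prone_mask))
  d_right <- dice(lung_mask(s_seg$lm, "right"), lung_mask(warped_prone_mask, "right"))
  d_left <- dice(lung_mask(s_seg$lm, "left"), lung_mask(warped_prone_mask, "left"))
  movement <- movement_summary(field, s_seg$lm, movement_percentile)

  structure(list(subject_id = subject_id,
                 qc = list(pass = TRUE, reasons = character(0),
                           affine_dice = aqc$dice),
                 volume_report = vol_report, movement = movement,
                 dice_whole = d_whole, dice_right = d_right,
                 dice_left = d_left, affine = T, field = field,
                 masks = list(supine = s_seg$lm, prone = p_seg$lm,
                              prone_registered = prone_mask_reg,
                              prone_warped = warped_prone_mask)),
            class = "subject_result")
}

#' Flatten subject results into a cohort data frame
#'
#' @param results List of [analyze_subject()] results.
#' @return data.frame with one row per subject: volumes and deltas per
#'   region (mL), movement maxima (cm), Dice values and QC status.
#' @export
results_to_df <- function(results) {
  rows <- lapply(results, function(r) {
    base <- data.frame(subject_id = r$subject_id, qc_pass = r$qc$pass,
                       qc_reasons = paste(r$qc$reasons, collapse = "; "),
                       stringsAsFactors = FALSE)
    if (!is.null(r$volume_report)) {
      vr <- r$volume_report
      for (i in seq_len(nrow(vr))) {
        base[[paste0("supine_", vr$region[i], "_ml")]] <- vr$supine_ml[i]
        base[[paste0("prone_", vr$region[i], "_ml")]] <- vr$prone_ml[i]
        base[[paste0("delta_", vr$region[i], "_ml")]] <- vr$delta_ml[i]
      }
    }
    if (!is.null(r$movement)) {
      base$max_x_cm <- r$movement$max_abs_x_cm
      base$max_y_cm <- r$movement$max_abs_y_cm
      base$max_z_cm <- r$movement$max_abs_z_cm
      base$max_3d_cm <- r$movement$max_3d_cm
    }
    base$dice_whole <- r$dice_whole
    base$dice_right <- r$dice_right
    base$dice_left <- r$dice_left
    base
  })
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(all_cols, names(r))) r[[nm]] <- NA
    r[all_cols]
  })
  do.call(rbind, rows)
}
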