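# NIfTI and CSV readers/writers. All on-disk volumes are normalised on read to
# the package axis convention (+x right->left, +y anterior->posterior,
# +z inferior->superior), i.e. NIfTI "LPS" storage order, regardless of how
# the file stores its axes.

# Reorient a niftiImage to LPS and return list(values, grid). Errors on
# non-orthogonal (oblique) acquisitions.
.nifti_to_grid <- function(img, path, obliquity_tol = 1e-3) {
  code <- attr(RNifti::xform(img), "code")
  if (is.null(code) || code == 0) {
    # no spatial transform stored: take the array as already being in the
    # package axis order, with pixdim spacing and a zero origin
    values <- array(as.vector(as.array(img)), dim(img))
    sp <- abs(RNifti::pixdim(img))[seq_len(3)]
    sp[!is.finite(sp) | sp <= 0] <- 1
    return(list(values = values, grid = grid3d(dim(values)[1:3], sp, c(0, 0, 0))))
  }
  RNifti::orientation(img) <- "LPS"
  m <- RNifti::xform(img)
  rot <- m[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0))
    stop("read: degenerate voxel spacing in '", path, "'")
  dircos <- sweep(rot, 2, spacing, "/")
  # after LPS reorientation the direction cosines must be -x, -y, +z
  target <- diag(c(-1, -1, 1))
  if (max(abs(dircos - target)) > obliquity_tol)
    stop("read: '", path, "' has oblique voxel axes (direction cosines ",
         "deviate from axis-aligned by more than ", obliquity_tol,
         "); reslice upstream before import")
  # xform offset = RAS world position of voxel (0,0,0); convert to LPS
  origin <- c(-m[1, 4], -m[2, 4], m[3, 4])
  values <- array(as.vector(as.array(img)), dim(img))  # drop NIfTI attributes
  grid <- grid3d(dim(values), spacing, origin)
  list(values = values, grid = grid)
}

# Build an RNifti image whose sform encodes a grid under the package
# convention. dat may be 3D or 4D (4th dimension = vector components).
.grid_to_nifti <- function(dat, grid) {
  sp <- grid$spacing
  or <- grid$origin
  m <- rbind(c(-sp[1], 0, 0, -or[1]),
             c(0, -sp[2], 0, -or[2]),
             c(0, 0, sp[3], or[3]),
             c(0, 0, 0, 1))
  pd <- if (length(dim(dat)) == 4L) c(sp, 1) else sp
  img <- RNifti::asNifti(dat, pixdim = pd)
  RNifti::`sform<-`(img, structure(m, code = 2L))
}

#' Read a 3D NIfTI volume
#'
#' Reads a scalar NIfTI file, permutes/flips axes into the package
#' patient-anatomy convention, and extracts spacing and origin from the
#' stored transform. Oblique acquisitions (direction cosines further than
#' `1e-3` from axis-aligned after permutation) are rejected rather than
#' resliced.
#'
#' @param path Path to a `.nii` or `.nii.gz` file with a 3D scalar dataset.
#' @return A [volume3d()] with `unit_tag = "HU"`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("read_volume: '", path, "' is not a 3D scalar dataset (",
         length(dim(img)), " dimensions); displacement fields go through ",
         "import_field()")
  g <- .nifti_to_grid(img, path)
  volume3d(g$values, g$grid, unit_tag = "HU")
}

#' Write a 3D volume as NIfTI
#'
#' @param vol A [volume3d()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- .grid_to_nifti(vol$values, vol$grid)
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop("write_volume: cannot write '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}

#' Read a lobe label map from NIfTI
#'
#' As [read_volume()] but integer-valued; any label outside [lobe_legend]
#' raises a validation error naming the offending labels.
#'
#' @param path Path to a NIfTI file of integer labels.
#' @return A [labelmap()].
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path)) stop("read_labelmap: file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("read_labelmap: '", path, "' is not a 3D dataset")
  g <- .nifti_to_grid(img, path)
  vals <- round(g$values)
  if (max(abs(vals - g$values)) > 1e-6)
    stop("read_labelmap: '", path, "' contains non-integer values")
  labelmap(array(as.integer(vals), dim = dim(vals)), g$grid)
}

#' Write a lobe label map as NIfTI
#' @param lm A [labelmap()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labelmap <- function(lm, path) {
  stopifnot(inherits(lm, "labelmap"))
  img <- .grid_to_nifti(lm$labels, lm$grid)
  tryCatch(RNifti::writeNifti(img, path, datatype = "int16"),
           error = function(e) stop("write_labelmap: cannot write '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}

#' Read subject metadata from CSV
#'
#' Expects a header with columns `subject_id`, `fibrosis_extent`,
#' `pattern_group`, `fvc_l`; `fvc_l` may be blank (missing spirometry).
#'
#' @param path CSV path (UTF-8, comma-separated).
#' @return A list of [subject_record()] objects.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("read_subjects: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "fibrosis_extent", "pattern_group", "fvc_l")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("read_subjects: missing columns: ", paste(missing_cols, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    fvc <- df$fvc_l[i]
    if (is.character(fvc) && !nzchar(trimws(fvc))) fvc <- NA_real_
    subject_record(df$subject_id[i], df$fibrosis_extent[i],
                   df$pattern_group[i], fvc)
  })
}

#' Convert subject records to a data frame
#' @param subjects List of [subject_record()] objects.
#' @return data.frame with one row per subject.
#' @export
subjects_to_df <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s$subject_id, fibrosis_extent = s$fibrosis_extent,
               pattern_group = s$pattern_group, fvc_l = s$fvc_l,
               stringsAsFactors = FALSE)))
}

#' Write a displacement field as 4D NIfTI plus a units sidecar
#'
#' The 4th dimension holds the (x, y, z) components in the package
#' convention. A JSON sidecar (`<path>.json`) records the units (`"mm"`) and
#' component convention so that [import_field()] can validate them.
#'
#' @param field A [displacement_field()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
export_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- .grid_to_nifti(field$vectors, field$grid)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(units = "mm", components = "xyz",
                            convention = "LPS+"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Import an externally computed displacement field
#'
#' Accepts a 4D NIfTI with 3 components in (x, y, z) order. Units come from
#' the JSON sidecar written by [export_field()], or must be stated with
#' `units`; fields stored in voxel units are converted to mm through the
#' grid spacing.
#'
#' @param path Path to a 4D NIfTI file.
#' @param expected_grid A [grid3d()] the field must live on.
#' @param units `"mm"`, `"voxels"`, or `NULL` to require a sidecar.
#' @return A [displacement_field()] in mm on `expected_grid`.
#' @export
import_field <- function(path, expected_grid, units = NULL) {
  if (!file.exists(path)) stop("import_field: file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("import_field: '", path, "' must be 4D with 3 components, got ",
         paste(d, collapse = "x"))
  if (is.null(units)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("import_field: no units metadata for '", path,
           "'; pass units = \"mm\" or \"voxels\" explicitly")
    meta <- jsonlite::read_json(sidecar)
    units <- meta$units
  }
  units <- match.arg(units, c("mm", "voxels"))
  # vector components cannot be reoriented by axis permutation alone, so the
  # file must already be stored in the package (LPS) order
  if (!identical(RNifti::orientation(img), "LPS"))
    stop("import_field: '", path, "' is stored in ", RNifti::orientation(img),
         " order; fields must be written in LPS order (see export_field)")
  m <- RNifti::xform(img)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  origin <- c(-m[1, 4], -m[2, 4], m[3, 4])
  vec <- array(as.vector(as.array(img)), dim(img))
  g_in <- grid3d(dim(vec)[1:3], spacing, origin)
  if (!identical(g_in$shape, expected_grid$shape) ||
      !grids_equal(g_in, expected_grid, tol = 1e-3))
    stop("import_field: field grid does not match the expected grid")
  if (units == "voxels") {
    for (a in 1:3) vec[, , , a] <- vec[, , , a] * expected_grid$spacing[a]
  }
  displacement_field(vec, expected_grid)
}
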