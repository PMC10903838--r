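# Digital thoracic phantom: paired supine/prone volumes with five-lobe
# anatomy, a known pose difference, a known smooth dorsal-caudal deformation
# field, and fibrosis-like regions that locally damp the deformation. The
# generator is the ground-truth source for every recovery test in the
# package.

#' Phantom specification
#'
#' Defaults encode the study conditions the analysis assumes: a modest
#' residual prone-vs-supine pose difference (patient-anatomy coordinates
#' already absorb the 180-degree flip), a smooth dorsal-caudal expansion
#' peaking at `deformation_amplitude_mm`, a prone-minus-supine lower-lobe
#' volume gain targeted at `lower_lobe_expansion_ml`, and fibrosis-like
#' attenuation placed dorsal-basal subpleural whose displacement is damped
#' by `damping`.
#'
#' @param shape Voxels per axis (default c(96, 96, 96)).
#' @param spacing_mm mm per voxel (default c(3, 3, 3)).
#' @param lung_hu,body_hu,fibrosis_hu Tissue attenuations (defaults -850,
#'   40, -300 HU); exterior air is -1000 HU.
#' @param noise_sd_hu Gaussian noise standard deviation (default 20 HU),
#'   added independently to each scan after warping.
#' @param texture_sd_hu Standard deviation of the smooth parenchymal texture
#'   added inside the lungs (default 60 HU), emulating the
#'   vessel/parenchyma intensity structure that deformable registration
#'   tracks in real CT; it deforms with the anatomy (unlike `noise_sd_hu`).
#' @param texture_corr_mm Correlation length of the texture (default 12 mm).
#' @param fibrosis_extent Fraction of lung volume given fibrosis-like
#'   attenuation (default 0; at most 0.95).
#' @param pose_translation_mm,pose_euler_deg,pose_scale Pose of the prone
#'   scan relative to supine; `NULL` draws each uniformly from the default
#'   ranges (+-10 mm, +-8 degrees, scale in \[0.97, 1.03\], isotropic).
#' @param deformation_amplitude_mm Peak displacement magnitude (default 15).
#' @param damping Fractional amplitude reduction inside fibrotic voxels
#'   (default 0.8): the field there is multiplied by `1 - damping`.
#' @param lower_lobe_expansion_ml Target prone-minus-supine (RLL + LLL)
#'   volume gain (default 80 mL).
#' @param seed Integer seed; same seed, same phantom, bit for bit
#'   (Mersenne-Twister generator via R's default RNG).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing_mm = c(3, 3, 3),
                         lung_hu = -850, body_hu = 40, fibrosis_hu = -300,
                         noise_sd_hu = 20, texture_sd_hu = 60,
                         texture_corr_mm = 12, fibrosis_extent = 0,
                         pose_translation_mm = NULL, pose_euler_deg = NULL,
                         pose_scale = NULL, deformation_amplitude_mm = 15,
                         damping = 0.8, lower_lobe_expansion_ml = 80,
                         seed = 1L) {
  hu <- c(lung_hu, body_hu, fibrosis_hu)
  if (any(hu < -1024 | hu > 3071))
    stop("phantom_spec: HU values must lie in [-1024, 3071]")
  if (noise_sd_hu < 0) stop("phantom_spec: noise_sd_hu must be >= 0")
  if (texture_sd_hu < 0) stop("phantom_spec: texture_sd_hu must be >= 0")
  if (texture_corr_mm <= 0) stop("phantom_spec: texture_corr_mm must be positive")
  if (fibrosis_extent < 0 || fibrosis_extent > 0.95)
    stop("phantom_spec: fibrosis_extent must lie in [0, 0.95]; larger values ",
         "leave no compliant lung (infeasible spec)")
  if (deformation_amplitude_mm < 0)
    stop("phantom_spec: deformation_amplitude_mm must be >= 0")
  if (damping < 0 || damping > 1) stop("phantom_spec: damping must lie in [0, 1]")
  structure(list(shape = as.integer(rep(shape, length.out = 3)),
                 spacing_mm = as.numeric(rep(spacing_mm, length.out = 3)),
                 lung_hu = lung_hu, body_hu = body_hu, fibrosis_hu = fibrosis_hu,
                 noise_sd_hu = noise_sd_hu, texture_sd_hu = texture_sd_hu,
                 texture_corr_mm = texture_corr_mm,
                 fibrosis_extent = fibrosis_extent,
                 pose_translation_mm = pose_translation_mm,
                 pose_euler_deg = pose_euler_deg, pose_scale = pose_scale,
                 deformation_amplitude_mm = deformation_amplitude_mm,
                 damping = damping,
                 lower_lobe_expansion_ml = lower_lobe_expansion_ml,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Anatomy is laid out in fractions of the physical grid extent so any
# shape/spacing combination produces the same body plan.
.phantom_anatomy <- function(grid) {
  ext <- grid_extent(grid)
  pos <- voxel_coords(grid)
  u <- (pos$x - grid$origin[1] + grid$spacing[1] / 2) / ext[1]
  v <- (pos$y - grid$origin[2] + grid$spacing[2] / 2) / ext[2]
  w <- (pos$z - grid$origin[3] + grid$spacing[3] / 2) / ext[3]
  inside <- function(c3, s3) {
    ((u - c3[1]) / s3[1])^2 + ((v - c3[2]) / s3[2])^2 + ((w - c3[3]) / s3[3])^2 <= 1
  }
  body <- inside(c(0.50, 0.51, 0.50), c(0.47, 0.43, 0.49))
  right <- inside(c(0.31, 0.50, 0.54), c(0.155, 0.26, 0.33))
  left <- inside(c(0.69, 0.52, 0.54), c(0.145, 0.25, 0.32))
  # fissure planes in physical mm; lower lobes on the positive (dorsal-caudal)
  # side of the oblique planes
  mmpt <- function(f) grid$origin - grid$spacing / 2 + f * ext
  oblique_n <- c(0, sin(40 * pi / 180), -cos(40 * pi / 180))
  fissures <- list(
    right_oblique = list(point = mmpt(c(0.31, 0.52, 0.47)), normal = oblique_n),
    right_horizontal = list(point = mmpt(c(0.31, 0.44, 0.60)), normal = c(0, 0, 1)),
    left_oblique = list(point = mmpt(c(0.69, 0.54, 0.46)), normal = oblique_n))
  list(body = body, right = right & body, left = left & body,
       fissures = fissures, pos = pos)
}

# Smooth dorsal-caudal field: per lung, one constant-direction "movement"
# bump plus one radial "expansion" bump centred in the lower lobe. Returned
# as two normalised component fields (each with unit peak magnitude).
.phantom_bumps <- function(grid, labels) {
  pos <- voxel_coords(grid)
  ext <- grid_extent(grid)
  sig_move <- 0.14 * min(ext)
  sig_exp <- 0.16 * min(ext)
  dir_dc <- c(0, 0.6, -0.8)  # dorsal (+y), caudal (-z)
  zero <- array(0, grid$shape)
  move <- list(x = zero, y = zero, z = zero)
  expa <- list(x = zero, y = zero, z = zero)
  for (side in c("right", "left")) {
    lower_lab <- if (side == "right") 3L else 5L
    lung_labs <- if (side == "right") 1:3 else 4:5
    lsel <- labels %in% lung_labs
    sel <- labels == lower_lab
    if (!any(sel)) sel <- lsel
    cx <- mean(pos$x[sel]); cy <- mean(pos$y[sel]); cz <- mean(pos$z[sel])
    # dorsal-caudal shift of the movement-bump centre, placing peak motion in
    # the dorsal-basal region (where fibrosis sits when present)
    mx <- cx; my <- cy + 0.08 * ext[2]; mz <- cz - 0.06 * ext[3]
    r2m <- (pos$x - mx)^2 + (pos$y - my)^2 + (pos$z - mz)^2
    g <- exp(-r2m / (2 * sig_move^2))
    move$x <- move$x + dir_dc[1] * g
    move$y <- move$y + dir_dc[2] * g
    move$z <- move$z + dir_dc[3] * g
    # outward radial bump centred in the lower lobe: positive divergence
    # there, i.e. local volume gain of the mapped lobe
    dx <- pos$x - cx; dy <- pos$y - cy; dz <- pos$z - cz
    r2 <- dx^2 + dy^2 + dz^2
    ge <- exp(-r2 / (2 * sig_exp^2)) / (sig_exp * exp(-0.5))
    expa$x <- expa$x + dx * ge
    expa$y <- expa$y + dy * ge
    expa$z <- expa$z + dz * ge
  }
  norm_of <- function(f) max(sqrt(f$x^2 + f$y^2 + f$z^2))
  nm <- norm_of(move); ne <- norm_of(expa)
  list(move = lapply(move, function(a) a / nm),
       expand = lapply(expa, function(a) a / ne))
}

# Fibrosis mask: top `extent` fraction of lung voxels ranked by a
# dorsal-basal-subpleural score.
.phantom_fibrosis <- function(grid, lung, extent) {
  if (extent <= 0) return(array(FALSE, grid$shape))
  pos <- voxel_coords(grid)
  ext <- grid_extent(grid)
  v <- (pos$y - grid$origin[2]) / ext[2]
  w <- (pos$z - grid$origin[3]) / ext[3]
  dt <- cpp_chamfer_dt(array(as.integer(!lung), grid$shape), grid$shape,
                       grid$spacing)
  score <- 1.2 * v + 1.0 * (1 - w) + 0.6 * pmax(0, 1 - dt / 20)
  idx <- which(lung)
  k <- max(1L, round(extent * length(idx)))
  sel <- idx[order(score[idx], decreasing = TRUE)[seq_len(k)]]
  out <- array(FALSE, grid$shape)
  out[sel] <- TRUE
  out
}

# Smooth damping factor: exactly (1 - damping) at fibrotic voxels, ramping
# back to 1 over `ramp_mm` outside, so the damped field stays diffeomorphic
# and the attenuation of nearby compliant lung grows with `damping`.
.damping_factor <- function(grid, fibrosis, damping, ramp_mm = 48) {
  if (!any(fibrosis) || damping <= 0) return(array(1, grid$shape))
  dt <- cpp_chamfer_dt(array(as.integer(fibrosis), grid$shape), grid$shape,
                       grid$spacing)
  g <- pmax(0, 1 - dt / ramp_mm)
  1 - damping * g
}

#' Generate a paired supine/prone phantom
#'
#' Builds the supine anatomy (two ellipsoidal lungs inside a body ellipsoid,
#' partitioned into five lobes by fissure planes, with optional dorsal-basal
#' subpleural fibrosis), constructs the ground-truth displacement field and
#' pose, and produces the prone pair by warping the supine anatomy through
#' their composition, with independent noise on each scan.
#'
#' The ground-truth field lives on the supine grid and maps supine points to
#' affine-registered-prone points (the convention recovered by
#' [register_deformable()]). Before damping, its peak magnitude equals
#' `deformation_amplitude_mm` and its expansion component is scaled
#' iteratively until the prone-minus-supine lower-lobe volume gain is within
#' 2% of `lower_lobe_expansion_ml`. The field is then multiplied by
#' `1 - damping` inside fibrotic voxels (ramping smoothly back to 1 outside
#' them so the map cannot fold); with fibrosis present, peak movement and
#' realised lower-lobe gain therefore fall below the undamped values.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_pair` with fields `supine_vol`,
#'   `supine_labels`, `prone_vol`, `prone_labels`, `true_pose`, `true_field`,
#'   `fissures`, `fibrosis_mask`, and `spec`.
#' @export
generate_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  grid <- grid3d(spec$shape, spec$spacing_mm, origin = c(0, 0, 0))
  anat <- .phantom_anatomy(grid)
  lung <- anat$right | anat$left
  lungs_lr <- array(0L, grid$shape)
  lungs_lr[anat$right] <- 1L
  lungs_lr[anat$left] <- 4L
  labels <- assign_lobes(labelmap(lungs_lr, grid), anat$fissures)

  fibrosis <- .phantom_fibrosis(grid, lung, spec$fibrosis_extent)
  supine_hu <- array(-1000, grid$shape)
  supine_hu[anat$body] <- spec$body_hu
  supine_hu[lung] <- spec$lung_hu
  supine_hu[fibrosis] <- spec$fibrosis_hu
  if (spec$texture_sd_hu > 0) {
    # smooth correlated parenchymal texture; part of the anatomy, so it
    # deforms with the lungs
    tex <- array(rnorm(prod(grid$shape)), grid$shape)
    tex <- array(cpp_gaussian3d(as.double(tex), grid$shape,
                                spec$texture_corr_mm / grid$spacing),
                 grid$shape)
    tex <- tex / sd(tex) * spec$texture_sd_hu
    supine_hu[lung] <- supine_hu[lung] + tex[lung]
  }

  # pose: draw any unspecified component
  tr <- spec$pose_translation_mm
  eu <- spec$pose_euler_deg
  sc <- spec$pose_scale
  if (is.null(tr)) tr <- runif(3, -10, 10)
  if (is.null(eu)) eu <- runif(3, -8, 8)
  if (is.null(sc)) sc <- runif(1, 0.97, 1.03)
  lung_centroid <- c(mean(anat$pos$x[lung]), mean(anat$pos$y[lung]),
                     mean(anat$pos$z[lung]))
  pose <- affine_transform(translation = tr, euler_deg = eu, scale = sc,
                           center = lung_centroid)

  field <- .build_true_field(grid, labels, fibrosis, spec, pose)

  # prone pair: supine p corresponds to prone q = pose(p + field(p)); to
  # resample on the prone grid, invert: p = r + finv(r), r = pose^-1(q)
  prone <- .warp_supine_to_prone(supine_hu, labels$labels, grid, pose, field,
                                 spec)
  supine_vals <- supine_hu
  if (spec$noise_sd_hu > 0) {
    supine_vals <- supine_vals + array(rnorm(length(supine_hu), 0, spec$noise_sd_hu),
                                       grid$shape)
    prone$hu <- prone$hu + array(rnorm(length(supine_hu), 0, spec$noise_sd_hu),
                                 grid$shape)
  }
  structure(list(
    supine_vol = volume3d(supine_vals, grid, "HU"),
    supine_labels = labels,
    prone_vol = volume3d(prone$hu, grid, "HU"),
    prone_labels = labelmap(prone$labels, grid),
    true_pose = pose,
    true_field = field,
    fissures = anat$fissures,
    fibrosis_mask = fibrosis,
    spec = spec), class = "phantom_pair")
}

# Compose movement and expansion bumps and scale them so that, before
# damping, the peak magnitude equals the deformation amplitude and the
# lower-lobe volume gain matches the target (analytic Jacobian-integral
# solve, then refinement against the actually warped label map). The
# fibrosis damping factor is applied afterwards as a pure voxel-wise
# attenuation, so the field at fibrotic voxels is exactly (1 - damping)
# times the corresponding undamped field; with fibrosis present the realised
# lower-lobe gain falls below the target, mirroring restricted expansion in
# fibrotic lungs.
.build_true_field <- function(grid, labels, fibrosis, spec, pose) {
  amp <- spec$deformation_amplitude_mm
  zero4 <- array(0, c(grid$shape, 3))
  if (amp <= 0) return(displacement_field(zero4, grid))
  bumps <- .phantom_bumps(grid, labels$labels)
  lower <- labels$labels %in% c(3L, 5L)
  vox_ml <- prod(grid$spacing) / 1000
  det_scale <- prod(pose$scale)
  target <- spec$lower_lobe_expansion_ml
  lower_ml <- sum(lower) * vox_ml
  tol_ml <- 0.02 * max(1, abs(target))

  lungm <- labels$labels > 0L
  assemble <- function(a, b) {
    fx <- a * bumps$move$x + b * bumps$expand$x
    fy <- a * bumps$move$y + b * bumps$expand$y
    fz <- a * bumps$move$z + b * bumps$expand$z
    # the amplitude contract is on whole-lung movement, so the peak is taken
    # over lung voxels
    list(fx = fx, fy = fy, fz = fz,
         peak = max(sqrt(fx^2 + fy^2 + fz^2)[lungm]))
  }
  gain <- function(f) {
    det <- cpp_jacobian_det(f$fx, f$fy, f$fz, grid$shape, grid$spacing)
    det_scale * (lower_ml + sum((det[lower] - 1)) * vox_ml) - lower_ml
  }
  solve_b <- function(a, b_start, tgt) {
    b_prev <- b_start
    g_prev <- gain(assemble(a, b_prev))
    if (abs(g_prev - tgt) <= tol_ml / 2) return(b_prev)
    b_cur <- b_prev + max(1, amp / 4)
    g_cur <- gain(assemble(a, b_cur))
    for (i in 1:15) {
      if (abs(g_cur - tgt) <= tol_ml / 2 || abs(g_cur - g_prev) < 1e-9) break
      b_next <- b_cur + (tgt - g_cur) * (b_cur - b_prev) / (g_cur - g_prev)
      b_next <- max(-3 * amp, min(3 * amp, b_next))
      b_prev <- b_cur; g_prev <- g_cur
      b_cur <- b_next
      g_cur <- gain(assemble(a, b_cur))
    }
    b_cur
  }
  solve_ab <- function(tgt, a0, b0) {
    a <- a0; b <- b0
    for (outer in 1:6) {
      b <- solve_b(a, b, tgt)
      f <- assemble(a, b)
      if (f$peak <= 1e-9) break
      ratio <- amp / f$peak
      if (abs(ratio - 1) < 0.005) break
      a <- a * ratio
      # b is re-solved on the next pass with the updated movement weight
    }
    list(a = a, b = b)
  }
  # measured lower-lobe gain of the undamped field, via the actual label warp
  measure <- function(f) {
    fld <- displacement_field(array(c(f$fx, f$fy, f$fz), c(grid$shape, 3)),
                              grid)
    warped <- .warp_supine_to_prone(labels$labels * 0, labels$labels, grid,
                                    pose, fld, spec)
    sum(warped$labels %in% c(3L, 5L)) * vox_ml - lower_ml
  }
  ab <- solve_ab(target, amp, 0)
  internal_target <- target
  for (pass in 1:3) {
    f <- assemble(ab$a, ab$b)
    measured <- measure(f)
    if (abs(measured - target) <= tol_ml) break
    internal_target <- internal_target + (target - measured)
    ab <- solve_ab(internal_target, ab$a, ab$b)
  }
  f <- assemble(ab$a, ab$b)
  damp <- .damping_factor(grid, fibrosis, spec$damping)
  fx <- f$fx * damp; fy <- f$fy * damp; fz <- f$fz * damp
  det <- cpp_jacobian_det(fx, fy, fz, grid$shape, grid$spacing)
  if (any(det[lungm] <= 0))
    stop("generate_phantom_pair: deformation folds (non-positive Jacobian); ",
         "reduce deformation_amplitude_mm")
  displacement_field(array(c(fx, fy, fz), c(grid$shape, 3)), grid)
}

.warp_supine_to_prone <- function(supine_hu, labels_arr, grid, pose, field,
                                  spec) {
  finv <- invert_field(field)
  inv_pose <- invert_affine(pose)
  pos <- voxel_coords(grid)
  r <- .affine_points(inv_pose, pos$x, pos$y, pos$z)
  sx <- r$x + .sample_at_mm(finv$vectors[, , , 1], grid, r$x, r$y, r$z, clamp_edge = TRUE)
  sy <- r$y + .sample_at_mm(finv$vectors[, , , 2], grid, r$x, r$y, r$z, clamp_edge = TRUE)
  sz <- r$z + .sample_at_mm(finv$vectors[, , , 3], grid, r$x, r$y, r$z, clamp_edge = TRUE)
  hu <- .sample_at_mm(supine_hu, grid, sx, sy, sz, fill = -1000)
  lab <- .sample_at_mm(labels_arr, grid, sx, sy, sz, nearest = TRUE, fill = 0)
  list(hu = array(hu, grid$shape),
       labels = array(as.integer(round(lab)), grid$shape))
}

#' Generate a synthetic cohort with fibrosis/FVC covariate structure
#'
#' Draws per-subject fibrosis extent from a discrete distribution over
#' \{0, 10, ..., 70\}%, couples the deformation amplitude negatively to
#' fibrosis (`amplitude = a0 - a1 * extent + noise`, floored at 2 mm) and FVC
#' positively to amplitude (`fvc = b0 + b1 * amplitude + noise`), emulating
#' cohorts where more fibrotic lungs move less and better lung function goes
#' with more movement. Fibrotic subjects also get proportionally damped
#' lower-lobe expansion targets.
#'
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param shape,spacing_mm Phantom grid (default 64^3 at 4.5 mm, covering the
#'   same physical extent as the default 96^3 at 3 mm).
#' @param a0,a1,amp_noise_sd Amplitude model: intercept mm, slope mm per
#'   percent fibrosis, noise sd mm (defaults 20, 0.15, 2).
#' @param b0,b1,fvc_noise_sd FVC model: intercept L, slope L per mm, noise sd
#'   L (defaults 1.5, 0.08, 0.3).
#' @param extent_probs Probabilities of fibrosis extents 0-70% in 10% steps
#'   (default gently decreasing).
#' @param damping Damping inside fibrotic voxels (default 0.8).
#' @return A list of class `phantom_cohort`: `pairs` (list of
#'   [generate_phantom_pair()] outputs), `subjects` (list of
#'   [subject_record()]), and `params`.
#' @export
generate_cohort <- function(n, seed = 1L, shape = c(64, 64, 64),
                            spacing_mm = c(4.5, 4.5, 4.5),
                            a0 = 20, a1 = 0.15, amp_noise_sd = 2,
                            b0 = 1.5, b1 = 0.08, fvc_noise_sd = 0.3,
                            extent_probs = c(0.25, 0.2, 0.15, 0.12, 0.1,
                                             0.08, 0.06, 0.04),
                            damping = 0.8) {
  if (n < 2) stop("generate_cohort: n must be >= 2")
  stopifnot(length(extent_probs) == 8)
  draws <- withr::with_seed(seed, {
    extent <- sample(seq(0, 70, by = 10), n, replace = TRUE,
                     prob = extent_probs)
    amp <- pmax(2, a0 - a1 * extent + rnorm(n, 0, amp_noise_sd))
    fvc <- pmax(0.5, b0 + b1 * amp + rnorm(n, 0, fvc_noise_sd))
    pattern <- ifelse(extent == 0, "normal",
                      ifelse(extent >= 30, "UIP_or_probable",
                             "indeterminate_or_alternative"))
    list(extent = extent, amp = amp, fvc = fvc, pattern = pattern)
  })
  pairs <- vector("list", n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- phantom_spec(shape = shape, spacing_mm = spacing_mm,
                         fibrosis_extent = draws$extent[i] / 100,
                         deformation_amplitude_mm = draws$amp[i],
                         damping = damping,
                         lower_lobe_expansion_ml = 80 * draws$amp[i] / 15,
                         seed = seed * 1000L + i)
    pairs[[i]] <- generate_phantom_pair(spec)
    subjects[[i]] <- subject_record(sprintf("S%03d", i), draws$extent[i],
                                    draws$pattern[i], draws$fvc[i])
  }
  structure(list(pairs = pairs, subjects = subjects,
                 params = list(n = n, seed = seed, a0 = a0, a1 = a1,
                               amp_noise_sd = amp_noise_sd, b0 = b0, b1 = b1,
                               fvc_noise_sd = fvc_noise_sd,
                               extent_probs = extent_probs, damping = damping)),
            class = "phantom_cohort")
}
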