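# Shear-free affine transforms (translation + rotation + per-axis scale) and
# mask-driven affine registration. Transforms map fixed-space physical points
# to moving-space points:  T(x) = C + R %*% (s * (x - C)) + t.

#' Construct a shear-free affine transform
#'
#' Parameterised as translation + rotation + per-axis scale about a centre;
#' no shear term exists by construction. Rotations use intrinsic x-y-z Euler
#' angles in degrees (`R = Rx %*% Ry %*% Rz`). The transform maps fixed-space
#' points into moving-space points, the convention used when resampling a
#' moving image onto a fixed grid.
#'
#' @param translation mm triple.
#' @param euler_deg Rotation angles (degrees) about x, y, z.
#' @param scale Per-axis positive scale triple (or scalar, recycled).
#' @param center mm triple; centre of rotation and scaling.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(translation = c(0, 0, 0), euler_deg = c(0, 0, 0),
                             scale = c(1, 1, 1), center = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  euler_deg <- as.numeric(euler_deg)
  scale <- rep(as.numeric(scale), length.out = 3)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(euler_deg) == 3,
            length(center) == 3, all(scale > 0))
  R <- euler_to_rot(euler_deg)
  structure(list(translation = translation, euler_deg = euler_deg,
                 rotation = R, scale = scale, center = center),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("affine_transform | t = (%.2f, %.2f, %.2f) mm | euler = (%.2f, %.2f, %.2f) deg | scale = (%.4f, %.4f, %.4f)\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$euler_deg[1], x$euler_deg[2], x$euler_deg[3],
              x$scale[1], x$scale[2], x$scale[3]))
  invisible(x)
}

#' Rotation matrix from intrinsic x-y-z Euler angles (degrees)
#' @param euler_deg Angle triple in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_rot <- function(euler_deg) {
  a <- euler_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Euler angles (degrees, intrinsic x-y-z) from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return Angle triple in degrees.
#' @export
rot_to_euler <- function(R) {
  b <- asin(max(-1, min(1, R[1, 3])))
  if (abs(cos(b)) > 1e-8) {
    a <- atan2(-R[2, 3], R[3, 3])
    g <- atan2(-R[1, 2], R[1, 1])
  } else {  # gimbal lock; fold everything into a
    a <- atan2(R[3, 2], R[2, 2])
    g <- 0
  }
  c(a, b, g) * 180 / pi
}

# Apply transform to an n x 3 matrix (or list of 3 arrays) of physical points.
.affine_points <- function(T, px, py, pz) {
  cx <- px - T$center[1]; cy <- py - T$center[2]; cz <- pz - T$center[3]
  sx <- cx * T$scale[1]; sy <- cy * T$scale[2]; sz <- cz * T$scale[3]
  R <- T$rotation
  list(x = R[1, 1] * sx + R[1, 2] * sy + R[1, 3] * sz + T$center[1] + T$translation[1],
       y = R[2, 1] * sx + R[2, 2] * sy + R[2, 3] * sz + T$center[2] + T$translation[2],
       z = R[3, 1] * sx + R[3, 2] * sy + R[3, 3] * sz + T$center[3] + T$translation[3])
}

#' Invert a shear-free affine transform
#' @param T An `affine_transform`.
#' @return The inverse `affine_transform` (exact; closed under the type
#'   because `inv(R diag(s)) = diag(1/s) t(R)` re-decomposes as rotation times
#'   scale only when the scale is isotropic; anisotropic scales are inverted
#'   through the polar decomposition and validated shear-free).
#' @export
invert_affine <- function(T) {
  M <- T$rotation %*% diag(T$scale)
  Minv <- solve(M)
  # offset: x = C + Minv %*% (y - C - t)
  .decompose_linear(Minv, center = T$center,
                    translation = as.numeric(-Minv %*% T$translation))
}

#' Compose two shear-free affine transforms
#' @param A,B `affine_transform`s; the result applies `B` first, then `A`
#'   (i.e. `compose_affine(A, B)(x) = A(B(x))`).
#' @return An `affine_transform`.
#' @export
compose_affine <- function(A, B) {
  Ma <- A$rotation %*% diag(A$scale)
  Mb <- B$rotation %*% diag(B$scale)
  M <- Ma %*% Mb
  # affine offsets: A(B(x)) = Ma (Mb (x - Cb) + Cb + tb - Ca) + Ca + ta
  off <- as.numeric(Ma %*% (B$center + B$translation - A$center) +
                      A$center + A$translation)
  # express about Cb: M (x - Cb) + off  ==  Cb + t' + M (x - Cb)
  .decompose_linear(M, center = B$center,
                    translation = off - B$center)
}

# Polar-decompose a 3x3 linear map into rotation * diagonal scale, asserting
# the shear residual is negligible, and package as an affine_transform.
.decompose_linear <- function(M, center, translation, tol = 1e-6) {
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {  # reflections never arise from our compositions
    sv$v[, 3] <- -sv$v[, 3]
    sv$d[3] <- -sv$d[3]
    R <- sv$u %*% t(sv$v)
  }
  P <- t(R) %*% M  # symmetric positive factor; diagonal iff shear-free
  s <- diag(P)
  shear <- max(abs(P - diag(s)))
  if (shear > max(tol, 1e-8 * max(abs(s))))
    stop("affine decomposition: shear residual ", format(shear),
         " exceeds tolerance; transform is not shear-free")
  out <- affine_transform(translation = translation, euler_deg = rot_to_euler(R),
                          scale = s, center = center)
  out
}

#' Resample an image through an affine transform
#'
#' Produces the image on `target_grid` whose value at voxel `p` is the input
#' sampled at `T(pos(p))` — i.e. `T` maps target (fixed) points into the
#' input (moving) image's space. Linear interpolation for volumes, nearest
#' for label maps.
#'
#' @param img A [volume3d()] or [labelmap()].
#' @param T An [affine_transform()].
#' @param target_grid A [grid3d()]; defaults to the input grid.
#' @param fill Fill value for out-of-volume samples (default -1024 for HU,
#'   0 otherwise).
#' @return Object of the same class as `img` on `target_grid`.
#' @export
apply_affine <- function(img, T, target_grid = NULL, fill = NULL) {
  stopifnot(inherits(T, "affine_transform"))
  src_grid <- img$grid
  if (is.null(target_grid)) target_grid <- src_grid
  pos <- voxel_coords(target_grid)
  p <- .affine_points(T, pos$x, pos$y, pos$z)
  if (inherits(img, "labelmap")) {
    if (is.null(fill)) fill <- 0
    out <- .sample_at_mm(img$labels, src_grid, p$x, p$y, p$z, nearest = TRUE,
                         fill = fill)
    return(labelmap(array(as.integer(round(out)), target_grid$shape), target_grid))
  }
  if (is.null(fill)) fill <- if (img$unit_tag == "HU") -1024 else 0
  out <- .sample_at_mm(img$values, src_grid, p$x, p$y, p$z, fill = fill)
  volume3d(array(out, target_grid$shape), target_grid, unit_tag = img$unit_tag)
}

# Mask centroid and second-moment tensor in physical coordinates.
.mask_moments <- function(mask, grid) {
  w <- as.double(mask)
  n <- sum(w)
  if (n == 0) stop("mask moments: empty mask")
  pos <- voxel_coords(grid)
  cx <- sum(pos$x * w) / n; cy <- sum(pos$y * w) / n; cz <- sum(pos$z * w) / n
  dx <- as.double(pos$x) - cx; dy <- as.double(pos$y) - cy; dz <- as.double(pos$z) - cz
  S <- matrix(c(sum(dx * dx * w), sum(dx * dy * w), sum(dx * dz * w),
                sum(dx * dy * w), sum(dy * dy * w), sum(dy * dz * w),
                sum(dx * dz * w), sum(dy * dz * w), sum(dz * dz * w)),
              3, 3) / n
  list(centroid = c(cx, cy, cz), cov = S, n = n,
       volume_mm3 = n * prod(grid$spacing))
}

# Downsample a numeric array on `grid` to at most `max_side` voxels per axis.
.downsample_grid <- function(values, grid, max_side) {
  if (max(grid$shape) <= max_side) return(list(values = values, grid = grid))
  f <- max(grid$shape) / max_side
  new_shape <- pmax(8L, as.integer(round(grid$shape / f)))
  new_spacing <- grid_extent(grid) / new_shape
  ng <- grid3d(new_shape, new_spacing, grid$origin +
                 (new_spacing - grid$spacing) / 2)
  pos <- voxel_coords(ng)
  out <- .sample_at_mm(values, grid, pos$x, pos$y, pos$z, fill = 0,
                       clamp_edge = TRUE)
  list(values = array(out, new_shape), grid = ng)
}

#' Estimate a shear-free affine transform between two lung masks
#'
#' Mask-driven registration of the moving (prone) whole-lung mask onto the
#' fixed (supine) whole-lung mask. Stage 1 is a closed-form initialisation:
#' translation from the centroid difference, rotation from the principal axes
#' of the second-moment tensors (sign-disambiguated towards the identity),
#' and scale from the mask volume ratio (isotropic by default) or from
#' moment-eigenvalue ratios (anisotropic). Stage 2 refines all nine
#' parameters by a gradient-free pattern search on the mean squared mismatch
#' between Gaussian-softened masks, evaluated on a downsampled grid.
#'
#' @param moving_mask,fixed_mask [labelmap()]s (any non-zero label counts as
#'   lung); grids may differ.
#' @param isotropic_scale Lock the scale isotropic (default `TRUE`).
#' @param max_iter Pattern-search iteration cap (default 200).
#' @param param_tol Pattern-search step tolerance (default 1e-3; mm / degrees
#'   / scale units).
#' @param refine_max_side Masks are downsampled to at most this many voxels
#'   per axis for the refinement objective (default 48).
#' @return An [affine_transform()] with attributes `dice` (achieved whole-lung
#'   Dice on the fixed grid) and `init_dice`.
#' @export
estimate_affine <- function(moving_mask, fixed_mask, isotropic_scale = TRUE,
                            max_iter = 200, param_tol = 1e-3,
                            refine_max_side = 48) {
  stopifnot(inherits(moving_mask, "labelmap"), inherits(fixed_mask, "labelmap"))
  mv <- lung_mask(moving_mask); fx <- lung_mask(fixed_mask)
  if (!any(mv)) stop("estimate_affine: moving mask is empty")
  if (!any(fx)) stop("estimate_affine: fixed mask is empty")
  mm <- .mask_moments(mv, moving_mask$grid)
  fm <- .mask_moments(fx, fixed_mask$grid)

  ef <- eigen(fm$cov, symmetric = TRUE)
  em <- eigen(mm$cov, symmetric = TRUE)
  # principal-axes rotation with the 180-degree ambiguity resolved by taking
  # the proper rotation nearest the identity among column sign flips
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
    Vm <- em$vectors %*% diag(c(s1, s2, s3))
    R <- Vm %*% t(ef$vectors)
    if (det(R) < 0) next
    ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
    if (is.null(best) || ang < best$ang) best <- list(R = R, ang = ang)
  }
  R0 <- best$R
  scale0 <- if (isotropic_scale) {
    rep((mm$volume_mm3 / fm$volume_mm3)^(1 / 3), 3)
  } else {
    as.numeric(sqrt(em$values / ef$values))
  }
  init <- .decompose_linear(R0 %*% diag(scale0), center = fm$centroid,
                            translation = mm$centroid - fm$centroid)

  # soft masks for the refinement objective
  fxd <- .downsample_grid(as.double(fx), fixed_mask$grid, refine_max_side)
  mvd <- .downsample_grid(as.double(mv), moving_mask$grid, refine_max_side)
  soft <- function(v, g) {
    array(cpp_gaussian3d(as.double(v), g$shape, rep(1.2, 3)), g$shape)
  }
  fsoft <- soft(fxd$values, fxd$grid)
  msoft <- soft(mvd$values, mvd$grid)
  pos <- voxel_coords(fxd$grid)
  keep <- fsoft > 0.01
  objective <- function(theta) {
    T <- .theta_to_affine(theta, fm$centroid, isotropic_scale)
    p <- .affine_points(T, pos$x, pos$y, pos$z)
    smp <- .sample_at_mm(msoft, mvd$grid, p$x, p$y, p$z, fill = 0)
    mean((smp - fsoft)^2)
  }
  theta <- c(init$translation, init$euler_deg,
             if (isotropic_scale) init$scale[1] else init$scale)
  steps <- c(rep(2, 3), rep(2, 3), rep(0.02, length(theta) - 6))
  f0 <- objective(theta)
  init_obj <- f0
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (j in seq_along(theta)) {
      for (dir in c(1, -1)) {
        cand <- theta
        cand[j] <- cand[j] + dir * steps[j]
        fc <- objective(cand)
        if (fc < f0 - 1e-14) {
          theta <- cand; f0 <- fc; improved <- TRUE
          break
        }
      }
    }
    if (!improved) {
      steps <- steps / 2
      if (all(steps < param_tol)) break
    }
  }
  refined <- .theta_to_affine(theta, fm$centroid, isotropic_scale)

  dice_of <- function(T) {
    reg <- apply_affine(moving_mask, T, fixed_mask$grid)
    dice(lung_mask(reg), fx)
  }
  d_init <- dice_of(init)
  d_ref <- dice_of(refined)
  # refinement never worsens the result: fall back to the initialisation
  out <- if (d_ref >= d_init) refined else init
  attr(out, "dice") <- max(d_ref, d_init)
  attr(out, "init_dice") <- d_init
  out
}

.theta_to_affine <- function(theta, center, isotropic_scale) {
  scale <- if (isotropic_scale) rep(theta[7], 3) else theta[7:9]
  affine_transform(translation = theta[1:3], euler_deg = theta[4:6],
                   scale = scale, center = center)
}

#' Affine registration quality-control gate
#'
#' Mirrors cohort exclusion for registration failure: the subject fails QC
#' when the whole-lung Dice between the fixed mask and the affine-registered
#' moving mask falls below `threshold`.
#'
#' @param fixed_mask,registered_moving_mask [labelmap()]s on the same grid.
#' @param threshold Minimum acceptable Dice (default 0.80).
#' @return A list with `pass` (logical), `dice`, and `reasons` (character).
#' @export
qc_affine <- function(fixed_mask, registered_moving_mask, threshold = 0.80) {
  d <- dice(lung_mask(fixed_mask), lung_mask(registered_moving_mask))
  list(pass = d >= threshold, dice = d,
       reasons = if (d >= threshold) character(0)
                 else sprintf("registration_failure: whole-lung Dice %.3f < %.2f",
                              d, threshold))
}

#' Serialize / deserialize an affine transform as JSON
#' @param T An [affine_transform()].
#' @param path JSON output path.
#' @return `write_affine` returns `path` invisibly; `read_affine` returns the
#'   transform.
#' @export
write_affine <- function(T, path) {
  jsonlite::write_json(list(translation_mm = T$translation,
                            euler_deg = T$euler_deg, scale = T$scale,
                            center_mm = T$center,
                            convention = "xyz-intrinsic"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(j$translation_mm, j$euler_deg, j$scale, j$center_mm)
}
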