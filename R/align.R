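#' 6-parameter rigid transform
#'
#' Maps points from the moving (follow-up) space into the fixed (baseline)
#' space: `p_fixed = R (p - c) + c + t`, where `R` rotates about the x, then
#' y, then z axis (`R = Rz Ry Rx`, angles in degrees), `c` is the rotation
#' center (the fixed volume's grid center, see [world_center()]) and `t` is
#' the translation in mm. This convention is pinned so transform files are
#' portable.
#'
#' @param rotation_deg numeric length-3, Euler angles in degrees (x, y, z
#'   order).
#' @param translation_mm numeric length-3, translation in mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  if (length(rotation_deg) != 3L || any(!is.finite(rotation_deg)))
    stop("`rotation_deg` must be 3 finite angles")
  if (length(translation_mm) != 3L || any(!is.finite(translation_mm)))
    stop("`translation_mm` must be 3 finite lengths")
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg, x-y-z): %s; trans (mm): %s\n",
              paste(signif(x$rotation_deg, 5), collapse = ", "),
              paste(signif(x$translation_mm, 5), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return 3x3 rotation matrix (`Rz Ry Rx`).
#' @export
rotation_matrix <- function(transform) {
  a <- transform$rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

# Euler angles (degrees, x-y-z application order, R = Rz Ry Rx) from a
# rotation matrix; the y angle is taken in (-90, 90].
euler_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  y <- asin(sy)
  if (abs(cos(y)) > 1e-9) {
    x <- atan2(R[3, 2], R[3, 3])
    z <- atan2(R[2, 1], R[1, 1])
  } else { # gimbal lock
    x <- atan2(-R[2, 3], R[2, 2])
    z <- 0
  }
  c(x, y, z) * 180 / pi
}

#' Invert a rigid transform
#'
#' The inverse maps fixed-space points back into moving space, using the
#' same rotation-about-center convention (the center must be the same point
#' in both spaces, which holds for the grid-center convention used
#' throughout).
#'
#' @param transform a [rigid_transform()].
#' @return a [rigid_transform()] such that composing the two gives identity.
#' @export
invert_transform <- function(transform) {
  R <- rotation_matrix(transform)
  rigid_transform(euler_from_matrix(t(R)),
                  as.numeric(-t(R) %*% transform$translation_mm))
}

#' Apply a rigid transform to world points
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @param center rotation center (mm).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(transform, points, center = c(0, 0, 0)) {
  points <- matrix(points, ncol = 3)
  R <- rotation_matrix(transform)
  sweep(t(R %*% (t(points) - center)), 2, -center - transform$translation_mm)
}

#' Write / read a rigid transform as JSON
#'
#' The file records `rotation_deg`, `translation_mm` and the rotation-center
#' convention (`"volume_center"`).
#'
#' @param transform a [rigid_transform()].
#' @param path JSON path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(rotation_deg = transform$rotation_deg,
                            translation_mm = transform$translation_mm,
                            center = "volume_center"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation_deg, x$translation_mm)
}

#' Resample a volume under a rigid transform
#'
#' Produces the moving volume on the reference grid: each reference voxel is
#' mapped back through the inverse transform and interpolated in the moving
#' volume. Voxels that map outside the moving field of view are filled with
#' the moving volume's background value (its 1st intensity percentile)
#' unless `fill` is given. Rotation is about the reference grid center.
#'
#' @param moving,reference [volume_image()] objects.
#' @param transform [rigid_transform()] mapping moving space to reference
#'   space.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill out-of-field fill value; default 1st percentile of `moving`.
#' @return [volume_image()] on the reference grid.
#' @export
resample_volume <- function(moving, transform, reference,
                            interpolation = c("linear", "nearest"),
                            fill = NULL) {
  stopifnot(is_volume_image(moving), is_volume_image(reference))
  interpolation <- match.arg(interpolation)
  if (is.null(fill)) fill <- background_value(moving)
  cen <- world_center(reference)
  vals <- cpp_resample_rigid(
    as.double(moving$values), dim(moving$values), moving$spacing,
    moving$origin, dim(reference$values), reference$spacing,
    reference$origin, as.double(rotation_matrix(transform)),
    transform$translation_mm, cen, interpolation == "nearest", fill)
  volume_image(array(vals, dim(reference$values)), reference$spacing,
               reference$origin, unit_state = moving$unit_state)
}

#' @rdname resample_volume
#' @param mask a [binary_mask()]; masks must use nearest-neighbor
#'   interpolation (linear interpolation of a binary image is an error).
#' @export
resample_mask <- function(mask, transform, reference,
                          interpolation = "nearest") {
  stopifnot(is_binary_mask(mask))
  if (!identical(interpolation, "nearest"))
    stop("masks must be resampled with nearest-neighbor interpolation")
  vol <- volume_image(array(as.double(mask$values), dim(mask$values)),
                      mask$spacing, mask$origin)
  ref <- if (is_binary_mask(reference))
    volume_image(array(0, dim(reference$values)), reference$spacing,
                 reference$origin)
  else reference
  out <- resample_volume(vol, transform, ref, interpolation = "nearest",
                         fill = 0)
  binary_mask(out$values != 0, ref$spacing, ref$origin)
}

## ---- registration -------------------------------------------------------

# intensity-weighted center of mass (weights shifted to be non-negative)
intensity_center <- function(vol) {
  w <- vol$values - min(vol$values)
  d <- dim(w)
  tot <- sum(w)
  vapply(1:3, function(a) {
    m <- apply(w, a, sum)
    sum((vol$origin[a] + (seq_len(d[a]) - 1) * vol$spacing[a]) * m) / tot
  }, numeric(1))
}

msd_loss <- function(par, moving, fixed, cen, fill = NULL) {
  if (is.null(fill)) fill <- background_value(moving)
  m <- cpp_msd_rigid(
    as.double(moving$values), dim(moving$values), moving$spacing,
    moving$origin, as.double(fixed$values), dim(fixed$values),
    fixed$spacing, fixed$origin,
    as.double(rotation_matrix(rigid_transform(par[1:3], par[4:6]))),
    par[4:6], cen, fill)
  if (is.nan(m)) stop("non-finite registration loss")
  m # +Inf encodes insufficient overlap and is a valid (worst) value
}

# smooth + decimate one pyramid level: Gaussian sigma = max(1, factor/2)
# voxels, then pick every stride-th voxel (stride defaults to the
# decimation factor). The finest level is smoothed too (sigma 1): mild
# smoothing removes the interpolation-noise ripple of the squared-
# difference metric without blunting the sub-voxel optimum.
pyramid_level <- function(vol, factor, stride = max(1L, as.integer(factor))) {
  sm <- cpp_gauss_blur(as.double(vol$values), dim(vol$values),
                       rep(max(1, factor / 2), 3))
  arr <- array(sm, dim(vol$values))
  if (stride <= 1L)
    return(volume_image(arr, vol$spacing, vol$origin, vol$unit_state))
  d <- dim(arr)
  idx <- lapply(d, function(n) seq(1L, n, by = stride))
  volume_image(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               vol$spacing * stride, vol$origin, vol$unit_state)
}

#' Rigid registration by multi-resolution mean-squared-difference descent
#'
#' Estimates the rigid transform aligning `moving` onto `fixed` by
#' minimizing the mean squared intensity difference over the fixed grid,
#' coarse to fine (factor-4 and factor-2 smoothed/decimated levels, then
#' full resolution), with derivative-free Nelder-Mead simplex optimization
#' per level starting from `init`. Both inputs should be intensity
#' normalized first ([normalize_intensity()]): normalization removes the
#' per-scan CBCT gain/offset that would otherwise defeat a squared-
#' difference metric. The result never has a higher full-resolution loss
#' than `init` (the initial transform is returned if the optimizer fails to
#' improve on it), and the final loss is reported so callers can detect
#' convergence to a poor local optimum when started outside the capture
#' range. Deterministic given inputs and options.
#'
#' @param moving,fixed [volume_image()] objects with overlapping content.
#' @param init initial [rigid_transform()], or `NULL` (default) for
#'   automatic moments initialization: translation from the two intensity
#'   centers of mass, rotation from a coarse grid probe. This extends the
#'   capture range well beyond what a simplex started at identity can
#'   cross.
#' @param levels integer decimation factors, coarse to fine.
#' @param max_iterations Nelder-Mead iteration cap per level (recycled to
#'   the number of levels; the default spends most work on the cheap
#'   coarse levels and uses the full-resolution level as a short polish).
#' @param restarts extra Nelder-Mead restarts per level (recycled), kept
#'   while each restart still improves the loss; repeated restarts at the
#'   (cheap, sparsely sampled) finest level are what carry the search
#'   through the curved rotation-translation valley in which a single
#'   simplex collapses early.
#' @param fixed_stride extra sampling stride of the fixed grid per level
#'   (recycled). At the finest level the metric is evaluated on every
#'   second fixed voxel while the moving image stays at full resolution:
#'   sub-voxel information is preserved by the interpolation of the
#'   moving image, and the 8-fold cheaper evaluations buy the restarts.
#' @param reltol relative convergence tolerance of the simplex.
#' @return list with `transform` ([rigid_transform()]), `loss_init`,
#'   `loss_final` (mean squared difference at full resolution), and
#'   `improved`.
#' @export
register_rigid <- function(moving, fixed, init = NULL,
                           levels = c(4, 2, 1),
                           max_iterations = c(400, 200, 300),
                           restarts = c(1, 1, 5), fixed_stride = c(1, 1, 2),
                           reltol = 1e-9) {
  stopifnot(is_volume_image(moving), is_volume_image(fixed))
  if (stats::sd(fixed$values) == 0 || stats::sd(moving$values) == 0)
    stop("cannot register constant images")
  max_iterations <- rep_len(max_iterations, length(levels))
  cen <- world_center(fixed)
  if (is.null(init)) {
    # Global initialization: a Nelder-Mead simplex started at identity
    # cannot walk across several mm of misalignment. The translation comes
    # from the intensity centers of mass refined by an exhaustive coarse
    # grid (the moments estimate alone is biased when anatomy crosses the
    # field-of-view boundary), the rotation from a coarse grid probe.
    t0 <- intensity_center(fixed) - intensity_center(moving)
    mv8 <- pyramid_level(moving, 2 * max(levels))
    fx8 <- pyramid_level(fixed, 2 * max(levels))
    fill8 <- background_value(mv8)
    steps <- seq(-6, 6, by = 1.5)
    best_t <- t0
    best_loss <- Inf
    for (tx in steps) for (ty in steps) for (tz in steps) {
      l <- msd_loss(c(0, 0, 0, t0 + c(tx, ty, tz)), mv8, fx8, cen, fill8)
      if (l < best_loss) {
        best_loss <- l
        best_t <- t0 + c(tx, ty, tz)
      }
    }
    mv4 <- pyramid_level(moving, max(levels))
    fx4 <- pyramid_level(fixed, max(levels))
    fill4 <- background_value(mv4)
    best_r <- c(0, 0, 0)
    best_loss <- Inf
    for (rx in c(-4, 0, 4)) for (ry in c(-4, 0, 4)) for (rz in c(-4, 0, 4)) {
      l <- msd_loss(c(rx, ry, rz, best_t), mv4, fx4, cen, fill4)
      if (l < best_loss) {
        best_loss <- l
        best_r <- c(rx, ry, rz)
      }
    }
    init <- rigid_transform(best_r, best_t)
  }
  restarts <- rep_len(restarts, length(levels))
  fixed_stride <- rep_len(fixed_stride, length(levels))
  par <- c(init$rotation_deg, init$translation_mm)
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- pyramid_level(moving, f)
    fx <- pyramid_level(fixed, f, stride = max(f, f * fixed_stride[li]))
    fill <- background_value(mv)
    # Nelder-Mead with restarts: in the long curved valley that couples
    # the weakly determined rotation with its compensating translation,
    # a single simplex collapses (reltol) far from the optimum; each
    # restart re-inflates it around the current best and resumes the
    # descent until the loss stops improving.
    best <- Inf
    for (r in seq_len(1L + restarts[li])) {
      opt <- stats::optim(par, msd_loss, moving = mv, fixed = fx,
                          cen = cen, fill = fill, method = "Nelder-Mead",
                          control = list(maxit = max_iterations[li],
                                         reltol = reltol))
      par <- opt$par
      if (opt$value >= best * (1 - 1e-6)) break
      best <- opt$value
    }
  }
  loss_init <- msd_loss(c(init$rotation_deg, init$translation_mm),
                        moving, fixed, cen)
  loss_final <- msd_loss(par, moving, fixed, cen)
  if (loss_final > loss_init) { # monotone acceptance
    par <- c(init$rotation_deg, init$translation_mm)
    loss_final <- loss_init
  }
  list(transform = rigid_transform(par[1:3], par[4:6]),
       loss_init = loss_init, loss_final = loss_final,
       improved = loss_final < loss_init)
}
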