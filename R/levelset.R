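#' Parameters of the threshold level-set segmentation
#'
#' The segmentation evolves a signed-distance field whose zero level is
#' driven outward where the intensity lies inside `[low, high]` and inward
#' outside it, under a mean-curvature smoothing term. Defaults reproduce
#' the study's settings on the normalized intensity scale: thresholds
#' 300/600 and curvature weighting 0.6.
#'
#' @param low,high intensity window in normalized units (`low < high`).
#' @param curvature_weight weight of the mean-curvature smoothing term
#'   (dimensionless, >= 0); larger values give smoother surfaces.
#' @param propagation_weight weight of the threshold-driven propagation
#'   force.
#' @param max_iterations iteration cap.
#' @param rms_tolerance convergence threshold on the RMS change of the
#'   field per iteration (voxel units).
#' @param band_half_width half-width of the active narrow band, voxels.
#' @param reinit_interval iterations between signed-distance
#'   reinitializations.
#' @param time_step explicit time step; defaults to the CFL-limited
#'   `0.45 / (1 + curvature_weight)` (voxel units) and may not exceed it.
#' @return a `level_set_params` list.
#' @export
level_set_params <- function(low = 300, high = 600, curvature_weight = 0.6,
                             propagation_weight = 1, max_iterations = 500,
                             rms_tolerance = 0.001, band_half_width = 4,
                             reinit_interval = 20, time_step = NULL) {
  if (low >= high) stop("`low` must be below `high`")
  if (curvature_weight < 0) stop("`curvature_weight` must be >= 0")
  cfl <- 0.45 / (1 + curvature_weight)
  if (is.null(time_step)) time_step <- cfl
  if (time_step <= 0 || time_step > cfl + 1e-12)
    stop(sprintf("`time_step` must lie in (0, %.4g] (CFL bound 0.45/(1 + curvature_weight))",
                 cfl))
  if (max_iterations < 1) stop("`max_iterations` must be >= 1")
  if (band_half_width < 2) stop("`band_half_width` must be >= 2 voxels")
  structure(list(low = low, high = high,
                 curvature_weight = curvature_weight,
                 propagation_weight = propagation_weight,
                 max_iterations = as.integer(max_iterations),
                 rms_tolerance = rms_tolerance,
                 band_half_width = band_half_width,
                 reinit_interval = as.integer(reinit_interval),
                 time_step = time_step),
            class = "level_set_params")
}

#' Threshold-derived propagation speed
#'
#' The speed is the smaller of the two ramps up from the window edges:
#' `F = I - low` below the window midpoint and `F = high - I` above it, so
#' that F is positive strictly inside `(low, high)`, exactly zero on the
#' thresholds and negative outside. The front therefore grows into in-range
#' voxels and retreats from out-of-range ones.
#'
#' @param vol a normalized [volume_image()].
#' @param low,high intensity window (normalized units).
#' @return a [volume_image()] holding the speed field.
#' @export
feature_speed <- function(vol, low = 300, high = 600) {
  stopifnot(is_volume_image(vol))
  if (low >= high) stop("`low` must be below `high`")
  mid <- (low + high) / 2
  v <- vol$values
  f <- ifelse(v < mid, v - low, high - v)
  volume_image(array(f, dim(v)), vol$spacing, vol$origin,
               unit_state = vol$unit_state)
}

#' Initialize the level-set field from the intensity window
#'
#' The initial region is the in-window voxel set `{low <= I <= high}`
#' intersected with the ROI, morphologically opened with a 1-voxel ball to
#' remove isolated noise voxels, and converted to a signed Euclidean
#' distance field (voxel units, negative inside, zero level on the region
#' boundary).
#'
#' @param vol normalized [volume_image()].
#' @param low,high intensity window.
#' @param roi optional [binary_mask()] restricting the initial region.
#' @return a `level_set_field`: list with `values` (the signed distance
#'   array, phi), `spacing`, `origin`.
#' @export
initialize_level_set <- function(vol, low = 300, high = 600, roi = NULL) {
  stopifnot(is_volume_image(vol))
  if (low >= high) stop("`low` must be below `high`")
  d <- dim(vol$values)
  mask <- vol$values >= low & vol$values <= high
  if (!is.null(roi)) {
    stop_if_geometry_differs(vol, roi, "volume and ROI")
    mask <- mask & roi$values
  }
  mask <- open_mask_1vox(mask, d)
  if (!any(mask)) {
    q <- stats::quantile(vol$values, c(0, .25, .5, .75, 1))
    stop(structure(class = c("graftquant_empty_window", "error",
                             "condition"),
                   list(message = sprintf(
      "no voxels in the intensity window [%g, %g] (after opening); intensity quantiles: %s",
      low, high, paste(signif(q, 4), collapse = " / ")),
                        call = sys.call(-1))))
  }
  phi <- cpp_signed_distance(as.logical(mask), d)
  structure(list(values = array(phi, d), spacing = vol$spacing,
                 origin = vol$origin),
            class = "level_set_field")
}

# morphological opening with the unit-radius Euclidean ball (6-neighbor)
open_mask_1vox <- function(mask, d) {
  if (!any(mask)) return(array(FALSE, d))
  # erosion: keep voxels at distance > 1 from the complement
  d2 <- cpp_edt_sq(as.logical(!mask), d, c(1, 1, 1))
  eroded <- array(d2 > 1 + 1e-9, d)
  if (!any(eroded)) return(array(FALSE, d))
  # dilation of the eroded set by the same ball
  d2 <- cpp_edt_sq(as.logical(eroded), d, c(1, 1, 1))
  array(d2 <= 1 + 1e-9, d)
}

#' Evolve the threshold level set to convergence
#'
#' Runs the narrow-band update
#' `phi <- phi - dt * (w_p F |grad phi|_upwind - w_c kappa |grad phi|)`
#' with periodic signed-distance reinitialization, stopping when the RMS
#' field change falls below `rms_tolerance` with a stable voxel
#' classification, or at `max_iterations`. See [level_set_params()] for the
#' parameters and [feature_speed()] for F.
#'
#' @param field a `level_set_field` from [initialize_level_set()].
#' @param speed a [volume_image()] holding the speed field on the same
#'   grid.
#' @param params a [level_set_params()].
#' @param speed_scale the speed value mapped to unit front velocity;
#'   defaults to the window half-width `(high - low) / 2`, the largest
#'   positive value [feature_speed()] can attain (larger magnitudes are
#'   clamped, keeping the CFL time step valid on any intensity scale).
#' @return a `level_set_field` with a `report` attribute: list with
#'   `iterations`, `rms`, `converged`.
#' @export
evolve_level_set <- function(field, speed, params = level_set_params(),
                             speed_scale = NULL) {
  if (!inherits(field, "level_set_field"))
    stop("`field` must come from initialize_level_set()")
  stopifnot(is_volume_image(speed))
  if (!identical(dim(field$values), dim(speed$values)))
    stop("field and speed must share the same grid")
  if (is.null(speed_scale)) speed_scale <- (params$high - params$low) / 2
  res <- cpp_levelset_evolve(
    as.double(field$values), as.double(speed$values), dim(field$values),
    params$propagation_weight, params$curvature_weight, params$time_step,
    params$max_iterations, params$rms_tolerance, params$band_half_width,
    params$reinit_interval, speed_scale)
  out <- structure(list(values = array(res$phi, dim(field$values)),
                        spacing = field$spacing, origin = field$origin),
                   class = "level_set_field")
  attr(out, "report") <- list(iterations = res$iterations, rms = res$rms,
                              converged = res$converged)
  out
}

#' Binary mask of the level-set interior
#'
#' @param field a `level_set_field`.
#' @return a [binary_mask()] of `{phi < 0}`.
#' @export
level_set_mask <- function(field) {
  if (!inherits(field, "level_set_field"))
    stop("`field` must be a level_set_field")
  binary_mask(field$values < 0, field$spacing, field$origin)
}

#' Segment bone with the threshold level set
#'
#' Convenience wrapper: builds the speed field, initializes from the
#' intensity window inside the ROI, evolves to convergence and returns the
#' field, the segmentation mask and the convergence report.
#'
#' @param vol normalized [volume_image()] (the working-resolution scan).
#' @param roi optional [binary_mask()].
#' @param params a [level_set_params()].
#' @return list with `field`, `mask`, `report`.
#' @export
segment_bone <- function(vol, roi = NULL, params = level_set_params()) {
  f <- feature_speed(vol, params$low, params$high)
  if (!is.null(roi)) {
    # the exclusion mask is a hard constraint: the front must never enter
    # the excluded region (host mandible, hardware), so the speed there is
    # maximal retreat
    scale <- (params$high - params$low) / 2
    f$values[!roi$values] <- -scale
  }
  init <- initialize_level_set(vol, params$low, params$high, roi)
  field <- evolve_level_set(init, f, params)
  list(field = field, mask = level_set_mask(field),
       report = attr(field, "report"))
}
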