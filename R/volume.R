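#' 3D scalar volume with voxel geometry
#'
#' A `volume_image` is a 3D numeric array of attenuation values together with
#' voxel spacing (mm/voxel), world origin (mm) and a unit-state flag. CBCT
#' voxel values are on an arbitrary per-scan scale (`"raw"`); after
#' [normalize_intensity()] they are in normalized units (`"normalized"`,
#' mean 0, SD 1000 by default). Only axis-aligned geometry is supported:
#' the world position of voxel index `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`.
#'
#' @param values 3D numeric array (all values finite).
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#'   A single number is recycled.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param unit_state `"raw"` or `"normalized"`.
#' @return An object of class `volume_image` with fields `values`,
#'   `spacing`, `origin`, `unit_state`.
#' @seealso [binary_mask()], [read_volume()], [write_volume()]
#' @export
volume_image <- function(values, spacing, origin = c(0, 0, 0),
                         unit_state = c("raw", "normalized")) {
  unit_state <- match.arg(unit_state)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (any(dim(values) < 1L)) stop("all three dimensions must be positive")
  if (!all(is.finite(values))) stop("all voxel values must be finite")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit_state = unit_state),
            class = "volume_image")
}

#' 3D binary mask aligned with a reference volume
#'
#' A `binary_mask` shares the voxel grid geometry of a [volume_image()]:
#' same shape, spacing and origin. Masks represent regions of interest,
#' metal exclusions and segmentation results. An empty mask is valid.
#'
#' @param values 3D logical array (numeric input is coerced by `!= 0`).
#' @param spacing,origin as in [volume_image()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (is.numeric(values)) {
    d <- dim(values)
    values <- array(values != 0, d)
  }
  if (!is.logical(values)) stop("`values` must be logical or numeric")
  if (anyNA(values)) stop("mask values must not be NA")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "binary_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, spacing %s mm, origin %s mm, %s units\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ","),
              x$unit_state))
  cat(sprintf("  value range [%.4g, %.4g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground (%.3g mm^3)\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$values), measure_volume(x)))
  invisible(x)
}

#' @rdname volume_image
#' @param x object to test.
#' @export
is_volume_image <- function(x) inherits(x, "volume_image")

#' @rdname binary_mask
#' @param x object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Volume of one voxel in mm^3
#' @param x a `volume_image` or `binary_mask`.
#' @return scalar, product of the three spacing components.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Do two grids share shape, spacing and origin?
#'
#' @param a,b `volume_image` or `binary_mask` objects.
#' @param tol geometric tolerance in mm.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_differs <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(sprintf("%s must share the same grid (shape, spacing, origin)", what))
  invisible(TRUE)
}

#' World coordinates of the grid center
#'
#' Center of the voxel lattice in world mm; rigid-transform rotations are
#' applied about this point.
#' @param x a `volume_image` or `binary_mask`.
#' @return numeric length-3 (mm).
#' @export
world_center <- function(x) {
  x$origin + (dim(x$values) - 1) / 2 * x$spacing
}

# world coordinate vectors along each axis (voxel centers)
axis_coords <- function(x) {
  d <- dim(x$values)
  lapply(1:3, function(a) x$origin[a] + (seq_len(d[a]) - 1) * x$spacing[a])
}

# background level used when resampling pushes voxels out of the field
background_value <- function(vol) {
  as.numeric(stats::quantile(vol$values, 0.01, names = FALSE))
}
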