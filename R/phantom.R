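#' Specification of the digital mandible-angle phantom
#'
#' Describes a paired-scan simulation of the study scene: a mandible slab
#' (trabecular interior, cortical shell on the buccal face), an onlay
#' cortical graft block (~10 x 10 mm footprint) fixed to the buccal face by
#' a titanium screw, surrounded by soft tissue. The follow-up scan carries a
#' programmed graft volume change (resorption or apposition with known
#' ground truth), a rigid misalignment, and each scan carries its own
#' arbitrary intensity gain/offset (CBCT units are not calibrated), Gaussian
#' blur and noise.
#'
#' The x axis is the bucco-lingual direction: the slab occupies
#' `x <= slab_thickness` and the graft sits on the face at larger x.
#' Tissue attenuations must be ordered `metal >> cortical > trabecular >
#' soft`; defaults are calibrated so that after mean-0/SD-1000 normalization
#' of the default scene, bone falls inside the study's 300-600 segmentation
#' window, soft tissue well below it and metal above the 3000 metal
#' threshold.
#'
#' @param field_of_view length-3 extent in mm.
#' @param spacing isotropic voxel size in mm (0.16 is the study's working
#'   resolution; 0.08 its native resolution).
#' @param slab_thickness,cortical_thickness mandible slab extent along x
#'   and thickness of its buccal cortical shell (mm).
#' @param graft_size graft block extents `c(x, y, z)` in mm (depth,
#'   height, width).
#' @param screw_radius,screw_embed,screw_protrusion screw cylinder radius,
#'   depth into the slab and protrusion beyond the graft face (mm); a zero
#'   radius omits the screw.
#' @param canal_radius radius (mm) of the mandibular (inferior alveolar
#'   nerve) canal, a soft-tissue tube running obliquely through the slab;
#'   zero omits it. Besides realism, this oblique landmark is what makes
#'   rotation about the screw axis identifiable to registration -- an
#'   idealized flat slab with an axis-aligned graft block is nearly
#'   rotation-symmetric about that axis.
#' @param graft_tilt_deg in-plane tilt of the graft block about the
#'   buccal (x) axis, degrees. A surgically placed block is oblique to the
#'   scanner axes; a perfectly grid-aligned block is also a degenerate
#'   special case whose long edges alias coherently against the voxel
#'   grid, imprinting spurious ~1-degree-period minima on any
#'   intensity-registration metric.
#' @param mu named attenuations `c(soft, trabecular, cortical, metal)` in
#'   raw scanner units (the graft block is cortical bone).
#' @param blur_sigma point-spread Gaussian sigma in mm.
#' @param noise_sigma additive Gaussian noise SD in raw units.
#' @param gain,offset length-2 per-scan intensity gain and offset
#'   (baseline, follow-up), applied to the whole acquired signal.
#' @param followup_volume_fraction target graft volume ratio V6/V0 (0 =
#'   complete resorption; the study's observed range spans 0 to 1.79).
#' @param misalignment [rigid_transform()] moving the scene between scans.
#' @param seed integer seed for the noise generator (R's Mersenne-Twister;
#'   the two scans use `seed` and `seed + 1`).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(field_of_view = c(20, 20, 20), spacing = 0.16,
                         slab_thickness = 5, cortical_thickness = 1.2,
                         graft_size = c(4, 10, 10), screw_radius = 0.8,
                         screw_embed = 4, screw_protrusion = 0.5,
                         canal_radius = 1, graft_tilt_deg = 8,
                         mu = c(soft = 0, trabecular = 54, cortical = 60,
                                metal = 2100),
                         blur_sigma = 0.08, noise_sigma = 4,
                         gain = c(1, 1), offset = c(0, 0),
                         followup_volume_fraction = 0.5,
                         misalignment = rigid_transform(c(2, -1.5, 1),
                                                        c(1.5, -1, 0.8)),
                         seed = 1L) {
  if (length(spacing) != 1L || spacing <= 0) stop("`spacing` must be > 0")
  if (length(field_of_view) != 3L || any(field_of_view <= 0))
    stop("`field_of_view` must be 3 positive extents")
  if (!all(c("soft", "trabecular", "cortical", "metal") %in% names(mu)))
    stop("`mu` must name soft, trabecular, cortical and metal")
  mu <- mu[c("soft", "trabecular", "cortical", "metal")]
  if (!(mu["metal"] > mu["cortical"] && mu["cortical"] > mu["trabecular"] &&
        mu["trabecular"] > mu["soft"]))
    stop("attenuations must satisfy metal > cortical > trabecular > soft")
  if (any(graft_size <= 0)) stop("graft extents must be positive")
  if (followup_volume_fraction < 0)
    stop("`followup_volume_fraction` must be >= 0")
  if (slab_thickness + graft_size[1] >= field_of_view[1] ||
      any(graft_size[2:3] >= field_of_view[2:3]))
    stop("graft does not fit inside the field of view")
  if (length(gain) != 2L || any(gain <= 0))
    stop("`gain` must be 2 positive scalars (baseline, follow-up)")
  if (length(offset) != 2L) stop("`offset` must be 2 scalars")
  if (!inherits(misalignment, "rigid_transform"))
    stop("`misalignment` must be a rigid_transform")
  structure(list(field_of_view = field_of_view, spacing = spacing,
                 slab_thickness = slab_thickness,
                 cortical_thickness = cortical_thickness,
                 graft_size = graft_size, screw_radius = screw_radius,
                 canal_radius = canal_radius, graft_tilt_deg = graft_tilt_deg,
                 screw_embed = screw_embed,
                 screw_protrusion = screw_protrusion, mu = mu,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 gain = gain, offset = offset,
                 followup_volume_fraction = followup_volume_fraction,
                 misalignment = misalignment, seed = as.integer(seed)),
            class = "phantom_spec")
}

# graft box test in scene coordinates: x-extent on the slab face, the
# y-z footprint rotated in-plane by the placement tilt
graft_box_from_coords <- function(spec, qx, qy, qz, cy, cz) {
  face <- spec$slab_thickness
  a <- spec$graft_tilt_deg * pi / 180
  ry <- cos(a) * (qy - cy) + sin(a) * (qz - cz)
  rz <- -sin(a) * (qy - cy) + cos(a) * (qz - cz)
  qx > face & qx <= face + spec$graft_size[1] &
    abs(ry) <= spec$graft_size[2] / 2 & abs(rz) <= spec$graft_size[3] / 2
}

# mandibular canal: an oblique soft-tissue tube through the slab interior,
# from (x1, 0.30 Ly, 0) to (x2, 0.55 Ly, Lz); returns a logical array
canal_mask_from_coords <- function(spec, qx, qy, qz, d, extent) {
  if (spec$canal_radius <= 0) return(NULL)
  face <- spec$slab_thickness
  a <- c(max(0.2, face - 3.8), 0.30 * extent[2], 0)
  b <- c(max(0.4, face - 2.2), 0.55 * extent[2], extent[3])
  u <- (b - a) / sqrt(sum((b - a)^2))
  # squared distance from each voxel to the canal axis
  wx <- qx - a[1]; wy <- qy - a[2]; wz <- qz - a[3]
  t <- wx * u[1] + wy * u[2] + wz * u[3]
  d2 <- (wx - t * u[1])^2 + (wy - t * u[2])^2 + (wz - t * u[3])^2
  d2 <= spec$canal_radius^2
}

#' Label codes of the phantom scene
#' @return named integer vector (background 0, trabecular 1, cortical 2,
#'   graft 3, metal 4).
#' @export
phantom_label_codes <- function() {
  c(background = 0L, trabecular = 1L, cortical = 2L, graft = 3L, metal = 4L)
}

#' Build the phantom label grid
#'
#' Rasterizes the scene of a [phantom_spec()] into the five label classes.
#' The graft block touches the slab's cortical face and the screw cylinder
#' intersects both graft and slab. Deterministic (no randomness is involved
#' in the geometry).
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_labels` object: integer array `values` plus `spacing`
#'   and `origin`.
#' @export
build_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing
  d <- as.integer(floor(spec$field_of_view / sp + 1e-9))
  x <- (seq_len(d[1]) - 1) * sp
  y <- (seq_len(d[2]) - 1) * sp
  z <- (seq_len(d[3]) - 1) * sp
  lab <- array(0L, d)
  face <- spec$slab_thickness
  # mandible slab with buccal cortical shell
  slab_x <- x <= face
  cort_x <- x <= face & x > face - spec$cortical_thickness
  lab[slab_x, , ] <- 1L
  lab[cort_x, , ] <- 2L
  # onlay graft block centered on the face, tilted in the face plane
  cy <- (d[2] - 1) / 2 * sp
  cz <- (d[3] - 1) / 2 * sp
  qx <- array(rep(x, times = d[2] * d[3]), d)
  qy <- array(rep(rep(y, each = d[1]), times = d[3]), d)
  qz <- array(rep(z, each = d[1] * d[2]), d)
  graft <- graft_box_from_coords(spec, qx, qy, qz, cy, cz)
  if (!any(graft)) stop("graft block rasterizes to zero voxels")
  lab[graft] <- 3L
  # titanium screw along x through graft into slab
  sx <- x > face - spec$screw_embed &
    x <= face + spec$graft_size[1] + spec$screw_protrusion
  r2 <- outer((y - cy)^2, (z - cz)^2, "+")
  in_r <- r2 <= spec$screw_radius^2
  if (spec$screw_radius > 0 && any(sx) && any(in_r)) {
    screw <- array(FALSE, d)
    screw[sx, , ] <- rep(in_r, each = sum(sx))
    lab[screw] <- 4L
  }
  # mandibular canal through the trabecular interior
  extent <- (d - 1) * sp
  canal <- canal_mask_from_coords(spec, qx, qy, qz, d, extent)
  if (!is.null(canal)) lab[canal & lab == 1L] <- 0L
  structure(list(values = lab, spacing = rep(sp, 3), origin = c(0, 0, 0)),
            class = "phantom_labels")
}

#' Change a mask's volume to a target fraction
#'
#' Emulates graft resorption (fraction < 1) or apposition (fraction > 1) by
#' thresholding the Euclidean distance transform at the sub-voxel offset
#' whose level set matches `fraction x volume(mask)`: shrinkage keeps the
#' interior deeper than the offset, growth adds the exterior shell within
#' it. Voxels tied at the critical distance (blocky shapes have whole tied
#' planes) are admitted in deterministic voxel order until the count is
#' exact, so the achieved volume always matches the rounded target. This
#' uniform surface offset is a modeling choice (the true remodeling
#' geometry of a graft surface is unknown); it preserves the blocky graft
#' shape.
#'
#' @param mask a non-empty [binary_mask()].
#' @param fraction target volume ratio (>= 0; 0 empties the mask, 1 returns
#'   it unchanged).
#' @param allowed optional [binary_mask()] restricting where growth may
#'   extend (e.g. soft tissue only); growth beyond it is an error.
#' @return a [binary_mask()].
#' @export
apply_volume_change <- function(mask, fraction, allowed = NULL) {
  stopifnot(is_binary_mask(mask))
  if (fraction < 0) stop("`fraction` must be >= 0")
  n0 <- sum(mask$values)
  if (n0 == 0L) stop("`mask` is empty")
  d <- dim(mask$values)
  if (fraction == 1) return(mask)
  if (fraction == 0)
    return(binary_mask(array(FALSE, d), mask$spacing, mask$origin))
  target <- round(fraction * n0)
  # Exact order-statistic threshold on the distance transform: keep the
  # `target` voxels deepest inside (shrink) or closest outside (growth).
  # This is the sub-voxel level-set threshold of the distance field, with a
  # deterministic voxel-order tie-break inside the (one voxel thick) tied
  # distance shell -- blocky shapes have large tied plateaus that a plain
  # scalar threshold cannot split.
  if (fraction < 1) {
    din <- sqrt(cpp_edt_sq(as.logical(!mask$values), d, c(1, 1, 1)))
    idx <- which(mask$values)
    keep <- idx[order(-din[idx], idx)][seq_len(target)]
    out <- array(FALSE, d)
    out[keep] <- TRUE
  } else {
    dout <- sqrt(cpp_edt_sq(as.logical(mask$values), d, c(1, 1, 1)))
    candidate <- !mask$values
    if (!is.null(allowed)) {
      stop_if_geometry_differs(mask, allowed, "mask and allowed region")
      candidate <- candidate & allowed$values
    }
    grow_target <- target - n0
    idx <- which(candidate)
    if (length(idx) < grow_target)
      stop("growth target unreachable: not enough room in the allowed region")
    add <- idx[order(dout[idx], idx)][seq_len(grow_target)]
    out <- mask$values
    out[add] <- TRUE
  }
  binary_mask(out, mask$spacing, mask$origin)
}

#' Simulate one CBCT scan of a labeled scene
#'
#' Maps labels to attenuations, applies the Gaussian point-spread blur,
#' adds seeded i.i.d. Gaussian noise, and finally applies the per-scan
#' intensity gain/offset to the whole acquired signal (modeling the
#' scanner's arbitrary, uncalibrated output mapping). For the follow-up
#' scan the scene is first moved rigidly by the spec's misalignment: the
#' moved scene is re-rasterized geometrically (analytic slab and screw in
#' back-transformed coordinates, graft via sub-voxel interpolation of its
#' signed-distance field), so the scan carries exactly one point-spread
#' blur like a real acquisition -- resampling the rendered image instead
#' would smuggle in a second, purely numerical smoothing.
#'
#' @param labels a `phantom_labels` grid (for the follow-up scan, the grid
#'   carrying the changed graft, in the baseline frame).
#' @param spec the [phantom_spec()].
#' @param which `"baseline"` or `"followup"`.
#' @return a raw-unit [volume_image()].
#' @export
simulate_scan <- function(labels, spec, which = c("baseline", "followup")) {
  stopifnot(inherits(labels, "phantom_labels"),
            inherits(spec, "phantom_spec"))
  which <- match.arg(which)
  iscan <- if (which == "baseline") 1L else 2L
  d <- dim(labels$values)
  lab <- labels$values
  if (which == "followup" && !is_identity_transform(spec$misalignment)) {
    lab <- moved_labels(labels, spec)
  }
  mu_by_code <- c(spec$mu[["soft"]], spec$mu[["trabecular"]],
                  spec$mu[["cortical"]], spec$mu[["cortical"]],
                  spec$mu[["metal"]]) # graft block is cortical bone
  img <- array(mu_by_code[lab + 1L], d)
  if (spec$blur_sigma > 0) {
    img <- array(cpp_gauss_blur(as.double(img), d,
                                rep(spec$blur_sigma / spec$spacing, 3)), d)
  }
  vals <- img
  if (spec$noise_sigma > 0) {
    vals <- vals + with_local_seed(spec$seed + iscan - 1L,
                                   array(stats::rnorm(prod(d), 0,
                                                      spec$noise_sigma), d))
  }
  vals <- spec$gain[iscan] * vals + spec$offset[iscan]
  volume_image(vals, labels$spacing, labels$origin, unit_state = "raw")
}

# Rasterize the scene labels after rigid motion: each voxel center is
# back-transformed into the scene frame, where slab, shell and screw are
# analytic; the (possibly remodeled) graft is classified by trilinear
# interpolation of its signed-distance field, preserving its sub-voxel
# surface. Out-of-field points become soft tissue.
moved_labels <- function(labels, spec) {
  d <- dim(labels$values)
  sp <- labels$spacing
  cen <- labels$origin + (d - 1) / 2 * sp
  tr <- spec$misalignment
  R <- rotation_matrix(tr)
  ax <- lapply(1:3, function(a) labels$origin[a] + (seq_len(d[a]) - 1) * sp[a])
  # q = R^T (p - c - t) + c, expanded over the separable coordinate grids
  px <- ax[[1]] - cen[1] - tr$translation_mm[1]
  py <- ax[[2]] - cen[2] - tr$translation_mm[2]
  pz <- ax[[3]] - cen[3] - tr$translation_mm[3]
  comp <- function(col) {
    outer(outer(R[1, col] * px, R[2, col] * py, "+"), R[3, col] * pz, "+") +
      cen[col]
  }
  qx <- comp(1); qy <- comp(2); qz <- comp(3)
  face <- spec$slab_thickness
  lab <- array(0L, d)
  lab[qx <= face] <- 1L
  lab[qx <= face & qx > face - spec$cortical_thickness] <- 2L
  # graft: interpolate its signed distance under the same motion
  graft <- labels$values == 3L
  if (any(graft)) {
    phi <- array(cpp_signed_distance(as.logical(graft), d), d)
    phi_vol <- volume_image(phi, sp, labels$origin)
    phi_moved <- resample_volume(phi_vol, tr, phi_vol, "linear",
                                 fill = max(phi))
    lab[phi_moved$values < 0] <- 3L
  }
  cy <- (d[2] - 1) / 2 * sp[2]
  cz <- (d[3] - 1) / 2 * sp[3]
  if (spec$screw_radius > 0) {
    screw <- (qy - cy)^2 + (qz - cz)^2 <= spec$screw_radius^2 &
      qx > face - spec$screw_embed &
      qx <= face + spec$graft_size[1] + spec$screw_protrusion
    lab[screw] <- 4L
  }
  extent <- (d - 1) * sp
  canal <- canal_mask_from_coords(spec, qx, qy, qz, d, extent)
  if (!is.null(canal)) lab[canal & lab == 1L] <- 0L
  lab
}

is_identity_transform <- function(t) {
  all(t$rotation_deg == 0) && all(t$translation_mm == 0)
}

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a paired baseline/follow-up phantom scan with ground truth
#'
#' Composes [build_labels()], [apply_volume_change()] and [simulate_scan()]:
#' the follow-up labels carry the resorbed/apposed graft (resorbed voxels
#' revert to soft tissue, apposed bone grows into soft tissue only), the
#' follow-up scan is rigidly misaligned, and the returned ROI excludes the
#' mandible slab (half-space at the slab face) and the dilated screw while
#' containing the graft with room for apposition. Ground-truth volumes are
#' exact voxel counts times the voxel volume, measured in the baseline
#' frame.
#'
#' @param spec a [phantom_spec()].
#' @return list with `baseline`, `followup` ([volume_image()]), `roi`
#'   ([binary_mask()]) and `truth` (a `phantom_truth`: ground-truth volumes
#'   in mm^3, the applied transform, and both label grids).
#' @export
generate_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels0 <- build_labels(spec)
  d <- dim(labels0$values)
  codes <- phantom_label_codes()
  graft0 <- binary_mask(labels0$values == codes[["graft"]], labels0$spacing,
                        labels0$origin)
  allowed <- binary_mask(
    array(labels0$values %in% codes[c("background", "graft")], d),
    labels0$spacing, labels0$origin)
  graft6 <- apply_volume_change(graft0, spec$followup_volume_fraction,
                                allowed = allowed)
  lab6 <- labels0$values
  lab6[graft0$values & !graft6$values] <- codes[["background"]]
  lab6[graft6$values] <- codes[["graft"]]
  labels6 <- structure(list(values = lab6, spacing = labels0$spacing,
                            origin = labels0$origin),
                       class = "phantom_labels")
  baseline <- simulate_scan(labels0, spec, "baseline")
  followup <- simulate_scan(labels6, spec, "followup")
  metal <- binary_mask(labels0$values == codes[["metal"]], labels0$spacing,
                       labels0$origin)
  metal_dil <- if (any(metal$values)) {
    d2 <- cpp_edt_sq(as.logical(metal$values), d, metal$spacing)
    binary_mask(array(d2 <= 0.48^2 + 1e-12, d), metal$spacing, metal$origin)
  } else metal
  roi <- build_roi_mask(baseline, metal = metal_dil,
                        exclusions = list(list(type = "halfspace",
                                               normal = c(1, 0, 0),
                                               offset = spec$slab_thickness)))
  vv <- voxel_volume(graft0)
  truth <- structure(list(
    graft_volume_baseline = sum(graft0$values) * vv,
    graft_volume_followup = sum(graft6$values) * vv,
    applied_transform = spec$misalignment,
    labels_baseline = labels0, labels_followup = labels6),
    class = "phantom_truth")
  list(baseline = baseline, followup = followup, roi = roi, truth = truth)
}

#' Simulate measurement-level trial data (no imaging)
#'
#' Draws per-patient graft volumes for a paired internal-control trial at
#' the measurement level: baseline volumes from a truncated normal
#' calibrated to the trial's observed distribution, per-side volume-change
#' fractions from side-specific normal distributions, plus an additive
#' measurement error on every volume. With identical fraction
#' distributions on both sides the design is exchangeable and the paired t
#' test's null holds exactly, which is what the type-I-error simulation
#' exercises. Used by [run_trial()] and for statistical calibration
#' experiments; the imaging pipeline is validated separately on phantoms.
#'
#' @param n_patients number of complete patients.
#' @param fraction_treated,fraction_control mean V6/V0 fraction per side
#'   (defaults mirror the trial's observed means: 1.35 treated, 0.42
#'   control).
#' @param fraction_sd SD of the per-graft fraction (default 0.30).
#' @param baseline_mean,baseline_sd,baseline_min baseline volume
#'   distribution in mm^3 (truncated normal).
#' @param measurement_sd additive measurement error SD in mm^3.
#' @param seed integer seed.
#' @return a measurement table (see [read_measurements()]).
#' @export
simulate_trial_measurements <- function(n_patients = 9,
                                        fraction_treated = 1.35,
                                        fraction_control = 0.42,
                                        fraction_sd = 0.30,
                                        baseline_mean = 320,
                                        baseline_sd = 150,
                                        baseline_min = 50,
                                        measurement_sd = 15,
                                        seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be >= 2")
  with_local_seed(seed, {
    rows <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      treated <- sample(c("Dx", "Sin"), 1)
      sides <- c("Dx", "Sin")
      for (s in sides) {
        v0 <- max(baseline_min, stats::rnorm(1, baseline_mean, baseline_sd))
        frac <- max(0, stats::rnorm(
          1, if (s == treated) fraction_treated else fraction_control,
          fraction_sd))
        v6 <- v0 * frac
        v0m <- max(0, v0 + stats::rnorm(1, 0, measurement_sd))
        v6m <- max(0, v6 + stats::rnorm(1, 0, measurement_sd))
        rows[[i]] <- rbind(rows[[i]], data.frame(
          patient_id = sprintf("sim%02d", i), treated_side = treated,
          side = s, timepoint = c("baseline", "6mo"),
          volume_mm3 = c(v0m, v6m), stringsAsFactors = FALSE))
      }
    }
    validate_measurements(do.call(rbind, rows))
  })
}
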