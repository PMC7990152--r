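#' Largest continuous segmented component within the ROI
#'
#' Implements the study's volume-of-interest rule: connected components of
#' the segmentation restricted to the ROI are labeled at the requested
#' connectivity (default 26, the permissive standard for 3D foreground) and
#' the component with the most voxels is returned. Size ties are broken
#' deterministically by the lexicographically smallest bounding-box corner
#' (in voxel indices), and the tie is recorded in the report.
#'
#' @param seg segmentation [binary_mask()].
#' @param roi optional ROI [binary_mask()] on the same grid.
#' @param connectivity 6, 18 or 26.
#' @return list with `mask` (the selected component as a [binary_mask()])
#'   and `report`, a `data.frame` with one row per component: `component`,
#'   `voxel_count`, `volume_mm3`, bounding box in mm
#'   (`xmin,ymin,zmin,xmax,ymax,zmax`) and `selected`; the report carries
#'   attributes `connectivity` and `tie`.
#' @export
largest_component_within <- function(seg, roi = NULL, connectivity = 26) {
  stopifnot(is_binary_mask(seg))
  fg <- seg$values
  if (!is.null(roi)) {
    stopifnot(is_binary_mask(roi))
    stop_if_geometry_differs(seg, roi, "segmentation and ROI")
    fg <- fg & roi$values
  }
  d <- dim(fg)
  empty_report <- data.frame(component = integer(), voxel_count = integer(),
                             volume_mm3 = numeric(), xmin = numeric(),
                             ymin = numeric(), zmin = numeric(),
                             xmax = numeric(), ymax = numeric(),
                             zmax = numeric(), selected = logical())
  if (!any(fg)) {
    out <- binary_mask(array(FALSE, d), seg$spacing, seg$origin)
    attr(empty_report, "connectivity") <- connectivity
    attr(empty_report, "tie") <- FALSE
    return(list(mask = out, report = empty_report))
  }
  labels <- cpp_label_components(as.logical(fg), d, as.integer(connectivity))
  labels <- array(labels, d)
  ncomp <- max(labels)
  counts <- tabulate(labels[labels > 0L], nbins = ncomp)
  vox <- voxel_volume(seg)
  # bounding boxes in voxel indices (1-based), converted to world mm
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- factor(labels[labels > 0L], levels = seq_len(ncomp))
  bb <- matrix(NA_real_, ncomp, 6)
  for (a in 1:3) {
    bb[, a] <- tapply(idx[, a], lab, min)
    bb[, a + 3] <- tapply(idx[, a], lab, max)
  }
  maxcount <- max(counts)
  cand <- which(counts == maxcount)
  tie <- length(cand) > 1L
  if (tie) {
    ord <- order(bb[cand, 1], bb[cand, 2], bb[cand, 3])
    sel <- cand[ord[1]]
  } else {
    sel <- cand
  }
  world_min <- sweep(sweep(bb[, 1:3, drop = FALSE] - 1, 2, seg$spacing, "*"),
                     2, seg$origin, "+")
  world_max <- sweep(sweep(bb[, 4:6, drop = FALSE] - 1, 2, seg$spacing, "*"),
                     2, seg$origin, "+")
  report <- data.frame(component = seq_len(ncomp), voxel_count = counts,
                       volume_mm3 = counts * vox,
                       xmin = world_min[, 1], ymin = world_min[, 2],
                       zmin = world_min[, 3], xmax = world_max[, 1],
                       ymax = world_max[, 2], zmax = world_max[, 3],
                       selected = seq_len(ncomp) == sel)
  attr(report, "connectivity") <- connectivity
  attr(report, "tie") <- tie
  list(mask = binary_mask(labels == sel, seg$spacing, seg$origin),
       report = report)
}

#' Volume of a binary mask in mm^3
#'
#' `volume = voxel count x spacing_x * spacing_y * spacing_z`.
#'
#' @param mask a [binary_mask()].
#' @return scalar volume in mm^3 (0 for an empty mask).
#' @export
measure_volume <- function(mask) {
  stopifnot(is_binary_mask(mask))
  sum(mask$values) * voxel_volume(mask)
}
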