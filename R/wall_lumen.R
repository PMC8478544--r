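#' Segmentation parameters
#'
#' All tunable thresholds and distances of the workflow, with the published
#' defaults. Both attenuation thresholds are in cm^-1 and all distances in
#' voxels; threshold comparisons are inclusive (`>=`).
#'
#' @param wall_threshold Fixed wall threshold (cm^-1); voxels at or above it
#'   inside the ROI form the wall draft. Default 6.0.
#' @param shell_erosion In-plane erosion of the ROI (voxels) whose residue,
#'   the 2-voxel inner boundary layer, closes wall discontinuities.
#'   Default 2.
#' @param lumen_close_distance Radius (voxels) of the dilation/erosion
#'   sequence that removes plaque-induced voids from the lumen draft.
#'   Default 5.
#' @param plaque_sigma Gaussian width (voxels) for plaque segmentation.
#'   Default 0.8.
#' @param plaque_support Gaussian kernel truncation radius (voxels); the
#'   kernel is renormalized to unit sum after truncation. Default 1.
#' @param plaque_threshold Plaque threshold (cm^-1) applied to the smoothed
#'   attenuation inside the lumen. Default 2.0.
#' @param opening_distance Radius (voxels) of the plaque-refinement opening.
#'   Default 1.
#' @param min_component_fraction Connected components smaller than this
#'   fraction of the total post-opening plaque volume are discarded.
#'   Default 0.02.
#' @param closing_distance Radius (voxels) of the plaque-refinement closing.
#'   Default 3.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(wall_threshold = 6.0,
                       shell_erosion = 2,
                       lumen_close_distance = 5,
                       plaque_sigma = 0.8,
                       plaque_support = 1,
                       plaque_threshold = 2.0,
                       opening_distance = 1,
                       min_component_fraction = 0.02,
                       closing_distance = 3) {
  p <- list(wall_threshold = wall_threshold,
            shell_erosion = shell_erosion,
            lumen_close_distance = lumen_close_distance,
            plaque_sigma = plaque_sigma,
            plaque_support = plaque_support,
            plaque_threshold = plaque_threshold,
            opening_distance = opening_distance,
            min_component_fraction = min_component_fraction,
            closing_distance = closing_distance)
  dists <- c("shell_erosion", "lumen_close_distance", "plaque_support",
             "opening_distance", "closing_distance")
  for (d in dists)
    if (p[[d]] < 0) am_stop(sprintf("%s must be >= 0", d), "am_value_error")
  if (p$wall_threshold <= 0 || p$plaque_threshold <= 0)
    am_stop("thresholds must be > 0", "am_value_error")
  if (p$min_component_fraction < 0 || p$min_component_fraction > 1)
    am_stop("min_component_fraction must be in [0, 1]", "am_value_error")
  if (p$plaque_sigma < 0)
    am_stop("plaque_sigma must be >= 0", "am_value_error")
  structure(p, class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat("seg_params:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Threshold the wall draft
#'
#' Applies the fixed wall threshold to the grayscale data within the aortic
#' ROI: a voxel enters the draft exactly when it lies in the ROI and its
#' attenuation is at or above `wall_threshold`.
#'
#' @param volume A [grayscale_volume()].
#' @param roi ROI [binary_mask()] on the same grid.
#' @param params A [seg_params()].
#' @return A [binary_mask()] with role `"wall_draft"`.
#' @export
threshold_wall_draft <- function(volume, roi, params = seg_params()) {
  check_same_grid(volume, roi, "volume and ROI")
  mask_like(roi, roi$data & (volume$data >= params$wall_threshold),
            "wall_draft")
}

#' Close the aortic boundary with the ROI shell
#'
#' The thresholded wall draft can be discontinuous where the wall is
#' under-stained or interrupted by branch ostia. Because the manual contours
#' follow the outer wall, the inner boundary layer of the ROI (the residue
#' of eroding the ROI in-plane by `shell_erosion` voxels) traces the wall
#' even across gaps; its union with the draft is guaranteed to be a closed
#' boundary around the lumen.
#'
#' @param wall_draft Wall draft [binary_mask()].
#' @param roi ROI [binary_mask()] on the same grid.
#' @param params A [seg_params()].
#' @return A [binary_mask()] with role `"wall_draft"` (closed boundary).
#' @export
build_closed_boundary <- function(wall_draft, roi, params = seg_params()) {
  check_same_grid(wall_draft, roi, "wall draft and ROI")
  eroded <- disc_erode_slicewise(roi$data, params$shell_erosion)
  nonempty <- apply(roi$data, 1, any)
  emptied <- apply(eroded, 1, any) == FALSE & nonempty
  if (any(emptied))
    am_stop(sprintf(
      "ROI too thin: in-plane erosion by %g voxels empties %d nonempty slice(s)",
      params$shell_erosion, sum(emptied)), "am_degenerate_roi_error")
  shell <- roi$data & !eroded
  mask_like(roi, wall_draft$data | shell, "wall_draft")
}

#' Extract the lumen draft as the interior cavity
#'
#' Inverts the closed boundary within the ROI and keeps the connected
#' component (6-connectivity) with the largest voxel count: the inside
#' volume of the aorta. Label numbering is deterministic (raster order), so
#' ties break toward the smallest label.
#'
#' @param closed_boundary Closed-boundary [binary_mask()] (subset of ROI).
#' @param roi ROI [binary_mask()].
#' @return A [binary_mask()] with role `"lumen_draft"`.
#' @export
extract_lumen_draft <- function(closed_boundary, roi) {
  check_same_grid(closed_boundary, roi, "boundary and ROI")
  interior <- roi$data & !closed_boundary$data
  if (!any(interior))
    am_stop("no interior cavity: boundary fills the whole ROI",
            "am_empty_lumen_error")
  lab <- label_components(interior, 6L)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)  # ties -> smallest label (raster order)
  mask_like(roi, lab == keep, "lumen_draft")
}

#' Fill plaque-induced voids in the lumen draft
#'
#' Highly stained plaques can be confounded with the wall during
#' thresholding, leaving enclosed voids in the lumen draft. A morphological
#' closing (dilation then erosion with a Euclidean ball of radius
#' `lumen_close_distance`, computed in a padded bounding box so the result
#' is not clipped at array borders) absorbs voids of diameter below twice
#' the distance. The closed lumen is re-intersected with the in-plane-eroded
#' ROI so it can never touch the ROI border.
#'
#' @param lumen_draft Lumen draft [binary_mask()].
#' @param params A [seg_params()].
#' @param roi Optional ROI [binary_mask()]; when supplied the result is
#'   constrained to `erode(roi, shell_erosion)`.
#' @return A [binary_mask()] with role `"lumen"`.
#' @export
fill_lumen_voids <- function(lumen_draft, params = seg_params(), roi = NULL) {
  closed <- ball_close(lumen_draft$data, params$lumen_close_distance)
  if (!is.null(roi)) {
    check_same_grid(lumen_draft, roi, "lumen draft and ROI")
    closed <- closed & disc_erode_slicewise(roi$data, params$shell_erosion)
  }
  mask_like(lumen_draft, closed, "lumen")
}

#' Compose the aorta and wall masks
#'
#' The aorta mask is the union of the thresholded wall draft and the lumen
#' mask; the final wall mask is the aorta minus the lumen. Draft voxels that
#' overlap the lumen (stained plaque confounded with wall) are therefore
#' assigned to the lumen, not the wall.
#'
#' @param wall_draft Wall draft [binary_mask()] (the thresholded draft, not
#'   the shell-closed boundary).
#' @param lumen Lumen [binary_mask()] on the same grid.
#' @return A `wall_lumen_result`: list with `wall_mask`, `lumen_mask`,
#'   `aorta_mask`, and `intermediate` (empty here), satisfying
#'   `wall == aorta \ lumen`, `wall ∩ lumen == ∅`, `aorta == wall ∪ lumen`.
#' @export
compose_wall_lumen <- function(wall_draft, lumen) {
  check_same_grid(wall_draft, lumen, "wall draft and lumen")
  aorta <- wall_draft$data | lumen$data
  wall <- aorta & !lumen$data
  structure(list(wall_mask = mask_like(lumen, wall, "wall"),
                 lumen_mask = mask_like(lumen, lumen$data, "lumen"),
                 aorta_mask = mask_like(lumen, aorta, "aorta"),
                 intermediate = list()),
            class = "wall_lumen_result")
}

#' @export
print.wall_lumen_result <- function(x, ...) {
  cat(sprintf("wall_lumen_result: wall %d, lumen %d, aorta %d voxels\n",
              sum(x$wall_mask$data), sum(x$lumen_mask$data),
              sum(x$aorta_mask$data)))
  invisible(x)
}

#' Segment wall and lumen inside the ROI
#'
#' Chains the wall/lumen stages: threshold the wall draft, close the
#' boundary with the ROI shell, extract the interior cavity, fill
#' plaque-induced voids, optionally apply manual lumen edits, and compose
#' the final wall/lumen/aorta masks. Manual verification of the lumen is
#' exposed as voxel-patch edits (masks of voxels to add or remove) applied
#' between void-filling and composition, keeping the pipeline scriptable.
#'
#' @param volume A [grayscale_volume()].
#' @param roi ROI [binary_mask()] from [interpolate_roi()].
#' @param params A [seg_params()].
#' @param manual_lumen_edits Optional `list(add = <mask or array>,
#'   remove = <mask or array>)` voxel patches.
#' @param keep_intermediates Retain the draft masks in `$intermediate`.
#' @return A `wall_lumen_result` (see [compose_wall_lumen()]).
#' @export
segment_wall_lumen <- function(volume, roi, params = seg_params(),
                               manual_lumen_edits = NULL,
                               keep_intermediates = FALSE) {
  draft <- threshold_wall_draft(volume, roi, params)
  boundary <- build_closed_boundary(draft, roi, params)
  lumen_draft <- extract_lumen_draft(boundary, roi)
  lumen <- fill_lumen_voids(lumen_draft, params, roi = roi)
  if (!is.null(manual_lumen_edits)) {
    get_arr <- function(x) if (inherits(x, "binary_mask")) x$data else x
    ldat <- lumen$data
    if (!is.null(manual_lumen_edits$add))
      ldat <- ldat | get_arr(manual_lumen_edits$add)
    if (!is.null(manual_lumen_edits$remove))
      ldat <- ldat & !get_arr(manual_lumen_edits$remove)
    lumen <- mask_like(lumen, ldat, "lumen")
  }
  res <- compose_wall_lumen(draft, lumen)
  if (keep_intermediates)
    res$intermediate <- list(wall_draft = draft, shell_boundary = boundary,
                             lumen_draft = lumen_draft)
  res
}
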