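#' Threshold the plaque draft inside the lumen
#'
#' Smooths the full attenuation volume with a Gaussian kernel (width
#' `plaque_sigma` voxels, truncated at `plaque_support` voxels radius and
#' renormalized to unit sum) and thresholds it at `plaque_threshold` within
#' the lumen mask: all stained tissue inside the aortic lumen. Smoothing is
#' computed on the whole volume, not the masked region, so attenuation just
#' outside the lumen contributes to boundary voxels exactly as in the
#' scanner pipeline.
#'
#' @param volume A [grayscale_volume()].
#' @param lumen Lumen [binary_mask()] on the same grid.
#' @param params A [seg_params()].
#' @return A [binary_mask()] with role `"plaque_draft"`.
#' @export
threshold_plaque_draft <- function(volume, lumen, params = seg_params()) {
  check_same_grid(volume, lumen, "volume and lumen")
  sm <- gaussian_smooth(volume$data, params$plaque_sigma,
                        params$plaque_support)
  mask_like(lumen, lumen$data & (sm >= params$plaque_threshold),
            "plaque_draft")
}

#' Refine the plaque draft
#'
#' Three refinement passes: (i) morphological opening with a Euclidean ball
#' of radius `opening_distance` removes sub-element speckle, including the
#' one-voxel partial-volume rind along the wall; (ii) connected components
#' (26-connectivity) smaller than `min_component_fraction` of the total
#' post-opening plaque volume are discarded; (iii) morphological closing
#' with radius `closing_distance` fills internal gaps. An empty draft
#' passes through empty.
#'
#' @param draft Plaque draft [binary_mask()].
#' @param params A [seg_params()].
#' @return A [binary_mask()] with role `"plaque"`.
#' @export
refine_plaque <- function(draft, params = seg_params()) {
  x <- ball_open(draft$data, params$opening_distance)
  if (any(x) && params$min_component_fraction > 0) {
    lab <- label_components(x, 26L)
    counts <- tabulate(lab[lab > 0L])
    small <- which(counts < params$min_component_fraction * sum(counts))
    if (length(small) > 0) x <- x & !(array(lab %in% small, dim(x)))
  }
  x <- ball_close(x, params$closing_distance)
  mask_like(draft, x, "plaque")
}

#' Detect lesions as plaque-wall contact
#'
#' Aortic lesions are the regions of contact between plaques and the wall:
#' the one-voxel-thick layer of plaque face-adjacent to the wall, computed
#' as the intersection of the plaque with the one-voxel dilation of the
#' wall.
#'
#' @param plaque Plaque [binary_mask()].
#' @param wall Wall [binary_mask()] on the same grid; must be disjoint from
#'   the plaque.
#' @return A [binary_mask()] with role `"lesion"`.
#' @export
detect_lesions <- function(plaque, wall) {
  check_same_grid(plaque, wall, "plaque and wall")
  if (any(plaque$data & wall$data))
    am_stop("plaque and wall masks overlap", "am_value_error")
  mask_like(plaque, plaque$data & ball_dilate(wall$data, 1), "lesion")
}

#' Segment plaques and lesions
#'
#' Chains plaque thresholding, refinement, and lesion detection. After
#' refinement the plaque is re-intersected with the lumen so closing cannot
#' push plaque into the wall; the result therefore always satisfies
#' `plaque ⊆ lumen` and `lesion ⊆ plaque`.
#'
#' @param volume A [grayscale_volume()].
#' @param wall_lumen A `wall_lumen_result` from [segment_wall_lumen()].
#' @param params A [seg_params()].
#' @param keep_intermediates Retain the draft masks in `$intermediate`.
#' @return A `plaque_result`: list with `plaque_mask`, `lesion_mask`,
#'   `intermediate`.
#' @export
segment_plaques <- function(volume, wall_lumen, params = seg_params(),
                            keep_intermediates = FALSE) {
  draft <- threshold_plaque_draft(volume, wall_lumen$lumen_mask, params)
  refined <- refine_plaque(draft, params)
  plaque <- mask_like(refined, refined$data & wall_lumen$lumen_mask$data,
                      "plaque")
  lesion <- detect_lesions(plaque, wall_lumen$wall_mask)
  res <- structure(list(plaque_mask = plaque, lesion_mask = lesion,
                        intermediate = list()),
                   class = "plaque_result")
  if (keep_intermediates)
    res$intermediate <- list(plaque_draft = draft, refined = refined)
  res
}

#' @export
print.plaque_result <- function(x, ...) {
  cat(sprintf("plaque_result: plaque %d, lesion %d voxels\n",
              sum(x$plaque_mask$data), sum(x$lesion_mask$data)))
  invisible(x)
}

#' Concatenated label volume
#'
#' Combines wall, plaque, and lesion into one integer label volume
#' (0 background, 1 wall, 2 plaque, 3 lesion) for rendering and export;
#' lesions overwrite plaque, plaque overwrites wall.
#'
#' @param wall_lumen A `wall_lumen_result`.
#' @param plaque_result A `plaque_result`.
#' @return Integer 3D array.
#' @export
label_volume <- function(wall_lumen, plaque_result) {
  lab <- array(0L, dim(wall_lumen$wall_mask$data))
  lab[wall_lumen$wall_mask$data] <- 1L
  lab[plaque_result$plaque_mask$data] <- 2L
  lab[plaque_result$lesion_mask$data] <- 3L
  lab
}
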