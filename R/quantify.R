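#' Mask volume by voxel counting
#'
#' Exact volume: voxel count times voxel_size^3, no estimation.
#'
#' @param mask A [binary_mask()].
#' @return Volume in mm^3.
#' @examples
#' m <- binary_mask(array(TRUE, c(10, 10, 10)), 0.01, "lumen")
#' mask_volume(m)  # 1000 voxels at 10 um -> 0.001 mm^3
#' @export
mask_volume <- function(mask) {
  sum(mask$data) * mask$voxel_size^3
}

#' Triangulated mask surface area
#'
#' Surface area as the summed triangle areas of an iso-surface
#' triangulation of the mask at level 0.5. To remove the orientation bias
#' of triangulating a staircase binary boundary, the binary field is first
#' smoothed with a narrow Gaussian (`smooth_sigma` voxels, default 1.0, at
#' which the estimator's residual bias on digitized spheres is below half a
#' percent); for objects thinner than the kernel (where the smoothed field
#' never reaches the level) the raw binary field is triangulated instead.
#'
#' @param mask A non-empty [binary_mask()].
#' @param smooth_sigma Pre-triangulation smoothing width in voxels.
#' @return Surface area in mm^2.
#' @export
mask_surface <- function(mask, smooth_sigma = 1.0) {
  if (!any(mask$data))
    am_stop("cannot measure the surface of an empty mask", "am_value_error")
  tri <- surface_triangles(mask$data, level = 0.5, smooth_sigma = smooth_sigma)
  sum(triangle_areas(tri)) * mask$voxel_size^2
}

#' Lesion surface
#'
#' Lesions are quasi-planar one-voxel-thick sheets, so the anatomically
#' meaningful surface is one side only: 50 percent of the triangulated
#' lesion mask surface. An empty lesion has zero surface.
#'
#' @param lesion Lesion [binary_mask()] (possibly empty).
#' @return Surface in mm^2.
#' @export
lesion_surface <- function(lesion) {
  if (!any(lesion$data)) return(0)
  0.5 * mask_surface(lesion)
}

#' Local wall thickness
#'
#' Model-independent thickness by a distance-transform algorithm: the
#' thickness at a voxel is the diameter of the largest sphere that fits
#' inside the wall and contains that voxel (Euclidean distance transform
#' followed by inscribed-sphere propagation). Returns the mean over wall
#' voxels and the per-voxel distribution.
#'
#' @param wall Non-empty wall [binary_mask()].
#' @return List with `mean` (mm) and `distribution` (numeric vector, mm,
#'   one value per wall voxel).
#' @export
wall_thickness <- function(wall) {
  if (!any(wall$data))
    am_stop("cannot measure thickness of an empty wall mask",
            "am_value_error")
  d <- dim(wall$data)
  # pad so a mask touching the array border still sees background
  x <- pad_array(wall$data, 1L)
  th <- array(cpp_local_thickness(as.logical(x), as_dim3(x)), dim(x))
  th <- crop_array(th, 1L, d)
  vals <- th[wall$data] * wall$voxel_size
  list(mean = mean(vals), distribution = vals)
}

#' Volumetric outcomes and fractions
#'
#' Plaque volume fraction = 100 * plaque volume / lumen volume, and lesion
#' surface fraction = 100 * lesion surface / lumen surface. The denominator
#' is the full anatomical lumen (bounded by the inner wall, containing the
#' plaque), so fractions stay within 0..100.
#'
#' @param wall_lumen A `wall_lumen_result`.
#' @param plaque_result A `plaque_result`.
#' @return List with `lumen_volume`, `plaque_volume`, `aorta_volume`,
#'   `wall_volume` (mm^3), `lumen_surface`, `lesion_surface` (mm^2),
#'   `plaque_volume_fraction`, `lesion_surface_fraction` (percent), and
#'   `mean_wall_thickness` (mm).
#' @export
volume_fractions <- function(wall_lumen, plaque_result) {
  lumen <- wall_lumen$lumen_mask
  if (!any(lumen$data))
    am_stop("empty lumen mask: fractions undefined", "am_value_error")
  lumen_volume <- mask_volume(lumen)
  plaque_volume <- mask_volume(plaque_result$plaque_mask)
  aorta_volume <- mask_volume(wall_lumen$aorta_mask)
  wall_volume <- mask_volume(wall_lumen$wall_mask)
  lumen_surface <- mask_surface(lumen)
  lesion_surf <- lesion_surface(plaque_result$lesion_mask)
  thickness <- if (any(wall_lumen$wall_mask$data))
    wall_thickness(wall_lumen$wall_mask)$mean else NA_real_
  list(lumen_volume = lumen_volume,
       plaque_volume = plaque_volume,
       aorta_volume = aorta_volume,
       wall_volume = wall_volume,
       lumen_surface = lumen_surface,
       lesion_surface = lesion_surf,
       plaque_volume_fraction = 100 * plaque_volume / lumen_volume,
       lesion_surface_fraction = 100 * lesion_surf / lumen_surface,
       mean_wall_thickness = thickness)
}

# iso-contour of a 2D binary slice; same smoothing-with-fallback scheme as
# mask_surface, in 2D. Returns segments (y1,x1,y2,x2) in voxel units.
slice_contour_segments <- function(slice, smooth_sigma = 1.0) {
  x <- matrix(as.numeric(slice), nrow(slice), ncol(slice))
  p <- if (smooth_sigma > 0) as.integer(ceiling(3 * smooth_sigma)) + 1L else 1L
  xp <- matrix(0, nrow(x) + 2L * p, ncol(x) + 2L * p)
  xp[p + seq_len(nrow(x)), p + seq_len(ncol(x))] <- x
  if (smooth_sigma > 0) {
    sm <- array(cpp_gaussian3(as.numeric(xp), c(dim(xp), 1L), smooth_sigma,
                              as.integer(ceiling(3 * smooth_sigma))),
                dim(xp))
    if (max(sm) >= 0.5) xp <- sm
  }
  segs <- cpp_iso_segments2d(xp, 0.5)
  if (nrow(segs) > 0) segs <- segs - p
  segs
}

#' Per-slice stenosis and lesion-length metrics
#'
#' For every axial slice with a nonempty lumen: lumen and plaque
#' cross-sectional areas (voxel counting), stenosis = 100 * plaque area /
#' lumen area, the lumen perimeter as the length of the sub-voxel
#' iso-contour of the lumen slice, the lesion length as the summed length
#' of lumen-contour segments passing through the lesion contact band, and
#' lesion length fraction = 100 * lesion length / lumen perimeter.
#'
#' @param wall_lumen A `wall_lumen_result`.
#' @param plaque_result A `plaque_result`.
#' @param slice_range Optional 1-based inclusive `c(first, last)` axial
#'   range to analyze.
#' @return A data frame with one row per analyzed slice: `slice` (0-based
#'   axial index), `lumen_area`, `plaque_area` (mm^2), `stenosis` (percent),
#'   `lumen_perimeter`, `lesion_length` (mm), `lesion_length_fraction`
#'   (percent).
#' @export
per_slice_metrics <- function(wall_lumen, plaque_result, slice_range = NULL) {
  lumen <- wall_lumen$lumen_mask
  plaque <- plaque_result$plaque_mask
  lesion <- plaque_result$lesion_mask
  vs <- lumen$voxel_size
  d <- dim(lumen$data)
  idx <- seq_len(d[1])
  if (!is.null(slice_range))
    idx <- idx[idx >= slice_range[1] & idx <= slice_range[2]]

  rows <- lapply(idx, function(i) {
    lsl <- lumen$data[i, , ]
    if (!any(lsl)) return(NULL)  # skipped: no lumen on this slice
    psl <- plaque$data[i, , ]
    esl <- lesion$data[i, , ]
    lumen_area <- sum(lsl) * vs^2
    plaque_area <- sum(psl) * vs^2
    segs <- slice_contour_segments(lsl)
    seg_len <- if (nrow(segs) > 0)
      sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
    else numeric(0)
    perimeter <- sum(seg_len) * vs
    lesion_len <- 0
    if (any(esl) && nrow(segs) > 0) {
      # contact band: lesion voxels dilated in-plane so the sub-voxel
      # contour (which runs ~half a voxel outside the lumen voxels) is
      # captured
      band <- array(cpp_sqdist_to_mask(as.logical(esl), c(d[2], d[3], 1L)),
                    c(d[2], d[3])) <= 1.5^2 + 1e-7
      my <- pmin(pmax(round((segs[, 1] + segs[, 3]) / 2) + 1, 1), d[2])
      mx <- pmin(pmax(round((segs[, 2] + segs[, 4]) / 2) + 1, 1), d[3])
      hit <- band[cbind(my, mx)]
      lesion_len <- sum(seg_len[hit]) * vs
    }
    data.frame(slice = i - 1L,
               lumen_area = lumen_area,
               plaque_area = plaque_area,
               stenosis = 100 * plaque_area / lumen_area,
               lumen_perimeter = perimeter,
               lesion_length = lesion_len,
               lesion_length_fraction =
                 if (perimeter > 0) 100 * lesion_len / perimeter else 0)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(slice = integer(0), lumen_area = numeric(0),
                      plaque_area = numeric(0), stenosis = numeric(0),
                      lumen_perimeter = numeric(0), lesion_length = numeric(0),
                      lesion_length_fraction = numeric(0))
  out
}

#' Full quantitative report for one specimen
#'
#' Combines [volume_fractions()] and [per_slice_metrics()] into the
#' per-specimen outcome set.
#'
#' @param wall_lumen A `wall_lumen_result`.
#' @param plaque_result A `plaque_result`.
#' @param slice_range Optional 1-based `c(first, last)` axial range.
#' @return A `quant_report`: list of scalar outcomes plus `per_slice`
#'   data frame.
#' @export
quantify_specimen <- function(wall_lumen, plaque_result, slice_range = NULL) {
  rep <- volume_fractions(wall_lumen, plaque_result)
  rep$per_slice <- per_slice_metrics(wall_lumen, plaque_result, slice_range)
  class(rep) <- "quant_report"
  rep
}

#' @export
print.quant_report <- function(x, ...) {
  cat("quant_report:\n")
  cat(sprintf("  lumen volume          %.5g mm^3\n", x$lumen_volume))
  cat(sprintf("  plaque volume         %.5g mm^3\n", x$plaque_volume))
  cat(sprintf("  aorta volume          %.5g mm^3\n", x$aorta_volume))
  cat(sprintf("  lumen surface         %.5g mm^2\n", x$lumen_surface))
  cat(sprintf("  lesion surface        %.5g mm^2\n", x$lesion_surface))
  cat(sprintf("  plaque volume frac    %.3g %%\n", x$plaque_volume_fraction))
  cat(sprintf("  lesion surface frac   %.3g %%\n", x$lesion_surface_fraction))
  cat(sprintf("  mean wall thickness   %.5g mm\n", x$mean_wall_thickness))
  cat(sprintf("  per-slice rows        %d\n", nrow(x$per_slice)))
  invisible(x)
}

#' Write a quant report to CSV
#'
#' One-row scalar CSV plus a per-slice CSV next to it
#' (`<stem>_per_slice.csv`).
#'
#' @param report A `quant_report`.
#' @param path Output CSV path for the scalar row.
#' @param id Specimen identifier recorded in the CSV.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, id = "specimen") {
  scalars <- report[setdiff(names(report), "per_slice")]
  df <- cbind(data.frame(id = id), as.data.frame(scalars))
  write.csv(df, path, row.names = FALSE)
  ps_path <- sub("\\.csv$", "_per_slice.csv", path)
  write.csv(report$per_slice, ps_path, row.names = FALSE)
  invisible(path)
}
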