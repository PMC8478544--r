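#' Rasterize a closed contour on one slice
#'
#' Fills the interior of a simple closed polygon on a 2D pixel grid: a pixel
#' belongs to the interior when its center lies inside the polygon
#' (even-odd rule) or exactly on its boundary. Coordinates are 0-based
#' voxel-center in-plane coordinates (axis-2, axis-3).
#'
#' @param polygon n x 2 matrix of vertices; the polygon must be simple
#'   (non self-intersecting) with at least 3 vertices and non-zero area. A
#'   repeated closing vertex is allowed.
#' @param slice_shape Length-2 integer vector, the in-plane extents.
#' @return Logical matrix of dimension `slice_shape`.
#' @examples
#' sq <- rbind(c(2, 2), c(2, 10), c(10, 10), c(10, 2))
#' sum(rasterize_contour(sq, c(16, 16)))  # 81
#' @export
rasterize_contour <- function(polygon, slice_shape) {
  poly <- validate_polygon(polygon)
  cpp_rasterize_polygon(poly, as.integer(slice_shape[1]),
                        as.integer(slice_shape[2]))
}

# signed distance of a 2D binary slice: negative inside, positive outside,
# in voxel units (center-to-center)
signed_distance_2d <- function(slice) {
  d <- dim(slice)
  din <- sqrt(array(cpp_sqdist_to_mask(as.logical(slice), c(d, 1L)), d))
  dout <- sqrt(array(cpp_sqdist_to_mask(as.logical(!slice), c(d, 1L)), d))
  din - dout
}

#' Interpolate sparse contours into a dense 3D ROI
#'
#' Turns manually drawn outer-aorta contours at sparse axial slices into a
#' dense region-of-interest mask by shape-based interpolation: each bounding
#' contour is rasterized and converted to a signed distance field (negative
#' inside), the two fields are blended linearly by fractional slice
#' position, and the blend is thresholded at <= 0. Contoured slices
#' reproduce their exact rasterization; slices outside the contoured range
#' stay empty. Because no vertex correspondence between slices is needed,
#' radius and position changes interpolate smoothly.
#'
#' @param contours A [contour_set()] (slice indices are 0-based axial
#'   indices; `mm` polygons are converted using `voxel_size` and `origin`).
#' @param volume_shape Length-3 integer vector, the full grid extents.
#' @param voxel_size Voxel size in mm (required for the output mask and for
#'   `mm` contours).
#' @param origin Physical origin in mm.
#' @return A [binary_mask()] with role `"roi"` and an extra element
#'   `source_slices` listing the manually contoured (0-based) slices.
#' @export
interpolate_roi <- function(contours, volume_shape, voxel_size,
                            origin = c(0, 0, 0)) {
  if (!inherits(contours, "contour_set"))
    am_stop("`contours` must be a contour_set", "am_value_error")
  if (length(contours$contours) < 2L)
    am_stop("ROI interpolation needs at least 2 contoured slices",
            "am_value_error")
  volume_shape <- as.integer(volume_shape)
  slices <- vapply(contours$contours, function(ct) ct$slice, integer(1))
  if (any(slices < 0L) || any(slices > volume_shape[1] - 1L))
    am_stop("contour slice index outside the volume extent", "am_value_error")

  shp2 <- volume_shape[2:3]
  rasters <- lapply(contours$contours, function(ct) {
    poly <- ct$polygon
    if (contours$units == "mm")
      poly <- sweep(poly, 2, origin[2:3]) / voxel_size
    rasterize_contour(poly, shp2)
  })
  sdfs <- lapply(rasters, signed_distance_2d)

  roi <- array(FALSE, volume_shape)
  for (k in seq_along(slices))
    roi[slices[k] + 1L, , ] <- rasters[[k]]
  for (k in seq_len(length(slices) - 1L)) {
    s0 <- slices[k]; s1 <- slices[k + 1L]
    if (s1 - s0 < 2L) next
    for (s in (s0 + 1L):(s1 - 1L)) {
      f <- (s - s0) / (s1 - s0)
      roi[s + 1L, , ] <- ((1 - f) * sdfs[[k]] + f * sdfs[[k + 1L]]) <= 0
    }
  }

  out <- binary_mask(roi, voxel_size, "roi", origin)
  out$source_slices <- slices
  out
}
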