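#' Grayscale attenuation volume
#'
#' A 3D scalar field of linear attenuation values (cm^-1) on an isotropic
#' voxel grid. Axis 1 is the axial (cranio-caudal) axis; a "slice" is always
#' a plane perpendicular to axis 1. Voxel indices are 0-based in physical
#' mapping: position (mm) = index * voxel_size + origin (voxel-center
#' convention).
#'
#' @param data 3D numeric array of attenuation values (cm^-1). All values
#'   must be finite.
#' @param voxel_size Isotropic voxel edge length in mm (> 0).
#' @param origin Physical offset of voxel (0,0,0) in mm; length-3 numeric.
#' @return An object of class `grayscale_volume`.
#' @examples
#' vol <- grayscale_volume(array(0, c(4, 4, 4)), voxel_size = 0.01)
#' @export
grayscale_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    am_stop("`data` must be a 3D array", "am_value_error")
  if (any(dim(data) < 1L))
    am_stop("all three dimensions must be >= 1", "am_value_error")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    am_stop("`voxel_size` must be a single positive number", "am_value_error")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    am_stop("attenuation values must be finite (no NaN/Inf)", "am_value_error")
  if (length(origin) != 3L || !all(is.finite(origin)))
    am_stop("`origin` must be a finite 3-vector", "am_value_error")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "grayscale_volume")
}

#' @export
print.grayscale_volume <- function(x, ...) {
  cat(sprintf("grayscale_volume: %s voxels, %.4g mm/voxel, range [%.3g, %.3g] cm^-1\n",
              paste(dim(x$data), collapse = " x "), x$voxel_size,
              min(x$data), max(x$data)))
  invisible(x)
}

mask_roles <- c("roi", "wall_draft", "lumen_draft", "lumen", "wall", "aorta",
                "plaque_draft", "plaque", "lesion")

#' Binary segmentation mask
#'
#' A 3D boolean field on the same grid as the volume it was derived from,
#' with a role label naming the segmentation state it represents.
#'
#' @param data 3D logical array.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param role One of `"roi"`, `"wall_draft"`, `"lumen_draft"`, `"lumen"`,
#'   `"wall"`, `"aorta"`, `"plaque_draft"`, `"plaque"`, `"lesion"`.
#' @param origin Physical offset in mm (3-vector).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size, role, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    am_stop("`data` must be a 3D array", "am_value_error")
  if (is.numeric(data)) {
    data <- array(data != 0, dim(data))
  }
  if (!is.logical(data))
    am_stop("`data` must be logical", "am_value_error")
  if (any(is.na(data)))
    am_stop("mask values must not be NA", "am_value_error")
  if (length(role) != 1L || !(role %in% mask_roles))
    am_stop(sprintf("`role` must be one of: %s",
                    paste(mask_roles, collapse = ", ")), "am_value_error")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    am_stop("`voxel_size` must be a single positive number", "am_value_error")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 role = role, origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask [%s]: %s voxels, %d set, %.4g mm/voxel\n",
              x$role, paste(dim(x$data), collapse = " x "),
              sum(x$data), x$voxel_size))
  invisible(x)
}

# derive a mask on the grid of a parent volume/mask
mask_like <- function(parent, data, role) {
  binary_mask(data, voxel_size = parent$voxel_size, role = role,
              origin = parent$origin)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    am_stop(sprintf("%s must share the same grid (shape and voxel size)", what),
            "am_grid_error")
  invisible(TRUE)
}

#' Sparse per-slice outer contours
#'
#' Ordered closed polygons drawn on axial slices, defining the outer aortic
#' boundary at sparse slice indices. Polygons are simple (non
#' self-intersecting) closed vertex sequences in in-plane coordinates
#' (axis-2, axis-3), either voxel units (0-based voxel centers) or mm.
#'
#' @param contours List of `list(slice = <integer>, polygon = <n x 2 matrix>)`
#'   entries; slice indices must be strictly increasing 1-based axial indices.
#' @param units `"voxel"` or `"mm"`.
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(contours, units = c("voxel", "mm")) {
  units <- match.arg(units)
  if (!is.list(contours) || length(contours) < 1L)
    am_stop("`contours` must be a non-empty list", "am_value_error")
  idx <- vapply(contours, function(ct) as.numeric(ct$slice), numeric(1))
  if (any(idx != round(idx)) || any(diff(idx) <= 0))
    am_stop("slice indices must be strictly increasing integers",
            "am_value_error")
  contours <- lapply(contours, function(ct) {
    poly <- validate_polygon(ct$polygon)
    list(slice = as.integer(ct$slice), polygon = poly)
  })
  structure(list(contours = contours, units = units), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("contour_set: %d contours on slices %s (%s units)\n",
              length(x$contours),
              paste(vapply(x$contours, function(ct) ct$slice, integer(1)),
                    collapse = ", "),
              x$units))
  invisible(x)
}

# Validate a closed simple polygon: >= 3 distinct vertices, non-zero area,
# no self-intersection. A repeated final vertex is dropped.
validate_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L)
    am_stop("polygon must be an n x 2 coordinate matrix", "am_value_error")
  n <- nrow(poly)
  if (n >= 2L && all(poly[1, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L)
    am_stop("polygon needs at least 3 vertices", "am_value_error")
  if (!all(is.finite(poly)))
    am_stop("polygon vertices must be finite", "am_value_error")
  a <- polygon_area(poly)
  if (abs(a) < 1e-12)
    am_stop("polygon is degenerate (zero area)", "am_value_error")
  if (polygon_self_intersects(poly))
    am_stop("polygon is self-intersecting", "am_value_error")
  poly
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  0.5 * sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])
}

# O(E^2) proper-crossing test between non-adjacent edges
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  p1 <- poly
  p2 <- poly[c(2:n, 1), , drop = FALSE]
  seg_cross <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      if (seg_cross(p1[i, ], p2[i, ], p1[j, ], p2[j, ])) return(TRUE)
    }
  }
  FALSE
}
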