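# 3D raster morphology on logical arrays. All "distance = n voxels"
# operations use a Euclidean ball of radius n (distance-transform
# thresholding), isotropic in 3D. Voxels outside the array have no
# influence: dilation cannot reach in from outside and erosion does not
# treat the border as background. Callers that need unclipped behaviour
# (closing) pad first.

as_dim3 <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  as.integer(d)
}

sqdist_to <- function(mask) {
  array(cpp_sqdist_to_mask(as.logical(mask), as_dim3(mask)),
        dim = dim(mask))
}

#' @rdname morphology
#' @export
ball_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- sqdist_to(mask)
  array(d <= radius^2 + 1e-7, dim = dim(mask))
}

#' @rdname morphology
#' @export
ball_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- sqdist_to(!mask)
  array(mask & !(d <= radius^2 + 1e-7), dim = dim(mask))
}

pad_array <- function(x, p, value = FALSE) {
  d <- dim(x)
  out <- array(value, d + 2L * p)
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3])] <- x
  out
}

crop_array <- function(x, p, d) {
  x[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), drop = FALSE]
}

#' Euclidean-ball morphology
#'
#' Dilation, erosion, opening, and closing of a 3D logical array with a
#' Euclidean ball of the given radius (in voxels), implemented by
#' thresholding the exact squared Euclidean distance transform. Opening and
#' closing are computed in a padded bounding box so they are not clipped at
#' array borders.
#'
#' @param mask 3D logical array.
#' @param radius Ball radius in voxels (>= 0; 0 is the identity).
#' @return 3D logical array of the same shape.
#' @name morphology
#' @export
ball_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  p <- as.integer(ceiling(radius)) + 1L
  x <- pad_array(mask, p)
  x <- ball_dilate(x, radius)
  x <- ball_erode(x, radius)
  crop_array(x, p, dim(mask))
}

#' @rdname morphology
#' @export
ball_open <- function(mask, radius) {
  if (radius <= 0) return(mask)
  p <- as.integer(ceiling(radius)) + 1L
  x <- pad_array(mask, p)
  x <- ball_erode(x, radius)
  x <- ball_dilate(x, radius)
  crop_array(x, p, dim(mask))
}

# In-plane (per axial slice) erosion with a 2D Euclidean disc; used for the
# ROI shell, which follows the manually drawn contours slice by slice.
disc_erode_slicewise <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- dim(mask)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) {
    sl <- mask[i, , ]
    if (!any(sl)) next
    dist <- array(cpp_sqdist_to_mask(as.logical(!sl), c(d[2], d[3], 1L)),
                  dim = c(d[2], d[3]))
    out[i, , ] <- sl & !(dist <= radius^2 + 1e-7)
  }
  out
}

#' Connected-component labeling
#'
#' Labels connected components of a 3D logical array under 6- or
#' 26-connectivity. Components are numbered deterministically: the
#' component whose first voxel comes earliest in column-major raster order
#' receives label 1.
#'
#' @param mask 3D logical array.
#' @param connectivity 6 (face) or 26 (face/edge/corner).
#' @return Integer array of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 6L) {
  if (!connectivity %in% c(6L, 26L))
    am_stop("connectivity must be 6 or 26", "am_value_error")
  array(cpp_label_components(as.logical(mask), as_dim3(mask),
                             as.integer(connectivity)),
        dim = dim(mask))
}

# Gaussian smoothing of a 3D numeric array; kernel truncated at `support`
# voxels radius and renormalized to unit sum. Reflecting boundaries.
gaussian_smooth <- function(x, sigma, support) {
  array(cpp_gaussian3(as.numeric(x), as_dim3(x), sigma, as.integer(support)),
        dim = dim(x))
}
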