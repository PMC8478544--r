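#' Read a 3D attenuation volume
#'
#' Reads either a single-file NIfTI volume (`.nii` / `.nii.gz`) or a
#' directory of equally sized 2D TIFF slices in lexicographic order (one
#' slice per file, stacked along axis 1, the axial axis). Stored values are
#' multiplied by `units_scale`, the single place where attenuation
#' calibration happens: native 16-bit scanner integers can be mapped to
#' linear attenuation in cm^-1 (e.g. stored value 6000 with
#' `units_scale = 0.001` becomes 6.0 cm^-1). All downstream thresholds
#' assume cm^-1.
#'
#' @param path File or directory path.
#' @param units_scale Scalar multiplier applied to stored values.
#' @param voxel_size_override Voxel size in mm; required for TIFF stacks
#'   (which carry no calibrated size) and overrides NIfTI metadata when
#'   given.
#' @return A [grayscale_volume()].
#' @export
read_volume <- function(path, units_scale = 1, voxel_size_override = NULL) {
  if (!file.exists(path))
    am_stop(sprintf("path does not exist: %s", path), "am_io_error")
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L)
      am_stop(sprintf("no TIFF slices found in %s", path), "am_io_error")
    slices <- lapply(files, function(f) {
      s <- tryCatch(tiff::readTIFF(f, as.is = TRUE),
                    error = function(e)
                      am_stop(sprintf("unreadable TIFF %s: %s", f,
                                      conditionMessage(e)), "am_io_error"))
      if (length(dim(s)) == 3L) s <- s[, , 1]  # drop extra channels
      s
    })
    shp <- dim(slices[[1]])
    if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
      am_stop("slices in stack have inconsistent shapes", "am_format_error")
    if (is.null(voxel_size_override))
      am_stop("TIFF stacks carry no voxel size; voxel_size_override required",
              "am_config_error")
    data <- array(0, c(length(slices), shp))
    for (i in seq_along(slices)) data[i, , ] <- slices[[i]]
    return(grayscale_volume(data * units_scale, voxel_size_override))
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      am_stop(sprintf("unreadable volume %s: %s", path,
                                      conditionMessage(e)), "am_io_error"))
    data <- array(as.numeric(img), dim(img))
    if (length(dim(data)) != 3L)
      am_stop("volume must be 3D", "am_format_error")
    vs <- voxel_size_override
    if (is.null(vs)) {
      pd <- RNifti::pixdim(img)[1:3]
      if (any(!is.finite(pd)) || any(pd <= 0))
        am_stop("volume has no usable voxel size; supply voxel_size_override",
                "am_config_error")
      if (diff(range(pd)) > 1e-6 * mean(pd))
        am_stop("anisotropic voxels are not supported; supply voxel_size_override",
                "am_config_error")
      # pixdim is stored as float32; snap to 7 significant digits
      vs <- signif(pd[1], 7)
    }
    return(grayscale_volume(data * units_scale, vs))
  }
  am_stop(sprintf("unrecognized volume format: %s", path), "am_format_error")
}

#' Write a volume to a NIfTI file
#'
#' Stored at full double precision so read-back reproduces the data exactly.
#'
#' @param vol A [grayscale_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "grayscale_volume"))
    am_stop("`vol` must be a grayscale_volume", "am_value_error")
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- rep(vol$voxel_size, 3)
  tryCatch(RNifti::writeNifti(img, path, datatype = "double"),
           error = function(e)
             am_stop(sprintf("cannot write %s: %s", path,
                             conditionMessage(e)), "am_io_error"))
  invisible(path)
}

#' Write and read binary masks
#'
#' Masks are stored as 8-bit NIfTI volumes (0/255) with a JSON sidecar
#' (`<path>.json`) carrying the role label, so a round-trip reproduces the
#' boolean array, voxel size, and role exactly.
#'
#' @param mask A [binary_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   [binary_mask()].
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "binary_mask"))
    am_stop("`mask` must be a binary_mask", "am_value_error")
  arr <- array(ifelse(mask$data, 255L, 0L), dim(mask$data))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(mask$voxel_size, 3)
  tryCatch(RNifti::writeNifti(img, path, datatype = "uint8"),
           error = function(e)
             am_stop(sprintf("cannot write %s: %s", path,
                             conditionMessage(e)), "am_io_error"))
  jsonlite::write_json(list(role = mask$role, voxel_size = mask$voxel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @param role Role label used when no JSON sidecar is present.
#' @export
read_mask <- function(path, role = NULL) {
  if (!file.exists(path))
    am_stop(sprintf("path does not exist: %s", path), "am_io_error")
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img) > 0, dim(img))
  vs <- signif(RNifti::pixdim(img)[1], 7)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(role)) role <- meta$role
    if (!is.null(meta$voxel_size)) vs <- as.numeric(meta$voxel_size)
  }
  if (is.null(role))
    am_stop("mask role unknown: no sidecar and no `role` given",
            "am_config_error")
  binary_mask(data, vs, role)
}

#' Read and write sparse contour files
#'
#' Plain-text schema (one file per specimen):
#' \preformatted{
#' # aortamorph contour set v1
#' units voxel
#' slice 12
#' 40.0 48.0
#' 40.0 80.0
#' 72.0 80.0
#' ...
#' slice 40
#' ...
#' }
#' Lines starting with `#` and blank lines are ignored. `units` is `voxel`
#' (0-based voxel-center coordinates) or `mm`. Each `slice <index>` line
#' (0-based axial index) is followed by one `<axis2> <axis3>` vertex pair
#' per line; polygons are implicitly closed.
#'
#' @param path Contour file path.
#' @return `read_contours` returns a [contour_set()].
#' @export
read_contours <- function(path) {
  if (!file.exists(path))
    am_stop(sprintf("contour file does not exist: %s", path), "am_io_error")
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  units <- "voxel"
  contours <- list()
  cur_slice <- NULL
  cur_pts <- NULL
  flush <- function() {
    if (!is.null(cur_slice)) {
      contours[[length(contours) + 1L]] <<-
        list(slice = cur_slice, polygon = do.call(rbind, cur_pts))
    }
  }
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "units") {
      units <- tok[2]
    } else if (tok[1] == "slice") {
      flush()
      cur_slice <- as.integer(tok[2])
      cur_pts <- list()
    } else {
      v <- suppressWarnings(as.numeric(tok))
      if (length(v) != 2L || any(is.na(v)))
        am_stop(sprintf("malformed contour line: '%s'", ln), "am_format_error")
      cur_pts[[length(cur_pts) + 1L]] <- v
    }
  }
  flush()
  if (length(contours) == 0L)
    am_stop("contour file contains no contours", "am_format_error")
  contour_set(contours, units = units)
}

#' @rdname read_contours
#' @param contours A [contour_set()].
#' @export
write_contours <- function(contours, path) {
  if (!inherits(contours, "contour_set"))
    am_stop("`contours` must be a contour_set", "am_value_error")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# aortamorph contour set v1", con)
  writeLines(paste("units", contours$units), con)
  for (ct in contours$contours) {
    writeLines(paste("slice", ct$slice), con)
    apply(ct$polygon, 1, function(v)
      writeLines(sprintf("%.10g %.10g", v[1], v[2]), con))
  }
  invisible(path)
}

# Iso-surface triangulation of a (binary or scalar) 3D field at `level`.
# The field is zero-padded so the surface closes at array borders; with
# smooth_sigma > 0 a Gaussian-smoothed copy is triangulated instead, falling
# back to the raw field when the smoothed field never reaches the level
# (objects thinner than the kernel). Returns an ntri x 9 matrix of vertex
# coordinates (a1,a2,a3 per vertex) in 0-based voxel units.
surface_triangles <- function(arr, level = 0.5, smooth_sigma = 0) {
  x <- array(as.numeric(arr), dim(arr))
  p <- if (smooth_sigma > 0) as.integer(ceiling(3 * smooth_sigma)) + 1L else 1L
  xp <- pad_array(x, p, 0)
  if (smooth_sigma > 0) {
    sm <- gaussian_smooth(xp, smooth_sigma, ceiling(3 * smooth_sigma))
    if (max(sm) >= level) xp <- sm
  }
  tri <- cpp_iso_triangles(as.numeric(xp), as_dim3(xp), level)
  if (nrow(tri) > 0) tri <- tri - p  # back to unpadded 0-based coordinates
  tri
}

triangle_areas <- function(tri) {
  if (nrow(tri) == 0) return(numeric(0))
  ux <- tri[, 4] - tri[, 1]; uy <- tri[, 5] - tri[, 2]; uz <- tri[, 6] - tri[, 3]
  vx <- tri[, 7] - tri[, 1]; vy <- tri[, 8] - tri[, 2]; vz <- tri[, 9] - tri[, 3]
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Export a mask boundary as a triangle mesh
#'
#' Triangulates the 0.5 iso-surface of the binary mask (marching tetrahedra
#' on a zero-padded copy, so the mesh is closed and 2-manifold) and writes
#' an ASCII STL or PLY file. Vertex coordinates are physical:
#' `voxel index * voxel_size + origin`, in mm.
#'
#' @param mask A non-empty [binary_mask()].
#' @param path Output path ending in `.stl` or `.ply`.
#' @return Invisibly, the number of triangles written.
#' @export
export_mesh <- function(mask, path) {
  if (!inherits(mask, "binary_mask"))
    am_stop("`mask` must be a binary_mask", "am_value_error")
  if (!any(mask$data))
    am_stop("cannot export a mesh of an empty mask", "am_value_error")
  tri <- surface_triangles(mask$data)
  verts <- tri * mask$voxel_size
  verts[, c(1, 4, 7)] <- verts[, c(1, 4, 7)] + mask$origin[1]
  verts[, c(2, 5, 8)] <- verts[, c(2, 5, 8)] + mask$origin[2]
  verts[, c(3, 6, 9)] <- verts[, c(3, 6, 9)] + mask$origin[3]
  ext <- tolower(tools::file_ext(path))
  if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid aortamorph", con)
    body <- apply(verts, 1, function(v) {
      paste0("facet normal 0 0 0\n outer loop\n",
             sprintf("  vertex %.9g %.9g %.9g\n", v[1], v[2], v[3]),
             sprintf("  vertex %.9g %.9g %.9g\n", v[4], v[5], v[6]),
             sprintf("  vertex %.9g %.9g %.9g\n", v[7], v[8], v[9]),
             " endloop\nendfacet")
    })
    writeLines(body, con)
    writeLines("endsolid aortamorph", con)
  } else if (ext == "ply") {
    vm <- rbind(verts[, 1:3], verts[, 4:6], verts[, 7:9])
    n <- nrow(verts)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", 3L * n),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", n),
                 "property list uchar int vertex_indices", "end_header"), con)
    ord <- as.vector(t(cbind(seq_len(n), seq_len(n) + n, seq_len(n) + 2L * n))) - 1L
    writeLines(sprintf("%.9g %.9g %.9g", vm[, 1], vm[, 2], vm[, 3]), con)
    idx <- matrix(ord, ncol = 3, byrow = TRUE)
    writeLines(sprintf("3 %d %d %d", idx[, 1], idx[, 2], idx[, 3]), con)
  } else {
    am_stop(sprintf("unsupported mesh format: .%s (use .stl or .ply)", ext),
            "am_format_error")
  }
  invisible(nrow(verts))
}
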