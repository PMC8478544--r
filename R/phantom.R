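#' Parametric synthetic aorta phantom
#'
#' Describes a curved-tube phantom of a PTA-stained aorta: a
#' high-attenuation wall around a low-attenuation lumen, optional
#' wall-attached crescent (circular-segment) plaques at intermediate
#' attenuation, optional branch-induced wall gaps, partial-volume blur, and
#' additive Gaussian noise. Cross-sections are circles in axial planes, so
#' closed-form areas and volumes are available as ground truth. Default
#' attenuations (0.2 background / 0.5 lumen / 3.5 plaque / 8.0 wall cm^-1)
#' straddle the two segmentation thresholds (2.0, 6.0 cm^-1); they are
#' synthetic fixture constants, not measured PTA values.
#'
#' @param shape Grid extents, axial axis first. Default `c(128, 128, 128)`.
#' @param voxel_size Voxel size in mm. Default 0.01 (10 um).
#' @param centerline `"straight"` or `list(type = "arc", radius = <mm>)`: a
#'   circular arc in the (axial, axis-2) plane bowing the tube center.
#' @param lumen_radius Inner wall radius in mm.
#' @param wall_thickness Wall thickness in mm.
#' @param wall_attenuation,lumen_attenuation,background_attenuation
#'   Attenuation classes in cm^-1.
#' @param plaques List of plaque entries, each a list with `angle` (deg,
#'   angular position of the plaque on the wall), `axial_range` (mm,
#'   `c(z0, z1)`), `depth` (mm, maximal radial protrusion into the lumen;
#'   must be < `lumen_radius`), `attenuation` (cm^-1, default 3.5), and
#'   optionally `depth_taper` (`c(d0, d1)` mm, linear axial taper overriding
#'   `depth`), `core_radius` / `core_attenuation` (a small spherical highly
#'   stained core inside the plaque, emulating plaque confounded with the
#'   wall).
#' @param branch_gaps List of wall discontinuities, each a list with
#'   `axial_position` (mm), `angular_span` (deg), and optionally `angle`
#'   (deg, default 90) and `axial_extent` (mm, default twice the wall
#'   thickness).
#' @param blur_sigma Gaussian partial-volume blur width in voxels.
#' @param noise_sd Additive zero-mean Gaussian noise sd in cm^-1.
#' @param seed Integer RNG seed used for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 128),
                         voxel_size = 0.01,
                         centerline = "straight",
                         lumen_radius = 0.25,
                         wall_thickness = 0.08,
                         wall_attenuation = 8.0,
                         lumen_attenuation = 0.5,
                         background_attenuation = 0.2,
                         plaques = list(),
                         branch_gaps = list(),
                         blur_sigma = 0,
                         noise_sd = 0,
                         seed = 1L) {
  if (lumen_radius <= 0 || wall_thickness <= 0)
    am_stop("lumen_radius and wall_thickness must be > 0", "am_value_error")
  for (p in plaques) {
    depths <- if (!is.null(p$depth_taper)) p$depth_taper else p$depth
    if (any(depths >= lumen_radius))
      am_stop("plaque depth must be smaller than the lumen radius",
              "am_value_error")
  }
  spec <- list(shape = as.integer(shape), voxel_size = voxel_size,
               centerline = centerline, lumen_radius = lumen_radius,
               wall_thickness = wall_thickness,
               wall_attenuation = wall_attenuation,
               lumen_attenuation = lumen_attenuation,
               background_attenuation = background_attenuation,
               plaques = plaques, branch_gaps = branch_gaps,
               blur_sigma = blur_sigma, noise_sd = noise_sd,
               seed = as.integer(seed))
  r_out <- lumen_radius + wall_thickness
  max_off <- centerline_offset_mm(spec, max(shape[1] - 1, 0) * voxel_size / 2)
  half_extent <- (min(shape[2:3]) / 2 - 3) * voxel_size
  if (r_out + abs(max_off) > half_extent)
    am_stop("wall does not fit inside the grid (wall thicker than available space)",
            "am_value_error")
  structure(spec, class = "phantom_spec")
}

# in-plane (axis-2) offset of the tube center at axial position z (mm),
# relative to the grid center; arc bows symmetrically about the mid-slice
centerline_offset_mm <- function(spec, z) {
  if (identical(spec$centerline, "straight")) return(0 * z)
  R <- spec$centerline$radius
  zmid <- (spec$shape[1] - 1) * spec$voxel_size / 2
  dz <- z - zmid
  if (any(abs(dz) > R))
    am_stop("arc radius smaller than half the axial extent", "am_value_error")
  R - sqrt(R^2 - dz^2)
}

circular_segment_area <- function(r, depth) {
  depth <- pmin(pmax(depth, 0), 2 * r)
  h <- r - depth
  r^2 * acos(pmin(pmax(h / r, -1), 1)) - h * sqrt(pmax(r^2 - h^2, 0))
}

plaque_depth_at <- function(p, z) {
  z0 <- p$axial_range[1]; z1 <- p$axial_range[2]
  if (!is.null(p$depth_taper)) {
    f <- (z - z0) / (z1 - z0)
    p$depth_taper[1] + f * (p$depth_taper[2] - p$depth_taper[1])
  } else {
    rep(p$depth, length(z))
  }
}

#' Generate a synthetic aorta volume with ground truth
#'
#' Rasterizes the crisp attenuation classes of the phantom geometry,
#' applies Gaussian blur (partial-volume emulation) and additive noise, and
#' returns the volume together with ground-truth masks and closed-form
#' volumes. Ground truth is the pre-blur crisp geometry, so recovery errors
#' measured against it honestly include partial-volume effects. The result
#' is deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [grayscale_volume()]) and `ground_truth`:
#'   masks `lumen`, `wall`, `plaque`, `lesion` (the anatomical lumen
#'   contains the plaque; the wall mask ignores branch gaps, which exist
#'   only in the attenuation image), plus `analytic_lumen_volume`,
#'   `analytic_plaque_volume` (mm^3), and `analytic_wall_thickness` (mm).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    am_stop("`spec` must be a phantom_spec", "am_value_error")
  d <- spec$shape
  vs <- spec$voxel_size
  r_in <- spec$lumen_radius
  r_out <- r_in + spec$wall_thickness

  att <- array(spec$background_attenuation, d)
  lumen_gt <- array(FALSE, d)
  wall_gt <- array(FALSE, d)
  plaque_gt <- array(FALSE, d)

  yc0 <- (d[2] - 1) / 2
  xc0 <- (d[3] - 1) / 2
  ymm <- (seq_len(d[2]) - 1) * vs
  xmm <- (seq_len(d[3]) - 1) * vs

  for (i in seq_len(d[1])) {
    z <- (i - 1) * vs
    cy <- yc0 * vs + centerline_offset_mm(spec, z)
    cx <- xc0 * vs
    dy <- ymm - cy
    dx <- xmm - cx
    rho <- sqrt(outer(dy^2, dx^2, "+"))
    lum <- rho < r_in
    wal <- rho >= r_in & rho < r_out
    lumen_gt[i, , ] <- lum
    wall_gt[i, , ] <- wal

    sl <- att[i, , ]
    sl[lum] <- spec$lumen_attenuation
    sl[wal] <- spec$wall_attenuation

    for (p in spec$plaques) {
      if (z < p$axial_range[1] || z > p$axial_range[2]) next
      dep <- plaque_depth_at(p, z)
      if (dep <= 0) next
      a <- p$angle * pi / 180
      proj <- outer(dy * cos(a), dx * sin(a), "+")
      reg <- lum & proj >= (r_in - dep)
      plaque_gt[i, , ] <- plaque_gt[i, , ] | reg
      p_att <- if (is.null(p$attenuation)) 3.5 else p$attenuation
      sl[reg] <- p_att
      if (!is.null(p$core_radius) && p$core_radius > 0) {
        zc <- mean(p$axial_range)
        cyc <- cy + (r_in - dep / 2) * cos(a)
        cxc <- cx + (r_in - dep / 2) * sin(a)
        d2 <- outer((ymm - cyc)^2, (xmm - cxc)^2, "+") + (z - zc)^2
        core <- reg & (d2 <= p$core_radius^2)
        sl[core] <- p$core_attenuation
      }
    }

    for (g in spec$branch_gaps) {
      ext <- if (is.null(g$axial_extent)) 2 * spec$wall_thickness else g$axial_extent
      if (abs(z - g$axial_position) > ext / 2) next
      g_angle <- if (is.null(g$angle)) 90 else g$angle
      theta <- outer(dy, dx, function(yy, xx) atan2(xx, yy)) * 180 / pi
      dtheta <- (theta - g_angle + 180) %% 360 - 180
      hole <- wal & abs(dtheta) <= g$angular_span / 2
      sl[hole] <- spec$background_attenuation
    }
    att[i, , ] <- sl
  }

  if (spec$blur_sigma > 0)
    att <- gaussian_smooth(att, spec$blur_sigma,
                           ceiling(3 * spec$blur_sigma))
  if (spec$noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(spec$seed)
    att <- att + array(rnorm(prod(d), 0, spec$noise_sd), d)
  }

  lesion_gt <- plaque_gt & ball_dilate(wall_gt, 1)

  axial_len <- d[1] * vs
  analytic_plaque <- 0
  for (p in spec$plaques) {
    z0 <- max(p$axial_range[1], 0)
    z1 <- min(p$axial_range[2], (d[1] - 1) * vs)
    if (z1 <= z0) next
    zz <- seq(z0, z1, length.out = 512)
    aa <- circular_segment_area(r_in, plaque_depth_at(p, zz))
    analytic_plaque <- analytic_plaque +
      sum((aa[-1] + aa[-length(aa)]) / 2 * diff(zz))
  }

  gt <- list(
    lumen = binary_mask(lumen_gt, vs, "lumen"),
    wall = binary_mask(wall_gt, vs, "wall"),
    plaque = binary_mask(plaque_gt, vs, "plaque"),
    lesion = binary_mask(lesion_gt, vs, "lesion"),
    analytic_lumen_volume = pi * r_in^2 * axial_len,
    analytic_plaque_volume = analytic_plaque,
    analytic_wall_thickness = spec$wall_thickness)

  list(volume = grayscale_volume(att, vs), ground_truth = gt)
}

#' Synthetic outer contours for a phantom
#'
#' Circles of radius `outer radius + margin` voxels traced around the
#' phantom centerline at evenly spaced axial slices, emulating the manual
#' outer-aorta contouring step. The small margin keeps the 2-voxel ROI
#' shell overlapping the outer wall, which is what closes branch gaps.
#'
#' @param spec A [phantom_spec()].
#' @param n_contours Number of contoured slices (first and last always
#'   included).
#' @param margin_voxels Contour radius margin beyond the outer wall, voxels.
#' @param n_vertices Polygon vertices per contour.
#' @return A [contour_set()] in voxel units.
#' @export
phantom_contours <- function(spec, n_contours = 10, margin_voxels = 1,
                             n_vertices = 72) {
  d <- spec$shape
  vs <- spec$voxel_size
  r <- (spec$lumen_radius + spec$wall_thickness) / vs + margin_voxels
  slices <- unique(round(seq(0, d[1] - 1, length.out = n_contours)))
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  contours <- lapply(slices, function(s) {
    z <- s * vs
    cy <- (d[2] - 1) / 2 + centerline_offset_mm(spec, z) / vs
    cx <- (d[3] - 1) / 2
    list(slice = as.integer(s),
         polygon = cbind(cy + r * cos(theta), cx + r * sin(theta)))
  })
  contour_set(contours, units = "voxel")
}

#' Fixed phantom test suite
#'
#' Documented fixture phantoms with fixed seeds, one difficulty level per
#' call: `clean` (crisp classes, no blur or noise), `blurred` (partial
#' volume blur sigma 0.8 voxel), `noisy` (blur 0.8 plus noise sd of 5
#' percent of the wall attenuation), `branch` (a 60 degree wall gap closed
#' by the ROI shell), and `confounded` (a highly stained 6.5 cm^-1 plaque
#' core above the wall threshold, exercising lumen void filling).
#'
#' @param level One of `"clean"`, `"blurred"`, `"noisy"`, `"branch"`,
#'   `"confounded"`.
#' @param shape Grid extents for the suite phantoms.
#' @return List with one entry per phantom: `list(spec, volume,
#'   ground_truth)`.
#' @export
phantom_suite <- function(level = c("clean", "blurred", "noisy", "branch",
                                    "confounded"),
                          shape = c(128, 128, 128)) {
  level <- match.arg(level)
  vs <- 0.01
  zlen <- (shape[1] - 1) * vs
  base_plaque <- list(angle = 0, axial_range = c(0.25 * zlen, 0.75 * zlen),
                      depth = 0.15, attenuation = 3.5)
  spec <- switch(level,
    clean = phantom_spec(shape = shape, plaques = list(base_plaque),
                         blur_sigma = 0, noise_sd = 0, seed = 101L),
    blurred = phantom_spec(shape = shape, plaques = list(base_plaque),
                           blur_sigma = 0.8, noise_sd = 0, seed = 102L),
    noisy = phantom_spec(shape = shape, plaques = list(base_plaque),
                         blur_sigma = 0.8, noise_sd = 0.05 * 8.0,
                         seed = 103L),
    branch = phantom_spec(shape = shape,
                          branch_gaps = list(list(
                            axial_position = 0.5 * zlen, angular_span = 60,
                            angle = 90)),
                          blur_sigma = 0, noise_sd = 0, seed = 104L),
    confounded = phantom_spec(shape = shape,
                              plaques = list(c(base_plaque, list(
                                core_radius = 0.03,
                                core_attenuation = 6.5))),
                              blur_sigma = 0, noise_sd = 0, seed = 105L))
  ph <- generate_phantom(spec)
  list(list(spec = spec, volume = ph$volume,
            ground_truth = ph$ground_truth))
}

#' Run the full pipeline on a phantom
#'
#' Convenience wrapper used by tests and validation scripts: builds the
#' synthetic contours, interpolates the ROI, segments wall/lumen and
#' plaques, and quantifies.
#'
#' @param ph A `list(volume, ground_truth)` from [generate_phantom()].
#' @param spec The generating [phantom_spec()].
#' @param params A [seg_params()].
#' @return List with `roi`, `wall_lumen`, `plaque`, `report`.
#' @export
run_phantom_pipeline <- function(ph, spec, params = seg_params()) {
  contours <- phantom_contours(spec)
  roi <- interpolate_roi(contours, dim(ph$volume$data), ph$volume$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi, params)
  pr <- segment_plaques(ph$volume, wl, params)
  list(roi = roi, wall_lumen = wl, plaque = pr,
       report = quantify_specimen(wl, pr))
}
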