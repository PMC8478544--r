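test_that("plaque threshold smooths then compares inclusively within the lumen", {
  d <- c(16, 16, 16)
  lum <- binary_mask(array(c(TRUE, FALSE), d), 0.01, "lumen")
  # constant field at 2.5: smoothing preserves constants, whole lumen marked
  v25 <- grayscale_volume(array(2.5, d), 0.01)
  expect_identical(threshold_plaque_draft(v25, lum)$data, lum$data)
  # constant 1.9 is below the 2.0 cm^-1 threshold -> empty
  v19 <- grayscale_volume(array(1.9, d), 0.01)
  expect_equal(sum(threshold_plaque_draft(v19, lum)$data), 0)
  # random volume: separable implementation equals direct convolution oracle
  set.seed(51)
  v <- grayscale_volume(array(runif(prod(d), 0, 4), d), 0.01)
  draft <- threshold_plaque_draft(v, lum)
  sm <- o_gauss(v$data, 0.8, 1)
  expect_identical(draft$data, lum$data & (sm >= 2.0))
})

test_that("plaque refinement: opening kills speckle, volume filter drops small components", {
  d <- c(24, 40, 40)
  # single isolated voxel -> removed by the opening
  lone <- array(FALSE, d)
  lone[12, 20, 20] <- TRUE
  out <- refine_plaque(binary_mask(lone, 0.01, "plaque_draft"))
  expect_equal(sum(out$data), 0)
  # one large and one small blob, both surviving the opening; the small one
  # falls below 2% of the post-opening total and is removed
  big <- make_ball(6, pad = 2)                       # ~900 voxels
  blob <- array(FALSE, d)
  blob[4:20, 4:20, 4:20][big] <- TRUE
  blob[10:12, 30:32, 30:32] <- TRUE                  # 27-voxel box
  draft <- binary_mask(blob, 0.01, "plaque_draft")
  opened <- aortamorph:::ball_open(blob, 1)
  lab <- o_label(opened, 26)
  counts <- tabulate(lab[lab > 0])
  expect_length(counts, 2)
  expect_lt(min(counts), 0.02 * sum(counts))
  refined <- refine_plaque(draft)
  expect_false(any(refined$data[10:12, 30:32, 30:32]))
  expect_gt(sum(refined$data), 0.9 * max(counts))
  # a solid ball passes through nearly unchanged
  ballm <- binary_mask(make_ball(6), 0.01, "plaque_draft")
  ref2 <- refine_plaque(ballm)
  expect_lt(abs(sum(ref2$data) / sum(ballm$data) - 1), 0.05)
  # empty draft -> empty result
  e <- binary_mask(array(FALSE, c(6, 6, 6)), 0.01, "plaque_draft")
  expect_equal(sum(refine_plaque(e)$data), 0)
})

test_that("lesions are exactly the face-adjacent plaque layer", {
  d <- c(20, 30, 30)
  wall <- array(FALSE, d)
  wall[, 1:3, ] <- TRUE   # flat wall slab
  # floating plaque sphere, no contact -> empty lesion
  farp <- array(FALSE, d)
  farp[8:12, 15:19, 15:19] <- TRUE
  les0 <- detect_lesions(binary_mask(farp, 0.01, "plaque"),
                         binary_mask(wall, 0.01, "wall"))
  expect_equal(sum(les0$data), 0)
  # hemisphere seated on the wall: lesion equals the 6-adjacency oracle
  g <- expand.grid(i = 1:20, j = 1:30, k = 1:30)
  hemi <- array((g$i - 10)^2 + (g$j - 3.6)^2 + (g$k - 15)^2 <= 5^2 & g$j >= 4,
                d)
  les1 <- detect_lesions(binary_mask(hemi, 0.01, "plaque"),
                         binary_mask(wall, 0.01, "wall"))
  expect_identical(les1$data, o_adjacent_layer(hemi, wall))
  expect_gt(sum(les1$data), 0)
  # tube phantom: plaque lining the whole wall -> lesion is the full shell
  tube <- make_tube_parts(n_ax = 8, n_in = 26, r_in = 8, wall = 3)
  ring <- tube$lumen & !aortamorph:::ball_erode(tube$lumen, 1.5)
  les2 <- detect_lesions(binary_mask(ring, 0.01, "plaque"),
                         binary_mask(tube$wall, 0.01, "wall"))
  expect_identical(les2$data, o_adjacent_layer(ring, tube$wall))
  # overlap between plaque and wall is rejected
  expect_error(detect_lesions(binary_mask(wall, 0.01, "plaque"),
                              binary_mask(wall, 0.01, "wall")),
               class = "am_value_error")
})

test_that("plaque-free phantom yields exactly zero plaque volume", {
  spec <- small_phantom_spec()
  ph <- fixture("small_clean_phantom", generate_phantom(spec))
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi)
  pr <- segment_plaques(ph$volume, wl)
  expect_equal(sum(pr$plaque_mask$data), 0)
  expect_equal(sum(pr$lesion_mask$data), 0)
})

test_that("a crescent plaque is recovered within 10% and respects containment", {
  spec <- small_phantom_spec(plaques = list(small_plaque()), blur_sigma = 0.8,
                             noise_sd = 0.4, seed = 52L)
  ph <- generate_phantom(spec)
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi)
  pr <- segment_plaques(ph$volume, wl)
  measured <- mask_volume(pr$plaque_mask)
  expect_lt(abs(measured / ph$ground_truth$analytic_plaque_volume - 1), 0.10)
  expect_true(all(wl$lumen_mask$data[pr$plaque_mask$data]))
  expect_true(all(pr$plaque_mask$data[pr$lesion_mask$data]))
})

test_that("two distant plaques stay two components", {
  spec <- small_phantom_spec(plaques = list(
    list(angle = 0, axial_range = c(0.08, 0.20), depth = 0.10,
         attenuation = 3.5),
    list(angle = 180, axial_range = c(0.40, 0.52), depth = 0.10,
         attenuation = 3.5)))
  ph <- generate_phantom(spec)
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi)
  pr <- segment_plaques(ph$volume, wl)
  lab <- label_components(pr$plaque_mask$data, 26L)
  expect_equal(max(lab), 2)
})

test_that("label volume encodes background/wall/plaque/lesion as 0/1/2/3", {
  spec <- small_phantom_spec(plaques = list(small_plaque()))
  ph <- generate_phantom(spec)
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi)
  pr <- segment_plaques(ph$volume, wl)
  lab <- label_volume(wl, pr)
  expect_setequal(unique(as.vector(lab)), 0:3)
  expect_true(all(lab[pr$lesion_mask$data] == 3L))
  expect_true(all(lab[pr$plaque_mask$data & !pr$lesion_mask$data] == 2L))
  expect_true(all(lab[wl$wall_mask$data] == 1L))
})
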