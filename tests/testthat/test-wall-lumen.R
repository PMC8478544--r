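test_that("wall threshold is inclusive at 6.0 cm^-1 and matches per-voxel comparison", {
  set.seed(41)
  d <- c(16, 16, 16)
  vol <- grayscale_volume(array(runif(prod(d), 0, 10), d), 0.01)
  vol$data[1, 1, 1] <- 6.5
  vol$data[1, 1, 2] <- 5.9
  vol$data[1, 1, 3] <- 6.0
  roi <- binary_mask(array(runif(prod(d)) < 0.8, d), 0.01, "roi")
  roi$data[1, 1, 1:3] <- TRUE
  draft <- threshold_wall_draft(vol, roi)
  expect_true(draft$data[1, 1, 1])    # 6.5 in
  expect_false(draft$data[1, 1, 2])   # 5.9 out
  expect_true(draft$data[1, 1, 3])    # inclusive comparison
  expect_identical(draft$data, roi$data & (vol$data >= 6.0))
  # all-zero volume -> empty draft
  z <- grayscale_volume(array(0, d), 0.01)
  expect_equal(sum(threshold_wall_draft(z, roi)$data), 0)
  # grid mismatch
  roi2 <- binary_mask(array(TRUE, c(8, 8, 8)), 0.01, "roi")
  expect_error(threshold_wall_draft(vol, roi2), class = "am_grid_error")
})

test_that("boundary closure is the union of draft and the in-plane ROI shell", {
  # solid-cylinder ROI with empty draft -> a 2-voxel ring on every slice
  tube <- make_tube_parts(n_ax = 8, n_in = 30, r_in = 10, wall = 3)
  roi_arr <- tube$lumen | tube$wall
  roi <- binary_mask(roi_arr, 0.01, "roi")
  empty_draft <- binary_mask(array(FALSE, dim(roi_arr)), 0.01, "wall_draft")
  cb <- build_closed_boundary(empty_draft, roi)
  for (i in c(1, 4, 8)) {
    sl <- roi_arr[i, , ]
    er <- sl
    dist <- aortamorph:::sqdist_to(!sl)
    expect_identical(cb$data[i, , ], sl & dist <= 4 + 1e-7)
  }
  # random draft -> exact set-algebra oracle (shell from in-plane erosion)
  set.seed(42)
  draft <- binary_mask(roi_arr & array(runif(length(roi_arr)) < 0.2,
                                       dim(roi_arr)), 0.01, "wall_draft")
  cb2 <- build_closed_boundary(draft, roi)
  shell_oracle <- array(FALSE, dim(roi_arr))
  for (i in seq_len(dim(roi_arr)[1])) {
    sl <- roi_arr[i, , ]
    er <- o_erode(array(sl, c(dim(sl), 1)), 2)[, , 1]
    shell_oracle[i, , ] <- sl & !er
  }
  expect_identical(cb2$data, draft$data | shell_oracle)
  # a draft already forming a tube stays a superset of tube and shell
  full_draft <- binary_mask(tube$wall, 0.01, "wall_draft")
  cb3 <- build_closed_boundary(full_draft, roi)
  expect_true(all(cb3$data[tube$wall]))
  expect_true(all(cb3$data[shell_oracle]))
})

test_that("a ROI thinner than the shell erosion is a degenerate-ROI error", {
  d <- c(4, 20, 20)
  roi_arr <- array(FALSE, d)
  roi_arr[, 9:11, 5:15] <- TRUE  # 3 voxels wide: in-plane erosion by 2 empties it
  roi <- binary_mask(roi_arr, 0.01, "roi")
  draft <- binary_mask(array(FALSE, d), 0.01, "wall_draft")
  expect_error(build_closed_boundary(draft, roi),
               class = "am_degenerate_roi_error")
})

test_that("lumen draft extraction keeps the largest interior cavity", {
  tube <- make_tube_parts(n_ax = 10, n_in = 34, r_in = 10, wall = 3)
  roi_arr <- aortamorph:::ball_dilate(tube$lumen | tube$wall, 1)
  roi <- binary_mask(roi_arr, 0.01, "roi")
  boundary <- binary_mask((tube$wall | roi_arr) & !tube$lumen, 0.01,
                          "wall_draft")
  ld <- extract_lumen_draft(boundary, roi)
  # flood-fill oracle from the axis
  ref <- o_largest_component(roi_arr & !boundary$data, 6)
  expect_identical(ld$data, ref)
  expect_equal(sum(ld$data), sum(tube$lumen))
  # boundary filling the whole ROI -> empty-lumen error
  full <- binary_mask(roi_arr, 0.01, "wall_draft")
  expect_error(extract_lumen_draft(full, roi), class = "am_empty_lumen_error")
  # two cavities: the larger one wins
  d <- c(6, 24, 24)
  roi2 <- binary_mask(array(TRUE, d), 0.01, "roi")
  bnd <- array(TRUE, d)
  bnd[2:5, 3:12, 3:12] <- FALSE    # 4*10*10 = 400 voxel cavity
  bnd[2:3, 16:20, 16:17] <- FALSE  # 2*5*2  =  20 voxel cavity
  ld2 <- extract_lumen_draft(binary_mask(bnd, 0.01, "wall_draft"), roi2)
  expect_equal(sum(ld2$data), 400)
  expect_true(all(ld2$data[2:5, 3:12, 3:12]))
})

test_that("void filling absorbs an interior plaque void and never shrinks a convex draft", {
  tube <- make_tube_parts(n_ax = 16, n_in = 30, r_in = 9, wall = 3)
  solid <- tube$lumen
  g <- expand.grid(i = 1:16, j = 1:30, k = 1:30)
  void <- array((g$i - 8)^2 + (g$j - 15.5)^2 + (g$k - 15.5)^2 <= 3^2,
                dim(solid))
  draft <- binary_mask(solid & !void, 0.01, "lumen_draft")
  filled <- fill_lumen_voids(draft, seg_params())
  expect_equal(sum(filled$data), sum(solid))
  expect_true(all(filled$data[solid]))
  # already-convex mask: non-decreasing, no change beyond the boundary
  conv <- binary_mask(solid, 0.01, "lumen_draft")
  out <- fill_lumen_voids(conv, seg_params())
  expect_true(all(out$data[solid]))
  # empty draft passes through empty
  e <- binary_mask(array(FALSE, dim(solid)), 0.01, "lumen_draft")
  expect_equal(sum(fill_lumen_voids(e, seg_params())$data), 0)
})

test_that("wall/lumen composition is exact set algebra with overlap assigned to lumen", {
  tube <- make_tube_parts(n_ax = 6, n_in = 26, r_in = 8, wall = 3)
  wd <- binary_mask(tube$wall, 0.01, "wall_draft")
  lum <- binary_mask(tube$lumen, 0.01, "lumen")
  res <- compose_wall_lumen(wd, lum)
  expect_identical(res$wall_mask$data, tube$wall)
  expect_identical(res$lumen_mask$data, tube$lumen)
  expect_identical(res$aorta_mask$data, tube$wall | tube$lumen)
  # overlapping draft (stained plaque): overlap goes to the lumen
  wd2_arr <- tube$wall
  wd2_arr[3, 14:16, 14:16] <- TRUE  # inside the lumen
  res2 <- compose_wall_lumen(binary_mask(wd2_arr, 0.01, "wall_draft"), lum)
  expect_false(any(res2$wall_mask$data & res2$lumen_mask$data))
  expect_true(all(res2$lumen_mask$data[3, 14:16, 14:16]))
  expect_false(any(res2$wall_mask$data[3, 14:16, 14:16]))
  # random pair equals brute-force set algebra
  set.seed(43)
  d <- c(10, 10, 10)
  a <- array(runif(prod(d)) < 0.4, d)
  b <- array(runif(prod(d)) < 0.4, d)
  r3 <- compose_wall_lumen(binary_mask(a, 0.01, "wall_draft"),
                           binary_mask(b, 0.01, "lumen"))
  expect_identical(r3$aorta_mask$data, a | b)
  expect_identical(r3$wall_mask$data, (a | b) & !b)
})

test_that("full wall/lumen segmentation recovers a clean tube phantom", {
  spec <- small_phantom_spec()
  ph <- fixture("small_clean_phantom", generate_phantom(spec))
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi)
  analytic <- pi * (0.20)^2 * 64 * 0.01
  expect_lt(abs(mask_volume(wl$lumen_mask) / analytic - 1), 0.05)
  # set-algebra invariants hold exactly
  expect_false(any(wl$wall_mask$data & wl$lumen_mask$data))
  expect_identical(wl$aorta_mask$data,
                   wl$wall_mask$data | wl$lumen_mask$data)
  expect_true(all(wl$aorta_mask$data[!roi$data] == FALSE))
})

test_that("a branch gap still yields a closed lumen inside the eroded ROI", {
  spec <- small_phantom_spec(branch_gaps = list(list(
    axial_position = 0.32, angular_span = 60, angle = 90)))
  ph <- generate_phantom(spec)
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl <- segment_wall_lumen(ph$volume, roi)
  contained <- aortamorph:::disc_erode_slicewise(roi$data, 1)
  expect_true(all(contained[wl$lumen_mask$data]))
  expect_gt(sum(wl$lumen_mask$data), 0.8 * sum(ph$ground_truth$lumen$data))
})

test_that("manual lumen edits add and remove exactly the requested voxels", {
  spec <- small_phantom_spec()
  ph <- fixture("small_clean_phantom", generate_phantom(spec))
  roi <- interpolate_roi(phantom_contours(spec), spec$shape, spec$voxel_size)
  wl0 <- segment_wall_lumen(ph$volume, roi)
  patch <- array(FALSE, spec$shape)
  inside <- which(wl0$lumen_mask$data)[1:10]
  patch[inside] <- TRUE
  wl1 <- segment_wall_lumen(ph$volume, roi,
                            manual_lumen_edits = list(remove = patch))
  expect_identical(wl1$lumen_mask$data, wl0$lumen_mask$data & !patch)
  wl2 <- segment_wall_lumen(ph$volume, roi,
                            manual_lumen_edits = list(add = patch))
  expect_identical(wl2$lumen_mask$data, wl0$lumen_mask$data | patch)
})
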