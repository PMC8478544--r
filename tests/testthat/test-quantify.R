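test_that("mask volume is exact voxel counting", {
  m <- binary_mask(array(TRUE, c(10, 10, 10)), 0.01, "lumen")
  expect_equal(mask_volume(m), 0.001)  # 1000 voxels at 10 um
  e <- binary_mask(array(FALSE, c(4, 4, 4)), 0.01, "lumen")
  expect_equal(mask_volume(e), 0)
  set.seed(61)
  r <- array(runif(12^3) < 0.4, c(12, 12, 12))
  rm <- binary_mask(r, 0.02, "plaque")
  count <- 0L
  for (i in seq_along(r)) if (r[i]) count <- count + 1L
  expect_equal(mask_volume(rm), count * 0.02^3)
})

test_that("triangulated sphere surface is within 3% and converges with radius", {
  errs <- vapply(c(10, 20, 40), function(r) {
    m <- binary_mask(make_ball(r), 1, "lumen")
    abs(mask_surface(m) / (4 * pi * r^2) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.03)
  expect_lt(errs[3], errs[1])  # error decreasing from r=10 to r=40
})

test_that("cube surface is within 10% and a single voxel has positive area", {
  cube <- array(FALSE, c(28, 28, 28))
  cube[5:24, 5:24, 5:24] <- TRUE
  m <- binary_mask(cube, 1, "lumen")
  expect_lt(abs(mask_surface(m) / (6 * 20^2) - 1), 0.10)
  sv <- array(FALSE, c(3, 3, 3))
  sv[2, 2, 2] <- TRUE
  a <- mask_surface(binary_mask(sv, 1, "lumen"))
  expect_true(is.finite(a) && a > 0)
  expect_error(mask_surface(binary_mask(array(FALSE, c(3, 3, 3)), 1, "lumen")),
               class = "am_value_error")
})

test_that("lesion surface is half the triangulated surface, zero when empty", {
  e <- binary_mask(array(FALSE, c(4, 4, 4)), 0.01, "lesion")
  expect_equal(lesion_surface(e), 0)
  # one-voxel-thick disc of radius 10
  g <- expand.grid(j = 1:25, k = 1:25)
  disc <- matrix((g$j - 13)^2 + (g$k - 13)^2 <= 10^2, 25, 25)
  sheet <- array(FALSE, c(5, 25, 25))
  sheet[3, , ] <- disc
  m <- binary_mask(sheet, 1, "lesion")
  expect_equal(lesion_surface(m), 0.5 * mask_surface(m))
  expect_lt(abs(lesion_surface(m) / (pi * 10^2) - 1), 0.15)
})

test_that("wall thickness recovers slabs, tubes, and sheets within one voxel", {
  slab <- array(FALSE, c(20, 20, 12))
  slab[, , 4:8] <- TRUE  # 5 voxels thick at 10 um
  wt <- wall_thickness(binary_mask(slab, 0.01, "wall"))
  expect_lt(abs(wt$mean - 0.05), 0.01)
  expect_length(wt$distribution, sum(slab))
  tube <- make_tube_parts(n_ax = 20, n_in = 34, r_in = 10, wall = 3)
  wt2 <- wall_thickness(binary_mask(tube$wall, 0.01, "wall"))
  expect_lt(abs(wt2$mean - 0.03), 0.01)
  sheet <- array(FALSE, c(10, 10, 5))
  sheet[, , 3] <- TRUE
  wt3 <- wall_thickness(binary_mask(sheet, 0.01, "wall"))
  expect_equal(wt3$mean, 0.01)  # one-voxel sheet -> one voxel diameter
  expect_error(wall_thickness(binary_mask(array(FALSE, c(3, 3, 3)), 0.01,
                                          "wall")),
               class = "am_value_error")
})

fake_wall_lumen <- function(wall, lumen, vs = 0.01) {
  compose_wall_lumen(binary_mask(wall, vs, "wall_draft"),
                     binary_mask(lumen, vs, "lumen"))
}

fake_plaque_result <- function(plaque, wall, vs = 0.01) {
  pm <- binary_mask(plaque, vs, "plaque")
  structure(list(plaque_mask = pm,
                 lesion_mask = detect_lesions(pm, binary_mask(wall, vs, "wall")),
                 intermediate = list()),
            class = "plaque_result")
}

test_that("volume fractions follow the ratio definitions", {
  tube <- make_tube_parts(n_ax = 10, n_in = 30, r_in = 9, wall = 3)
  # plaque occupying a known tenth of the lumen voxel count
  n_pl <- round(sum(tube$lumen) * 0.1)
  plaque <- array(FALSE, dim(tube$lumen))
  plaque[which(tube$lumen)[seq_len(n_pl)]] <- TRUE
  wl <- fake_wall_lumen(tube$wall, tube$lumen)
  pr <- fake_plaque_result(plaque, wl$wall_mask$data)
  vf <- volume_fractions(wl, pr)
  expect_equal(vf$plaque_volume_fraction,
               100 * n_pl / sum(tube$lumen))
  expect_equal(vf$lesion_surface_fraction,
               100 * lesion_surface(pr$lesion_mask) / mask_surface(wl$lumen_mask))
  # empty plaque -> both fractions zero
  pr0 <- fake_plaque_result(array(FALSE, dim(tube$lumen)), tube$wall)
  vf0 <- volume_fractions(wl, pr0)
  expect_equal(vf0$plaque_volume_fraction, 0)
  expect_equal(vf0$lesion_surface_fraction, 0)
  # empty lumen -> error
  wl_empty <- fake_wall_lumen(tube$wall, array(FALSE, dim(tube$lumen)))
  expect_error(volume_fractions(wl_empty, pr0), class = "am_value_error")
})

test_that("per-slice metrics: clean disc, full occlusion, and area consistency", {
  tube <- make_tube_parts(n_ax = 8, n_in = 52, r_in = 20, wall = 3)
  wl <- fake_wall_lumen(tube$wall, tube$lumen)
  pr0 <- fake_plaque_result(array(FALSE, dim(tube$lumen)), tube$wall)
  ps <- per_slice_metrics(wl, pr0)
  expect_equal(nrow(ps), 8)
  expect_true(all(ps$stenosis == 0))
  expect_true(all(abs(ps$lumen_perimeter / (2 * pi * 20 * 0.01) - 1) < 0.05))
  # fully occluded slices -> stenosis 100%
  pr_full <- fake_plaque_result(tube$lumen, tube$wall)
  ps_full <- per_slice_metrics(wl, pr_full)
  expect_true(all(ps_full$stenosis == 100))
  # per-slice plaque areas integrate exactly to the plaque volume
  set.seed(62)
  plaque <- tube$lumen & array(runif(length(tube$lumen)) < 0.3,
                               dim(tube$lumen))
  pr_r <- structure(list(plaque_mask = binary_mask(plaque, 0.01, "plaque"),
                         lesion_mask = binary_mask(array(FALSE, dim(plaque)),
                                                   0.01, "lesion"),
                         intermediate = list()), class = "plaque_result")
  ps_r <- per_slice_metrics(wl, pr_r)
  expect_equal(sum(ps_r$plaque_area) * 0.01, mask_volume(pr_r$plaque_mask))
  # slices without lumen are skipped
  lum2 <- tube$lumen
  lum2[3, , ] <- FALSE
  wl2 <- fake_wall_lumen(tube$wall, lum2)
  ps2 <- per_slice_metrics(wl2, pr0)
  expect_false(2L %in% ps2$slice)   # 0-based index of the emptied slice
  expect_equal(nrow(ps2), 7)
})

test_that("half-annulus plaque contacts about half the lumen circumference", {
  tube <- make_tube_parts(n_ax = 8, n_in = 52, r_in = 20, wall = 3)
  ring <- tube$lumen & !aortamorph:::ball_erode(tube$lumen, 2.5)
  half <- array(FALSE, dim(ring))
  half[, 27:52, ] <- TRUE
  plaque <- ring & half
  wl <- fake_wall_lumen(tube$wall, tube$lumen)
  pr <- fake_plaque_result(plaque, wl$wall_mask$data)
  ps <- per_slice_metrics(wl, pr)
  expect_true(all(abs(ps$lesion_length_fraction - 50) < 10))
})

test_that("aorta volume equals wall plus lumen volume exactly", {
  tube <- make_tube_parts(n_ax = 6, n_in = 30, r_in = 9, wall = 3)
  wl <- fake_wall_lumen(tube$wall, tube$lumen)
  expect_equal(mask_volume(wl$aorta_mask),
               mask_volume(wl$wall_mask) + mask_volume(wl$lumen_mask))
})

test_that("quant reports round-trip to CSV", {
  td <- withr::local_tempdir()
  tube <- make_tube_parts(n_ax = 6, n_in = 30, r_in = 9, wall = 3)
  wl <- fake_wall_lumen(tube$wall, tube$lumen)
  pr <- fake_plaque_result(array(FALSE, dim(tube$lumen)), tube$wall)
  rep <- quantify_specimen(wl, pr)
  p <- file.path(td, "report.csv")
  write_report(rep, p, id = "toy")
  df <- read.csv(p)
  expect_equal(df$lumen_volume, rep$lumen_volume)
  expect_equal(df$id, "toy")
  ps <- read.csv(file.path(td, "report_per_slice.csv"))
  expect_equal(nrow(ps), nrow(rep$per_slice))
})
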