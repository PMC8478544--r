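# Geometric fixtures built in code, plus a cache so expensive phantoms are
# generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

make_ball <- function(r, pad = 3, center = NULL) {
  n <- 2 * (r + pad) + 1
  if (is.null(center)) center <- rep(r + pad + 1, 3)
  g <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  array((g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2 <= r^2,
        c(n, n, n))
}

# digital hollow tube along axis 1 inside a larger grid; returns the parts
make_tube_parts <- function(n_ax = 20, n_in = 40, r_in = 10, wall = 3,
                            center = NULL) {
  if (is.null(center)) center <- rep((n_in + 1) / 2, 2)
  g <- expand.grid(j = seq_len(n_in), k = seq_len(n_in))
  rho2 <- (g$j - center[1])^2 + (g$k - center[2])^2
  lum_sl <- matrix(rho2 < r_in^2, n_in, n_in)
  wall_sl <- matrix(rho2 >= r_in^2 & rho2 < (r_in + wall)^2, n_in, n_in)
  lum <- array(rep(lum_sl, n_ax), c(n_in, n_in, n_ax))
  wal <- array(rep(wall_sl, n_ax), c(n_in, n_in, n_ax))
  # put axial axis first
  lum <- aperm(lum, c(3, 1, 2))
  wal <- aperm(wal, c(3, 1, 2))
  list(lumen = lum, wall = wal, r_in = r_in, wall_thickness = wall)
}

# small straight-tube phantom spec used by the unit tests (64 axial slices,
# lumen radius 20 voxels, wall 6 voxels at 10 um)
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(64, 64, 64), voxel_size = 0.01,
               lumen_radius = 0.20, wall_thickness = 0.06, ...)
}

small_plaque <- function(depth = 0.12, att = 3.5, ...) {
  list(angle = 0, axial_range = c(0.16, 0.47), depth = depth,
       attenuation = att, ...)
}

clean_suite_run <- function() {
  fixture("clean_suite_run", {
    ph <- phantom_suite("clean")[[1]]
    c(ph, list(result = run_phantom_pipeline(
      list(volume = ph$volume, ground_truth = ph$ground_truth), ph$spec)))
  })
}

# axially tapered plaque so per-slice stenosis spans a wide range, the
# situation the per-slice manual-comparison design needs
taper_run <- function() {
  fixture("taper_run", {
    spec <- phantom_spec(shape = c(96, 96, 96), voxel_size = 0.01,
                         lumen_radius = 0.20, wall_thickness = 0.06,
                         plaques = list(list(angle = 0,
                                             axial_range = c(0.05, 0.90),
                                             depth = 0.1,
                                             depth_taper = c(0.02, 0.17),
                                             attenuation = 3.5)),
                         seed = 83L)
    ph <- generate_phantom(spec)
    c(ph, list(spec = spec, result = run_phantom_pipeline(ph, spec)))
  })
}

noisy_suite_run <- function() {
  fixture("noisy_suite_run", {
    ph <- phantom_suite("noisy")[[1]]
    c(ph, list(result = run_phantom_pipeline(
      list(volume = ph$volume, ground_truth = ph$ground_truth), ph$spec)))
  })
}
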