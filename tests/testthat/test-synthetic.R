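test_that("zero-amplitude motion is the identity and the map is cyclic", {
  mo <- synth_motion(centre = c(0, 0, 0), s_peak = 1, t_peak = 4, n_frames = 10)
  p <- matrix(rnorm(30), ncol = 3)
  for (t in c(0, 2.5, 4, 9)) expect_equal(apply_motion(mo, p, t), p)
  mo2 <- synth_motion(centre = c(1, 2, 3), s_peak = 1.1, t_peak = 4, n_frames = 10)
  expect_equal(apply_motion(mo2, p, 0), p)
  expect_equal(apply_motion(mo2, p, 10), apply_motion(mo2, p, 0))
  expect_equal(apply_motion(mo2, p, 12.3), apply_motion(mo2, p, 2.3))
})

test_that("peak-frame scaling is exact by construction", {
  cen <- c(5, -3, 2)
  mo <- synth_motion(centre = cen, s_peak = 1.1, t_peak = 4, n_frames = 10)
  p <- matrix(rnorm(60, sd = 20), ncol = 3)
  moved <- apply_motion(mo, p, 4)
  r0 <- sqrt(rowSums(sweep(p, 2, cen)^2))
  r1 <- sqrt(rowSums(sweep(moved, 2, cen)^2))
  expect_equal(r1, 1.1 * r0, tolerance = 1e-12)
})

test_that("motion parameter validation rejects bad inputs", {
  expect_error(synth_motion(s_peak = 0), "s_peak")
  expect_error(synth_motion(n_frames = 1), "n_frames")
  expect_error(synth_motion(t_peak = 0), "t_peak")
  expect_error(synth_motion(t_peak = 10, n_frames = 10), "t_peak")
})

test_that("ground-truth strain matches the closed form under uniform scaling", {
  sp <- fix_sphere(3, 20)
  body <- sp$mesh$element_labels == "body"
  e1 <- sp$mesh$vertices[sp$mesh$triangles[, 2], ] -
    sp$mesh$vertices[sp$mesh$triangles[, 1], ]
  fib <- e1 / sqrt(rowSums(e1^2))
  cen <- colMeans(sp$mesh$vertices)
  for (s in c(1.05, 1.1)) {
    mo <- synth_motion(centre = cen, s_peak = s, t_peak = 4, n_frames = 10)
    gt <- ground_truth_strain(mo, sp$mesh, fib, 4)
    expect_equal(gt$area_strain, rep(100 * (s^2 - 1), nrow(gt)),
                 tolerance = 1e-9)
    expect_equal(gt$fibre_strain, rep(100 * (s - 1), nrow(gt)),
                 tolerance = 1e-9)
    gt0 <- ground_truth_strain(mo, sp$mesh, fib, 0)
    expect_equal(max(abs(gt0$area_strain)), 0, tolerance = 1e-12)
  }
})

test_that("reservoir of a uniform-scaling ground-truth transient is closed form", {
  sp <- fix_sphere(2, 15)
  e1 <- sp$mesh$vertices[sp$mesh$triangles[, 2], ] -
    sp$mesh$vertices[sp$mesh$triangles[, 1], ]
  fib <- e1 / sqrt(rowSums(e1^2))
  mo <- synth_motion(centre = colMeans(sp$mesh$vertices), s_peak = 1.08,
                     t_peak = 4, n_frames = 10)
  regions <- rep("body_all", nrow(sp$mesh$triangles))
  st <- strain_transients(propagate_mesh(sp$mesh, mo), fib, regions)
  ga <- st$value[st$scope == "global" & st$metric == "area"]
  gf <- st$value[st$scope == "global" & st$metric == "fibre"]
  expect_equal(reservoir_strain(ga), 100 * (1.08^2 - 1), tolerance = 1e-9)
  expect_equal(reservoir_strain(gf), 100 * (1.08 - 1), tolerance = 1e-9)
})

test_that("rasterised sphere volume matches the closed form within 5%", {
  sp <- fix_sphere(3, 20)
  img <- rasterize_mesh(sp$mesh, c(64, 64, 64), 1, inside = 300, outside = 50,
                        blur_sigma = 0, noise_sd = 0)
  nin <- sum(img > (300 + 50) / 2)
  expect_lt(abs(nin - 4 / 3 * pi * 20^3) / (4 / 3 * pi * 20^3), 0.05)
})

test_that("rasterisation respects the seed contract", {
  sp <- fix_sphere(2, 12)
  base <- function(...) rasterize_mesh(sp$mesh, c(32, 32, 32), 1.2, ...)
  expect_identical(base(noise_sd = 0), base(noise_sd = 0))
  expect_identical(base(noise_sd = 5, seed = 3), base(noise_sd = 5, seed = 3))
  expect_false(identical(base(noise_sd = 5, seed = 3),
                         base(noise_sd = 5, seed = 4)))
})

test_that("rasterisation rejects a mesh without field-of-view margin", {
  sp <- fix_sphere(2, 30)
  expect_error(rasterize_mesh(sp$mesh, c(32, 32, 32), 1), "margin")
})

test_that("iso-level surface extraction recovers the sphere radius within a voxel", {
  sp <- fix_sphere(3, 20)
  img <- rasterize_mesh(sp$mesh, c(64, 64, 64), 1.5, inside = 300,
                        outside = 50, blur_sigma = 1, noise_sd = 0)
  pts <- isosurface_points(img, 175)
  r <- sqrt(rowSums(sweep(pts, 2, colMeans(sp$mesh$vertices))^2))
  expect_lt(max(abs(r - 20)), 1.5)
})

test_that("orifice overlap is rejected with a parameter error", {
  # shrink the anatomy so orifice cones overlap is triggered via radii? the
  # spec fixes orifice directions; overlapping is simulated by patching the
  # spec table through the internal helper
  spec <- lastrain:::orifice_spec()
  d <- spec$pv_1$dir
  expect_lt(acos(sum(d * spec$pv_2$dir)),
            (spec$pv_1$angle + spec$pv_2$angle) * pi / 180 * 3)
  # directions closer than the sum of angular radii must error
  local_spec <- spec
  local_spec$pv_2$dir <- spec$pv_1$dir
  testthat::with_mocked_bindings(
    orifice_spec = function() local_spec,
    expect_error(synth_anatomy("la", seed = 1), "overlap"),
    .package = "lastrain")
})
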