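test_that("displacement of a zero lattice is zero; outside points are flagged", {
  lv <- bspline_lattice(c(0, 0, 0), c(10, 10, 10), c(6, 6, 6), 4)
  mf <- motion_field(list(lv), 10)
  p <- matrix(runif(30, 5, 25), ncol = 3)
  u <- evaluate_displacement(mf, p, 3)
  expect_equal(max(abs(u)), 0)
  expect_warning(u2 <- evaluate_displacement(mf, rbind(c(1e4, 0, 0)), 3),
                 "outside")
  expect_true(attr(u2, "outside")[1])
  expect_equal(as.numeric(u2), c(0, 0, 0))
})

test_that("spatial partition of unity: constant coefficients give a constant field", {
  lv <- bspline_lattice(c(-50, -50, -50), c(25, 25, 25), c(8, 8, 8), 4)
  cf <- array(0, c(prod(lv$dims), 4, 3))
  cf[, 2, 1] <- 5
  lv$coef <- as.numeric(cf)
  mf <- motion_field(list(lv), 10)
  wt <- lastrain:::temporal_weights_cpp(3, 10, 4) -
    lastrain:::temporal_weights_cpp(0, 10, 4)
  p <- matrix(runif(60, -20, 20), ncol = 3)
  u <- evaluate_displacement(mf, p, 3)
  expect_equal(u[, 1], rep(5 * wt[2], nrow(p)), tolerance = 1e-12)
  expect_equal(max(abs(u[, 2:3])), 0)
})

test_that("temporal periodicity and the reference-frame constraint hold", {
  lv <- bspline_lattice(c(-50, -50, -50), c(20, 20, 20), c(9, 9, 9), 5)
  set.seed(11)
  lv$coef <- rnorm(length(lv$coef))
  mf <- motion_field(list(lv), 10)
  p <- matrix(runif(90, -30, 30), ncol = 3)
  expect_equal(max(abs(evaluate_displacement(mf, p, 0))), 0)
  expect_equal(evaluate_displacement(mf, p, 10),
               evaluate_displacement(mf, p, 0), tolerance = 1e-12)
  expect_equal(evaluate_displacement(mf, p, 13.7),
               evaluate_displacement(mf, p, 3.7), tolerance = 1e-12)
})

test_that("regularisers: zero lattice, constant field, and L1 homogeneity", {
  lv <- bspline_lattice(c(0, 0, 0), c(10, 10, 10), c(6, 6, 6), 4)
  mf <- motion_field(list(lv), 10)
  r0 <- regularisers(mf)
  expect_equal(r0$bending_energy, 0)
  expect_equal(r0$sparsity, 0)
  # spatially constant displacement: zero bending energy, positive sparsity
  cf <- array(0, c(prod(lv$dims), 4, 3))
  cf[, 2, 1] <- 2
  lv$coef <- as.numeric(cf)
  r1 <- regularisers(motion_field(list(lv), 10))
  expect_equal(r1$bending_energy, 0, tolerance = 1e-12)
  expect_gt(r1$sparsity, 0)
  # doubling coefficients doubles the L1 norm as eps -> 0
  lv2 <- lv
  lv2$coef <- 2 * lv$coef
  r2 <- regularisers(motion_field(list(lv2), 10), eps = 1e-9)
  r1b <- regularisers(motion_field(list(lv), 10), eps = 1e-9)
  expect_equal(r2$sparsity / r1b$sparsity, 2, tolerance = 1e-6)
})

test_that("nmi: self-similarity, symmetry, independence, degenerate images", {
  set.seed(5)
  A <- array(runif(64^3), c(64, 64, 64))
  B <- array(runif(64^3), c(64, 64, 64))
  expect_equal(nmi(A, A), 2)
  expect_equal(nmi(A, B), nmi(B, A))
  expect_lt(abs(nmi(A, B, bins = 32) - 1), 0.05)
  expect_equal(nmi(array(1, c(4, 4, 4)), array(runif(64), c(4, 4, 4))), 1)
})

test_that("objective gradient matches finite differences", {
  set.seed(3)
  dims <- c(10, 10, 10)
  blur <- function(x) {
    y <- lastrain:::gaussian_blur3_cpp(array(runif(prod(dims)) * 100, dims),
                                       as.integer(dims), 1)
    array(y, dims)
  }
  f0 <- blur(); f1 <- blur()
  lv <- bspline_lattice(c(-6, -6, -6), c(8, 8, 8), c(5, 5, 5), 3)
  set.seed(4)
  lv$coef <- rnorm(length(lv$coef), 0, 0.4)
  obj <- function(coef, grad = TRUE) {
    lvl <- lv; lvl$coef <- coef
    lastrain:::ffd_objective_cpp(list(lvl), as.numeric(f0), as.integer(dims),
                                 c(0, 0, 0), c(2, 2, 2), list(as.numeric(f1)),
                                 1, 4, 16L, 0.01, 0.001, 0.01,
                                 if (grad) 0L else -1L, 0)
  }
  g <- obj(lv$coef)$grad
  h <- 1e-5
  idx <- sample(length(lv$coef), 12)
  num <- vapply(idx, function(i) {
    cp <- lv$coef; cp[i] <- cp[i] + h
    cm <- lv$coef; cm[i] <- cm[i] - h
    (obj(cp, FALSE)$value - obj(cm, FALSE)$value) / (2 * h)
  }, numeric(1))
  expect_equal(g[idx], num, tolerance = 1e-2)
})

test_that("registering identical frames yields (near) zero motion", {
  sp <- fix_sphere(2, 12)
  img <- rasterize_mesh(sp$mesh, c(32, 32, 32), 1.5, blur_sigma = 1)
  ser <- image_series(list(img, img, img), 1.5, attr(img, "origin"))
  mf <- register_series(ser, registration_config(max_iter = 15))
  p <- as.matrix(expand.grid(x = seq(-12, 12, 6), y = seq(-12, 12, 6),
                             z = seq(-12, 12, 6)))
  u <- rbind(evaluate_displacement(mf, p, 1), evaluate_displacement(mf, p, 2))
  # a small drift (~0.2 of a voxel) remains from interpolation-induced
  # histogram sharpening; see the methods vignette
  expect_lt(mean(sqrt(rowSums(u^2))), 0.5)
})

test_that("a 2 mm translation is recovered within 0.5 mm on the blob surface", {
  fx <- fix_blob_series()
  mf <- register_series(fx$series, registration_config(max_iter = c(40, 30)))
  u <- evaluate_displacement(mf, fx$anatomy$mesh$vertices, 1)
  err <- sqrt(rowSums(sweep(u, 2, c(2, 0, 0))^2))
  expect_lt(mean(err), 0.5)
  # objective decreased
  lg <- attr(mf, "log")
  expect_lt(lg$value[nrow(lg)], lg$value[1])
})

test_that("registration is equivariant under global intensity rescaling", {
  fx <- fix_blob_series()
  cfg <- registration_config(max_iter = c(30, 20))
  mf1 <- register_series(fx$series, cfg)
  ser2 <- fx$series
  ser2$frames <- lapply(ser2$frames, function(f) {
    g <- 3 * f + 40
    attributes(g) <- attributes(f)
    g
  })
  mf2 <- register_series(ser2, cfg)
  p <- fx$anatomy$mesh$vertices
  u1 <- evaluate_displacement(mf1, p, 1)
  u2 <- evaluate_displacement(mf2, p, 1)
  expect_lt(mean(sqrt(rowSums((u1 - u2)^2))), 0.15)
})

test_that("increasing bending-energy weight monotonically shrinks the field", {
  fx <- fix_blob_series()
  mean_u <- vapply(c(1e-3, 1e-1, 10), function(be) {
    mf <- register_series(fx$series,
                          registration_config(be = be, max_iter = 15,
                                              level_factors = 1 / 4))
    p <- fx$anatomy$mesh$vertices
    mean(sqrt(rowSums(evaluate_displacement(mf, p, 1)^2)))
  }, numeric(1))
  expect_true(all(diff(mean_u) < 0))
})

test_that("2D mode (flat axis) reproduces the planar solution on the central slice", {
  fx <- fix_blob_series()
  # central slice of both frames as a 2D problem
  sl <- function(f) {
    k <- dim(f)[3] %/% 2 + 1
    array(f[, , k], c(dim(f)[1], dim(f)[2], 1))
  }
  f2d <- lapply(fx$series$frames, sl)
  ser2d <- image_series(f2d, c(1.5, 1.5, 1), c(0, 0, 0))
  cfg <- registration_config(max_iter = c(30, 20))
  mf2d <- register_series(ser2d, cfg)
  # 3D volume constant along z built from the same slice
  nz <- 12
  f3d <- lapply(fx$series$frames, function(f) {
    k <- dim(f)[3] %/% 2 + 1
    array(rep(f[, , k], nz), c(dim(f)[1], dim(f)[2], nz))
  })
  ser3d <- image_series(f3d, c(1.5, 1.5, 1.5), c(0, 0, 0))
  mf3d <- register_series(ser3d, cfg)
  g <- expand.grid(x = seq(15, 45, 5), y = seq(15, 45, 5))
  u2 <- evaluate_displacement(mf2d, cbind(g$x, g$y, 0), 1)
  u3 <- evaluate_displacement(mf3d, cbind(g$x, g$y, nz * 1.5 / 2), 1)
  expect_lt(mean(sqrt(rowSums((u2[, 1:2] - u3[, 1:2])^2))), 0.75)
})

test_that("motion-field least-squares fitting reproduces an analytic motion", {
  mo <- synth_motion(centre = c(0, 0, 0), s_peak = 1.08, t_peak = 4,
                     n_frames = 10)
  lower <- c(-45, -45, -45); upper <- c(45, 45, 45)
  lv <- lastrain:::level_covering(lower, upper, c(12, 12, 12), 4)
  mf <- fit_motion_field(mo, list(lv), lower, upper, 10, n_samples = 13)
  p <- matrix(runif(150, -35, 35), ncol = 3)
  for (t in c(2, 4, 7)) {
    truth <- apply_motion(mo, p, t) - p
    err <- sqrt(rowSums((evaluate_displacement(mf, p, t) - truth)^2))
    expect_lt(median(err), 0.15)
  }
})

test_that("configuration validation rejects invalid weights", {
  expect_error(registration_config(sw = -1), "SW")
  expect_error(registration_config(be = Inf), "SW|BE")
  expect_error(registration_config(bins = 4), "bins")
})
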