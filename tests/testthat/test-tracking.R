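test_that("mesh propagation preserves topology and handles trivial motions", {
  sp <- fix_sphere(2, 10)
  lv <- bspline_lattice(c(-40, -40, -40), c(20, 20, 20), c(6, 6, 6), 4)
  mf0 <- motion_field(list(lv), 6)
  meshes <- propagate_mesh(sp$mesh, mf0)
  for (m in meshes) {
    expect_identical(m$triangles, sp$mesh$triangles)
    expect_identical(m$element_labels, sp$mesh$element_labels)
    expect_equal(m$vertices, sp$mesh$vertices)
  }
  # uniform translation preserves areas
  mo <- synth_motion(centre = c(0, 0, 0), s_peak = 1.001, n_frames = 6, t_peak = 3)
  tr_meshes <- lapply(0:2, function(t) {
    m <- sp$mesh
    m$vertices <- sweep(m$vertices, 2, c(3, -1, 2) * t, `+`)
    m
  })
  for (m in tr_meshes)
    expect_equal(triangle_areas(m), triangle_areas(sp$mesh), tolerance = 1e-12)
})

test_that("dice coefficient equals the voxel-count oracle on random masks", {
  set.seed(21)
  for (i in 1:50) {
    a <- array(runif(1000) > 0.6, c(10, 10, 10))
    b <- array(runif(1000) > 0.4, c(10, 10, 10))
    if (sum(a) == 0 || sum(b) == 0) next
    oracle <- 2 * sum(a & b) / (sum(a) + sum(b))
    expect_identical(dice_coefficient(a, b), oracle)
    expect_identical(dice_coefficient(a, b), dice_coefficient(b, a))
  }
  expect_error(dice_coefficient(array(0, c(2, 2, 2)), array(1, c(2, 2, 2))),
               "empty")
})

test_that("half-overlapping cubes have Dice exactly 0.5", {
  a <- array(0L, c(8, 8, 8)); a[1:4, 1:4, 1:4] <- 1L
  b <- array(0L, c(8, 8, 8)); b[1:4, 1:4, 3:6] <- 1L
  expect_equal(dice_coefficient(a, b), 0.5)
})

test_that("surface distances: identical meshes and translated flat sheets", {
  sh <- flat_sheet(10, 6)
  expect_equal(surface_distances(sh, sh), list(asd = 0, dhd = 0))
  for (d in c(0.5, 2)) {
    sh2 <- sh
    sh2$vertices[, 3] <- d
    sd <- surface_distances(sh2, sh)
    expect_equal(sd$asd, d, tolerance = 1e-12)
    expect_equal(sd$dhd, d, tolerance = 1e-12)
  }
})

test_that("point-to-mesh distance agrees with an independent oracle", {
  set.seed(31)
  ico <- lastrain:::icosphere(0)
  for (rep in 1:10) {
    mesh <- surface_mesh(ico$vertices * runif(1, 5, 15) +
                           matrix(rnorm(3), nrow(ico$vertices), 3,
                                  byrow = TRUE),
                         ico$triangles)
    P <- matrix(rnorm(30, sd = 10), ncol = 3)
    d_cpp <- lastrain:::point_mesh_distance_cpp(P, mesh$vertices,
                                                mesh$triangles - 1L)
    d_r <- point_mesh_distance_oracle(P, mesh)
    expect_equal(d_cpp, d_r, tolerance = 1e-9)
  }
})

test_that("ASD is symmetric, directed Hausdorff generally is not", {
  sh <- flat_sheet(10, 6)
  # deform one corner of the second sheet only
  sh2 <- sh
  sh2$vertices[1, 3] <- 4
  ab <- surface_distances(sh, sh2)
  ba <- surface_distances(sh2, sh)
  expect_equal(ab$asd, ba$asd, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ab$dhd, ba$dhd)))
})

test_that("warped segmentation tracks a translation", {
  fx <- fix_blob_series()
  seg <- rasterize_mesh(fx$anatomy$mesh, c(40, 40, 40), 1.5,
                        origin = attr(fx$series$frames[[1]], "origin"),
                        inside = 1, outside = 0, blur_sigma = 0)
  seg <- array((seg >= 0.5) * 1L, c(40, 40, 40))
  attr(seg, "spacing") <- rep(1.5, 3); attr(seg, "origin") <- attr(fx$series$frames[[1]], "origin")
  mf <- register_series(fx$series, registration_config(max_iter = c(30, 20)))
  m2 <- fx$anatomy$mesh
  m2$vertices <- sweep(m2$vertices, 2, c(2, 0, 0), `+`)
  truth <- rasterize_mesh(m2, c(40, 40, 40), 1.5, origin = attr(seg, "origin"),
                          inside = 1, outside = 0, blur_sigma = 0)
  truth <- array((truth >= 0.5) * 1L, c(40, 40, 40))
  tracked <- warp_segmentation(seg, mf, 1)
  acc <- accuracy_metrics(propagate_mesh(fx$anatomy$mesh, mf)[[2]], m2,
                          tracked, truth, case = "blob", frame = 1L)
  expect_gt(acc$dsc, 0.95)
  expect_lt(acc$asd, 0.5)
  expect_lt(acc$dhd, 1.5)
})

test_that("fold assignment partitions cases with balanced sizes", {
  f <- make_folds(30, 5, seed = 2)
  expect_length(f, 30)
  expect_true(all(table(f) == 6))
  # stratified: both labels appear in every fold
  lab <- rep(c("a", "b"), each = 15)
  fs <- make_folds(lab, 5, seed = 2)
  expect_true(all(table(fs, lab) == 3))
})

test_that("grid search evaluates the full 63-point grid and respects dominance", {
  sw_values <- c(0, 10^seq(-4, 3, length.out = 8))  # 9 values
  be_values <- 10^seq(-3, 3, length.out = 7)        # 7 values
  set.seed(13)
  cases <- paste0("case", 1:10)
  grid <- expand.grid(case = cases, sw = sw_values, be = be_values,
                      stringsAsFactors = FALSE)
  # combination (sw_values[3], be_values[4]) strictly dominates
  best <- grid$sw == sw_values[3] & grid$be == be_values[4]
  grid$dsc <- runif(nrow(grid), 0.7, 0.9); grid$dsc[best] <- 0.99
  grid$asd <- runif(nrow(grid), 0.5, 2); grid$asd[best] <- 0.01
  grid$dhd <- runif(nrow(grid), 2, 6); grid$dhd[best] <- 0.1
  res <- hyperparameter_search(grid, k_folds = 5, seed = 1)
  expect_identical(res$n_combinations, 63L)
  expect_equal(nrow(res$grid), 63L)
  expect_true(all(res$per_fold$sw == sw_values[3]))
  expect_true(all(res$per_fold$be == be_values[4]))
  expect_equal(res$optimum$sw, sw_values[3])
  # each case in exactly one test fold
  expect_true(all(table(res$folds$fold) == 2))
  expect_identical(sort(res$folds$case), sort(cases))
})

test_that("grid search is invariant to row and grid-value ordering", {
  set.seed(14)
  grid <- expand.grid(case = paste0("c", 1:8), sw = c(0, 0.1, 1),
                      be = c(0.01, 0.1), stringsAsFactors = FALSE)
  grid$dsc <- runif(nrow(grid), 0.6, 0.95)
  grid$asd <- runif(nrow(grid), 0.3, 2)
  grid$dhd <- runif(nrow(grid), 1, 5)
  r1 <- hyperparameter_search(grid, k_folds = 4, seed = 3)
  r2 <- hyperparameter_search(grid[sample(nrow(grid)), ], k_folds = 4, seed = 3)
  expect_equal(r1$optimum, r2$optimum)
  expect_equal(r1$grid, r2$grid)
})

test_that("self-consistent verification reports zero error", {
  sp <- fix_sphere(2, 12)
  img <- rasterize_mesh(sp$mesh, c(32, 32, 32), 1.5, blur_sigma = 1)
  lv <- lastrain:::level_covering(attr(img, "origin"),
                                  attr(img, "origin") + 31 * 1.5,
                                  rep(12, 3), 4)
  mo <- synth_motion(centre = colMeans(sp$mesh$vertices), s_peak = 1.05,
                     t_peak = 2, n_frames = 5)
  mf <- fit_motion_field(mo, list(lv), attr(img, "origin"),
                         attr(img, "origin") + 31 * 1.5, 5, n_samples = 9)
  e1 <- sp$mesh$vertices[sp$mesh$triangles[, 2], ] -
    sp$mesh$vertices[sp$mesh$triangles[, 1], ]
  fib <- e1 / sqrt(rowSums(e1^2))
  res <- verify_synthetic(img, sp$mesh, mf,
                          registration_config(max_iter = 5), fib,
                          rep("all", nrow(sp$mesh$triangles)),
                          reregister = FALSE)
  expect_equal(max(res$rmse$median_mm), 0)
  expect_equal(max(res$strain_error$abs_error), 0)
})
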