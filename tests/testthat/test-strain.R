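tri0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))

test_that("element strains: identity, uniform scale, anisotropic closed form", {
  s <- element_strains(tri0, tri0, c(1, 0, 0))
  expect_equal(as.numeric(s), c(0, 0), tolerance = 1e-12)
  # uniform in-plane scale 1.1: area +21%, fibre +10% for any fibre direction
  for (ang in c(0, 0.3, 1.2)) {
    f <- c(cos(ang), sin(ang), 0)
    s <- element_strains(tri0, 1.1 * tri0, f)
    expect_equal(as.numeric(s), c(21, 10), tolerance = 1e-9)
  }
  # F = diag(1.2, 0.9), fibre at 45 degrees: 100 (sqrt((1.44+0.81)/2) - 1)
  def <- tri0 %*% diag(c(1.2, 0.9, 1))
  f45 <- c(1, 1, 0) / sqrt(2)
  s <- element_strains(tri0, def, f45)
  expect_equal(as.numeric(s["fibre_strain"]), 100 * (sqrt(1.125) - 1),
               tolerance = 1e-9)
  expect_equal(as.numeric(s["area_strain"]), 100 * (1.2 * 0.9 - 1),
               tolerance = 1e-9)
})

test_that("fibre aligned with a principal stretch reports that stretch", {
  for (lam in c(0.8, 1.05, 1.3)) {
    def <- tri0 %*% diag(c(lam, 1.1, 1))
    s <- element_strains(tri0, def, c(1, 0, 0))
    expect_equal(as.numeric(s["fibre_strain"]), 100 * (lam - 1),
                 tolerance = 1e-9)
  }
})

test_that("strains are objective: rigid motion gives exactly zero", {
  sp <- fix_sphere(2, 10)
  R <- random_rotation(3)
  meshes <- list(sp$mesh, sp$mesh, sp$mesh)
  meshes[[2]]$vertices <- sp$mesh$vertices %*% t(R)
  meshes[[3]]$vertices <- sweep(sp$mesh$vertices %*% t(R), 2, c(5, -2, 1), `+`)
  e1 <- sp$mesh$vertices[sp$mesh$triangles[, 2], ] -
    sp$mesh$vertices[sp$mesh$triangles[, 1], ]
  fib <- e1 / sqrt(rowSums(e1^2))
  st <- strain_transients(meshes, fib, rep("all", nrow(sp$mesh$triangles)))
  expect_lt(max(abs(st$value)), 1e-9)
})

test_that("degenerate reference triangles are rejected", {
  bad <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(element_strains(bad, bad, c(1, 0, 0)), "degenerate")
})

test_that("spatially uniform motion makes every regional transient global", {
  la <- fix_la()
  uacr <- fix_la_uac()
  fib <- map_fibres(la$mesh, uacr$uac)
  mo <- synth_motion(centre = colMeans(la$mesh$vertices), s_peak = 1.06,
                     t_peak = 2, n_frames = 5)
  st <- strain_transients(propagate_mesh(la$mesh, mo), fib, uacr$regions)
  for (m in c("area", "fibre"))
    for (f in 0:4) {
      v <- st$value[st$metric == m & st$frame == f]
      expect_lt(diff(range(v)), 1e-9)
    }
})

test_that("reservoir strain is max minus min", {
  expect_equal(reservoir_strain(c(0, 5, 12, 8, 3)), 12)
  expect_equal(reservoir_strain(0:9), 9)
  expect_equal(reservoir_strain(c(-4, 2, 10, 1)), 14)
  expect_error(reservoir_strain(3), "2 frames")
})

test_that("regional markers: normalisation formula and peak-frame range", {
  mk_transients <- function(peaks, global_peak = 4) {
    scopes <- c("global", paste0("r", seq_along(peaks)))
    pk <- c(global_peak, peaks)
    dplyr::bind_rows(lapply(seq_along(scopes), function(i) {
      v <- sin(pi * (0:9) / 9) * 10
      v <- v * 0 ; v[pk[i] + 1] <- 10 + i  # single peak at the named frame
      tibble::tibble(frame = 0:9, metric = "area", scope = scopes[i],
                     value = v)
    }))
  }
  tr <- mk_transients(c(2, 4, 7, 3, 5))
  mk <- regional_markers(tr)
  expect_equal(mk$delta_t$delta_t, 5)
  # explicit normalisation: regional 30, global 20 -> +0.5
  tr2 <- dplyr::bind_rows(
    tibble::tibble(frame = 0:3, metric = "area", scope = "global",
                   value = c(0, 10, 20, 5)),
    tibble::tibble(frame = 0:3, metric = "area", scope = "r1",
                   value = c(0, 15, 30, 5)))
  mk2 <- regional_markers(tr2)
  expect_equal(mk2$normalised$normalised, 0.5)
  # zero global reservoir is an error
  tr3 <- dplyr::bind_rows(
    tibble::tibble(frame = 0:3, metric = "area", scope = "global", value = 0),
    tibble::tibble(frame = 0:3, metric = "area", scope = "r1", value = 0))
  expect_error(regional_markers(tr3), "zero")
})

test_that("volume metrics: unit cube, emptying fraction, constant volume", {
  cm <- cube_mesh(1)
  vm <- volume_metrics(list(cm, cm))
  expect_equal(vm$edv_ml, 0.001, tolerance = 1e-12)
  expect_equal(vm$laef_pct, 0)
  # V_max 100 ml, V_min 68 ml -> LAEF 32%
  big <- cube_mesh(100^(1 / 3) * 10)  # 100 ml
  small <- cube_mesh(68^(1 / 3) * 10)
  vm2 <- volume_metrics(list(big, small))
  expect_equal(vm2$laef_pct, 32, tolerance = 1e-9)
})

test_that("a strain report carries all markers and tidies to a tibble", {
  la <- fix_la()
  uacr <- fix_la_uac()
  fib <- map_fibres(la$mesh, uacr$uac)
  mo <- synth_motion(centre = colMeans(la$mesh$vertices), s_peak = 1.05,
                     t_peak = 2, n_frames = 5)
  meshes <- propagate_mesh(la$mesh, mo)
  rep <- strain_report(strain_transients(meshes, fib, uacr$regions), meshes)
  td <- tidy(rep)
  expect_setequal(unique(td$scope),
                  c("global", "posterior", "septum", "lateral", "anterior",
                    "inferior"))
  gl <- glance(rep)
  expect_true(all(c("reservoir_area", "reservoir_fibre", "delta_t_area",
                    "delta_t_fibre", "edv_ml", "laef_pct") %in% names(gl)))
  expect_equal(gl$reservoir_area, 100 * (1.05^2 - 1), tolerance = 1e-9)
})
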