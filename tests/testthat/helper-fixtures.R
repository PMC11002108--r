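# Shared fixtures, built in code and memoised per test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

fix_sphere <- function(sub = 2, r = 10)
  memo(paste0("sphere", sub, "_", r),
       synth_anatomy("sphere", radii = r, subdivisions = sub, seed = 1))

fix_la <- function() memo("la_default", synth_anatomy("la", seed = 1))

fix_la_uac <- function() {
  la <- fix_la()
  memo("la_uac", compute_uac(la$mesh, la$landmarks))
}

# regular flat rectangular sheet in the z = 0 plane, nx x ny vertices
flat_sheet <- function(nx = 15, ny = 8, dx = 1, dy = 1) {
  g <- expand.grid(x = (seq_len(nx) - 1) * dx, y = (seq_len(ny) - 1) * dy)
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1) * nx + i
  tris <- list()
  for (j in seq_len(ny - 1))
    for (i in seq_len(nx - 1)) {
      tris[[length(tris) + 1L]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
      tris[[length(tris) + 1L]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
    }
  surface_mesh(v, do.call(rbind, tris))
}

# closed axis-aligned cube surface mesh with edge length a, corner at origin
cube_mesh <- function(a = 1) {
  v <- as.matrix(expand.grid(x = c(0, a), y = c(0, a), z = c(0, a)))
  tri <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = a
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = a
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = a
  lastrain:::orient_consistently(surface_mesh(v, tri))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# exact point-to-triangle distance, independent R implementation
# (candidate enumeration: plane projection + three edge segments)
pt_tri_dist_r <- function(p, a, b, cc) {
  seg <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    t <- min(max(t, 0), 1)
    sqrt(sum((a + t * ab - p)^2))
  }
  n <- lastrain:::vcross(b - a, cc - a)
  cands <- c(seg(p, a, b), seg(p, b, cc), seg(p, a, cc))
  nn <- sqrt(sum(n^2))
  if (nn > 1e-12) {
    n <- n / nn
    q <- p - sum((p - a) * n) * n
    # barycentric inside test
    v0 <- b - a; v1 <- cc - a; v2 <- q - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    if (u >= 0 && v >= 0 && u + v <= 1) cands <- c(cands, sqrt(sum((q - p)^2)))
  }
  min(cands)
}

point_mesh_distance_oracle <- function(P, mesh) {
  vapply(seq_len(nrow(P)), function(i) {
    min(vapply(seq_len(nrow(mesh$triangles)), function(t) {
      tr <- mesh$triangles[t, ]
      pt_tri_dist_r(P[i, ], mesh$vertices[tr[1], ], mesh$vertices[tr[2], ],
                    mesh$vertices[tr[3], ])
    }, numeric(1)))
  }, numeric(1))
}

# one small registration-ready two-frame series: blob translated by d mm
fix_blob_series <- function() {
  memo("blob_series", {
    sp <- synth_anatomy("sphere", radii = 14, subdivisions = 3, seed = 1)
    dims <- c(40, 40, 40); spacing <- 1.5
    i0 <- rasterize_mesh(sp$mesh, dims, spacing, inside = 300, outside = 50,
                         blur_sigma = 1)
    m2 <- sp$mesh
    m2$vertices <- sweep(m2$vertices, 2, c(2, 0, 0), `+`)
    i1 <- rasterize_mesh(m2, dims, spacing, origin = attr(i0, "origin"),
                         inside = 300, outside = 50, blur_sigma = 1)
    list(anatomy = sp,
         series = image_series(list(i0, i1), spacing, attr(i0, "origin")))
  })
}
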