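#' Harmonic scalar field on a surface mesh
#'
#' Discrete harmonic interpolation with cotangent weights: solves the
#' Laplace equation on the mesh with Dirichlet values fixed at the given
#' vertices (direct sparse solve, exact to solver precision).
#'
#' @param mesh a [surface_mesh()]
#' @param dirichlet named numeric vector: names are vertex indices, values
#'   the boundary values
#' @return per-vertex field
#' @export
solve_laplace <- function(mesh, dirichlet) {
  if (length(dirichlet) == 0) abort("empty Dirichlet set")
  n <- nrow(mesh$vertices)
  bidx <- as.integer(names(dirichlet))
  if (any(is.na(bidx)) || any(bidx < 1) || any(bidx > n))
    abort("invalid Dirichlet vertex indices")
  L <- cotan_laplacian(mesh)
  free <- setdiff(seq_len(n), bidx)
  u <- numeric(n)
  u[bidx] <- dirichlet
  if (length(free) > 0) {
    rhs <- -L[free, bidx, drop = FALSE] %*% dirichlet
    sol <- tryCatch(Matrix::solve(L[free, free], rhs),
                    error = function(e)
                      abort("Laplace system singular: disconnected interior component?"))
    u[free] <- as.numeric(sol)
  }
  u
}

# cotangent-weight Laplacian (positive semi-definite convention: L u = 0
# interior, diagonal = sum of weights)
cotan_laplacian <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  n <- nrow(v)
  ii <- jj <- integer(0); xx <- numeric(0)
  for (corner in 1:3) {
    a <- tr[, corner]
    b <- tr[, corner %% 3 + 1]
    cc <- tr[, (corner + 1) %% 3 + 1]
    # cot of the angle at a, opposite edge (b, cc)
    e1 <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    e2 <- v[cc, , drop = FALSE] - v[a, , drop = FALSE]
    dot <- rowSums(e1 * e2)
    crs <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    cot <- dot / pmax(sqrt(rowSums(crs^2)), 1e-12)
    w <- cot / 2
    ii <- c(ii, b, cc); jj <- c(jj, cc, b); xx <- c(xx, w, w)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::Diagonal(x = Matrix::rowSums(W)) - W
}

#' Default five-region specification in coordinate space
#'
#' Axis-aligned rectangles of the (alpha, beta) unit square, checked in
#' order; the first match labels the element.  Loaded from the bundled JSON
#' spec unless a path is given.
#'
#' @param path optional JSON file with fields `label`, `alpha`, `beta`
#' @return tibble with columns `label`, `alpha_min`, `alpha_max`,
#'   `beta_min`, `beta_max`
#' @export
region_spec <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "regions_default.json", package = "lastrain")
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble(label = js$label,
         alpha_min = js$alpha[, 1], alpha_max = js$alpha[, 2],
         beta_min = js$beta[, 1], beta_max = js$beta[, 2])
}

# classify boundary loops of an anatomy mesh by nearest orifice landmark
classify_loops <- function(mesh, landmarks) {
  loops <- boundary_loops(mesh)
  lm_names <- c("mv_centre", "pv_ostium_1", "pv_ostium_2", "pv_ostium_3",
                "pv_ostium_4", "laa_ostium")
  lm_names <- intersect(lm_names, names(landmarks))
  out <- list()
  for (loop in loops) {
    cen <- colMeans(mesh$vertices[loop, , drop = FALSE])
    d <- vapply(lm_names, function(nm) sum((landmarks[[nm]] - cen)^2), numeric(1))
    out[[lm_names[which.min(d)]]] <- loop
  }
  out
}

#' Universal-atrial-coordinate-style fields and wall regions
#'
#' Computes two harmonic coordinates on the mesh: `alpha` (lateral 0 to
#' septal 1) anchored at two landmark-seeded geodesic paths running from the
#' appendage/right-inferior-vein rims down to the mitral rim, and `beta`
#' (mitral rim 0 to posterior roof path 1) anchored at the mitral boundary
#' loop and a roof geodesic between the two superior vein rims.  Elements
#' are then labelled with the five wall regions by their coordinate-space
#' centroid falling in the configured rectangles.
#'
#' @param mesh a [surface_mesh()] with labelled orifice rims
#' @param landmarks landmark list as produced by [synth_anatomy()]
#' @param spec region rectangles, see [region_spec()]
#' @return list with `uac` (tibble vertex/alpha/beta), `regions`
#'   (per-element label, `NA` for rim elements) and `paths` (the boundary
#'   vertex paths used)
#' @export
compute_uac <- function(mesh, landmarks, spec = region_spec()) {
  need <- c("mv_centre", "pv_ostium_1", "pv_ostium_2", "pv_ostium_3",
            "laa_ostium", "septal_seed", "lateral_seed")
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) abort(paste("missing landmarks:", paste(miss, collapse = ", ")))
  loops <- classify_loops(mesh, landmarks)
  if (is.null(loops$mv_centre)) abort("no mitral boundary loop found")
  mv_loop <- loops$mv_centre

  near_loop <- function(lmname, target) {
    loop <- loops[[lmname]]
    if (is.null(loop)) return(nearest_vertex(mesh, landmarks[[gsub("_rim", "", lmname)]]))
    loop[which.min(rowSums(sweep(mesh$vertices[loop, , drop = FALSE], 2, target)^2))]
  }
  v_ss <- nearest_vertex(mesh, landmarks$septal_seed)
  v_ls <- nearest_vertex(mesh, landmarks$lateral_seed)
  v_pv2 <- near_loop("pv_ostium_2", landmarks$septal_seed)
  v_laa <- near_loop("laa_ostium", landmarks$lateral_seed)
  v_mv_s <- mv_loop[which.min(rowSums(sweep(
    mesh$vertices[mv_loop, , drop = FALSE], 2, mesh$vertices[v_ss, ])^2))]
  v_mv_l <- mv_loop[which.min(rowSums(sweep(
    mesh$vertices[mv_loop, , drop = FALSE], 2, mesh$vertices[v_ls, ])^2))]

  septal_path <- unique(c(geodesic_path(mesh, v_pv2, v_ss),
                          geodesic_path(mesh, v_ss, v_mv_s)))
  lateral_path <- unique(c(geodesic_path(mesh, v_laa, v_ls),
                           geodesic_path(mesh, v_ls, v_mv_l)))
  if (length(intersect(septal_path, lateral_path)) > 0)
    abort("degenerate boundary paths: septal and lateral paths share vertices")

  # posterior roof path: superior-vein rim to superior-vein rim through the
  # point nearest the mid-ostial (posterior roof) position
  roof_target <- (landmarks$pv_ostium_1 + landmarks$pv_ostium_3) / 2
  v_roof <- nearest_vertex(mesh, roof_target)
  v_pv1 <- near_loop("pv_ostium_1", roof_target)
  v_pv3 <- near_loop("pv_ostium_3", roof_target)
  roof_path <- unique(c(geodesic_path(mesh, v_pv1, v_roof),
                        geodesic_path(mesh, v_roof, v_pv3)))

  # the thin vertex paths are anchored together with the adjacent orifice
  # boundary loops: loops have a resolution-independent geometric extent, so
  # the harmonic fields converge under mesh refinement instead of the
  # path constraints losing capacity
  lat_set <- unique(c(lateral_path, loops$laa_ostium))
  sep_set <- unique(c(septal_path, loops$pv_ostium_1, loops$pv_ostium_2))
  if (length(intersect(lat_set, sep_set)) > 0)
    abort("degenerate boundary paths: lateral and septal anchor sets overlap")
  roof_set <- unique(c(roof_path, loops$pv_ostium_1, loops$pv_ostium_3))
  alpha <- solve_laplace(mesh, setNames(
    c(rep(0, length(lat_set)), rep(1, length(sep_set))),
    c(lat_set, sep_set)))
  beta <- solve_laplace(mesh, setNames(
    c(rep(0, length(mv_loop)), rep(1, length(roof_set))),
    c(mv_loop, roof_set)))
  alpha <- pmin(pmax(alpha, 0), 1)
  beta <- pmin(pmax(beta, 0), 1)

  regions <- assign_regions(mesh, alpha, beta, spec)
  list(uac = tibble(vertex = seq_len(nrow(mesh$vertices)),
                    alpha = alpha, beta = beta),
       regions = regions,
       paths = list(septal = septal_path, lateral = lateral_path,
                    roof = roof_path, mv = mv_loop))
}

# per-element region labels from coordinate-space centroids
assign_regions <- function(mesh, alpha, beta, spec) {
  tr <- mesh$triangles
  ca <- (alpha[tr[, 1]] + alpha[tr[, 2]] + alpha[tr[, 3]]) / 3
  cb <- (beta[tr[, 1]] + beta[tr[, 2]] + beta[tr[, 3]]) / 3
  lab <- rep(NA_character_, nrow(tr))
  body <- mesh$element_labels == "body"
  for (i in seq_len(nrow(spec))) {
    hit <- body & is.na(lab) &
      ca >= spec$alpha_min[i] & ca <= spec$alpha_max[i] &
      cb >= spec$beta_min[i] & cb <= spec$beta_max[i]
    lab[hit] <- spec$label[i]
  }
  # numerically outside every rectangle: nearest rectangle centre
  rest <- which(body & is.na(lab))
  if (length(rest)) {
    cx <- (spec$alpha_min + spec$alpha_max) / 2
    cy <- (spec$beta_min + spec$beta_max) / 2
    for (i in rest)
      lab[i] <- spec$label[which.min((ca[i] - cx)^2 + (cb[i] - cy)^2)]
  }
  lab
}

#' Fibre atlas on the coordinate unit square
#'
#' Fibre angles theta(alpha, beta) in radians, measured from the
#' alpha-coordinate direction, sampled on a regular grid over the unit
#' square and interpolated bilinearly.
#'
#' @param theta matrix of angles, rows indexing `alpha`, columns `beta`
#' @param alpha,beta grid coordinates (ascending, spanning 0..1)
#' @return object of class `fibre_atlas`
#' @export
fibre_atlas <- function(theta,
                        alpha = seq(0, 1, length.out = nrow(theta)),
                        beta = seq(0, 1, length.out = ncol(theta))) {
  theta <- as.matrix(theta)
  if (any(!is.finite(theta))) abort("atlas angles must be finite")
  if (min(alpha) > 0 || max(alpha) < 1 || min(beta) > 0 || max(beta) < 1)
    abort("atlas grid must cover the unit square")
  structure(list(theta = theta, alpha = alpha, beta = beta),
            class = "fibre_atlas")
}

#' Read or bundle-load a fibre atlas
#'
#' The bundled default is a smooth synthetic atlas (not measured human
#' fibre data); real atlases are ingested through the same JSON grid format
#' (`alpha`, `beta`, `theta` row-major by alpha).
#'
#' @param path JSON atlas file; default loads the bundled synthetic atlas
#' @return a [fibre_atlas()]
#' @export
read_fibre_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atlas_synthetic.json", package = "lastrain")
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  fibre_atlas(matrix(js$theta, nrow = length(js$alpha), byrow = FALSE),
              js$alpha, js$beta)
}

# bilinear interpolation of the atlas at coordinate points
atlas_theta <- function(atlas, a, b) {
  ai <- findInterval(a, atlas$alpha, all.inside = TRUE)
  bi <- findInterval(b, atlas$beta, all.inside = TRUE)
  a0 <- atlas$alpha[ai]; a1 <- atlas$alpha[ai + 1]
  b0 <- atlas$beta[bi]; b1 <- atlas$beta[bi + 1]
  fa <- (a - a0) / (a1 - a0); fb <- (b - b0) / (b1 - b0)
  t00 <- atlas$theta[cbind(ai, bi)]
  t10 <- atlas$theta[cbind(ai + 1, bi)]
  t01 <- atlas$theta[cbind(ai, bi + 1)]
  t11 <- atlas$theta[cbind(ai + 1, bi + 1)]
  (1 - fa) * (1 - fb) * t00 + fa * (1 - fb) * t10 +
    (1 - fa) * fb * t01 + fa * fb * t11
}

#' Map a fibre atlas onto the mesh
#'
#' For each body element the atlas angle is interpolated at the element's
#' coordinate-space centroid and realised in the element's tangent plane:
#' the first frame axis is the in-plane normalised surface gradient of
#' `alpha`; the second is its in-plane orthogonal complement oriented
#' towards the `beta` gradient (Gram-Schmidt), so the angle is defined in an
#' orthonormal frame.  Elements with a vanishing `alpha` gradient receive
#' the average of their neighbours' fibres and are flagged.
#'
#' @param mesh a [surface_mesh()]
#' @param uac coordinate tibble from [compute_uac()]
#' @param atlas a [fibre_atlas()]
#' @return M x 3 matrix of unit in-plane fibres (rows `NA` for non-body
#'   elements), with logical attribute `fallback` marking degenerate
#'   elements
#' @export
map_fibres <- function(mesh, uac, atlas = read_fibre_atlas()) {
  alpha <- uac$alpha; beta <- uac$beta
  tr <- mesh$triangles; v <- mesh$vertices
  m <- nrow(tr)
  body <- mesh$element_labels == "body"
  fib <- matrix(NA_real_, m, 3)
  fallback <- rep(FALSE, m)

  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  nrm <- triangle_normals(mesh)
  u1 <- e1 / sqrt(rowSums(e1^2))
  u2 <- cbind(nrm[, 2] * u1[, 3] - nrm[, 3] * u1[, 2],
              nrm[, 3] * u1[, 1] - nrm[, 1] * u1[, 3],
              nrm[, 1] * u1[, 2] - nrm[, 2] * u1[, 1])

  grad_field <- function(f) {
    # per-element in-plane gradient of a linear vertex field
    df1 <- f[tr[, 2]] - f[tr[, 1]]
    df2 <- f[tr[, 3]] - f[tr[, 1]]
    p11 <- rowSums(e1 * u1); p12 <- rowSums(e1 * u2)
    p21 <- rowSums(e2 * u1); p22 <- rowSums(e2 * u2)
    det <- p11 * p22 - p12 * p21
    gx <- (p22 * df1 - p12 * df2) / det
    gy <- (-p21 * df1 + p11 * df2) / det
    u1 * gx + u2 * gy
  }
  ga <- grad_field(alpha)
  gb <- grad_field(beta)
  gal <- sqrt(rowSums(ga^2))

  ca <- (alpha[tr[, 1]] + alpha[tr[, 2]] + alpha[tr[, 3]]) / 3
  cb <- (beta[tr[, 1]] + beta[tr[, 2]] + beta[tr[, 3]]) / 3
  th <- atlas_theta(atlas, pmin(pmax(ca, 0), 1), pmin(pmax(cb, 0), 1))

  ok <- body & gal > 1e-8
  ea <- ga / pmax(gal, 1e-300)
  # in-plane orthogonal complement of ea, oriented towards grad beta
  eb <- cbind(nrm[, 2] * ea[, 3] - nrm[, 3] * ea[, 2],
              nrm[, 3] * ea[, 1] - nrm[, 1] * ea[, 3],
              nrm[, 1] * ea[, 2] - nrm[, 2] * ea[, 1])
  sgn <- ifelse(rowSums(eb * gb) < 0, -1, 1)
  eb <- eb * sgn
  f <- cos(th) * ea + sin(th) * eb
  f <- f / sqrt(rowSums(f^2))
  fib[ok, ] <- f[ok, ]

  # degenerate elements: neighbour average (shared-vertex neighbours)
  degen <- which(body & !ok)
  if (length(degen)) {
    for (i in degen) {
      nb <- which(body & rowSums(matrix(tr %in% tr[i, ], ncol = 3)) > 0)
      nb <- setdiff(nb, i)
      nb <- nb[!is.na(fib[nb, 1])]
      if (length(nb) == 0) abort("isolated degenerate element in fibre mapping")
      fm <- colMeans(fib[nb, , drop = FALSE])
      # project into the element plane and renormalise
      fm <- fm - sum(fm * nrm[i, ]) * nrm[i, ]
      fib[i, ] <- fm / sqrt(sum(fm^2))
      fallback[i] <- TRUE
    }
    warn(sprintf("%d element(s) used neighbour-averaged fibres", length(degen)))
  }
  attr(fib, "fallback") <- fallback
  fib
}
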