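#' Generate a synthetic left-atrial (or spherical) anatomy
#'
#' Builds a closed ellipsoid-based endocardial surface by subdividing an
#' icosahedron, optionally perturbing it with smooth radial bumps, and cutting
#' six circular orifices (mitral valve, four pulmonary veins, appendage).
#' Elements adjacent to each orifice boundary are labelled as rim elements;
#' everything else is `"body"`.  The anatomy's coordinate convention is:
#' +x septal, -x lateral, +y posterior, +z towards the roof.
#'
#' @param preset `"la"` (ellipsoid with orifices) or `"sphere"` (closed sphere)
#' @param radii semi-axes in mm; a single number is used for all three
#' @param subdivisions icosahedron subdivision level (>= 2)
#' @param bump_amplitude relative amplitude of smooth radial shape
#'   perturbations (dimensionless; 0 disables)
#' @param n_bumps number of Gaussian bumps drawn for the perturbation
#' @param orifices logical; cut the six orifices (default `TRUE` for `"la"`)
#' @param seed integer seed controlling the bump pattern
#' @return a list of class `la_anatomy` with elements `mesh`
#'   (a [surface_mesh()]) and `landmarks` (named list of 3-vectors, mm):
#'   `mv_centre`, `pv_ostium_1..4`, `laa_ostium`, `septal_seed`,
#'   `lateral_seed`
#' @export
synth_anatomy <- function(preset = c("la", "sphere"), radii = NULL,
                          subdivisions = 4, bump_amplitude = NULL,
                          n_bumps = 6, orifices = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (subdivisions < 2) abort("subdivision level must be >= 2")
  if (is.null(radii)) radii <- if (preset == "la") c(32, 27, 24) else 30
  if (length(radii) == 1) radii <- rep(radii, 3)
  if (any(radii <= 0)) abort("radii must be positive")
  if (is.null(orifices)) orifices <- preset == "la"
  if (is.null(bump_amplitude)) bump_amplitude <- if (preset == "la") 0.03 else 0

  ico <- icosphere(subdivisions)
  unit <- ico$vertices

  if (bump_amplitude > 0) {
    set.seed(seed)
    dirs <- matrix(rnorm(3 * n_bumps), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amps <- rnorm(n_bumps, 0, bump_amplitude)
    scale <- rep(1, nrow(unit))
    for (k in seq_len(n_bumps)) {
      ca <- as.numeric(unit %*% dirs[k, ])
      scale <- scale + amps[k] * exp(-(acos(pmin(pmax(ca, -1), 1)))^2 / (2 * 0.6^2))
    }
    v <- unit * scale
  } else v <- unit

  v <- sweep(v, 2, radii, `*`)
  mesh <- surface_mesh(v, ico$triangles)
  mesh <- orient_consistently(mesh)

  spec <- orifice_spec()
  landmarks <- list()
  if (orifices) {
    ang <- sapply(spec, function(s) s$angle)
    nm <- names(spec)
    for (i in seq_along(spec))
      for (j in seq_len(i - 1)) {
        sep <- acos(sum(spec[[i]]$dir * spec[[j]]$dir))
        if (sep < (spec[[i]]$angle + spec[[j]]$angle) * pi / 180 + 0.02)
          abort(sprintf("orifices '%s' and '%s' overlap", nm[i], nm[j]))
      }
    lab <- mesh$element_labels
    keep <- rep(TRUE, nrow(mesh$triangles))
    which_orifice <- rep(NA_character_, nrow(mesh$triangles))
    for (nmi in names(spec)) {
      s <- spec[[nmi]]
      ca <- unit %*% s$dir
      inside <- acos(pmin(pmax(ca, -1), 1)) < s$angle * pi / 180
      tri_in <- inside[mesh$triangles[, 1]] & inside[mesh$triangles[, 2]] &
        inside[mesh$triangles[, 3]]
      keep[tri_in] <- FALSE
      which_orifice[tri_in] <- nmi
    }
    # rim = kept triangles sharing a vertex with a removed triangle
    for (nmi in names(spec)) {
      rimv <- unique(as.vector(mesh$triangles[!keep & which_orifice == nmi, ]))
      touches <- matrix(mesh$triangles %in% rimv, ncol = 3)
      rim_tri <- keep & rowSums(touches) > 0
      lab[rim_tri] <- paste0(nmi, "_rim")
    }
    mesh <- surface_mesh(mesh$vertices[, , drop = FALSE],
                         mesh$triangles[keep, , drop = FALSE],
                         lab[keep])
    mesh <- drop_unused_vertices(mesh)
    # landmarks: orifice boundary-loop centroid projected to the nearest
    # rim vertex (keeps landmarks on the surface)
    for (nmi in names(spec)) {
      rim_tri <- which(mesh$element_labels == paste0(nmi, "_rim"))
      rv <- unique(as.vector(mesh$triangles[rim_tri, ]))
      cen <- colMeans(mesh$vertices[rv, , drop = FALSE])
      d2 <- rowSums(sweep(mesh$vertices[rv, , drop = FALSE], 2, cen)^2)
      landmarks[[landmark_name(nmi)]] <- mesh$vertices[rv[which.min(d2)], ]
    }
  }
  landmarks$septal_seed <- surface_point(mesh, c(1, 0.15, 0.05))
  landmarks$lateral_seed <- surface_point(mesh, c(-1, -0.25, 0.05))
  structure(list(mesh = mesh, landmarks = landmarks, preset = preset,
                 radii = radii, seed = seed),
            class = "la_anatomy")
}

landmark_name <- function(orifice) {
  switch(orifice,
         mv = "mv_centre", laa = "laa_ostium",
         pv_1 = "pv_ostium_1", pv_2 = "pv_ostium_2",
         pv_3 = "pv_ostium_3", pv_4 = "pv_ostium_4")
}

orifice_spec <- function() {
  nrm <- function(x) x / sqrt(sum(x^2))
  list(
    mv   = list(dir = c(0, 0, -1), angle = 38),
    pv_1 = list(dir = nrm(c(0.62, 0.62, 0.48)), angle = 15),   # right superior
    pv_2 = list(dir = nrm(c(0.72, 0.67, -0.18)), angle = 14),  # right inferior
    pv_3 = list(dir = nrm(c(-0.62, 0.62, 0.48)), angle = 15),  # left superior
    pv_4 = list(dir = nrm(c(-0.72, 0.67, -0.18)), angle = 14), # left inferior
    laa  = list(dir = nrm(c(-0.58, -0.62, 0.52)), angle = 16)
  )
}

# vertex on the surface nearest to a direction from the origin
surface_point <- function(mesh, dir) {
  dir <- dir / sqrt(sum(dir^2))
  vn <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  mesh$vertices[which.max(vn %*% dir), ]
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$triangles)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(map[mesh$triangles], ncol = 3),
               mesh$element_labels)
}

#' @export
print.la_anatomy <- function(x, ...) {
  cat("<la_anatomy> preset:", x$preset, "\n")
  print(x$mesh)
  invisible(x)
}

# subdivided icosahedron on the unit sphere
icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- (v[a, ] + v[b, ])
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(cc, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  list(vertices = v, triangles = f)
}

#' Ground-truth cyclic motion model
#'
#' Analytic radial scaling about a centre point with a smooth cyclic temporal
#' profile: `phi(x, t) = c + s(t, x) * (x - c)` with
#' `s(t, x) = 1 + (s_peak - 1) * a(x) * w(t)`, where `w` is a raised-cosine
#' bump satisfying `w(0) = w(F) = 0` and `w(t_peak) = 1`, and `a(x)` is an
#' optional smooth spatial amplitude modulation (default 1 everywhere).
#' The map is the identity at frame 0 and periodic with period `n_frames`,
#' so ground-truth strain is available in closed form.
#'
#' @param centre 3-vector (mm) about which the anatomy scales
#' @param s_peak peak radial scale factor (> 0); 1 means no motion
#' @param t_peak frame of peak expansion (0 < t_peak < n_frames)
#' @param n_frames frames per cardiac cycle (>= 2)
#' @param amplitude_fn optional function taking an N x 3 point matrix and
#'   returning a per-point amplitude multiplier
#' @return an object of class `ground_truth_motion`
#' @export
synth_motion <- function(centre = c(0, 0, 0), s_peak = 1.08, t_peak = 4,
                         n_frames = 10, amplitude_fn = NULL) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (s_peak <= 0) abort("s_peak must be > 0")
  if (t_peak <= 0 || t_peak >= n_frames) abort("t_peak must lie in (0, n_frames)")
  structure(list(centre = centre, s_peak = s_peak, t_peak = t_peak,
                 n_frames = n_frames, amplitude_fn = amplitude_fn),
            class = "ground_truth_motion")
}

# temporal profile: raised-cosine bump, w(0)=w(F)=0, w(t_peak)=1, C1, periodic
motion_profile <- function(t, t_peak, n_frames) {
  t <- t %% n_frames
  ifelse(t <= t_peak,
         0.5 * (1 - cos(pi * t / t_peak)),
         0.5 * (1 + cos(pi * (t - t_peak) / (n_frames - t_peak))))
}

#' Apply a ground-truth motion to points
#'
#' @param motion a [synth_motion()] object
#' @param points N x 3 matrix (mm)
#' @param t frame time (continuous; periodic in `n_frames`)
#' @return N x 3 matrix of moved points
#' @export
apply_motion <- function(motion, points, t) {
  points <- rbind(points)  # tolerate a single 3-vector
  w <- motion_profile(t, motion$t_peak, motion$n_frames)
  a <- if (is.null(motion$amplitude_fn)) 1 else motion$amplitude_fn(points)
  s <- 1 + (motion$s_peak - 1) * a * w
  cen <- matrix(motion$centre, nrow(points), 3, byrow = TRUE)
  cen + (points - cen) * s
}

#' Exact per-element strain of a ground-truth motion
#'
#' Applies the analytic motion to each triangle's vertices and evaluates the
#' element strains, giving ground truth exact up to floating point.
#'
#' @param motion a [synth_motion()] object
#' @param mesh reference [surface_mesh()] (frame 0)
#' @param fibres M x 3 matrix of unit in-plane fibre directions per element
#'   (body elements; others may be `NA`)
#' @param t frame
#' @return tibble with columns `element`, `label`, `area_strain`,
#'   `fibre_strain` (percent)
#' @export
ground_truth_strain <- function(motion, mesh, fibres, t) {
  vdef <- apply_motion(motion, mesh$vertices, t)
  def_mesh <- mesh
  def_mesh$vertices <- vdef
  element_strain_table(mesh, def_mesh, fibres)
}

#' Image series container
#'
#' @param frames list of 3D numeric arrays sharing dimensions
#' @param spacing voxel spacing (mm), length 1 or 3
#' @param origin world coordinate of voxel (0, 0, 0), mm
#' @param frame_fraction optional percentages of the R-R interval
#' @return object of class `image_series`
#' @export
image_series <- function(frames, spacing, origin = c(0, 0, 0),
                         frame_fraction = NULL) {
  if (length(frames) < 2) abort("an image series needs at least 2 frames")
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) abort("spacing must be positive")
  d <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), d)) abort("frames must share dimensions")
  if (is.null(frame_fraction))
    frame_fraction <- seq(0, length.out = length(frames), by = 100 / length(frames))
  structure(list(frames = frames, spacing = spacing, origin = origin,
                 frame_fraction = frame_fraction),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("<image_series> ", length(x$frames), " frames of ",
      paste(d, collapse = "x"), " voxels, spacing ",
      paste(signif(x$spacing, 3), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Rasterise a closed mesh into a voxel image
#'
#' Voxels inside the surface receive `inside`, the rest `outside`; the
#' boundary can be smoothed with a Gaussian kernel and Gaussian noise added.
#' Meshes with open orifices are capped first.
#'
#' @param mesh a [surface_mesh()]
#' @param dims voxel grid dimensions (length 3)
#' @param spacing voxel spacing mm (length 1 or 3)
#' @param origin world position of voxel (0,0,0); `NULL` centres the grid on
#'   the mesh
#' @param inside,outside intensities
#' @param blur_sigma boundary smoothing, in voxels (0 = crisp)
#' @param noise_sd additive Gaussian noise standard deviation
#' @param seed seed for the noise
#' @return 3D array with attributes `spacing` and `origin`
#' @export
rasterize_mesh <- function(mesh, dims = c(64, 64, 64), spacing = 1.5,
                           origin = NULL, inside = 300, outside = 50,
                           blur_sigma = 1, noise_sd = 0, seed = 1) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  closed <- if (length(boundary_loops(mesh)) > 0) cap_orifices(mesh) else mesh
  ext <- dims * spacing
  if (is.null(origin)) {
    cen <- colMeans(closed$vertices)
    origin <- cen - ext / 2 + spacing / 2
  }
  rng_lo <- apply(closed$vertices, 2, min)
  rng_hi <- apply(closed$vertices, 2, max)
  if (any(rng_lo < origin + 3 * spacing) ||
      any(rng_hi > origin + (dims - 4) * spacing))
    abort("mesh does not fit in the field of view with a 3-voxel margin")
  img <- rasterize_mesh_cpp(closed$vertices, closed$triangles - 1L,
                            as.integer(dims), origin, spacing, inside, outside)
  if (blur_sigma > 0) img <- gaussian_blur3_cpp(img, as.integer(dims), blur_sigma)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + array(rnorm(prod(dims), 0, noise_sd), dims)
  }
  img <- array(img, dims)
  attr(img, "spacing") <- spacing
  attr(img, "origin") <- origin
  img
}

#' Rasterise an image series from an anatomy and ground-truth motion
#'
#' Each frame is the rasterisation of the anatomy moved by the analytic
#' motion, with per-frame seeded noise; frame 0 also yields the binary
#' blood-pool segmentation.
#'
#' @param anatomy a [synth_anatomy()] result
#' @param motion a [synth_motion()] object
#' @inheritParams rasterize_mesh
#' @return list with `images` (an [image_series()]), `segmentation`
#'   (binary array, frame 0) and `origin`/`spacing`
#' @export
synth_image_series <- function(anatomy, motion, dims = c(64, 64, 64),
                               spacing = 1.5, inside = 300, outside = 50,
                               blur_sigma = 1, noise_sd = 5, seed = 1) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  mesh <- anatomy$mesh
  cen <- colMeans(mesh$vertices)
  origin <- cen - dims * spacing / 2 + spacing / 2
  frames <- vector("list", motion$n_frames)
  for (t in seq_len(motion$n_frames) - 1) {
    mt <- mesh
    mt$vertices <- apply_motion(motion, mesh$vertices, t)
    frames[[t + 1]] <- rasterize_mesh(mt, dims, spacing, origin, inside,
                                      outside, blur_sigma, noise_sd,
                                      seed = seed + 1000L * t)
  }
  seg <- rasterize_mesh(mesh, dims, spacing, origin, 1, 0,
                        blur_sigma = 0, noise_sd = 0)
  list(images = image_series(frames, spacing, origin),
       segmentation = array(seg >= 0.5, dims) * 1L,
       origin = origin, spacing = spacing)
}

#' Extract iso-level crossing points from a volume
#'
#' Lightweight surface extraction: returns the linearly interpolated points
#' where grid edges cross the given intensity level (the vertex set of a
#' marching-style isosurface, without faces).
#'
#' @param img 3D array with `spacing`/`origin` attributes (or pass explicitly)
#' @param level iso level
#' @param spacing,origin grid geometry if not carried as attributes
#' @return N x 3 matrix of world points (mm)
#' @export
isosurface_points <- function(img, level, spacing = attr(img, "spacing"),
                              origin = attr(img, "origin")) {
  isosurface_points_cpp(as.numeric(img), as.integer(dim(img)), origin,
                        spacing, level)
}
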