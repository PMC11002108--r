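#' Extract a two- or four-chamber planar view
#'
#' Defines the view plane from landmarks (two-chamber: mitral centre,
#' appendage ostium and the chamber centroid; four-chamber: mitral centre
#' and the two inferior vein ostia), resamples every frame of the series
#' into the plane, and intersects the ED mesh with the plane to obtain the
#' ED contour.  Contour segments arising from rim-labelled elements (mitral
#' valve, veins, appendage) are marked excluded and do not contribute to the
#' tracked body contour length.
#'
#' @param images an [image_series()]
#' @param ed_mesh reference [surface_mesh()]
#' @param landmarks landmark list (see [synth_anatomy()])
#' @param view `"2ch"` or `"4ch"`
#' @param plane_spacing in-plane sample spacing (mm; default the volume's
#'   in-plane spacing)
#' @param margin extra in-plane margin around the contour (mm)
#' @return object of class `planar_view`: plane definition, 2D
#'   [image_series()] (flat third axis), and the labelled contour segments
#'   in plane coordinates
#' @export
extract_view <- function(images, ed_mesh, landmarks, view = c("2ch", "4ch"),
                         plane_spacing = NULL, margin = 12) {
  view <- match.arg(view)
  p1 <- landmarks$mv_centre
  if (view == "2ch") {
    p2 <- landmarks$laa_ostium
    p3 <- colMeans(ed_mesh$vertices)
  } else {
    p2 <- landmarks$pv_ostium_2
    p3 <- landmarks$pv_ostium_4
  }
  n <- vcross(p2 - p1, p3 - p1)
  if (sqrt(sum(n^2)) < 1e-9) abort("degenerate view plane (collinear landmarks)")
  n <- n / sqrt(sum(n^2))
  ax1 <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  ax2 <- vcross(n, ax1)

  contour <- mesh_plane_contour(ed_mesh, p1, n, ax1, ax2)
  if (nrow(contour) == 0) abort("view plane does not intersect the chamber")

  if (is.null(plane_spacing)) plane_spacing <- images$spacing[1]
  lo <- c(min(c(contour$x1, contour$x2)), min(c(contour$y1, contour$y2))) - margin
  hi <- c(max(c(contour$x1, contour$x2)), max(c(contour$y1, contour$y2))) + margin
  nx <- ceiling((hi[1] - lo[1]) / plane_spacing) + 1
  ny <- ceiling((hi[2] - lo[2]) / plane_spacing) + 1

  g <- image_geometry(images)
  ij <- as.matrix(expand.grid(i = seq_len(nx) - 1, j = seq_len(ny) - 1))
  world <- matrix(p1, nrow(ij), 3, byrow = TRUE) +
    (lo[1] + ij[, 1] * plane_spacing) %o% ax1 +
    (lo[2] + ij[, 2] * plane_spacing) %o% ax2
  vox <- sweep(sweep(world, 2, g$origin), 2, g$spacing, `/`)
  frames <- lapply(images$frames, function(f)
    array(sample_volume(f, vox), c(nx, ny, 1)))

  # shift contour into the 2D grid's coordinate system (grid origin at 0)
  contour$x1 <- contour$x1 - lo[1]; contour$x2 <- contour$x2 - lo[1]
  contour$y1 <- contour$y1 - lo[2]; contour$y2 <- contour$y2 - lo[2]

  structure(list(
    view = view, plane_origin = p1, axes = rbind(ax1, ax2), normal = n,
    grid_offset = lo,
    images = image_series(frames, c(plane_spacing, plane_spacing, 1),
                          origin = c(0, 0, 0)),
    contour = contour), class = "planar_view")
}

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# trilinear sampling of a 3D array at fractional voxel coordinates
sample_volume <- function(f, vox) {
  d <- dim(f)
  vox <- pmin(pmax(vox, 0), matrix(d - 1, nrow(vox), 3, byrow = TRUE))
  i0 <- pmin(floor(vox[, 1]), d[1] - 2) ; fx <- vox[, 1] - i0
  j0 <- pmin(floor(vox[, 2]), d[2] - 2) ; fy <- vox[, 2] - j0
  k0 <- pmin(floor(vox[, 3]), max(d[3] - 2, 0)); fz <- vox[, 3] - k0
  if (d[3] == 1) { k0 <- 0; fz <- 0 }
  at <- function(di, dj, dk) f[cbind(i0 + di + 1, j0 + dj + 1,
                                     pmin(k0 + dk, d[3] - 1) + 1)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(0, 0, 0) + fx * at(1, 0, 0)) +
                fy * ((1 - fx) * at(0, 1, 0) + fx * at(1, 1, 0))) +
    fz * ((1 - fy) * ((1 - fx) * at(0, 0, 1) + fx * at(1, 0, 1)) +
            fy * ((1 - fx) * at(0, 1, 1) + fx * at(1, 1, 1)))
}

# intersect mesh with plane; segments in plane coordinates with exclusion
# flags from rim element labels
mesh_plane_contour <- function(mesh, origin, normal, ax1, ax2) {
  v <- mesh$vertices; tr <- mesh$triangles
  sd <- as.numeric(sweep(v, 2, origin) %*% normal)
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    s <- sd[tr[i, ]]
    if (all(s > 0) || all(s < 0)) next
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- s[e[1]]; b <- s[e[2]]
      if ((a > 0) != (b > 0)) {
        f <- a / (a - b)
        pts[[length(pts) + 1L]] <- v[tr[i, e[1]], ] +
          f * (v[tr[i, e[2]], ] - v[tr[i, e[1]], ])
      }
    }
    if (length(pts) != 2) next
    q1 <- pts[[1]] - origin; q2 <- pts[[2]] - origin
    rows[[length(rows) + 1L]] <- tibble(
      x1 = sum(q1 * ax1), y1 = sum(q1 * ax2),
      x2 = sum(q2 * ax1), y2 = sum(q2 * ax2),
      excluded = mesh$element_labels[i] != "body")
  }
  dplyr::bind_rows(rows)
}

# total length of the non-excluded contour, given endpoints possibly moved
contour_length <- function(contour, dx1 = 0, dy1 = 0, dx2 = 0, dy2 = 0) {
  keep <- !contour$excluded
  sub <- function(d) if (length(d) > 1) d[keep] else d
  sum(sqrt((contour$x2[keep] + sub(dx2) - contour$x1[keep] - sub(dx1))^2 +
             (contour$y2[keep] + sub(dy2) - contour$y1[keep] - sub(dy1))^2))
}

#' Two-dimensional global longitudinal strain
#'
#' Tracks the LA contour in the two planar views with the same registration
#' engine in 2D mode, computes the percentage change of the non-excluded
#' body contour length per frame, takes each view's reservoir (max - min)
#' strain, and averages the two views into the 2D GLS.
#'
#' @param view_2ch,view_4ch [extract_view()] results
#' @param config a [registration_config()]
#' @return list with `gls` (%), `per_view` tibble (view, reservoir), and
#'   `transients` tibble (view, frame, strain)
#' @export
gls_2d <- function(view_2ch, view_4ch, config = registration_config()) {
  one_view <- function(pv) {
    mf <- register_series(pv$images, config)
    F <- length(pv$images$frames)
    ep1 <- cbind(pv$contour$x1, pv$contour$y1, 0)
    ep2 <- cbind(pv$contour$x2, pv$contour$y2, 0)
    L0 <- contour_length(pv$contour)
    strain <- vapply(seq_len(F) - 1, function(t) {
      u1 <- evaluate_displacement(mf, ep1, t)
      u2 <- evaluate_displacement(mf, ep2, t)
      Lt <- contour_length(pv$contour, u1[, 1], u1[, 2], u2[, 1], u2[, 2])
      100 * (Lt - L0) / L0
    }, numeric(1))
    tibble(view = pv$view, frame = seq_len(F) - 1, strain = strain)
  }
  tr <- dplyr::bind_rows(one_view(view_2ch), one_view(view_4ch))
  per_view <- dplyr::summarise(dplyr::group_by(tr, .data$view),
                               reservoir = reservoir_strain(.data$strain),
                               .groups = "drop")
  list(gls = mean(per_view$reservoir), per_view = per_view, transients = tr)
}
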