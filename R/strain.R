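#' Area and fibre strain of a single surface element
#'
#' Area strain is the percentage area change of the triangle.  Fibre strain is
#' the percentage length change along the fibre direction:
#' `100 * (|F fhat| - 1)`, where `F` is the 2x2 in-plane deformation gradient
#' mapping reference edge vectors (expressed in a local orthonormal frame) to
#' deformed edge vectors, and `fhat` is the unit fibre in the reference frame.
#'
#' @param ref_triangle,def_triangle 3 x 3 matrices of vertex coordinates
#'   (rows = vertices, mm)
#' @param fibre unit 3-vector in the reference triangle plane
#' @return named numeric vector `c(area_strain, fibre_strain)` in percent
#' @export
element_strains <- function(ref_triangle, def_triangle, fibre) {
  ref_mesh <- list(vertices = ref_triangle, triangles = matrix(1:3, 1),
                   element_labels = "body")
  def_mesh <- list(vertices = def_triangle, triangles = matrix(1:3, 1),
                   element_labels = "body")
  out <- element_strain_table(ref_mesh, def_mesh, rbind(fibre))
  c(area_strain = out$area_strain, fibre_strain = out$fibre_strain)
}

# Vectorised per-element strains between two meshes with identical topology.
# fibres: M x 3 (rows may be NA for elements without a fibre).
element_strain_table <- function(ref_mesh, def_mesh, fibres = NULL) {
  vr <- ref_mesh$vertices; vd <- def_mesh$vertices
  tr <- ref_mesh$triangles
  m <- nrow(tr)

  e1r <- vr[tr[, 2], , drop = FALSE] - vr[tr[, 1], , drop = FALSE]
  e2r <- vr[tr[, 3], , drop = FALSE] - vr[tr[, 1], , drop = FALSE]
  e1d <- vd[tr[, 2], , drop = FALSE] - vd[tr[, 1], , drop = FALSE]
  e2d <- vd[tr[, 3], , drop = FALSE] - vd[tr[, 1], , drop = FALSE]

  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nr <- cross3(e1r, e2r)
  ar <- 0.5 * sqrt(rowSums(nr^2))
  nd <- cross3(e1d, e2d)
  ad <- 0.5 * sqrt(rowSums(nd^2))
  if (any(ar < 1e-9)) abort("degenerate reference triangle (area < 1e-9 mm^2)")
  area_strain <- 100 * (ad - ar) / ar

  fibre_strain <- rep(NA_real_, m)
  if (!is.null(fibres)) {
    ok <- rowSums(is.na(fibres)) == 0
    if (any(ok)) {
      # local orthonormal frames
      u1r <- e1r / sqrt(rowSums(e1r^2))
      nrn <- nr / sqrt(rowSums(nr^2))
      u2r <- cross3(nrn, u1r)
      u1d <- e1d / sqrt(rowSums(e1d^2))
      ndn <- nd / sqrt(rowSums(nd^2))
      u2d <- cross3(ndn, u1d)
      # edge vectors in local 2D frames
      a11 <- rowSums(e1r * u1r); a21 <- rowSums(e1r * u2r)
      a12 <- rowSums(e2r * u1r); a22 <- rowSums(e2r * u2r)
      b11 <- rowSums(e1d * u1d); b21 <- rowSums(e1d * u2d)
      b12 <- rowSums(e2d * u1d); b22 <- rowSums(e2d * u2d)
      det <- a11 * a22 - a12 * a21
      # F = B %*% solve(A), 2x2 per element
      f11 <- (b11 * a22 - b12 * a21) / det
      f12 <- (-b11 * a12 + b12 * a11) / det
      f21 <- (b21 * a22 - b22 * a21) / det
      f22 <- (-b21 * a12 + b22 * a11) / det
      fx <- rowSums(fibres * u1r)
      fy <- rowSums(fibres * u2r)
      fl <- sqrt(fx^2 + fy^2)
      fx <- fx / fl; fy <- fy / fl
      st <- sqrt((f11 * fx + f12 * fy)^2 + (f21 * fx + f22 * fy)^2)
      fibre_strain[ok] <- 100 * (st[ok] - 1)
    }
  }
  tibble(element = seq_len(m),
         label = ref_mesh$element_labels,
         area_strain = area_strain,
         fibre_strain = fibre_strain)
}

#' Global and regional strain transients
#'
#' Per frame, per-element strains are computed against frame 0 and averaged:
#' globally over all body elements and within each wall region.  Rim elements
#' are excluded.  Averages are unweighted element means by default; set
#' `area_weighted = TRUE` for reference-area weighting.
#'
#' @param meshes list of per-frame [surface_mesh()] objects with identical
#'   topology (frame 1 of the list = reference frame 0)
#' @param fibres M x 3 matrix of per-element unit fibre directions (rows for
#'   non-body elements may be `NA`)
#' @param regions character vector of per-element wall labels (`NA` for
#'   non-body elements)
#' @param area_weighted weight the element means by reference element area
#' @return tibble of class `strain_transients` with columns `frame`,
#'   `metric` (`"area"`/`"fibre"`), `scope` (`"global"` or region name) and
#'   `value` (percent strain)
#' @export
strain_transients <- function(meshes, fibres, regions, area_weighted = FALSE) {
  ref <- meshes[[1]]
  body <- ref$element_labels == "body"
  if (!any(body)) abort("mesh has no body elements")
  regs <- unique(regions[body & !is.na(regions)])
  if (any(is.na(regions[body])))
    abort("every body element needs a region label")
  for (r in regs) if (!any(regions[body] == r)) abort("empty region")
  w <- if (area_weighted) triangle_areas(ref) else rep(1, nrow(ref$triangles))

  rows <- list()
  for (f in seq_along(meshes)) {
    st <- element_strain_table(ref, meshes[[f]], fibres)
    for (metric in c("area", "fibre")) {
      vals <- if (metric == "area") st$area_strain else st$fibre_strain
      sel <- body & !is.na(vals)
      gl <- sum(vals[sel] * w[sel]) / sum(w[sel])
      rr <- vapply(regs, function(r) {
        s <- sel & regions == r
        sum(vals[s] * w[s]) / sum(w[s])
      }, numeric(1))
      rows[[length(rows) + 1L]] <- tibble(
        frame = f - 1L, metric = metric,
        scope = c("global", regs), value = c(gl, rr))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("strain_transients", class(out))
  out
}

#' Reservoir strain of a transient
#'
#' Maximum minus minimum strain over the cycle, which is robust to ECG
#' mis-triggering of the reference frame.
#' @param transient numeric vector of per-frame strain values (percent)
#' @return reservoir strain (percent)
#' @export
reservoir_strain <- function(transient) {
  if (length(transient) < 2) abort("transient needs at least 2 frames")
  max(transient) - min(transient)
}

#' Normalised regional strains and dyssynchrony interval
#'
#' Normalised regional reservoir strain is
#' `(reservoir_region - reservoir_global) / reservoir_global`; negative values
#' flag regions straining less than the global average.  The dyssynchrony
#' interval `delta_t` is the range (max - min) of the frames at which the
#' regional transients peak; argmax ties resolve to the earliest frame.
#'
#' @param transients a [strain_transients()] tibble
#' @return list with `normalised` (tibble: metric, scope, reservoir,
#'   normalised) and `delta_t` (tibble: metric, delta_t in frames)
#' @export
regional_markers <- function(transients) {
  res <- dplyr::summarise(
    dplyr::group_by(transients, .data$metric, .data$scope),
    reservoir = reservoir_strain(.data$value),
    peak_frame = .data$frame[which.max(.data$value)],
    .groups = "drop")
  norm_rows <- list()
  dt_rows <- list()
  for (m in unique(res$metric)) {
    rm <- res[res$metric == m, ]
    g <- rm$reservoir[rm$scope == "global"]
    if (g == 0) abort("global reservoir strain is zero; normalisation undefined")
    reg <- rm[rm$scope != "global", ]
    norm_rows[[m]] <- tibble(metric = m, scope = reg$scope,
                             reservoir = reg$reservoir,
                             normalised = (reg$reservoir - g) / g)
    dt_rows[[m]] <- tibble(metric = m,
                           delta_t = max(reg$peak_frame) - min(reg$peak_frame))
  }
  list(normalised = dplyr::bind_rows(norm_rows),
       delta_t = dplyr::bind_rows(dt_rows),
       reservoir = res)
}

#' Chamber volume metrics over the cycle
#'
#' Orifices are capped with centroid fans, volumes computed by the divergence
#' theorem, and converted to ml.  End-diastolic volume is the frame-0 volume;
#' the emptying fraction is `100 * (Vmax - Vmin) / Vmax`.
#'
#' @param meshes list of per-frame [surface_mesh()] objects
#' @return list with `volumes` (tibble frame/volume_ml), `edv_ml`, `laef_pct`
#' @export
volume_metrics <- function(meshes) {
  vols <- vapply(meshes, function(m) {
    closed <- if (length(boundary_loops(m)) > 0) cap_orifices(m) else m
    if (length(boundary_loops(closed)) > 0) abort("mesh not closed after capping")
    abs(mesh_volume(closed)) / 1000
  }, numeric(1))
  list(volumes = tibble(frame = seq_along(vols) - 1L, volume_ml = vols),
       edv_ml = vols[1],
       laef_pct = 100 * (max(vols) - min(vols)) / max(vols))
}

#' Assemble a strain report
#'
#' Gathers the global and regional reservoir strains, normalised regional
#' strains, dyssynchrony intervals, chamber volume metrics and (optionally)
#' the planar 2D GLS into one object with [tidy()]/[glance()] methods.
#'
#' @param transients a [strain_transients()] tibble
#' @param meshes per-frame meshes (for volumes); optional
#' @param gls_2d optional result of [gls_2d()]
#' @return object of class `strain_report`
#' @export
strain_report <- function(transients, meshes = NULL, gls_2d = NULL) {
  mk <- regional_markers(transients)
  vol <- if (!is.null(meshes)) volume_metrics(meshes) else NULL
  structure(list(transients = transients, reservoir = mk$reservoir,
                 normalised = mk$normalised, delta_t = mk$delta_t,
                 volumes = vol, gls_2d = gls_2d),
            class = "strain_report")
}

#' @export
print.strain_report <- function(x, ...) {
  cat("<strain_report>\n")
  g <- x$reservoir[x$reservoir$scope == "global", ]
  for (i in seq_len(nrow(g)))
    cat(sprintf("  global reservoir %s strain: %.2f %%\n",
                g$metric[i], g$reservoir[i]))
  for (i in seq_len(nrow(x$delta_t)))
    cat(sprintf("  delta-T (%s): %d frames\n", x$delta_t$metric[i],
                x$delta_t$delta_t[i]))
  if (!is.null(x$volumes))
    cat(sprintf("  LA EDV: %.1f ml, LAEF: %.1f %%\n",
                x$volumes$edv_ml, x$volumes$laef_pct))
  if (!is.null(x$gls_2d))
    cat(sprintf("  2D GLS: %.2f %%\n", x$gls_2d$gls))
  invisible(x)
}

#' @export
tidy.strain_report <- function(x, ...) {
  out <- dplyr::left_join(
    x$reservoir[, c("metric", "scope", "reservoir", "peak_frame")],
    x$normalised[, c("metric", "scope", "normalised")],
    by = c("metric", "scope"))
  out
}

#' @export
glance.strain_report <- function(x, ...) {
  g <- x$reservoir[x$reservoir$scope == "global", ]
  out <- tibble(
    reservoir_area = g$reservoir[g$metric == "area"],
    reservoir_fibre = g$reservoir[g$metric == "fibre"],
    delta_t_area = x$delta_t$delta_t[x$delta_t$metric == "area"],
    delta_t_fibre = x$delta_t$delta_t[x$delta_t$metric == "fibre"])
  if (!is.null(x$volumes)) {
    out$edv_ml <- x$volumes$edv_ml
    out$laef_pct <- x$volumes$laef_pct
  }
  if (!is.null(x$gls_2d)) out$gls_2d <- x$gls_2d$gls
  out
}
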