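#' Triangulated endocardial surface mesh
#'
#' Container for a triangulated left-atrial endocardial surface.  Vertices are
#' world coordinates in millimetres; triangles index into the vertex table
#' (1-based).  Each triangle carries an element label: `"body"` for the atrial
#' wall proper, or a rim label (`"mv_rim"`, `"pv_rim_1"` ... `"pv_rim_4"`,
#' `"laa_rim"`) for elements adjacent to an orifice boundary.  Rim elements are
#' excluded from all strain averages.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm)
#' @param triangles integer M x 3 matrix of 1-based vertex indices
#' @param element_labels character vector of length M (default all `"body"`)
#' @param vertex_labels optional named integer vector tagging landmark vertices
#' @return an object of class `surface_mesh`
#' @export
surface_mesh <- function(vertices, triangles, element_labels = NULL,
                         vertex_labels = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3L) abort("`vertices` must be an N x 3 matrix")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    abort("triangle indices out of bounds")
  if (is.null(element_labels)) element_labels <- rep("body", nrow(triangles))
  if (length(element_labels) != nrow(triangles))
    abort("`element_labels` must have one entry per triangle")
  m <- structure(list(vertices = vertices, triangles = triangles,
                      element_labels = as.character(element_labels),
                      vertex_labels = vertex_labels),
                 class = "surface_mesh")
  a <- triangle_areas(m)
  if (any(a < 1e-9)) abort("mesh contains degenerate triangles (area < 1e-9 mm^2)")
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles (",
      sum(x$element_labels == "body"), " body)\n", sep = "")
  invisible(x)
}

#' Per-triangle areas, normals and centroids
#'
#' @param mesh a [surface_mesh()]
#' @return `triangle_areas`: numeric vector of areas (mm^2);
#'   `triangle_normals`: M x 3 matrix of unit outward normals;
#'   `triangle_centroids`: M x 3 matrix (mm).
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cx^2))
}

#' @rdname triangle_areas
#' @export
triangle_normals <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cx / sqrt(rowSums(cx^2))
}

#' @rdname triangle_areas
#' @export
triangle_centroids <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  (v[tr[, 1], , drop = FALSE] + v[tr[, 2], , drop = FALSE] +
     v[tr[, 3], , drop = FALSE]) / 3
}

# unique undirected edges, M3 x 2, ordered pairs
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Euler characteristic V - E + F
#'
#' A closed sphere-topology surface has characteristic 2; removing each open
#' disc (orifice) subtracts 1.
#' @param mesh a [surface_mesh()]
#' @return integer
#' @export
euler_characteristic <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  used <- sort(unique(as.vector(mesh$triangles)))
  length(used) - nrow(e) + nrow(mesh$triangles)
}

# boundary edges: edges used by exactly one triangle
boundary_edges <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  ids <- names(tab)[tab == 1L]
  e[match(ids, key), , drop = FALSE]
}

# split boundary edges into closed loops (list of vertex index cycles)
boundary_loops <- function(mesh) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) return(list())
  adj <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  visited <- character(0)
  loops <- list()
  for (start in unique(as.vector(be))) {
    if (as.character(start) %in% visited) next
    loop <- start
    prev <- NA_integer_
    cur <- start
    repeat {
      nxt <- setdiff(adj[[as.character(cur)]], prev)
      nxt <- nxt[!nxt %in% loop[-1]]
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      if (nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
    }
    visited <- c(visited, as.character(loop))
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Close orifices with fan caps
#'
#' Each boundary loop is triangulated as a fan from its centroid, producing a
#' closed surface suitable for volume computation and rasterisation.  Cap
#' elements are labelled `"cap"`.
#' @param mesh a [surface_mesh()] with boundary loops
#' @return a closed `surface_mesh`
#' @export
cap_orifices <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (length(loops) == 0) return(mesh)
  v <- mesh$vertices; tr <- mesh$triangles; lab <- mesh$element_labels
  for (loop in loops) {
    cen <- colMeans(v[loop, , drop = FALSE])
    v <- rbind(v, cen)
    ci <- nrow(v)
    n <- length(loop)
    newt <- cbind(loop, c(loop[-1], loop[1]), rep(ci, n))
    tr <- rbind(tr, newt)
    lab <- c(lab, rep("cap", n))
  }
  out <- surface_mesh(v, tr, lab, mesh$vertex_labels)
  orient_consistently(out)
}

# Make triangle winding consistent across the mesh by flood fill, then flip
# globally if the signed volume is negative (closed meshes only).
orient_consistently <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  keys <- ekey(e[, 1], e[, 2])
  tri_of <- rep(seq_len(m), 3)
  by_edge <- split(seq_along(keys), keys)
  flipped <- rep(FALSE, m)
  seen <- rep(FALSE, m)
  for (seed in seq_len(m)) {
    if (seen[seed]) next
    queue <- seed
    seen[seed] <- TRUE
    while (length(queue)) {
      t0 <- queue[[1]]; queue <- queue[-1]
      dir0 <- directed_edges(tr[t0, ], flipped[t0])
      for (r in 1:3) {
        k <- ekey(dir0[r, 1], dir0[r, 2])
        others <- setdiff(tri_of[by_edge[[k]]], t0)
        for (t1 in others) {
          if (seen[t1]) next
          dir1 <- directed_edges(tr[t1, ], FALSE)
          shares_same <- any(dir1[, 1] == dir0[r, 1] & dir1[, 2] == dir0[r, 2])
          flipped[t1] <- shares_same  # consistent orientation = opposite directed edge
          seen[t1] <- TRUE
          queue <- c(queue, t1)
        }
      }
    }
  }
  tr[flipped, ] <- tr[flipped, c(1, 3, 2)]
  out <- mesh
  out$triangles <- tr
  if (length(boundary_loops(out)) == 0 && mesh_volume(out) < 0)
    out$triangles <- out$triangles[, c(1, 3, 2)]
  out
}

directed_edges <- function(t3, flip) {
  if (flip) t3 <- t3[c(1, 3, 2)]
  rbind(t3[c(1, 2)], t3[c(2, 3)], t3[c(3, 1)])
}

#' Signed volume of a closed mesh
#'
#' Divergence-theorem volume over the triangles; positive for outward
#' orientation.
#' @param mesh a closed [surface_mesh()]
#' @return volume in mm^3
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# connected components over triangles sharing an edge, restricted to a subset
triangle_components <- function(mesh, subset = NULL) {
  tr <- mesh$triangles
  if (is.null(subset)) subset <- seq_len(nrow(tr))
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  e <- rbind(tr[subset, c(1, 2), drop = FALSE],
             tr[subset, c(2, 3), drop = FALSE],
             tr[subset, c(3, 1), drop = FALSE])
  keys <- ekey(e[, 1], e[, 2])
  tri_of <- rep(subset, 3)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("t", tri_of), to = keys), directed = FALSE)
  comp <- igraph::components(g)$membership
  memb <- comp[paste0("t", subset)]
  split(subset, memb)
}

# vertex adjacency graph with Euclidean edge weights (for geodesic paths)
mesh_graph <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  v <- mesh$vertices
  w <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  g <- igraph::make_empty_graph(n = nrow(v), directed = FALSE)
  g <- igraph::add_edges(g, t(e))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic vertex path between two vertices
#'
#' Shortest path along mesh edges with Euclidean weights.
#' @param mesh a [surface_mesh()]
#' @param from,to vertex indices
#' @return integer vector of vertex indices
#' @export
geodesic_path <- function(mesh, from, to) {
  g <- mesh_graph(mesh)
  p <- igraph::shortest_paths(g, from, to, output = "vpath")$vpath[[1]]
  as.integer(p)
}

# nearest mesh vertex to a world point
nearest_vertex <- function(mesh, point) {
  d2 <- rowSums(sweep(mesh$vertices, 2, point)^2)
  which.min(d2)
}
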