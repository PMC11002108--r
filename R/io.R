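#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti keeping the package's `spacing`/`origin`
#' attribute convention in sync with the NIfTI sform.
#'
#' @param img 3D array with `spacing` and `origin` attributes
#' @param path output `.nii` / `.nii.gz` path
#' @return `read_image_nifti` returns the array with attributes set
#' @export
write_image_nifti <- function(img, path) {
  spacing <- attr(img, "spacing") %||% c(1, 1, 1)
  origin <- attr(img, "origin") %||% c(0, 0, 0)
  ni <- RNifti::asNifti(array(as.numeric(img), dim(img)))
  RNifti::pixdim(ni) <- spacing
  m <- diag(4)
  m[1:3, 1:3] <- diag(spacing)
  m[1:3, 4] <- origin
  ni <- RNifti::`sform<-`(ni, structure(m, code = 2L))
  ni <- RNifti::`qform<-`(ni, structure(m, code = 2L))
  RNifti::writeNifti(ni, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  ni <- RNifti::readNifti(path)
  x <- RNifti::xform(ni)
  img <- array(as.numeric(ni), dim(ni))
  attr(img, "spacing") <- abs(diag(x)[1:3])
  attr(img, "origin") <- x[1:3, 4]
  img
}

#' Read and write volumes as MetaImage (.mha)
#'
#' Minimal uncompressed single-file MetaImage support (text header,
#' little-endian float64 payload), written here because no installed R
#' package reads the format.
#'
#' @inheritParams write_image_nifti
#' @export
write_image_mha <- function(img, path) {
  spacing <- attr(img, "spacing") %||% c(1, 1, 1)
  origin <- attr(img, "origin") %||% c(0, 0, 0)
  d <- dim(img)
  hdr <- paste0(
    "ObjectType = Image\nNDims = 3\nBinaryData = True\n",
    "BinaryDataByteOrderMSB = False\nCompressedData = False\n",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1\n",
    "Offset = ", paste(origin, collapse = " "), "\n",
    "CenterOfRotation = 0 0 0\n",
    "ElementSpacing = ", paste(spacing, collapse = " "), "\n",
    "DimSize = ", paste(d, collapse = " "), "\n",
    "ElementType = MET_DOUBLE\nElementDataFile = LOCAL\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.numeric(img), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_image_mha
#' @export
read_image_mha <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  txt_end <- grepRaw("ElementDataFile = LOCAL\n", raw) +
    nchar("ElementDataFile = LOCAL\n") - 1
  hdr_lines <- strsplit(rawToChar(raw[1:txt_end]), "\n")[[1]]
  gv <- function(key) {
    ln <- grep(paste0("^", key, " ="), hdr_lines, value = TRUE)
    strsplit(sub(paste0(key, " = "), "", ln), " ")[[1]]
  }
  d <- as.integer(gv("DimSize"))
  spacing <- as.numeric(gv("ElementSpacing"))
  origin <- as.numeric(gv("Offset"))
  vals <- readBin(raw[(txt_end + 1):length(raw)], "numeric", prod(d),
                  size = 8, endian = "little")
  img <- array(vals, d)
  attr(img, "spacing") <- spacing
  attr(img, "origin") <- origin
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write meshes as legacy ASCII VTK polydata
#'
#' Element labels travel as an integer `CELL_DATA` array plus a label
#' dictionary in the VTK title line, so a written mesh round-trips.
#'
#' @param mesh a [surface_mesh()]
#' @param path `.vtk` file path
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  labs <- unique(mesh$element_labels)
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("labels=", paste(labs, collapse = ",")),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(mesh$vertices), "double")), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  m <- nrow(mesh$triangles)
  writeLines(paste("POLYGONS", m, 4 * m), con)
  write(t(cbind(3L, mesh$triangles - 1L)), con, ncolumns = 4)
  writeLines(c(paste("CELL_DATA", m), "SCALARS element_label int 1",
               "LOOKUP_TABLE default"), con)
  write(match(mesh$element_labels, labs) - 1L, con, ncolumns = 9)
  invisible(path)
}

#' @rdname write_mesh_vtk
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  labs <- NULL
  if (grepl("^labels=", lines[2]))
    labs <- strsplit(sub("^labels=", "", lines[2]), ",")[[1]]
  ip <- grep("^POINTS", lines)
  np <- as.integer(strsplit(lines[ip], " +")[[1]][2])
  pts <- scan(text = paste(lines[(ip + 1):length(lines)], collapse = "\n"),
              n = 3 * np, quiet = TRUE)
  v <- matrix(pts, ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)
  m <- as.integer(strsplit(lines[it], " +")[[1]][2])
  polys <- scan(text = paste(lines[(it + 1):length(lines)], collapse = "\n"),
                n = 4 * m, quiet = TRUE)
  pm <- matrix(polys, ncol = 4, byrow = TRUE)
  tri <- pm[, 2:4, drop = FALSE] + 1L
  el <- NULL
  il <- grep("^LOOKUP_TABLE", lines)
  if (length(il) && !is.null(labs)) {
    codes <- scan(text = paste(lines[(il[1] + 1):length(lines)], collapse = "\n"),
                  n = m, quiet = TRUE)
    el <- labs[codes + 1L]
  }
  surface_mesh(v, tri, el)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [surface_mesh()]
#' @param path `.ply` file path
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$triangles)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  write(t(cbind(3L, mesh$triangles - 1L)), con, ncolumns = 4)
  invisible(path)
}

#' Read and write landmark sets as JSON
#'
#' Format: an object mapping landmark names to `[x, y, z]` (mm).
#' @param landmarks named list of 3-vectors
#' @param path JSON path
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, as.numeric), path, digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(js, as.numeric)
}

#' Serialise a motion field to JSON
#'
#' The JSON carries the lattice geometry (origins, spacings, dims, temporal
#' counts, frame count) and the coefficient arrays.
#'
#' @param motion a [motion_field()]
#' @param path JSON path
#' @export
write_motion_field <- function(motion, path) {
  jsonlite::write_json(
    list(n_frames = motion$n_frames,
         levels = lapply(motion$levels, function(l)
           list(origin = l$origin, spacing = l$spacing, dims = l$dims,
                n_temporal = l$n_temporal, coef = l$coef))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_motion_field
#' @export
read_motion_field <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  levels <- lapply(seq_len(nrow(js$levels)), function(i) {
    l <- js$levels[i, ]
    bspline_lattice(unlist(l$origin), unlist(l$spacing),
                    unlist(l$dims), l$n_temporal, unlist(l$coef))
  })
  motion_field(levels, js$n_frames)
}

#' Write a strain report to CSV and JSON
#'
#' `transients.csv` (frame-level curves), `markers.csv` (reservoir and
#' normalised regional strains), and `summary.json` (scalar markers).
#'
#' @param report a [strain_report()]
#' @param dir output directory (created if needed)
#' @param seed seed recorded in the summary for provenance
#' @return the directory, invisibly
#' @export
write_strain_report <- function(report, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$transients, file.path(dir, "transients.csv"),
            row.names = FALSE)
  write.csv(tidy(report), file.path(dir, "markers.csv"), row.names = FALSE)
  jsonlite::write_json(c(as.list(glance(report)), list(seed = seed)),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
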