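# Mesh interchange. Canonical fixture format is the CSV dialect:
#   vertices.csv: vertex_id, x_mm, y_mm, z_mm, label   (0-based vertex_id)
#   faces.csv:    v0, v1, v2                           (0-based indices)
# PLY (ascii), OBJ and VTK legacy polydata are supported with labels in a
# sidecar CSV (vertex_id, label; 0-based) when the format carries none.

#' Load an atrial surface mesh
#'
#' @param path mesh file (`.ply`, `.obj`, `.vtk`) or, for
#'   `format = "csv"`, the vertices CSV (its companion `*faces*.csv` is
#'   found by replacing "vertices" with "faces" in the filename, or may be
#'   given via `faces_path`).
#' @param format one of `"ply"`, `"obj"`, `"vtk"`, `"csv"`; default guessed
#'   from the extension.
#' @param labels_path optional sidecar CSV with columns
#'   `vertex_id` (0-based), `label`.
#' @param faces_path companion faces CSV for `format = "csv"`.
#' @return An [atrial_surface()].
#' @export
load_surface <- function(path, format = NULL, labels_path = NULL,
                         faces_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "obj", "vtk", "csv"))
  m <- switch(format,
              ply = read_ply_ascii(path),
              obj = read_obj(path),
              vtk = read_vtk_polydata(path),
              csv = read_mesh_csv(path, faces_path))
  labels <- m$labels
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path)
    labels <- rep(NA_character_, nrow(m$vertices))
    labels[lab$vertex_id + 1L] <- as.character(lab$label)
    if (anyNA(labels)) stop("label sidecar does not cover every vertex")
  }
  atrial_surface(m$vertices, m$faces, labels)
}

#' Save an atrial surface mesh
#'
#' @param surface an [atrial_surface()].
#' @param path output file; extension selects the format unless `format`
#'   is given. For `"csv"`, `path` is the vertices CSV and a faces CSV is
#'   written next to it.
#' @param format `"ply"`, `"obj"`, `"vtk"` or `"csv"`.
#' @param labels_path optional path for a label sidecar CSV (written for
#'   ply/obj/vtk when the surface is labelled and `labels_path` is given).
#' @return Invisibly `path`.
#' @export
save_surface <- function(surface, path, format = NULL, labels_path = NULL) {
  stopifnot(inherits(surface, "atrial_surface"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("ply", "obj", "vtk", "csv"))
  switch(format,
         ply = write_ply_ascii(surface, path),
         obj = write_obj(surface, path),
         vtk = write_vtk_polydata(surface, path),
         csv = write_mesh_csv(surface, path))
  if (!is.null(labels_path) && !is.null(surface$labels) && format != "csv") {
    utils::write.csv(data.frame(vertex_id = seq_len(nrow(surface$vertices)) - 1L,
                                label = surface$labels),
                     labels_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

read_mesh_csv <- function(vertices_path, faces_path = NULL) {
  if (is.null(faces_path))
    faces_path <- sub("vertices", "faces", vertices_path, fixed = TRUE)
  if (identical(faces_path, vertices_path) || !file.exists(faces_path))
    stop("faces CSV not found for ", vertices_path)
  vd <- utils::read.csv(vertices_path)
  fd <- utils::read.csv(faces_path)
  need <- c("vertex_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(vd)))
    stop("vertices CSV needs columns: ", paste(need, collapse = ", "))
  if (!all(c("v0", "v1", "v2") %in% names(fd)))
    stop("faces CSV needs columns v0, v1, v2")
  ord <- order(vd$vertex_id)
  vd <- vd[ord, ]
  if (!identical(as.integer(vd$vertex_id), seq_len(nrow(vd)) - 1L))
    stop("vertex_id must be 0..n-1")
  labels <- if ("label" %in% names(vd)) as.character(vd$label) else NULL
  list(vertices = cbind(vd$x_mm, vd$y_mm, vd$z_mm),
       faces = cbind(fd$v0, fd$v1, fd$v2) + 1L,
       labels = labels)
}

write_mesh_csv <- function(surface, vertices_path) {
  faces_path <- sub("vertices", "faces", vertices_path, fixed = TRUE)
  if (identical(faces_path, vertices_path))
    stop("vertices CSV filename must contain 'vertices' so the faces file ",
         "can be named")
  vd <- data.frame(vertex_id = seq_len(nrow(surface$vertices)) - 1L,
                   x_mm = surface$vertices[, 1],
                   y_mm = surface$vertices[, 2],
                   z_mm = surface$vertices[, 3])
  if (!is.null(surface$labels)) vd$label <- surface$labels
  utils::write.csv(vd, vertices_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(v0 = surface$faces[, 1] - 1L,
                              v1 = surface$faces[, 2] - 1L,
                              v2 = surface$faces[, 3] - 1L),
                   faces_path, row.names = FALSE, quote = FALSE)
}

read_ply_ascii <- function(path) {
  head <- readLines(path, n = 100)
  if (head[1] != "ply") stop("not a PLY file: ", path)
  if (!any(grepl("^format ascii", head)))
    stop("only ascii PLY is supported (binary PLY detected in ", path, ")")
  endh <- which(head == "end_header")[1]
  if (is.na(endh)) stop("PLY header not terminated within 100 lines")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", head, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", head, value = TRUE)))
  body <- readLines(path)[-(1:endh)]
  vparts <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                  function(x) as.numeric(x[1:3])))
  frows <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  fparts <- do.call(rbind, lapply(frows, function(x) {
    if (as.integer(x[1]) != 3) stop("non-triangular face in PLY")
    as.integer(x[2:4])
  }))
  list(vertices = vparts, faces = fparts + 1L, labels = NULL)
}

write_ply_ascii <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
}

read_obj <- function(path) {
  ln <- readLines(path)
  vlines <- grep("^v ", ln, value = TRUE)
  flines <- grep("^f ", ln, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(vlines, "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) {
    idx <- sub("/.*", "", x[-1])
    if (length(idx) != 3) stop("non-triangular face in OBJ")
    as.integer(idx)
  }))
  list(vertices = v, faces = f, labels = NULL)
}

write_obj <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  writeLines(c(paste("v", v[, 1], v[, 2], v[, 3]),
               paste("f", f[, 1], f[, 2], f[, 3])), path)
}

read_vtk_polydata <- function(path) {
  ln <- readLines(path)
  if (!grepl("ASCII", ln[3]))
    stop("only ASCII legacy VTK is supported")
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  # collect numbers until 3*np values read
  vals <- numeric(0)
  i <- ip + 1
  while (length(vals) < 3 * np) {
    vals <- c(vals, as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  v <- matrix(vals[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  ipoly <- grep("^POLYGONS", ln)[1]
  hdr <- as.integer(strsplit(ln[ipoly], "\\s+")[[1]][2:3])
  fvals <- integer(0)
  i <- ipoly + 1
  while (length(fvals) < hdr[2]) {
    fvals <- c(fvals, as.integer(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  f <- matrix(fvals, ncol = 4, byrow = TRUE)
  if (any(f[, 1] != 3)) stop("non-triangular polygon in VTK")
  list(vertices = v, faces = f[, 2:4, drop = FALSE] + 1L, labels = NULL)
}

# Writes legacy VTK polydata; optional named per-vertex scalar array
# (used for atlas output).
write_vtk_polydata <- function(surface, path, scalars = NULL,
                               scalars_name = "probability") {
  v <- surface$vertices
  f <- surface$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "atrial surface", "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(v), "float")), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(paste("POLYGONS", nrow(f), 4 * nrow(f)), con)
  writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  if (!is.null(scalars)) {
    writeLines(c(paste("POINT_DATA", nrow(v)),
                 paste("SCALARS", scalars_name, "float 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(ifelse(is.na(scalars), -1, scalars)), con)
  }
}
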