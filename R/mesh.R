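# Labelled triangulated left-atrial surface: vertices (mm), triangle faces,
# per-vertex anatomical region labels.

#' Region labels used on an atrial surface
#' @export
ATRIAL_REGIONS <- c("BODY", "LSPV", "RSPV", "LIPV", "RIPV", "MV_RIM")

#' Pulmonary-vein region labels
#' @export
PV_LABELS <- c("LSPV", "RSPV", "LIPV", "RIPV")

#' Construct a labelled atrial surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates in mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices
#'   (triangles only).
#' @param labels character vector of length n with values in
#'   [ATRIAL_REGIONS] (anything outside the list is an error). May be
#'   `NULL` for unlabelled meshes (registration then unavailable).
#' @param validate run [validate_surface()] (default TRUE).
#' @return An object of class `atrial_surface`.
#' @export
atrial_surface <- function(vertices, faces, labels = NULL, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be n x 3")
  if (ncol(faces) != 3) stop("faces must be triangles (m x 3)")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(vertices))
      stop("labels must have one entry per vertex")
    bad <- setdiff(unique(labels), ATRIAL_REGIONS)
    if (length(bad))
      stop("unknown region labels: ", paste(bad, collapse = ", "))
  }
  s <- structure(list(vertices = vertices, faces = faces, labels = labels),
                 class = "atrial_surface")
  if (validate) validate_surface(s)
  if (is.null(labels) || !all(PV_LABELS %in% labels))
    if (!is.null(labels))
      warning("not all four PV labels present; registration unavailable")
  s
}

#' Validate an atrial surface mesh
#'
#' Checks face indices, absence of unreferenced vertices and of degenerate
#' (zero-area) triangles. Errors name the first offending face.
#'
#' @param surface an `atrial_surface`.
#' @return Invisibly `TRUE`.
#' @export
validate_surface <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  if (any(f < 1) || any(f > nrow(v))) stop("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3])) {
    bad <- which(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3])[1]
    stop("degenerate face (repeated vertex) at face ", bad)
  }
  unref <- setdiff(seq_len(nrow(v)), unique(as.vector(f)))
  if (length(unref))
    stop("unreferenced vertices present (e.g. vertex ", unref[1], ")")
  a <- face_areas(surface)
  if (any(a <= 1e-12)) {
    stop("zero-area triangle at face ", which(a <= 1e-12)[1])
  }
  invisible(TRUE)
}

#' @export
print.atrial_surface <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabelled"
         else paste(names(table(x$labels)), table(x$labels),
                    sep = ":", collapse = " ")
  cat(sprintf("<atrial_surface> %d vertices, %d faces (%s)\n",
              nrow(x$vertices), nrow(x$faces), lab))
  invisible(x)
}

#' Per-face triangle areas (mm^2)
#' @param surface an `atrial_surface`.
#' @return numeric vector of face areas.
#' @export
face_areas <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area (mm^2)
#' @param surface an `atrial_surface`.
#' @export
surface_area <- function(surface) sum(face_areas(surface))

# Unique undirected edges as a 2-column matrix of vertex indices.
mesh_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Boundary vertices: endpoints of edges used by exactly one face.
boundary_vertices <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  once <- names(cnt)[cnt == 1L]
  if (!length(once)) return(integer(0))
  parts <- do.call(rbind, strsplit(once, " "))
  sort(unique(as.integer(parts)))
}

# Discrete curvature measure per vertex: (|k1| + |k2|)/2 from the
# cotangent-Laplacian mean curvature and angle-deficit Gaussian curvature.
# Boundary vertices get NA (their one-ring is incomplete).
vertex_curvature <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  n <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]
  p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  cot_at <- function(a, b, c) {
    # cotangent of the angle at a, in triangle (a, b, c)
    u <- b - a; w <- c - a
    dot <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    dot / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-300)
  }
  c1 <- cot_at(p1, p2, p3) # angle at vertex 1, opposite edge (2,3)
  c2 <- cot_at(p2, p3, p1)
  c3 <- cot_at(p3, p1, p2)
  # cotangent weights per undirected edge
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  ww <- 0.5 * c(c1, c1, c2, c2, c3, c3)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  deg <- Matrix::rowSums(W)
  L <- W - Matrix::Diagonal(n, deg) # Laplacian: L x ~ -2 A H n
  lx <- as.numeric(L %*% v[, 1])
  ly <- as.numeric(L %*% v[, 2])
  lz <- as.numeric(L %*% v[, 3])
  area3 <- rep(face_areas(surface) / 3, 3)
  A <- as.numeric(Matrix::sparseMatrix(i = c(i1, i2, i3),
                                       j = rep(1L, 3 * nrow(f)),
                                       x = area3, dims = c(n, 1)))
  H <- sqrt(lx^2 + ly^2 + lz^2) / (2 * pmax(A, 1e-300)) # |mean curvature|
  # Gaussian curvature via angle deficit
  ang_at <- function(a, b, c) {
    u <- b - a; w <- c - a
    acos(pmin(1, pmax(-1, rowSums(u * w) /
                        (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2))))))
  }
  a1 <- ang_at(p1, p2, p3); a2 <- ang_at(p2, p3, p1); a3 <- ang_at(p3, p1, p2)
  angsum <- as.numeric(Matrix::sparseMatrix(i = c(i1, i2, i3),
                                            j = rep(1L, 3 * nrow(f)),
                                            x = c(a1, a2, a3),
                                            dims = c(n, 1)))
  K <- (2 * pi - angsum) / pmax(A, 1e-300)
  m <- ifelse(K < 0, sqrt(pmax(H^2 - K, 0)), H)
  m[boundary_vertices(surface)] <- NA_real_
  m
}

# Intersection of a plane (point p0, unit normal nrm) with the mesh,
# optionally restricted to a face subset. Returns a list of closed
# polylines, each a list(points = k x 3 matrix in traversal order).
mesh_plane_intersection <- function(surface, p0, nrm, face_subset = NULL) {
  v <- surface$vertices
  f <- surface$faces
  if (!is.null(face_subset)) f <- f[face_subset, , drop = FALSE]
  s <- as.numeric((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% nrm)
  s[s == 0] <- 1e-12 # nudge exact hits off the plane for robustness
  sf <- matrix(s[f], ncol = 3)
  crosses <- (sf[, 1] * sf[, 2] < 0) + (sf[, 2] * sf[, 3] < 0) +
             (sf[, 3] * sf[, 1] < 0)
  fi <- which(crosses == 2)
  if (!length(fi)) return(list())
  edge_id <- function(i, j) paste(pmin(i, j), pmax(i, j))
  # for each crossing face, the two crossed edges and intersection points
  segs_from <- character(0); segs_to <- character(0)
  pts <- list()
  edge_point <- function(i, j) {
    t <- s[i] / (s[i] - s[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  seg_a <- vector("list", length(fi)); seg_b <- vector("list", length(fi))
  ida <- character(length(fi)); idb <- character(length(fi))
  wt_of <- list() # per crossed edge: endpoints and interpolation parameter
  for (k in seq_along(fi)) {
    tri <- f[fi[k], ]
    combs <- rbind(tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    hit <- which(s[combs[, 1]] * s[combs[, 2]] < 0)
    e1 <- combs[hit[1], ]; e2 <- combs[hit[2], ]
    seg_a[[k]] <- edge_point(e1[1], e1[2])
    seg_b[[k]] <- edge_point(e2[1], e2[2])
    ida[k] <- edge_id(e1[1], e1[2])
    idb[k] <- edge_id(e2[1], e2[2])
    wt_of[[ida[k]]] <- c(e1[1], e1[2], s[e1[1]] / (s[e1[1]] - s[e1[2]]))
    wt_of[[idb[k]]] <- c(e2[1], e2[2], s[e2[1]] / (s[e2[1]] - s[e2[2]]))
  }
  # chain segments: nodes are crossed edges, links are faces
  all_ids <- unique(c(ida, idb))
  pt_of <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (k in seq_along(fi)) { pt_of[[ida[k]]] <- seg_a[[k]]
                             pt_of[[idb[k]]] <- seg_b[[k]] }
  nbr <- stats::setNames(vector("list", length(all_ids)), all_ids)
  for (k in seq_along(fi)) {
    nbr[[ida[k]]] <- c(nbr[[ida[k]]], idb[k])
    nbr[[idb[k]]] <- c(nbr[[idb[k]]], ida[k])
  }
  visited <- stats::setNames(rep(FALSE, length(all_ids)), all_ids)
  curves <- list()
  for (start in all_ids) {
    if (visited[[start]]) next
    path <- character(0)
    cur <- start; prev <- NA_character_
    repeat {
      visited[[cur]] <- TRUE
      path <- c(path, cur)
      nxt <- setdiff(nbr[[cur]], prev)
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[1]
    }
    closed <- start %in% nbr[[path[length(path)]]] && length(path) > 2
    pts_mat <- do.call(rbind, pt_of[path])
    ew <- do.call(rbind, wt_of[path])
    curves[[length(curves) + 1]] <- list(points = pts_mat, closed = closed,
                                         edge_i = ew[, 1], edge_j = ew[, 2],
                                         edge_t = ew[, 3])
  }
  curves
}

# Closest points on the mesh to a set of query points.
# Returns list(points = n x 3, distance, face).
project_points_onto_surface <- function(surface, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  v <- surface$vertices
  f <- surface$faces
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  cent <- (A + B + C) / 3
  rad <- sqrt(pmax(rowSums((A - cent)^2),
                   rowSums((B - cent)^2),
                   rowSums((C - cent)^2)))
  out_p <- matrix(NA_real_, nrow(pts), 3)
  out_d <- numeric(nrow(pts))
  out_f <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    dc <- sqrt(colSums((t(cent) - p)^2))
    ub <- min(dc + rad)
    keep <- which(dc - rad <= ub + 1e-9)
    cp <- closest_point_on_triangles(p, A[keep, , drop = FALSE],
                                     B[keep, , drop = FALSE],
                                     C[keep, , drop = FALSE])
    j <- which.min(cp$d2)
    out_p[i, ] <- cp$pts[j, ]
    out_d[i] <- sqrt(cp$d2[j])
    out_f[i] <- keep[j]
  }
  list(points = out_p, distance = out_d, face = out_f)
}

# Vectorised closest point from p to each triangle (A, B, C).
# Ericson, Real-Time Collision Detection, 5.1.5.
closest_point_on_triangles <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  res <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set <- function(idx, val) {
    res[idx & !done, ] <<- val[idx & !done, , drop = FALSE]
    done <<- done | idx
  }
  set(d1 <= 0 & d2 <= 0, A)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  set(d3 >= 0 & d4 <= d3, B)
  vc <- d1 * d4 - d3 * d2
  vv <- ifelse(abs(d1 - d3) < 1e-300, 0, d1 / (d1 - d3))
  set(vc <= 0 & d1 >= 0 & d3 <= 0, A + vv * ab)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  set(d6 >= 0 & d5 <= d6, C)
  vb <- d5 * d2 - d1 * d6
  ww <- ifelse(abs(d2 - d6) < 1e-300, 0, d2 / (d2 - d6))
  set(vb <= 0 & d2 >= 0 & d6 <= 0, A + ww * ac)
  va <- d3 * d6 - d5 * d4
  w2 <- ifelse(abs((d4 - d3) + (d5 - d6)) < 1e-300, 0,
               (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + w2 * (C - B))
  denom <- va + vb + vc
  vbn <- ifelse(abs(denom) < 1e-300, 0, vb / denom)
  vcn <- ifelse(abs(denom) < 1e-300, 0, vc / denom)
  set(rep(TRUE, n), A + vbn * ab + vcn * ac)
  list(pts = res, d2 = rowSums((res - P)^2))
}

# Subdivided icosahedron on the unit sphere.
build_icosphere <- function(subdiv = 5) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ue <- unique(e)
    key <- function(m) m[, 1] * (nrow(v) + 1) + m[, 2]
    mid_idx <- nrow(v) + match(key(e), key(ue))
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_idx[seq_len(nrow(f))]
    m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_idx[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}
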