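# Gaussian-kernel probability atlas of AVD-GP sites on the reference
# surface: per-patient kernel-normalised fields from binary site outcomes,
# masked cohort averaging, peak detection and the area-concentration
# statistic.

#' Per-patient AVD-GP probability field
#'
#' Each mapped site carries outcome probability 1 (AVD-GP of either
#' subtype) or 0 (HFS negative) and is weighted by a Gaussian kernel
#' `w_i(x) = exp(-d(x, x_i)^2 / (2 sigma^2))` with `d` the 3D Euclidean
#' distance and `sigma` the catheter-position uncertainty scale (default
#' 5 mm). The field at a vertex is the kernel-normalised weighted sum
#' `sum(p_i w_i) / sum(w_i)` — a Nadaraya-Watson estimate — and is
#' UNDEFINED (NA) where the total kernel weight falls below
#' `weight_cutoff` (default the kernel value at 3 sigma, so areas further
#' than ~3 sigma from every tested site are masked out rather than
#' extrapolated).
#'
#' @param positions n x 3 matrix of site positions on the reference
#'   surface (mm).
#' @param p binary outcome per site (1 = AVD-GP, 0 = negative).
#' @param surface the reference [atrial_surface()].
#' @param sigma_mm kernel scale in mm (> 0).
#' @param weight_cutoff minimum total kernel weight for a defined value.
#' @return An object of class `probability_field`: `values` (per vertex,
#'   NA where undefined), `coverage` (1 where defined), `sigma_mm`,
#'   `surface`.
#' @export
patient_field <- function(positions, p, surface, sigma_mm = 5,
                          weight_cutoff = exp(-4.5)) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  p <- as.numeric(p)
  if (nrow(positions) == 0) stop("at least one mapped site is required")
  if (length(p) != nrow(positions))
    stop("p must have one outcome per site")
  if (!all(p %in% c(0, 1))) stop("site outcomes must be binary (0/1)")
  if (sigma_mm <= 0) stop("sigma_mm must be positive")
  v <- surface$vertices
  d2 <- outer(rowSums(v^2), rowSums(positions^2), "+") -
    2 * v %*% t(positions)
  W <- exp(-pmax(d2, 0) / (2 * sigma_mm^2))
  tot <- rowSums(W)
  val <- as.numeric(W %*% p) / tot
  val[tot < weight_cutoff] <- NA_real_
  structure(list(values = val, coverage = as.integer(!is.na(val)),
                 sigma_mm = sigma_mm, weight_cutoff = weight_cutoff,
                 surface = surface),
            class = "probability_field")
}

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf(paste0("<probability_field> %d vertices (%d defined), ",
                     "sigma %.1f mm, range [%.3f, %.3f]\n"),
              length(x$values), sum(!is.na(x$values)), x$sigma_mm,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Average probability fields across patients
#'
#' Per-vertex masked arithmetic mean: patients whose field is undefined at
#' a vertex (no local HFS coverage) are excluded from that vertex's mean
#' rather than imputed as 0 — "not tested" is not "tested negative". The
#' per-vertex number of contributing patients is recorded as coverage.
#'
#' @param fields list of [patient_field()] results on the same reference
#'   surface and sigma.
#' @return A `probability_field` whose `coverage` counts contributing
#'   patients (NA values where no patient contributes).
#' @export
cohort_average <- function(fields) {
  if (!length(fields)) stop("no fields to average")
  ref <- fields[[1]]
  for (f in fields) {
    if (!isTRUE(all.equal(f$surface$vertices, ref$surface$vertices)) ||
        f$sigma_mm != ref$sigma_mm)
      stop("all fields must share the reference surface and sigma")
  }
  V <- do.call(cbind, lapply(fields, function(f) f$values))
  cov <- rowSums(!is.na(V))
  val <- rowMeans(V, na.rm = TRUE)
  val[cov == 0] <- NA_real_
  structure(list(values = val, coverage = as.integer(cov),
                 sigma_mm = ref$sigma_mm, weight_cutoff = ref$weight_cutoff,
                 surface = ref$surface),
            class = "probability_field")
}

#' Detect high-probability peaks in an atlas field
#'
#' Finds edge-connected components of vertices whose probability strictly
#' exceeds `threshold` (default 0.20, i.e. "greater than 20%"); each
#' component's maximum-probability vertex is its peak. Components are
#' returned sorted by peak probability, descending.
#'
#' @param field a [probability_field()].
#' @param threshold peak threshold (strict inequality).
#' @return list of `atlas_peak` objects: `component`, `vertex`,
#'   `peak_probability`, `members`, `annotation` (free text, empty).
#' @export
find_peaks <- function(field, threshold = 0.20) {
  val <- field$values
  if (all(is.na(val))) stop("field is undefined everywhere")
  sel <- which(!is.na(val) & val > threshold)
  if (!length(sel)) return(list())
  e <- mesh_edges(field$surface)
  e <- e[e[, 1] %in% sel & e[, 2] %in% sel, , drop = FALSE]
  remap <- match(seq_len(length(val)), sel)
  comp <- uf_components(length(sel), cbind(remap[e[, 1]], remap[e[, 2]]))
  groups <- split(sel, comp)
  peaks <- lapply(groups, function(g) {
    top <- g[which.max(val[g])]
    structure(list(vertex = top, peak_probability = val[top],
                   members = sort(g), annotation = ""),
              class = "atlas_peak")
  })
  ord <- order(vapply(peaks, function(p) p$peak_probability, numeric(1)),
               decreasing = TRUE)
  peaks <- peaks[ord]
  for (i in seq_along(peaks)) peaks[[i]]$component <- i
  peaks
}

#' @export
print.atlas_peak <- function(x, ...) {
  cat(sprintf("<atlas_peak> #%d at vertex %d: p=%.3f (%d member vertices)%s\n",
              x$component, x$vertex, x$peak_probability, length(x$members),
              if (nzchar(x$annotation)) paste0(" - ", x$annotation) else ""))
  invisible(x)
}

#' Area needed to contain a given share of AVD-GP sites
#'
#' Ranks triangles by field probability (mean of their vertex values,
#' undefined treated as lowest; ties broken by triangle index), assigns
#' each AVD-GP site to its nearest triangle, and accumulates triangle area
#' in rank order until the accumulated region contains at least
#' `site_coverage` of the sites. Returns accumulated area as a fraction of
#' the total surface area — e.g. "x% of the atrium contains 90% of
#' AVD-GPs".
#'
#' @param field a [probability_field()].
#' @param gp_positions n x 3 matrix of mapped AVD-GP site positions.
#' @param site_coverage required fraction of sites (default 0.90).
#' @return list with `area_fraction`, `area_mm2`, `n_triangles`,
#'   `sites_contained`.
#' @export
area_concentration <- function(field, gp_positions, site_coverage = 0.90) {
  gp_positions <- matrix(as.numeric(gp_positions), ncol = 3)
  if (nrow(gp_positions) == 0) stop("no AVD-GP sites supplied")
  surface <- field$surface
  fv <- matrix(field$values[surface$faces], ncol = 3)
  fprob <- rowMeans(fv)
  fprob[is.na(fprob)] <- -Inf
  ord <- order(-fprob, seq_along(fprob)) # ties by triangle index
  areas <- face_areas(surface)
  site_face <- project_points_onto_surface(surface, gp_positions)$face
  needed <- site_coverage * nrow(gp_positions)
  in_rank <- match(site_face, ord) # rank position of each site's triangle
  counts <- tabulate(in_rank, nbins = length(ord))
  cum_sites <- cumsum(counts)
  k <- which(cum_sites >= needed)[1]
  if (is.na(k)) k <- length(ord)
  list(area_fraction = sum(areas[ord[seq_len(k)]]) / sum(areas),
       area_mm2 = sum(areas[ord[seq_len(k)]]),
       n_triangles = k,
       sites_contained = cum_sites[k] / nrow(gp_positions))
}

#' Write an atlas field as CSV (vertex_id, probability, coverage_count)
#' @param field a [probability_field()].
#' @param path output CSV path.
#' @return Invisibly `path`.
#' @export
write_atlas_csv <- function(field, path) {
  utils::write.csv(data.frame(vertex_id = seq_along(field$values) - 1L,
                              probability = field$values,
                              coverage_count = field$coverage),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an atlas CSV written by [write_atlas_csv()]
#' @param path CSV path.
#' @param surface the reference [atrial_surface()] the field lives on.
#' @param sigma_mm kernel scale to record.
#' @return A `probability_field`.
#' @export
read_atlas_csv <- function(path, surface, sigma_mm = 5) {
  d <- utils::read.csv(path)
  d <- d[order(d$vertex_id), ]
  structure(list(values = d$probability,
                 coverage = as.integer(d$coverage_count),
                 sigma_mm = sigma_mm, weight_cutoff = exp(-4.5),
                 surface = surface),
            class = "probability_field")
}

#' Write an atlas field as legacy VTK polydata with a named scalar
#'
#' Undefined vertices are written with scalar value -1 (VTK has no NA).
#'
#' @param field a [probability_field()].
#' @param path output `.vtk` path.
#' @param scalars_name name of the scalar array.
#' @return Invisibly `path`.
#' @export
write_atlas_vtk <- function(field, path, scalars_name = "avd_gp_probability") {
  write_vtk_polydata(field$surface, path, scalars = field$values,
                     scalars_name = scalars_name)
  invisible(path)
}
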