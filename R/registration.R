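# Landmark registration of a patient atrial surface onto the reference
# shell: similarity (Procrustes) alignment, thin-plate-spline warp,
# held-out target registration error, and angle-based fiducial (phase)
# selection on the PV junction rings.

#' Least-squares similarity transform between paired point sets
#'
#' Closed-form Procrustes/Umeyama fit of rotation, isotropic scale and
#' translation minimising the summed squared distance
#' `sum || s R x_i + t - y_i ||^2`.
#'
#' @param source_pts,reference_pts n x 3 matrices of paired points
#'   (n >= 3, non-collinear).
#' @return An object of class `similarity_transform`: `R` (3 x 3 rotation),
#'   `s` (scale), `t` (translation), `rmse`.
#' @export
fit_similarity <- function(source_pts, reference_pts) {
  X <- as.matrix(source_pts); Y <- as.matrix(reference_pts)
  if (nrow(X) != nrow(Y) || ncol(X) != 3 || ncol(Y) != 3)
    stop("point sets must be paired n x 3 matrices")
  n <- nrow(X)
  if (n < 3) stop("at least 3 correspondences are required")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  C <- crossprod(Yc, Xc) / n
  sv <- svd(C)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) landmark configuration")
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  var_x <- sum(Xc^2) / n
  s <- sum(diag(diag(sv$d) %*% S)) / var_x
  t <- my - s * as.numeric(R %*% mx)
  mapped <- apply_similarity(list(R = R, s = s, t = t), X)
  structure(list(R = R, s = s, t = t,
                 rmse = sqrt(mean(rowSums((mapped - Y)^2)))),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#' @param tf a `similarity_transform` (or list with `R`, `s`, `t`).
#' @param pts n x 3 matrix.
#' @return n x 3 matrix of transformed points.
#' @export
apply_similarity <- function(tf, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(tf$s * pts %*% t(tf$R), 2, tf$t, "+")
}

#' Thin-plate-spline displacement field from landmark pairs
#'
#' Fits a 3D polyharmonic (thin-plate) spline with kernel `U(r) = r` to the
#' displacements `reference_pts - source_pts`. With `lambda = 0` the warp
#' interpolates the landmarks exactly and reproduces any affine map
#' exactly; `lambda > 0` trades interpolation for smoothness with noisy
#' landmarks.
#'
#' @param source_pts n x 3 control points (distinct).
#' @param reference_pts n x 3 target points.
#' @param lambda ridge regularisation (>= 0, default 0).
#' @return An object of class `tps_warp`.
#' @export
fit_nonrigid <- function(source_pts, reference_pts, lambda = 0) {
  X <- as.matrix(source_pts); Y <- as.matrix(reference_pts)
  if (nrow(X) != nrow(Y) || ncol(X) != 3)
    stop("point sets must be paired n x 3 matrices")
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))
  if (any(D2[upper.tri(D2)] < 1e-9))
    stop("coincident source landmarks")
  K <- D2 # U(r) = r in 3D
  P <- cbind(1, X)
  Mtop <- cbind(K + lambda * diag(n), P)
  Mbot <- cbind(t(P), matrix(0, 4, 4))
  M <- rbind(Mtop, Mbot)
  rhs <- rbind(Y - X, matrix(0, 4, 3))
  sol <- solve(M, rhs)
  structure(list(control = X, W = sol[seq_len(n), , drop = FALSE],
                 A = sol[n + 1:4, , drop = FALSE], lambda = lambda),
            class = "tps_warp")
}

#' Apply a thin-plate-spline warp to points
#' @param warp a `tps_warp` from [fit_nonrigid()].
#' @param pts n x 3 matrix.
#' @return n x 3 matrix of warped points.
#' @export
apply_warp <- function(warp, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  C <- warp$control
  G <- sqrt(pmax(outer(rowSums(pts^2), rowSums(C^2), "+") -
                   2 * pts %*% t(C), 0))
  pts + G %*% warp$W + cbind(1, pts) %*% warp$A
}

#' Register paired landmarks: similarity then thin-plate spline
#'
#' Fits the similarity on the `used` pairs, warps the similarity-aligned
#' used source landmarks onto their reference partners with a TPS, and
#' evaluates the held-out target registration error when held-out pairs
#' and a reference surface are available.
#'
#' @param source_pts,reference_pts all paired landmarks (n x 3 each).
#' @param used integer indices of pairs used for fitting.
#' @param held_out integer indices excluded from fitting (disjoint from
#'   `used`), scored by [compute_tre()].
#' @param lambda TPS regularisation.
#' @param reference_surface the reference [atrial_surface()] (for the
#'   closest-point projection step); may be `NULL`.
#' @param source_id,reference_id free-text identifiers.
#' @return An object of class `surface_registration`.
#' @export
register_landmarks <- function(source_pts, reference_pts, used,
                               held_out = integer(0), lambda = 0,
                               reference_surface = NULL,
                               source_id = "source",
                               reference_id = "reference") {
  source_pts <- as.matrix(source_pts); reference_pts <- as.matrix(reference_pts)
  if (length(intersect(used, held_out)))
    stop("used and held-out landmark sets must be disjoint")
  sim <- fit_similarity(source_pts[used, , drop = FALSE],
                        reference_pts[used, , drop = FALSE])
  aligned <- apply_similarity(sim, source_pts)
  warp <- fit_nonrigid(aligned[used, , drop = FALSE],
                       reference_pts[used, , drop = FALSE], lambda)
  reg <- structure(list(source_id = source_id, reference_id = reference_id,
                        source_pts = source_pts,
                        reference_pts = reference_pts,
                        used = used, held_out = held_out,
                        similarity = sim, warp = warp,
                        reference_surface = reference_surface,
                        tre_mm = NA_real_),
                   class = "surface_registration")
  if (length(held_out)) reg$tre_mm <- compute_tre(reg)
  reg
}

#' Map points through a registration onto the reference surface
#'
#' Applies the similarity transform, then the thin-plate-spline warp, then
#' projects each mapped point to its closest point on the reference
#' surface (when one is available), reporting the projection distance.
#'
#' @param registration a [register_landmarks()] result.
#' @param points n x 3 matrix in source-map space.
#' @param reference_surface reference [atrial_surface()]; defaults to the
#'   one stored in the registration. `NULL` skips projection.
#' @return list with `points` (n x 3 on the reference surface),
#'   `projection_distance` (mm per point).
#' @export
transform_to_reference <- function(registration, points,
                                   reference_surface =
                                     registration$reference_surface) {
  mapped <- apply_warp(registration$warp,
                       apply_similarity(registration$similarity,
                                        matrix(as.numeric(points), ncol = 3)))
  if (is.null(reference_surface))
    return(list(points = mapped,
                projection_distance = rep(0, nrow(mapped))))
  pr <- project_points_onto_surface(reference_surface, mapped)
  list(points = pr$points, projection_distance = pr$distance)
}

#' Held-out target registration error (mm)
#'
#' Mean Euclidean distance between the mapped held-out source landmarks
#' and their true positions on the reference shell; 0 is perfect
#' registration.
#'
#' @param registration a [register_landmarks()] result with a non-empty
#'   held-out set.
#' @return TRE in mm.
#' @export
compute_tre <- function(registration) {
  ho <- registration$held_out
  if (!length(ho)) stop("held-out landmark set is empty")
  mapped <- transform_to_reference(
    registration, registration$source_pts[ho, , drop = FALSE])$points
  truth <- registration$reference_pts[ho, , drop = FALSE]
  mean(sqrt(rowSums((mapped - truth)^2)))
}

#' @export
print.surface_registration <- function(x, ...) {
  cat(sprintf(paste0("<surface_registration> %s -> %s: %d used / %d ",
                     "held-out landmarks, scale %.3f, TRE %.3f mm\n"),
              x$source_id, x$reference_id, length(x$used),
              length(x$held_out), x$similarity$s, x$tre_mm))
  invisible(x)
}

#' Angle-based fiducial phase selection
#'
#' Chooses the per-PV angular offsets (phases) of the source landmark
#' rings that minimise the held-out target registration error against the
#' reference shell. For each candidate phase vector, rings of
#' `n_per_ring` landmarks are generated on each source junction curve,
#' paired index-wise with the reference rings (generated at
#' `reference_phases`), split into used (even 0-based indices) and
#' held-out (odd) pairs, registered with similarity + TPS, and scored with
#' [compute_tre()]. The search is an exhaustive per-PV grid over
#' `[0, 2*pi/n)` swept coordinate-wise (two passes) and then refined
#' jointly over the +/- one-step neighbourhood; among evaluated candidates
#' ties are broken by the lexicographically smallest phase vector.
#'
#' @param source_rings,reference_rings lists of four
#'   [find_junction_plane()] results (one per PV, same order).
#' @param reference_surface the reference [atrial_surface()].
#' @param n_per_ring landmarks per ring (default 8).
#' @param grid_steps phase grid resolution per PV (>= 2, default 16).
#' @param lambda TPS regularisation.
#' @param reference_phases phases of the reference rings (default 0).
#' @param source_id,reference_id identifiers carried into the result.
#' @return list with `phases`, `objective` (TRE mm), `grid_steps`,
#'   `registration` (the winning [register_landmarks()] fit) and the
#'   evaluation log.
#' @export
select_fiducial_phases <- function(source_rings, reference_rings,
                                   reference_surface, n_per_ring = 8,
                                   grid_steps = 16, lambda = 0,
                                   reference_phases = rep(0, 4),
                                   source_id = "source",
                                   reference_id = "reference") {
  if (grid_steps < 2) stop("grid_steps must be >= 2")
  if (length(source_rings) != 4 || length(reference_rings) != 4)
    stop("four junction rings (one per PV) are required on each surface")
  period <- 2 * pi / n_per_ring
  grid <- seq(0, period, length.out = grid_steps + 1)[seq_len(grid_steps)]
  ref_lm <- do.call(rbind, lapply(seq_len(4), function(k)
    generate_landmark_ring(reference_rings[[k]], n_per_ring,
                           reference_phases[k])$points))
  used <- which((seq_len(4 * n_per_ring) - 1) %% 2 == 0)
  held <- which((seq_len(4 * n_per_ring) - 1) %% 2 == 1)
  memo <- new.env(parent = emptyenv())
  evalphase <- function(ph) {
    key <- paste(sprintf("%.12f", ph), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    src_lm <- do.call(rbind, lapply(seq_len(4), function(k)
      generate_landmark_ring(source_rings[[k]], n_per_ring, ph[k])$points))
    reg <- register_landmarks(src_lm, ref_lm, used, held, lambda,
                              reference_surface, source_id, reference_id)
    memo[[key]] <- list(phases = ph, tre = reg$tre_mm, reg = reg)
    memo[[key]]
  }
  cur <- rep(0, 4)
  for (pass in 1:2) {
    for (k in seq_len(4)) {
      scores <- vapply(grid, function(g) {
        ph <- cur; ph[k] <- g
        evalphase(ph)$tre
      }, numeric(1))
      cur[k] <- grid[which.min(scores)]
    }
  }
  step <- period / grid_steps
  neigh <- expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1, d4 = -1:1)
  for (i in seq_len(nrow(neigh))) {
    ph <- (cur + as.numeric(neigh[i, ]) * step) %% period
    evalphase(ph)
  }
  entries <- lapply(ls(memo), function(k) memo[[k]])
  tres <- vapply(entries, function(e) e$tre, numeric(1))
  best <- min(tres)
  cand <- entries[tres <= best + 1e-12]
  ord <- order(vapply(cand, function(e)
    paste(sprintf("%020.12f", e$phases), collapse = ","), character(1)))
  win <- cand[[ord[1]]]
  log <- data.frame(do.call(rbind, lapply(entries, function(e)
    c(e$phases, e$tre))))
  names(log) <- c("phase1", "phase2", "phase3", "phase4", "tre_mm")
  list(phases = win$phases, objective = win$tre, grid_steps = grid_steps,
       registration = win$reg, evaluations = log)
}

#' Register a patient surface onto the reference shell
#'
#' End-to-end per-patient registration: detect the four PV junction rings
#' on both surfaces, select fiducial phases by held-out TRE, and return
#' the winning registration.
#'
#' @param source,reference labelled [atrial_surface()] meshes with all
#'   four PV regions.
#' @param n_per_ring,grid_steps,lambda see [select_fiducial_phases()].
#' @param source_id,reference_id identifiers.
#' @param reference_rings optional precomputed reference junction rings
#'   (compute once when registering a whole cohort).
#' @return list with `registration`, `phases`, `tre_mm`, `source_rings`,
#'   `reference_rings`.
#' @export
register_surfaces <- function(source, reference, n_per_ring = 8,
                              grid_steps = 16, lambda = 0,
                              source_id = "source",
                              reference_id = "reference",
                              reference_rings = NULL) {
  curv_s <- vertex_curvature(source)
  source_rings <- lapply(PV_LABELS, function(pv)
    find_junction_plane(source, pv, curvature = curv_s))
  if (is.null(reference_rings)) {
    curv_r <- vertex_curvature(reference)
    reference_rings <- lapply(PV_LABELS, function(pv)
      find_junction_plane(reference, pv, curvature = curv_r))
  }
  sel <- select_fiducial_phases(source_rings, reference_rings, reference,
                                n_per_ring, grid_steps, lambda,
                                source_id = source_id,
                                reference_id = reference_id)
  list(registration = sel$registration, phases = sel$phases,
       tre_mm = sel$objective, source_rings = source_rings,
       reference_rings = reference_rings)
}

#' Serialise a registration to JSON
#'
#' Writes similarity parameters, TPS control points and coefficients,
#' used/held-out landmark coordinates and the TRE. The reference surface
#' itself is referenced by id, not embedded.
#'
#' @param registration a [register_landmarks()] result.
#' @param path output file.
#' @param phases optional per-PV phases to record.
#' @return Invisibly `path`.
#' @export
write_registration_json <- function(registration, path, phases = NULL) {
  x <- list(source_id = registration$source_id,
            reference_id = registration$reference_id,
            similarity = list(R = registration$similarity$R,
                              s = registration$similarity$s,
                              t = registration$similarity$t),
            warp = list(control = registration$warp$control,
                        W = registration$warp$W, A = registration$warp$A,
                        lambda = registration$warp$lambda),
            used = registration$used, held_out = registration$held_out,
            source_landmarks = registration$source_pts,
            reference_landmarks = registration$reference_pts,
            tre_mm = registration$tre_mm)
  if (!is.null(phases)) x$phases <- phases
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a registration written by [write_registration_json()]
#' @param path JSON file.
#' @param reference_surface optional [atrial_surface()] to re-attach.
#' @return A `surface_registration`.
#' @export
read_registration_json <- function(path, reference_surface = NULL) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(source_id = x$source_id, reference_id = x$reference_id,
                 source_pts = matrix(unlist(x$source_landmarks), ncol = 3),
                 reference_pts = matrix(unlist(x$reference_landmarks),
                                        ncol = 3),
                 used = as.integer(x$used),
                 held_out = as.integer(x$held_out),
                 similarity = structure(list(R = matrix(unlist(x$similarity$R),
                                                        3, 3),
                                             s = x$similarity$s,
                                             t = as.numeric(x$similarity$t)),
                                        class = "similarity_transform"),
                 warp = structure(list(control = matrix(unlist(x$warp$control),
                                                        ncol = 3),
                                       W = matrix(unlist(x$warp$W), ncol = 3),
                                       A = matrix(unlist(x$warp$A), ncol = 3),
                                       lambda = x$warp$lambda),
                                  class = "tps_warp"),
                 reference_surface = reference_surface,
                 tre_mm = x$tre_mm,
                 phases = if (!is.null(x$phases)) as.numeric(x$phases)),
            class = "surface_registration")
}
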