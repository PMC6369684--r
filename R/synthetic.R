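# Synthetic cohort generator: labelled 4-PV atrial shells built from an
# analytic profile (so junction detection can be checked against closed
# forms), smooth patient-specific deformations with exact correspondence,
# Poisson-disk-style HFS site layouts, hotspot-structured ground-truth
# probability fields, and R-wave series realising each site label.

#' Geometry parameters for the synthetic reference shell
#'
#' The shell is an ellipsoidal body with four tubular PV stubs joined by
#' circular fillets and a mitral opening. Around each PV the surface is an
#' exact surface of revolution (sphere cap of radius matching the local
#' ellipsoid radius, toroidal fillet, cylinder), so principal curvatures
#' at the junction are known in closed form.
#'
#' @param body_radii ellipsoid semi-axes in mm (default c(27, 25, 23),
#'   i.e. ~50 mm axes).
#' @param pv_radius PV stub radius in mm.
#' @param fillet_radius fillet (ostial flare) radius in mm.
#' @param pv_length tube length beyond the fillet tangency in mm.
#' @param pv_dirs 4 x 3 matrix of PV axis directions (rows normalised;
#'   order LSPV, RSPV, LIPV, RIPV as in [PV_LABELS]).
#' @param mv_dir mitral-opening direction.
#' @param mv_angle_deg angular radius of the mitral opening.
#' @param subdiv icosphere subdivision level (default 5: 10242 vertices).
#' @return list of parameters for [make_reference_shell()].
#' @export
shell_params <- function(body_radii = c(27, 25, 23),
                         pv_radius = 6, fillet_radius = 4, pv_length = 8,
                         pv_dirs = rbind(LSPV = c(0.76, 0.44, 0.48),
                                         RSPV = c(-0.76, 0.44, 0.48),
                                         LIPV = c(0.76, 0.44, -0.48),
                                         RIPV = c(-0.76, 0.44, -0.48)),
                         mv_dir = c(0, -0.85, -0.53),
                         mv_angle_deg = 32, subdiv = 5) {
  pv_dirs <- pv_dirs / sqrt(rowSums(pv_dirs^2))
  rownames(pv_dirs) <- PV_LABELS
  list(body_radii = body_radii, pv_radius = pv_radius,
       fillet_radius = fillet_radius, pv_length = pv_length,
       pv_dirs = pv_dirs, mv_dir = mv_dir / sqrt(sum(mv_dir^2)),
       mv_angle = mv_angle_deg * pi / 180, subdiv = subdiv)
}

# Closed-form meridian profile of one PV junction as a surface of
# revolution: sphere radius R0, fillet radius rf tangent to sphere and to
# a cylinder of radius a, tube length L. Returns geometry and r(theta).
pv_profile <- function(R0, a, rf, L) {
  zf <- sqrt((R0 + rf)^2 - (a + rf)^2) # fillet centre axial position
  theta_c <- atan2(a, zf)              # cylinder tangency (the junction)
  theta_s <- atan2(a + rf, zf)         # sphere tangency
  z_end <- zf + L
  theta_end <- atan2(a, z_end)
  r_of_theta <- function(theta) {
    r <- rep(NA_real_, length(theta))
    sph <- theta >= theta_s
    r[sph] <- R0
    fil <- theta >= theta_c & theta < theta_s
    if (any(fil)) {
      dC <- sin(theta[fil]) * (a + rf) + cos(theta[fil]) * zf
      r[fil] <- dC - sqrt(pmax(dC^2 - ((a + rf)^2 + zf^2 - rf^2), 0))
    }
    cyl <- theta < theta_c
    r[cyl] <- a / sin(pmax(theta[cyl], 1e-9))
    r
  }
  # analytic curvature measure (|k1|+|k2|)/2 along the profile
  curvature_of_theta <- function(theta) {
    r <- r_of_theta(theta)
    rho <- r * sin(theta); z <- r * cos(theta)
    m <- rep(NA_real_, length(theta))
    sph <- theta >= theta_s
    m[sph] <- 1 / R0
    fil <- theta >= theta_c & theta < theta_s
    if (any(fil)) {
      # outward normal points toward the fillet centre (concave meridian)
      n_rho <- ((a + rf) - rho[fil]) / rf
      m[fil] <- (1 / rf + n_rho / rho[fil]) / 2
    }
    cyl <- theta < theta_c
    m[cyl] <- (0 + 1 / a) / 2
    m
  }
  list(R0 = R0, a = a, rf = rf, L = L, zf = zf,
       theta_c = theta_c, theta_s = theta_s,
       theta_end = theta_end, z_end = z_end,
       r_of_theta = r_of_theta, curvature_of_theta = curvature_of_theta)
}

#' Analytic maximal-curvature latitude of a synthetic PV junction
#'
#' Independent oracle for [find_junction_plane()] on generator shells:
#' evaluates the closed-form curvature measure of the junction's surface
#' of revolution on a dense latitude grid and returns the axial position
#' (along the PV axis, from the body centre) of its maximum.
#'
#' @param profile element of the `profiles` attribute of a
#'   [make_reference_shell()] surface.
#' @param n grid resolution.
#' @return list with `z` (axial position, mm) and `theta` (polar angle).
#' @export
junction_curvature_argmax <- function(profile, n = 20000) {
  th <- seq(profile$theta_end, profile$theta_s + 0.1, length.out = n)
  m <- profile$curvature_of_theta(th)
  k <- which.max(m)
  r <- profile$r_of_theta(th[k])
  list(z = r * cos(th[k]), theta = th[k])
}

# Monotone angular remap concentrating mesh resolution in the tube/fillet
# band [band1, band2] (radians, in the image domain); returns a function
# old_theta -> new_theta on [0, theta_R].
make_angle_remap <- function(theta_R, band = c(7, 23) * pi / 180,
                             gain = 6, edge = 2 * pi / 180) {
  th <- seq(0, theta_R, length.out = 2000)
  bump <- rep(0, length(th))
  core <- th >= band[1] & th <= band[2]
  bump[core] <- 1
  lo <- th > band[1] - edge & th < band[1]
  bump[lo] <- (1 + cos(pi * (band[1] - th[lo]) / edge)) / 2
  hi <- th > band[2] & th < band[2] + edge
  bump[hi] <- (1 + cos(pi * (th[hi] - band[2]) / edge)) / 2
  rho <- 1 + (gain - 1) * bump
  Fcum <- cumsum(rho) * (th[2] - th[1])
  Fcum <- Fcum - Fcum[1]
  inv <- stats::approxfun(Fcum * theta_R / Fcum[length(Fcum)], th, rule = 2)
  function(theta_old) inv(pmin(theta_old, theta_R))
}

#' Build the synthetic reference atrial shell
#'
#' Deterministic construction (the `seed` argument is accepted for API
#' symmetry but the shell is fully determined by `params`): a subdivided
#' icosphere is warped onto an ellipsoidal body carrying four
#' surface-of-revolution PV stubs with fillets and a mitral opening;
#' vertices inside the PV tube ends and the mitral cone are removed, and
#' region labels are assigned (PV labels cover tube + fillet up to the
#' sphere tangency; boundary vertices of the mitral opening are MV_RIM).
#'
#' The returned surface carries a `profiles` attribute (one [pv_profile()]
#' per PV, plus the axis) enabling closed-form oracles.
#'
#' @param params a [shell_params()] list.
#' @param seed unused; kept for interface symmetry.
#' @return A labelled [atrial_surface()].
#' @export
make_reference_shell <- function(params = shell_params(), seed = NULL) {
  ico <- build_icosphere(params$subdiv)
  u <- ico$vertices
  theta_R <- 30 * pi / 180
  br <- params$body_radii
  r_ell <- function(uu)
    1 / sqrt((uu[, 1] / br[1])^2 + (uu[, 2] / br[2])^2 + (uu[, 3] / br[3])^2)
  profiles <- list()
  theta_pv <- matrix(NA_real_, nrow(u), 4)
  remap <- make_angle_remap(theta_R)
  for (k in seq_len(4)) {
    d <- params$pv_dirs[k, ]
    R0k <- r_ell(matrix(d, 1, 3))
    cosang <- pmin(1, pmax(-1, as.numeric(u %*% d)))
    th <- acos(cosang)
    sel <- which(th < theta_R & th > 1e-9)
    th_new <- th
    th_new[sel] <- remap(th[sel])
    # rotate each selected direction toward the axis to its new angle
    w <- u[sel, , drop = FALSE] -
      outer(cosang[sel], d)
    w <- w / sqrt(rowSums(w^2))
    u[sel, ] <- outer(cos(th_new[sel]), d) + sin(th_new[sel]) * w
    theta_pv[, k] <- th_new
    profiles[[PV_LABELS[k]]] <- c(pv_profile(R0k, params$pv_radius,
                                             params$fillet_radius,
                                             params$pv_length),
                                  list(axis = d))
  }
  r <- r_ell(u)
  # the PV profile is added as a radial delta over the ellipsoid; the
  # delta and its slope vanish at the sphere tangency (the fillet is
  # tangent to the sphere), so no blending band is needed and the surface
  # stays an exact surface of revolution up to the slowly varying
  # ellipsoid background
  for (k in seq_len(4)) {
    pr <- profiles[[k]]
    th <- theta_pv[, k]
    inb <- which(th < pr$theta_s)
    r[inb] <- r[inb] + (pr$r_of_theta(th[inb]) - pr$R0)
  }
  verts <- u * r
  # removal: PV tube ends and mitral cone
  drop <- rep(FALSE, nrow(u))
  for (k in seq_len(4)) {
    pr <- profiles[[k]]
    drop <- drop | theta_pv[, k] < pr$theta_end + 0.005
  }
  mv_ang <- acos(pmin(1, pmax(-1, as.numeric(u %*% params$mv_dir))))
  drop <- drop | mv_ang < params$mv_angle
  keep <- which(!drop)
  fkeep <- ico$faces[rowSums(matrix(ico$faces %in% keep, ncol = 3)) == 3, ,
                     drop = FALSE]
  used <- sort(unique(as.vector(fkeep)))
  newid <- match(seq_len(nrow(u)), used)
  faces <- matrix(newid[fkeep], ncol = 3)
  verts <- verts[used, , drop = FALSE]
  theta_pv <- theta_pv[used, , drop = FALSE]
  mv_ang <- mv_ang[used]
  labels <- rep("BODY", nrow(verts))
  for (k in seq_len(4))
    labels[theta_pv[, k] <= profiles[[k]]$theta_s] <- PV_LABELS[k]
  surf0 <- structure(list(vertices = verts, faces = faces, labels = NULL),
                     class = "atrial_surface")
  bnd <- boundary_vertices(surf0)
  labels[intersect(bnd, which(mv_ang < params$mv_angle + 0.12))] <- "MV_RIM"
  s <- atrial_surface(verts, faces, labels)
  attr(s, "profiles") <- profiles
  attr(s, "params") <- params
  s
}

# low-order smooth scalar field on directions (l = 1, 2 harmonics)
harmonic_field <- function(u, coef) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  B <- cbind(x, y, z, x * y, y * z, z * x, x^2 - y^2, 3 * z^2 - 1)
  as.numeric(B %*% coef)
}

#' Deform the reference shell into a synthetic patient anatomy
#'
#' Applies a smooth low-frequency radial deformation (random degree-1/2
#' spherical-harmonic field scaled to RMS `deformation_scale_mm`) followed
#' by a random rigid motion. The patient mesh shares the reference mesh
#' topology, so the exact forward correspondence is the face/barycentric
#' identity — used by registration oracles. If the drawn deformation is
#' large enough to risk surface folding (radial shrink beyond 40% of the
#' local radius) the amplitude is damped and a message emitted.
#'
#' @param reference a [make_reference_shell()] surface.
#' @param deformation_scale_mm RMS radial deformation (default 3).
#' @param seed integer seed (deterministic per seed).
#' @return list: `surface` (the deformed, labelled patient mesh),
#'   `rigid` (list `R`, `t`), `coef` (harmonic coefficients),
#'   `reference` (the input).
#' @export
make_patient_shell <- function(reference, deformation_scale_mm = 3, seed = 1) {
  set.seed(seed)
  v <- reference$vertices
  ctr <- colMeans(v)
  rel <- sweep(v, 2, ctr)
  rad <- sqrt(rowSums(rel^2))
  u <- rel / rad
  coef <- stats::rnorm(8)
  f <- harmonic_field(u, coef)
  if (deformation_scale_mm > 0 && stats::sd(f) > 0) {
    f <- f * deformation_scale_mm / sqrt(mean(f^2))
  } else f <- f * 0
  shrink <- -f / rad
  if (max(shrink) > 0.4) {
    damp <- 0.4 / max(shrink)
    message("deformation damped by factor ", signif(damp, 3),
            " to avoid self-intersection")
    f <- f * damp
  }
  v2 <- sweep(u * (rad + f), 2, ctr, "+")
  # random rigid motion: rotation up to ~15 degrees, translation +/- 10 mm
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, -0.26, 0.26)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  t <- stats::runif(3, -10, 10)
  v3 <- sweep(v2 %*% t(R), 2, t, "+")
  surf <- atrial_surface(v3, reference$faces, reference$labels)
  list(surface = surf, rigid = list(R = R, t = t), coef = coef,
       deformation_scale_mm = deformation_scale_mm, reference = reference)
}

#' Sample an even HFS site layout on a surface
#'
#' Greedy farthest-point (Poisson-disk-like) selection from a dense
#' uniform-by-area candidate pool, targeting even coverage of the chamber:
#' the spacing parameter is a coverage target (every surface point should
#' lie within about `min_spacing_mm` of a tested site), not a hard minimum
#' pairwise distance. The realised site count is drawn within +/-20% of
#' `n_target`. Errors when `n_target` disks of radius `min_spacing_mm`/2
#' cannot pack into the surface area.
#'
#' @param surface an [atrial_surface()].
#' @param n_target target number of sites (default 75).
#' @param min_spacing_mm coverage spacing target (default 6).
#' @param seed integer seed.
#' @return list: `positions` (n x 3 on the surface), `face`, `bary`
#'   (barycentric coordinates), `n`.
#' @export
sample_sites <- function(surface, n_target = 75, min_spacing_mm = 6,
                         seed = 1) {
  set.seed(seed)
  A <- surface_area(surface)
  need <- n_target * pi * (min_spacing_mm / 2)^2
  if (need > A)
    stop("infeasible spacing: ", n_target, " sites at ", min_spacing_mm,
         " mm need ", round(need), " mm^2 but the surface has ", round(A),
         " mm^2 (achievable spacing <= ",
         round(2 * sqrt(A / (pi * n_target)), 1), " mm)")
  n <- round(stats::rnorm(1, n_target, 0.1 * n_target))
  n <- min(max(n, ceiling(0.8 * n_target)), floor(1.2 * n_target))
  m <- 30 * n_target
  fa <- face_areas(surface)
  fidx <- sample.int(length(fa), m, replace = TRUE, prob = fa)
  r1 <- stats::runif(m); r2 <- stats::runif(m)
  sw <- r1 + r2 > 1
  r1[sw] <- 1 - r1[sw]; r2[sw] <- 1 - r2[sw]
  b <- cbind(1 - r1 - r2, r1, r2)
  f <- surface$faces[fidx, , drop = FALSE]
  P <- surface$vertices[f[, 1], ] * b[, 1] +
    surface$vertices[f[, 2], ] * b[, 2] +
    surface$vertices[f[, 3], ] * b[, 3]
  picked <- integer(n)
  picked[1] <- sample.int(m, 1)
  dmin <- sqrt(rowSums((P - matrix(P[picked[1], ], m, 3, byrow = TRUE))^2))
  for (i in 2:n) {
    picked[i] <- which.max(dmin)
    dmin <- pmin(dmin, sqrt(rowSums(
      (P - matrix(P[picked[i], ], m, 3, byrow = TRUE))^2)))
  }
  list(positions = P[picked, , drop = FALSE], face = fidx[picked],
       bary = b[picked, , drop = FALSE], n = n)
}

#' Coverage radius of a site layout
#'
#' Largest distance from any mesh vertex to its nearest site — the
#' quantity the even-mapping protocol tries to keep near the spacing
#' target.
#'
#' @param surface an [atrial_surface()].
#' @param positions n x 3 site positions.
#' @return max-min distance in mm.
#' @export
site_coverage_radius <- function(surface, positions) {
  v <- surface$vertices
  positions <- matrix(as.numeric(positions), ncol = 3)
  d2 <- outer(rowSums(v^2), rowSums(positions^2), "+") -
    2 * v %*% t(positions)
  max(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Default ground-truth hotspot layout
#'
#' Three Gaussian hotspots mimicking the anatomy where AVD-GP probability
#' concentrates clinically: the septal wall (extending anteriorly), the
#' RSPV antrum and the RIPV base on the posterior wall. Centres are given
#' as directions and projected onto the surface.
#'
#' @param amplitudes hotspot amplitudes (probabilities added to the
#'   background; all >= 0.4 by default so atlas peaks clear the 20%
#'   detection threshold after kernel attenuation).
#' @param scale_mm Gaussian spatial scale of each hotspot.
#' @return data.frame with direction columns, amplitude, scale_mm, name.
#' @export
default_hotspots <- function(amplitudes = c(0.70, 0.55, 0.50),
                             scale_mm = c(5, 5, 5)) {
  dirs <- rbind(anteroseptal = c(-0.784, -0.588, 0.196),
                rspv_antrum = c(-0.30, 0.80, 0.52),
                ripv_base = c(-0.32, 0.82, -0.47))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  data.frame(dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
             amplitude = amplitudes, scale_mm = scale_mm,
             name = rownames(dirs))
}

#' Ground-truth AVD-GP probability field on the reference surface
#'
#' Background probability plus Gaussian bumps (3D Euclidean distance to
#' each hotspot centre), clamped to at most 1.
#'
#' @param reference the reference [atrial_surface()].
#' @param hotspots a [default_hotspots()]-shaped data.frame.
#' @param background floor probability everywhere (default 0.05).
#' @param field_mean_target optional target for the area-weighted mean of
#'   the field; when given, the background is adjusted (never below 0) to
#'   meet it.
#' @return list: `values` (per vertex), `centers` (hotspot centres on the
#'   surface), `hotspots`, `background`.
#' @export
ground_truth_field <- function(reference, hotspots = default_hotspots(),
                               background = 0.05,
                               field_mean_target = NULL) {
  v <- reference$vertices
  ctr <- colMeans(v)
  dirs <- as.matrix(hotspots[, c("dx", "dy", "dz")])
  # snap centre directions to the best-aligned atrial-body vertex (a
  # closest-point projection from outside can land on a protruding PV
  # stub instead of the antral wall)
  body <- if (!is.null(reference$labels)) which(reference$labels == "BODY")
          else seq_len(nrow(v))
  rel <- sweep(v[body, , drop = FALSE], 2, ctr)
  rel <- rel / sqrt(rowSums(rel^2))
  centers <- v[body[max.col(dirs %*% t(rel))], , drop = FALSE]
  bumps <- rep(0, nrow(v))
  for (k in seq_len(nrow(hotspots))) {
    d2 <- rowSums(sweep(v, 2, centers[k, ])^2)
    bumps <- bumps + hotspots$amplitude[k] *
      exp(-d2 / (2 * hotspots$scale_mm[k]^2))
  }
  if (!is.null(field_mean_target)) {
    va <- vertex_area_weights(reference)
    bump_mean <- sum(bumps * va) / sum(va)
    background <- max(0, field_mean_target - bump_mean)
  }
  list(values = pmin(1, background + bumps), centers = centers,
       hotspots = hotspots, background = background)
}

# per-vertex area weights (one third of incident face areas)
vertex_area_weights <- function(surface) {
  fa <- face_areas(surface) / 3
  as.numeric(Matrix::sparseMatrix(i = as.vector(surface$faces),
                                  j = rep(1L, 3 * nrow(surface$faces)),
                                  x = rep(fa, 3),
                                  dims = c(nrow(surface$vertices), 1)))
}

#' Baseline AF RR parameters for the beat-series simulator
#'
#' @param log_mean_rr,log_sd_rr log-normal parameters of AF RR intervals
#'   (ms); defaults give a ~700 ms median with ~15% variability.
#' @param brady_ratio_range range of the mean-RR ratio realised at
#'   bradycardia (B) sites.
#' @param asystole_ratio_range range of the pause ratio at asystole (A)
#'   sites.
#' @param a_fraction fraction of AVD-GP sites that are asystolic
#'   (default 0.8, the clinical 80/20 split).
#' @param hfs_duration_ms nominal stimulation duration.
#' @param ratio_log_mean,ratio_log_sd log-normal parameters of the AF
#'   variability ratio (longest late RR / mean early RR) used for
#'   threshold-calibration draws; defaults place the 99th percentile at
#'   ratio 2.6.
#' @return list of parameters.
#' @export
rr_params <- function(log_mean_rr = log(700), log_sd_rr = 0.15,
                      brady_ratio_range = c(1.6, 2.2),
                      asystole_ratio_range = c(3, 5),
                      a_fraction = 0.8, hfs_duration_ms = 10000,
                      ratio_log_mean = 0.405, ratio_log_sd = 0.2367) {
  list(log_mean_rr = log_mean_rr, log_sd_rr = log_sd_rr,
       brady_ratio_range = brady_ratio_range,
       asystole_ratio_range = asystole_ratio_range,
       a_fraction = a_fraction, hfs_duration_ms = hfs_duration_ms,
       ratio_log_mean = ratio_log_mean, ratio_log_sd = ratio_log_sd)
}

#' Simulate the R-wave series of one HFS application
#'
#' Realises a [beat_series()] consistent with a site label: negatives
#' continue baseline AF variability through the window; B sites scale the
#' in-window RR intervals to a mean ratio drawn from the bradycardia range
#' with single intervals capped below the asystole threshold; A sites
#' insert a ventricular pause exceeding the asystole ratio, with HFS
#' stopped mid-pause (the pause spans HFS cessation, as seen clinically).
#'
#' @param label `"A_AVD_GP"`, `"B_AVD_GP"` or `"NEGATIVE"`.
#' @param params an [rr_params()] list.
#' @return A [beat_series()].
#' @export
simulate_beat_series <- function(label, params = rr_params()) {
  rr_base <- stats::rlnorm(14, params$log_mean_rr, params$log_sd_rr)
  t <- cumsum(c(0, rr_base))
  base_mean <- mean(utils::tail(diff(t), 10))
  hfs_start <- t[length(t)] + 0.5 * stats::rlnorm(1, params$log_mean_rr,
                                                  params$log_sd_rr)
  dur <- params$hfs_duration_ms
  draw_rr <- function(n) stats::rlnorm(n, params$log_mean_rr,
                                       params$log_sd_rr)
  if (label == "NEGATIVE") {
    hfs_end <- hfs_start + dur
    tt <- t[length(t)]
    while (tt < hfs_end + 5000) {
      tt <- tt + draw_rr(1)
      t <- c(t, tt)
    }
  } else if (label == "B_AVD_GP") {
    hfs_end <- hfs_start + dur
    target <- stats::runif(1, params$brady_ratio_range[1],
                           params$brady_ratio_range[2])
    tt <- t[length(t)]
    while (tt < hfs_end) {
      rr <- min(base_mean * target * stats::rlnorm(1, 0, 0.05),
                2.25 * base_mean)
      tt <- tt + rr
      t <- c(t, tt)
    }
    while (tt < hfs_end + 5000) {
      tt <- tt + draw_rr(1)
      t <- c(t, tt)
    }
  } else if (label == "A_AVD_GP") {
    n_lead <- sample(0:2, 1)
    tt <- t[length(t)]
    if (hfs_start > tt) {
      # first in-window beat shortly after onset
      tt <- hfs_start + 0.3 * base_mean
      t <- c(t, tt)
    }
    if (n_lead > 0) for (i in seq_len(n_lead)) {
      tt <- tt + draw_rr(1) * 1.1
      t <- c(t, tt)
    }
    pause <- base_mean * stats::runif(1, params$asystole_ratio_range[1],
                                      params$asystole_ratio_range[2])
    hfs_end <- tt + 0.6 * pause # HFS stopped once asystole is recognised
    tt <- tt + pause
    t <- c(t, tt)
    for (i in 1:6) {
      tt <- tt + draw_rr(1)
      t <- c(t, tt)
    }
  } else stop("unknown label: ", label)
  beat_series(t, hfs_start, hfs_end, source = "synthetic")
}

#' Simulate a 20 s baseline AF segment
#' @param params an [rr_params()] list.
#' @return An [af_sample()].
#' @export
simulate_af_segment <- function(params = rr_params()) {
  t <- 0
  tt <- 0
  while (tt < 21000) {
    tt <- tt + stats::rlnorm(1, params$log_mean_rr, params$log_sd_rr)
    t <- c(t, tt)
  }
  af_sample(t)
}

#' Draw AF variability ratios from their log-normal model
#'
#' Ratio-level draws (longest late RR over mean early RR) from the fitted
#' log-normal, for threshold-calibration studies where the ratio
#' distribution itself is the object of interest.
#'
#' @param n number of draws.
#' @param params an [rr_params()] list (fields `ratio_log_mean`,
#'   `ratio_log_sd`).
#' @return numeric vector of ratios.
#' @export
simulate_af_ratios <- function(n, params = rr_params()) {
  stats::rlnorm(n, params$ratio_log_mean, params$ratio_log_sd)
}

#' Assign ground-truth labels and beat series to sampled sites
#'
#' Each site's true AVD-GP probability is the ground-truth field
#' interpolated (barycentrically) at the site's reference-frame position,
#' optionally scaled by a per-patient amplitude factor; the label is a
#' Bernoulli draw, AVD-GP sites split A/B with probability `a_fraction`,
#' and a [simulate_beat_series()] realises each label.
#'
#' @param sites a [sample_sites()] result (faces/barycentrics index the
#'   reference topology).
#' @param reference the reference [atrial_surface()].
#' @param truth a [ground_truth_field()] result.
#' @param params an [rr_params()] list.
#' @param amp_scale per-patient multiplicative factor on the field.
#' @return list: `label` (per site), `p_true`, `ref_positions` (n x 3,
#'   reference frame), `series` (list of [beat_series()]).
#' @export
assign_true_labels <- function(sites, reference, truth,
                               params = rr_params(), amp_scale = 1) {
  f <- reference$faces[sites$face, , drop = FALSE]
  vals <- matrix(truth$values[f], ncol = 3)
  p <- pmin(1, rowSums(vals * sites$bary) * amp_scale)
  refpos <- reference$vertices[f[, 1], ] * sites$bary[, 1] +
    reference$vertices[f[, 2], ] * sites$bary[, 2] +
    reference$vertices[f[, 3], ] * sites$bary[, 3]
  n <- length(p)
  is_gp <- stats::runif(n) < p
  is_a <- stats::runif(n) < params$a_fraction
  label <- ifelse(is_gp, ifelse(is_a, "A_AVD_GP", "B_AVD_GP"), "NEGATIVE")
  series <- lapply(label, simulate_beat_series, params = params)
  list(label = label, p_true = p, ref_positions = refpos, series = series)
}
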