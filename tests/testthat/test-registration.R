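# Similarity (Procrustes) + thin-plate-spline registration, held-out TRE
# and angle-based fiducial phase selection.

test_that("fit_similarity recovers exact and random similarities", {
  set.seed(101)
  X <- matrix(stats::rnorm(30), 10, 3)
  tf <- fit_similarity(X, X)
  expect_equal(tf$R, diag(3), tolerance = 1e-9)
  expect_equal(tf$s, 1, tolerance = 1e-9)
  expect_equal(tf$rmse, 0, tolerance = 1e-9)

  # 30-degree rotation about z with scale 1.2
  a <- pi / 6
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  Y <- 1.2 * X %*% t(Rz)
  tf <- fit_similarity(X, Y)
  expect_equal(tf$R, Rz, tolerance = 1e-9)
  expect_equal(tf$s, 1.2, tolerance = 1e-9)

  # random similarities recovered to 1e-9
  for (i in 1:25) {
    R <- random_rotation()
    s <- stats::runif(1, 0.5, 2)
    t <- stats::rnorm(3, sd = 10)
    Y <- sweep(s * X %*% t(R), 2, t, "+")
    tf <- fit_similarity(X, Y)
    expect_equal(tf$R, R, tolerance = 1e-9)
    expect_equal(tf$s, s, tolerance = 1e-9)
    expect_equal(tf$t, t, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("fit_similarity residual is a least-squares optimum", {
  # independent check: no small perturbation of (R, s, t) improves the fit
  set.seed(102)
  X <- matrix(stats::rnorm(36), 12, 3)
  Y <- 1.3 * X %*% t(random_rotation()) + matrix(stats::rnorm(36, sd = 0.3),
                                                 12, 3)
  tf <- fit_similarity(X, Y)
  rss <- function(R, s, t) sum((sweep(s * X %*% t(R), 2, t, "+") - Y)^2)
  base <- rss(tf$R, tf$s, tf$t)
  for (i in 1:200) {
    w <- stats::rnorm(3, sd = 1e-4)
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
                byrow = TRUE)
    Rp <- tf$R %*% (diag(3) + K) # small rotation perturbation
    expect_gte(rss(Rp, tf$s * (1 + stats::rnorm(1, sd = 1e-4)),
                   tf$t + stats::rnorm(3, sd = 1e-4)), base - 1e-12)
  }
  expect_error(fit_similarity(X[1:2, ], Y[1:2, ]), "at least 3")
  L <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_similarity(L, L), "collinear")
})

test_that("thin-plate spline: identity, affine reproduction, coincidence", {
  set.seed(103)
  C <- matrix(stats::rnorm(45, sd = 10), 15, 3)
  w0 <- fit_nonrigid(C, C, lambda = 0)
  P <- matrix(stats::rnorm(60, sd = 15), 20, 3)
  expect_equal(apply_warp(w0, P), P, tolerance = 1e-8)

  # pure translation reproduced everywhere
  tr <- c(3, -5, 2)
  wt <- fit_nonrigid(C, sweep(C, 2, tr, "+"))
  expect_equal(apply_warp(wt, P), sweep(P, 2, tr, "+"), tolerance = 1e-8)

  # general affine map reproduced everywhere (polynomial part exactness)
  A <- diag(3) + matrix(stats::rnorm(9, sd = 0.2), 3, 3)
  wa <- fit_nonrigid(C, C %*% t(A) + 1.5)
  expect_equal(apply_warp(wa, P), P %*% t(A) + 1.5, tolerance = 1e-7)

  expect_error(fit_nonrigid(rbind(C, C[1, ]), rbind(C, C[1, ])),
               "coincident")
  expect_error(fit_nonrigid(C, C, lambda = -1), ">= 0")
})

test_that("TPS generalises a smooth synthetic deformation", {
  ref <- fixture_reference()
  pat <- make_patient_shell(ref, 3, seed = 42)
  # landmark pairs sampled from the exact correspondence
  set.seed(44)
  li <- sample.int(nrow(ref$vertices), 60)
  warp <- fit_nonrigid(pat$surface$vertices[li, ], ref$vertices[li, ])
  unseen <- sample.int(nrow(ref$vertices), 400)
  mapped <- apply_warp(warp, pat$surface$vertices[unseen, ])
  err <- sqrt(rowSums((mapped - ref$vertices[unseen, ])^2))
  expect_lt(stats::median(err), 1.5)
})

test_that("landmark interpolation, projection and identity registration", {
  ref <- fixture_reference()
  rings <- fixture_rings()
  lm <- do.call(rbind, lapply(rings, function(r)
    generate_landmark_ring(r, 8, 0)$points))
  used <- seq(1, 32, by = 2); held <- seq(2, 32, by = 2)
  reg <- register_landmarks(lm, lm, used, held, reference_surface = ref,
                            source_id = "ref", reference_id = "ref")
  # identity registration: TRE = 0 and used landmarks map onto themselves
  expect_equal(reg$tre_mm, 0, tolerance = 1e-8)
  tr <- transform_to_reference(reg, lm[used, ])
  expect_equal(tr$points, lm[used, ], tolerance = 1e-8)
  expect_true(all(tr$projection_distance < 1e-6))
  # arbitrary points are unchanged under the identity fit
  set.seed(7)
  pts <- ref$vertices[sample.int(nrow(ref$vertices), 50), ]
  expect_equal(transform_to_reference(reg, pts)$points, pts,
               tolerance = 1e-6)
  expect_error(register_landmarks(lm, lm, used, used), "disjoint")
})

test_that("compute_tre: single displaced pair and distance-sum oracle", {
  set.seed(105)
  base <- matrix(stats::rnorm(24, sd = 10), 8, 3)
  # identity-fitting configuration with one held-out pair displaced 3 mm
  src <- rbind(base, base[1, ] + c(20, 0, 0))
  dst <- rbind(base, base[1, ] + c(20, 0, 0) + c(0, 3, 0))
  reg <- register_landmarks(src, dst, used = 1:8, held_out = 9)
  expect_equal(reg$tre_mm, 3, tolerance = 1e-6)

  # random registrations match a hand-computed mean distance
  for (i in 1:20) {
    src <- matrix(stats::rnorm(45, sd = 10), 15, 3)
    dst <- src + matrix(stats::rnorm(45, sd = 2), 15, 3)
    used <- 1:9; held <- 10:15
    reg <- register_landmarks(src, dst, used, held)
    mapped <- apply_warp(reg$warp, apply_similarity(reg$similarity,
                                                    src[held, ]))
    oracle <- mean(sqrt(rowSums((mapped - dst[held, ])^2)))
    expect_equal(reg$tre_mm, oracle, tolerance = 1e-12)
  }
  reg <- register_landmarks(src, dst, used = 1:15)
  expect_error(compute_tre(reg), "empty")
})

test_that("TRE is invariant to a common rigid motion", {
  set.seed(106)
  src <- matrix(stats::rnorm(45, sd = 10), 15, 3)
  dst <- src + matrix(stats::rnorm(45, sd = 2), 15, 3)
  reg <- register_landmarks(src, dst, used = 1:9, held_out = 10:15)
  for (i in 1:10) {
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 20)
    move <- function(p) sweep(p %*% t(R), 2, tr, "+")
    reg2 <- register_landmarks(move(src), move(dst), used = 1:9,
                               held_out = 10:15)
    expect_equal(reg2$tre_mm, reg$tre_mm, tolerance = 1e-9)
  }
})

test_that("phase selection: self-registration optimum and input checks", {
  ref <- fixture_reference()
  rings <- fixture_rings()
  sel <- select_fiducial_phases(rings, rings, ref, n_per_ring = 8,
                                grid_steps = 8)
  expect_equal(sel$objective, 0, tolerance = 1e-8)
  # ties broken lexicographically: the zero phase vector wins
  expect_equal(sel$phases, rep(0, 4), tolerance = 1e-12)
  expect_error(select_fiducial_phases(rings, rings, ref, grid_steps = 1),
               "grid_steps")
  expect_error(select_fiducial_phases(rings[1:3], rings, ref),
               "four junction rings")
})

test_that("phase selection compensates a constructed ring rotation", {
  ref <- fixture_reference()
  rings <- fixture_rings()
  n <- 8; steps <- 16
  period <- 2 * pi / n
  truth <- c(0.17, 0.33, 0.05, 0.29) # radians, within [0, period)
  sel <- select_fiducial_phases(rings, rings, ref, n_per_ring = n,
                                grid_steps = steps,
                                reference_phases = truth)
  step <- period / steps
  err <- abs((sel$phases - truth + period / 2) %% period - period / 2)
  expect_true(all(err <= step + 1e-9))
  expect_lt(sel$objective, 0.5)
})

test_that("selected phases beat fixed zero phases on a small cohort", {
  ref <- fixture_reference()
  curv <- fixture_curvature()
  ref_rings <- fixture_rings()
  set.seed(301)
  tre_sel <- tre_zero <- numeric(4)
  for (i in 1:4) {
    pat <- make_patient_shell(ref, 3, seed = 300 + i)
    cv <- vertex_curvature(pat$surface)
    src_rings <- lapply(PV_LABELS, function(pv)
      find_junction_plane(pat$surface, pv, curvature = cv))
    sel <- select_fiducial_phases(src_rings, ref_rings, ref,
                                  n_per_ring = 8, grid_steps = 8)
    tre_sel[i] <- sel$objective
    # fixed zero phases
    src_lm <- do.call(rbind, lapply(src_rings, function(r)
      generate_landmark_ring(r, 8, 0)$points))
    ref_lm <- do.call(rbind, lapply(ref_rings, function(r)
      generate_landmark_ring(r, 8, 0)$points))
    reg0 <- register_landmarks(src_lm, ref_lm, seq(1, 32, 2), seq(2, 32, 2),
                               reference_surface = ref)
    tre_zero[i] <- reg0$tre_mm
  }
  expect_lt(mean(tre_sel), mean(tre_zero))
  # registration quality commensurate with clinical accuracy (<= 3 mm)
  expect_lt(mean(tre_sel), 3)
})

test_that("registration JSON round-trips", {
  ref <- fixture_reference()
  rings <- fixture_rings()
  lm <- do.call(rbind, lapply(rings, function(r)
    generate_landmark_ring(r, 8, 0.1)$points))
  lm2 <- lm + matrix(stats::rnorm(length(lm), sd = 0.5), nrow(lm), 3)
  reg <- register_landmarks(lm2, lm, seq(1, 32, 2), seq(2, 32, 2),
                            reference_surface = ref, source_id = "P01")
  path <- withr::local_tempfile(fileext = ".json")
  write_registration_json(reg, path, phases = c(0.1, 0.2, 0.3, 0))
  back <- read_registration_json(path, ref)
  expect_equal(back$similarity$R, reg$similarity$R, tolerance = 1e-12)
  expect_equal(back$warp$W, reg$warp$W, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$tre_mm, reg$tre_mm, tolerance = 1e-12)
  expect_equal(back$phases, c(0.1, 0.2, 0.3, 0))
  expect_equal(compute_tre(back), reg$tre_mm, tolerance = 1e-9)
})
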