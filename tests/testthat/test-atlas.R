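# Kernel probability fields, cohort averaging, peak detection and the
# area-concentration statistic.

test_that("patient_field: constants, masking, symmetry", {
  surf <- flat_grid_surface(12, 2) # 22 x 22 mm sheet
  pos <- rbind(c(4, 4, 0), c(10, 16, 0), c(16, 6, 0))
  f1 <- patient_field(pos, c(1, 1, 1), surf, sigma_mm = 5)
  def <- f1$values[!is.na(f1$values)]
  expect_equal(def, rep(1, length(def)), tolerance = 1e-12)

  # single positive site: 1 at its vertex, undefined beyond 3 sigma
  f <- patient_field(rbind(c(0, 0, 0)), 1, surf, sigma_mm = 2)
  expect_equal(f$values[1], 1)
  far <- which(sqrt(rowSums(surf$vertices^2)) > 6 + 1e-9)
  expect_true(all(is.na(f$values[far])))
  near <- which(sqrt(rowSums(surf$vertices^2)) < 6 - 1e-9)
  expect_true(all(!is.na(f$values[near])))

  # vertex equidistant from one positive and one negative site
  f <- patient_field(rbind(c(6, 10, 0), c(14, 10, 0)), c(1, 0), surf)
  mid <- which(surf$vertices[, 1] == 10 & surf$vertices[, 2] == 10)
  expect_equal(f$values[mid], 0.5)

  expect_error(patient_field(matrix(0, 0, 3), numeric(0), surf),
               "at least one")
  expect_error(patient_field(pos, c(1, 0, 0.5), surf), "binary")
  expect_error(patient_field(pos, c(1, 0, 1), surf, sigma_mm = 0),
               "positive")
})

test_that("patient_field matches a brute-force double loop to 1e-12", {
  surf <- flat_grid_surface(8, 3)
  set.seed(201)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    pos <- cbind(stats::runif(n, 0, 21), stats::runif(n, 0, 21), 0)
    p <- stats::rbinom(n, 1, 0.4)
    sg <- stats::runif(1, 2, 8)
    f <- patient_field(pos, p, surf, sg)
    for (vi in sample.int(nrow(surf$vertices), 12)) {
      num <- den <- 0
      for (j in seq_len(n)) {
        w <- exp(-sum((surf$vertices[vi, ] - pos[j, ])^2) / (2 * sg^2))
        num <- num + p[j] * w
        den <- den + w
      }
      if (den >= exp(-4.5)) {
        expect_equal(f$values[vi], num / den, tolerance = 1e-12)
      } else {
        expect_true(is.na(f$values[vi]))
      }
    }
    # convex-combination property
    def <- f$values[!is.na(f$values)]
    expect_true(all(def >= min(p) - 1e-12 & def <= max(p) + 1e-12))
  }
})

test_that("shrinking sigma drives values to the nearest site outcome", {
  surf <- flat_grid_surface(8, 3)
  # sites near (but not on) well-separated vertices
  base <- rbind(c(3, 3, 0), c(15, 3, 0), c(3, 15, 0), c(15, 15, 0),
                c(9, 9, 0))
  set.seed(202)
  pos <- base + cbind(stats::runif(5, -0.2, 0.2),
                      stats::runif(5, -0.2, 0.2), 0)
  p <- c(1, 0, 1, 0, 1)
  nn <- apply(pos, 1, function(q)
    which.min(rowSums(sweep(surf$vertices, 2, q)^2)))
  dev_prev <- Inf
  for (sg in c(5, 2, 1, 0.5)) {
    f <- patient_field(pos, p, surf, sigma_mm = sg)
    dev <- max(abs(f$values[nn] - p))
    expect_lte(dev, dev_prev + 1e-12)
    dev_prev <- dev
  }
  expect_lt(dev_prev, 1e-6)
})

test_that("cohort_average: masked mean, permutation invariance, checks", {
  surf <- flat_grid_surface(6, 4)
  mkf <- function(vals) structure(
    list(values = vals, coverage = as.integer(!is.na(vals)),
         sigma_mm = 5, weight_cutoff = exp(-4.5), surface = surf),
    class = "probability_field")
  n <- nrow(surf$vertices)
  a <- mkf(rep(0.2, n))
  b <- mkf(rep(0.6, n))
  avg <- cohort_average(list(a, b))
  expect_true(all(avg$values == 0.4))
  expect_true(all(avg$coverage == 2L))
  # single patient: identity
  expect_equal(cohort_average(list(a))$values, a$values)
  # undefined patients are excluded, not imputed as zero
  cvals <- rep(0.9, n); cvals[1:5] <- NA
  cc <- mkf(cvals)
  avg <- cohort_average(list(a, b, cc))
  expect_equal(avg$values[1], 0.4)
  expect_equal(avg$coverage[1], 2L)
  expect_equal(avg$values[6], mean(c(0.2, 0.6, 0.9)))
  # permutation invariance
  set.seed(203)
  fl <- lapply(1:5, function(i) {
    v <- stats::runif(n); v[sample.int(n, 10)] <- NA; mkf(v)
  })
  a1 <- cohort_average(fl)
  a2 <- cohort_average(fl[c(3, 5, 1, 4, 2)])
  expect_equal(a1$values, a2$values)
  expect_equal(a1$coverage, a2$coverage)
  # mismatched surfaces rejected
  other <- flat_grid_surface(5, 4)
  bad <- structure(list(values = rep(0.1, nrow(other$vertices)),
                        coverage = rep(1L, nrow(other$vertices)),
                        sigma_mm = 5, weight_cutoff = exp(-4.5),
                        surface = other), class = "probability_field")
  expect_error(cohort_average(list(a, bad)), "share the reference")
})

test_that("find_peaks: thresholds are strict and components split", {
  surf <- flat_grid_surface(6, 4)
  n <- nrow(surf$vertices)
  mkf <- function(vals) structure(
    list(values = vals, coverage = as.integer(!is.na(vals)),
         sigma_mm = 5, weight_cutoff = exp(-4.5), surface = surf),
    class = "probability_field")
  expect_length(find_peaks(mkf(rep(0.1, n))), 0)
  # values exactly at the threshold are excluded (strict >)
  expect_length(find_peaks(mkf(rep(0.20, n)), threshold = 0.20), 0)
  expect_length(find_peaks(mkf(rep(1, n)), threshold = 1.0), 0)
  expect_error(find_peaks(mkf(rep(NA_real_, n))), "undefined")
})

test_that("find_peaks recovers the three generator hotspots", {
  ref <- fixture_reference()
  truth <- fixture_truth()
  # noise-free kernel-smoothed field (the atlas estimand)
  v <- ref$vertices
  va <- gpatlas:::vertex_area_weights(ref)
  sm <- vapply(seq_len(nrow(v)), function(i) {
    w <- exp(-rowSums(sweep(v, 2, v[i, ])^2) / 50) * va
    sum(w * truth$values) / sum(w)
  }, numeric(1))
  f <- structure(list(values = sm, coverage = rep(1L, nrow(v)),
                      sigma_mm = 5, weight_cutoff = exp(-4.5),
                      surface = ref), class = "probability_field")
  pk <- find_peaks(f, 0.20)
  expect_length(pk, 3)
  # sorted by peak probability, each within 10 mm of a distinct hotspot
  pp <- vapply(pk, function(p) p$peak_probability, numeric(1))
  expect_true(all(diff(pp) <= 0))
  hit <- vapply(pk, function(p) {
    d <- sqrt(rowSums(sweep(truth$centers, 2, v[p$vertex, ])^2))
    which.min(d) * (min(d) < 10)
  }, numeric(1))
  expect_setequal(hit, 1:3)
})

test_that("area_concentration: concentrated, uniform and full coverage", {
  surf <- flat_grid_surface(11, 2) # 20 x 20 mm, 200 triangles
  n <- nrow(surf$vertices)
  # high probability only in the lower-left 6x6 mm corner
  vals <- as.numeric(surf$vertices[, 1] <= 6 & surf$vertices[, 2] <= 6)
  f <- structure(list(values = vals, coverage = rep(1L, n), sigma_mm = 5,
                      weight_cutoff = exp(-4.5), surface = surf),
                 class = "probability_field")
  set.seed(204)
  gp <- cbind(stats::runif(40, 0.2, 5.8), stats::runif(40, 0.2, 5.8), 0)
  res <- area_concentration(f, gp, site_coverage = 0.90)
  patch <- sum(face_areas(surf)[rowMeans(matrix(
    vals[surf$faces], ncol = 3)) > 0.99]) / surface_area(surf)
  expect_lt(res$area_fraction, patch * 1.6)
  expect_gte(res$sites_contained, 0.90)

  # uniform field + uniform sites: fraction ~ 0.9 (rank ties by index)
  fu <- structure(list(values = rep(0.5, n), coverage = rep(1L, n),
                       sigma_mm = 5, weight_cutoff = exp(-4.5),
                       surface = surf), class = "probability_field")
  fr <- replicate(30, {
    gp <- cbind(stats::runif(60, 0, 20), stats::runif(60, 0, 20), 0)
    area_concentration(fu, gp, 0.90)$area_fraction
  })
  expect_equal(mean(fr), 0.9, tolerance = 0.05)

  # full coverage with one outlying site in a low-probability triangle
  vals2 <- vals; vals2[vals2 == 0] <- 0.01
  f2 <- structure(list(values = vals2, coverage = rep(1L, n), sigma_mm = 5,
                       weight_cutoff = exp(-4.5), surface = surf),
                  class = "probability_field")
  gp2 <- rbind(gp, c(19.5, 19.5, 0))
  res <- area_concentration(f2, gp2, site_coverage = 1.0)
  expect_gt(res$area_fraction, 0.95)
  expect_error(area_concentration(f, matrix(0, 0, 3)), "no AVD-GP")
})

test_that("atlas CSV round-trip preserves values and coverage", {
  surf <- flat_grid_surface(6, 4)
  n <- nrow(surf$vertices)
  set.seed(205)
  vals <- stats::runif(n); vals[c(3, 9)] <- NA
  f <- structure(list(values = vals, coverage = as.integer(!is.na(vals)),
                      sigma_mm = 5, weight_cutoff = exp(-4.5),
                      surface = surf), class = "probability_field")
  path <- withr::local_tempfile(fileext = ".csv")
  write_atlas_csv(f, path)
  back <- read_atlas_csv(path, surf)
  expect_equal(back$values, f$values, tolerance = 1e-12)
  expect_equal(back$coverage, f$coverage)
  # VTK export writes a parsable mesh
  vp <- withr::local_tempfile(fileext = ".vtk")
  write_atlas_vtk(f, vp)
  m <- load_surface(vp)
  expect_equal(m$vertices, surf$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
})
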