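# Shared fixtures, memoised across test files (shell construction and
# junction detection are the expensive parts).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

fixture_reference <- function() fixture("ref", make_reference_shell())

fixture_curvature <- function()
  fixture("curv", vertex_curvature(fixture_reference()))

fixture_rings <- function()
  fixture("rings", lapply(PV_LABELS, function(pv)
    find_junction_plane(fixture_reference(), pv,
                        curvature = fixture_curvature())))

fixture_truth <- function()
  fixture("truth", ground_truth_field(fixture_reference()))

# small flat grid surface (no labels) for kernel-field tests
flat_grid_surface <- function(n = 12, spacing = 2) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  v <- cbind((g$x - 1) * spacing, (g$y - 1) * spacing, 0)
  id <- function(i, j) (j - 1) * n + i
  f <- list()
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    f[[length(f) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
    f[[length(f) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  }
  atrial_surface(v, do.call(rbind, f))
}

# open cylinder (radius r, length L) with the bottom band labelled BODY and
# the rest one PV: uniform curvature along the sweep
cylinder_surface <- function(r = 5, L = 20, n_az = 32, n_len = 25,
                             body_frac = 0.15) {
  zs <- seq(0, L, length.out = n_len)
  az <- seq(0, 2 * pi, length.out = n_az + 1)[seq_len(n_az)]
  v <- do.call(rbind, lapply(zs, function(z)
    cbind(r * cos(az), r * sin(az), z)))
  id <- function(i, j) (j - 1) * n_az + i # i azimuth, j ring
  f <- list()
  for (j in seq_len(n_len - 1)) for (i in seq_len(n_az)) {
    i2 <- if (i == n_az) 1L else i + 1L
    f[[length(f) + 1]] <- c(id(i, j), id(i2, j), id(i, j + 1))
    f[[length(f) + 1]] <- c(id(i2, j), id(i2, j + 1), id(i, j + 1))
  }
  labels <- ifelse(rep(zs, each = n_az) <= body_frac * L, "BODY", "LSPV")
  # only one PV present: the missing-PV warning is expected here
  suppressWarnings(atrial_surface(v, do.call(rbind, f), labels))
}

# beat series with explicit pre-HFS intervals and in/post-window intervals;
# the first in-window R falls exactly at hfs_start when align_start = TRUE
series_from_intervals <- function(pre, during, hfs_dur,
                                  align_start = TRUE, post = rep(800, 3)) {
  t_pre <- cumsum(c(0, pre))
  if (align_start) {
    hfs_start <- t_pre[length(t_pre)] + 1
    t_in <- hfs_start + cumsum(c(0, during))
  } else {
    hfs_start <- t_pre[length(t_pre)] + 1
    t_in <- hfs_start - 1 + cumsum(during)
  }
  tmax <- t_in[length(t_in)]
  beat_series(c(t_pre, t_in, tmax + cumsum(post)),
              hfs_start, hfs_start + hfs_dur)
}

random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}
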