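#' Construct a beat series around a high-frequency stimulation window
#'
#' A `beat_series` holds the R-wave times (ms) recorded around one
#' endocardial high-frequency stimulation (HFS) application, together with
#' the stimulation on/off times. R-peaks are assumed already extracted
#' (from the arterial pressure trace or the right-ventricular electrogram);
#' no waveform processing happens here.
#'
#' At least 11 R-waves (10 RR intervals) must precede `hfs_start`, because
#' the baseline is defined as the mean of the 10 RR intervals immediately
#' preceding stimulation. Series violating this are rejected.
#'
#' @param r_times numeric vector of strictly increasing R-wave times in ms.
#' @param hfs_start,hfs_end stimulation window bounds in ms,
#'   `hfs_start < hfs_end`.
#' @param source free-text channel tag (e.g. `"arterial"` or `"rv_egm"`).
#' @return An object of class `beat_series`.
#' @examples
#' bs <- beat_series(seq(0, 20000, by = 800), hfs_start = 10000,
#'                   hfs_end = 15000)
#' baseline_mean_rr(bs)
#' @export
beat_series <- function(r_times, hfs_start, hfs_end, source = "arterial") {
  r_times <- as.numeric(r_times)
  stopifnot(is.numeric(hfs_start), is.numeric(hfs_end), length(hfs_start) == 1,
            length(hfs_end) == 1)
  if (anyNA(r_times) || any(!is.finite(r_times)))
    stop("r_times must be finite and non-missing")
  if (is.unsorted(r_times, strictly = TRUE))
    stop("r_times must be strictly increasing")
  if (hfs_start >= hfs_end)
    stop("hfs_start must precede hfs_end")
  n_pre <- sum(r_times < hfs_start)
  if (n_pre < 11)
    stop("rejected: fewer than 11 R-waves precede HFS onset (",
         n_pre, " found); 10 baseline RR intervals are required")
  structure(list(r_times = r_times, hfs_start = hfs_start,
                 hfs_end = hfs_end, source = source),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d R-waves, HFS window [%g, %g] ms (%s)\n",
              length(x$r_times), x$hfs_start, x$hfs_end, x$source))
  invisible(x)
}

#' Baseline mean RR interval before HFS
#'
#' Arithmetic mean of the 10 RR intervals immediately preceding the HFS
#' onset. This beat-count-based window (not a fixed 10 s span) is the
#' baseline against which the HFS response is judged.
#'
#' @param series a [beat_series()].
#' @return Baseline mean RR in ms.
#' @export
baseline_mean_rr <- function(series) {
  stopifnot(inherits(series, "beat_series"))
  pre <- series$r_times[series$r_times < series$hfs_start]
  rr <- diff(utils::tail(pre, 11))
  mean(rr)
}

#' RR statistics during an HFS application
#'
#' Computes the mean and maximum RR interval response to HFS:
#' * `hfs_mean_rr` — the span from the first R-wave at/after `hfs_start`
#'   to the first R-wave at/after `hfs_end`, divided by the number of RR
#'   intervals in that span (the mean RR during stimulation).
#' * `hfs_max_rr` — the longest single RR interval whose right endpoint
#'   falls in `(hfs_start, t_last]`, where `t_last` is the first R-wave
#'   at/after `hfs_end`. The interval that bridges the end of stimulation
#'   counts: an asystolic pause typically spans HFS cessation.
#'
#' If no R-wave occurs inside the stimulation window (complete asystole
#' throughout HFS), the single bridging interval from the last pre-HFS
#' R-wave to the first post-HFS R-wave is used for both statistics.
#'
#' @param series a [beat_series()].
#' @param horizon_ms rejection horizon: if no R-wave occurs within
#'   `horizon_ms` after `hfs_end` the recording is considered truncated.
#' @return An object of class `rr_stats`: a list with `baseline_mean_rr`,
#'   `hfs_mean_rr`, `hfs_max_rr`, `mean_ratio`, `max_ratio` (ratios are
#'   relative to the baseline mean RR).
#' @export
hfs_rr_stats <- function(series, horizon_ms = 30000) {
  stopifnot(inherits(series, "beat_series"))
  t <- series$r_times
  base <- baseline_mean_rr(series)
  i_last <- which(t >= series$hfs_end)
  if (length(i_last) == 0 ||
      t[i_last[1]] - series$hfs_end > horizon_ms)
    stop("rejected: no R-wave within ", horizon_ms,
         " ms after HFS cessation (recording truncated)")
  i_last <- i_last[1]
  t_last <- t[i_last]
  i_first <- which(t >= series$hfs_start)[1]
  if (i_first == 1)
    stop("no R-wave precedes HFS onset") # unreachable for valid beat_series
  if (t[i_first] >= t_last && i_first >= i_last) {
    # no R-wave strictly inside the window: bridge last pre-HFS R to first
    # post-HFS R
    i_pre <- i_first - 1
    bridge <- t_last - t[i_pre]
    hfs_mean <- bridge
    hfs_max <- bridge
  } else {
    k <- i_last - i_first
    if (k == 0) { # single R inside window equal to t_last edge case
      i_pre <- i_first - 1
      bridge <- t_last - t[i_pre]
      hfs_mean <- bridge
      hfs_max <- bridge
    } else {
      hfs_mean <- (t_last - t[i_first]) / k
      # intervals with right endpoint in (hfs_start, t_last]
      right <- which(t > series$hfs_start & t <= t_last)
      right <- right[right >= 2]
      hfs_max <- max(t[right] - t[right - 1])
    }
  }
  structure(list(baseline_mean_rr = base,
                 hfs_mean_rr = hfs_mean,
                 hfs_max_rr = hfs_max,
                 mean_ratio = hfs_mean / base,
                 max_ratio = hfs_max / base),
            class = "rr_stats")
}

#' @export
print.rr_stats <- function(x, ...) {
  cat(sprintf(paste0("<rr_stats> baseline %.1f ms | HFS mean %.1f ms ",
                     "(x%.2f) | HFS max %.1f ms (x%.2f)\n"),
              x$baseline_mean_rr, x$hfs_mean_rr, x$mean_ratio,
              x$hfs_max_rr, x$max_ratio))
  invisible(x)
}

#' Classify an HFS site from its RR statistics
#'
#' A site is an atrioventricular-dissociating ganglionated plexus (AVD-GP)
#' site when HFS causes a >= 50% increase in the mean RR interval relative
#' to baseline. Subtypes:
#' * `A_AVD_GP` (asystole): any single RR interval during HFS exceeds
#'   `asystole_ratio_threshold` times the baseline mean (strictly greater;
#'   default 2.5, i.e. a > 150% single-RR prolongation).
#' * `B_AVD_GP` (bradycardia): the mean-RR criterion is met
#'   (`mean_ratio >= mean_increase_threshold`, inclusive) without asystole.
#' * `NEGATIVE` otherwise.
#'
#' The asystole criterion is checked first, so a short burst terminated at
#' asystole onset is labelled `A_AVD_GP` regardless of its mean ratio.
#'
#' @param stats an `rr_stats` object from [hfs_rr_stats()], or any list
#'   with finite `mean_ratio` and `max_ratio`.
#' @param mean_increase_threshold mean-RR ratio defining an AVD-GP
#'   (default 1.5 = +50%).
#' @param asystole_ratio_threshold single-RR ratio defining asystole
#'   (default 2.5; see [derive_asystole_threshold()] for its calibration).
#' @return A character scalar: `"A_AVD_GP"`, `"B_AVD_GP"` or `"NEGATIVE"`.
#' @export
classify_site <- function(stats, mean_increase_threshold = 1.5,
                          asystole_ratio_threshold = 2.5) {
  if (!is.numeric(mean_increase_threshold) || mean_increase_threshold <= 0 ||
      !is.numeric(asystole_ratio_threshold) || asystole_ratio_threshold <= 0)
    stop("thresholds must be positive numbers")
  if (!is.finite(stats$mean_ratio) || !is.finite(stats$max_ratio))
    stop("RR ratios must be finite")
  if (stats$max_ratio > asystole_ratio_threshold) return("A_AVD_GP")
  if (stats$mean_ratio >= mean_increase_threshold) return("B_AVD_GP")
  "NEGATIVE"
}

#' Convert between an RR ratio and a percent increase over baseline
#'
#' A ratio of 2.5 times baseline is identically a +150% increase; these
#' helpers make the equivalence explicit where thresholds are reported.
#'
#' @param ratio RR interval expressed as a multiple of baseline.
#' @param pct percent increase over baseline.
#' @return The corresponding percent increase / ratio.
#' @export
ratio_to_pct_increase <- function(ratio) 100 * (ratio - 1)

#' @rdname ratio_to_pct_increase
#' @export
pct_increase_to_ratio <- function(pct) 1 + pct / 100

#' Baseline AF RR-variability sample
#'
#' A 20 s atrial-fibrillation R-wave segment used to calibrate the asystole
#' threshold: the derived statistic is the longest RR interval in the last
#' 10 s divided by the mean RR interval of the first 10 s. The segment
#' clock starts at its first R-wave.
#'
#' @param r_times strictly increasing R-wave times (ms) spanning >= 20 s.
#' @return An object of class `af_sample` with the `ratio` field.
#' @export
af_sample <- function(r_times) {
  r_times <- as.numeric(r_times)
  if (is.unsorted(r_times, strictly = TRUE))
    stop("r_times must be strictly increasing")
  t0 <- r_times[1]
  if (r_times[length(r_times)] - t0 < 20000)
    stop("AF segment must span at least 20 s of beats")
  rr <- diff(r_times)
  right <- r_times[-1] - t0
  first10 <- rr[right <= 10000]
  last10 <- rr[right > 10000 & right <= 20000]
  if (length(first10) < 2 || length(last10) < 1)
    stop("AF segment has too few beats in one of its 10 s halves")
  ratio <- max(last10) / mean(first10)
  structure(list(r_times = r_times, ratio = ratio), class = "af_sample")
}

#' Calibrate the asystole ratio threshold from AF variability
#'
#' Given baseline AF RR-variability samples (each contributing the ratio of
#' its longest late RR to its early mean RR), the ratios are
#' log-transformed, checked for normality (Shapiro-Wilk, reported but not
#' enforced), and the threshold is placed at the one-tailed upper quantile
#' of the fitted log-normal: `exp(mu_log + z * sd_log)` with
#' `z = qnorm(1 - tail_mass)`. At the default 1% tail mass z is 2.33 (to
#' 2 d.p.); a single RR prolongation beyond the resulting ratio has a < 1%
#' chance of arising from ordinary AF variability.
#'
#' `shapiro.test()` accepts at most 5000 observations; larger calibration
#' sets are subsampled deterministically (evenly spaced order statistics)
#' for the normality report only — the quantile fit always uses all ratios.
#'
#' @param samples a list of [af_sample()] objects, or a numeric vector of
#'   ratios directly.
#' @param tail_mass one-tailed false-positive mass (default 0.01).
#' @param operational_threshold the rounded threshold actually used for
#'   classification (default 2.5).
#' @return An object of class `threshold_derivation` with fields
#'   `log_ratios`, `normality_p`, `mu_log`, `sd_log`, `z`,
#'   `derived_ratio_threshold`, `operational_threshold`.
#' @export
derive_asystole_threshold <- function(samples, tail_mass = 0.01,
                                      operational_threshold = 2.5) {
  ratios <- if (is.numeric(samples)) samples
            else vapply(samples, function(s) s$ratio, numeric(1))
  if (length(ratios) < 3)
    stop("at least 3 AF variability samples are required")
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("rejected: all ratios must be finite and positive")
  if (!is.numeric(tail_mass) || tail_mass <= 0 || tail_mass >= 1)
    stop("tail_mass must be in (0, 1)")
  lr <- log(ratios)
  sw <- if (stats::sd(lr) == 0) {
    NA_real_ # degenerate: Shapiro-Wilk undefined for constant data
  } else {
    x <- if (length(lr) > 5000) {
      sort(lr)[round(seq(1, length(lr), length.out = 5000))]
    } else lr
    stats::shapiro.test(x)$p.value
  }
  mu <- mean(lr)
  sd <- stats::sd(lr)
  z <- stats::qnorm(1 - tail_mass)
  structure(list(log_ratios = lr,
                 normality_p = sw,
                 mu_log = mu, sd_log = sd, z = z,
                 derived_ratio_threshold = exp(mu + z * sd),
                 operational_threshold = operational_threshold,
                 tail_mass = tail_mass),
            class = "threshold_derivation")
}

#' @export
print.threshold_derivation <- function(x, ...) {
  cat(sprintf(paste0("<threshold_derivation> n=%d  Shapiro-Wilk p=%s\n",
                     "  log-ratio mean %.4f, sd %.4f; z=%.2f (tail %.3g)\n",
                     "  derived ratio threshold %.3f (operational %.2f)\n"),
              length(x$log_ratios),
              ifelse(is.na(x$normality_p), "NA",
                     sprintf("%.3f", x$normality_p)),
              x$mu_log, x$sd_log, x$z, x$tail_mass,
              x$derived_ratio_threshold, x$operational_threshold))
  invisible(x)
}
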