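# HFS response classification from R-wave series, and threshold
# calibration from AF variability.

test_that("baseline_mean_rr: equal spacing, worked fixture, and oracle", {
  bs <- beat_series(seq(0, 16000, by = 800), 16001, 26000)
  expect_equal(baseline_mean_rr(bs), 800)

  # 10 pre-HFS intervals constructed to average 952 ms
  pre <- c(940, 960, 950, 955, 945, 952, 948, 958, 962, 950)
  expect_equal(mean(pre), 952)
  bs <- series_from_intervals(c(800, pre), c(900, 900), hfs_dur = 1500)
  expect_equal(baseline_mean_rr(bs), 952)

  # random intervals against a direct summation oracle
  set.seed(11)
  for (i in 1:50) {
    rr <- stats::runif(sample.int(10, 1) + 10, 400, 1500)
    t <- cumsum(c(0, rr))
    bs <- beat_series(c(t, max(t) + c(500, 1000, 1600)),
                      max(t) + 1, max(t) + 1200)
    oracle <- sum(rr[(length(rr) - 9):length(rr)]) / 10
    expect_equal(baseline_mean_rr(bs), oracle)
  }
})

test_that("beat_series rejects invalid input", {
  expect_error(beat_series(seq(0, 7200, by = 800), 7201, 12000),
               "fewer than 11")
  expect_error(beat_series(c(0, 800, 800, 1600), 1601, 3000),
               "strictly increasing")
  expect_error(beat_series(seq(0, 16000, 800), 9000, 9000), "precede")
})

test_that("hfs_rr_stats reproduces the worked bradycardia example", {
  pre <- c(940, 960, 950, 955, 945, 952, 948, 958, 962, 950)
  # first R after HFS onset at 0 (relative), first R after cessation at
  # 6440 ms, 4 intervals in between
  bs <- series_from_intervals(c(800, pre), c(1500, 1700, 1600, 1640),
                              hfs_dur = 6000)
  st <- hfs_rr_stats(bs)
  expect_equal(st$baseline_mean_rr, 952)
  expect_equal(st$hfs_mean_rr, 1610)
  expect_equal(st$hfs_max_rr, 1700)
  expect_gt(st$mean_ratio, 1.5) # > 50% increase in mean RR
  expect_lt(st$hfs_max_rr, 2.5 * 952)
  expect_equal(classify_site(st), "B_AVD_GP")
})

test_that("hfs_rr_stats: no-effect window and bridging-pause rule", {
  bs <- series_from_intervals(rep(800, 11), rep(800, 13), hfs_dur = 10000)
  st <- hfs_rr_stats(bs)
  expect_equal(st$mean_ratio, 1.0)
  expect_equal(st$max_ratio, 1.0)

  # complete asystole: no R inside the window; the bridging interval from
  # the last pre-HFS R to the first post-HFS R is both mean and max
  t_pre <- cumsum(c(0, rep(800, 11)))
  last <- max(t_pre)
  bs <- beat_series(c(t_pre, last + 3000, last + 3800),
                    hfs_start = last + 100, hfs_end = last + 1900)
  st <- hfs_rr_stats(bs)
  expect_equal(st$hfs_mean_rr, 3000)
  expect_equal(st$hfs_max_rr, 3000)
  expect_equal(classify_site(st), "A_AVD_GP") # 3000/800 = 3.75 > 2.5
})

test_that("hfs_rr_stats agrees with a brute-force interval enumerator", {
  brute <- function(t, s, e) {
    i_first <- min(which(t >= s)); i_last <- min(which(t >= e))
    base <- mean(diff(t[t < s])[(sum(t < s) - 10):(sum(t < s) - 1)])
    if (i_first >= i_last) {
      b <- t[i_last] - t[max(which(t < s))]
      return(c(base, b, b))
    }
    mean_rr <- (t[i_last] - t[i_first]) / (i_last - i_first)
    rr <- diff(t)
    right <- t[-1]
    mx <- max(rr[right > s & right <= t[i_last]])
    c(base, mean_rr, mx)
  }
  set.seed(21)
  for (i in 1:1000) {
    rr <- stats::rlnorm(30, log(700), 0.3)
    t <- cumsum(c(0, rr))
    s <- stats::runif(1, t[13], t[16])
    e <- s + stats::runif(1, 2000, 8000)
    if (max(t) < e + 100) t <- c(t, e + cumsum(stats::runif(3, 200, 900)))
    bs <- beat_series(t, s, e)
    st <- hfs_rr_stats(bs)
    o <- brute(t, s, e)
    expect_equal(c(st$baseline_mean_rr, st$hfs_mean_rr, st$hfs_max_rr), o,
                 tolerance = 1e-12)
  }
})

test_that("hfs_rr_stats rejects truncated recordings", {
  bs <- beat_series(seq(0, 16000, by = 800), 15500, 17000)
  expect_error(hfs_rr_stats(bs, horizon_ms = 100), "truncated")
})

test_that("classify_site thresholds and boundary semantics", {
  st <- function(mean_ratio, max_ratio)
    list(mean_ratio = mean_ratio, max_ratio = max_ratio)
  expect_equal(classify_site(st(1.0, 1.0)), "NEGATIVE")
  expect_equal(classify_site(st(1.5, 2.0)), "B_AVD_GP")  # inclusive >= 50%
  expect_equal(classify_site(st(1.2, 2.6)), "A_AVD_GP")  # 2.6 > 2.5
  expect_equal(classify_site(st(1.2, 2.5)), "NEGATIVE")  # strictly > 2.5
  expect_equal(classify_site(st(3.0, 2.4)), "B_AVD_GP")
  expect_error(classify_site(st(1, 1), mean_increase_threshold = 0),
               "positive")
  expect_error(classify_site(st(1, 1), asystole_ratio_threshold = -1),
               "positive")
  expect_error(classify_site(st(NaN, 1)), "finite")
})

test_that("classify_site is monotone in both ratios", {
  set.seed(5)
  for (i in 1:200) {
    mr <- stats::runif(1, 0.8, 3); xr <- stats::runif(1, 0.8, 4)
    l0 <- classify_site(list(mean_ratio = mr, max_ratio = xr))
    l_up_max <- classify_site(list(mean_ratio = mr,
                                   max_ratio = xr + stats::runif(1, 0, 2)))
    # increasing max_ratio never moves the label away from A
    if (l0 == "A_AVD_GP") expect_identical(l_up_max, "A_AVD_GP")
    # increasing mean_ratio never moves B back to NEGATIVE
    l_up_mean <- classify_site(list(mean_ratio = mr + stats::runif(1, 0, 2),
                                    max_ratio = xr))
    if (l0 == "B_AVD_GP") expect_true(l_up_mean != "NEGATIVE")
  }
})

test_that("ratio/percent threshold equivalence helpers", {
  expect_identical(pct_increase_to_ratio(150), 2.5)
  expect_identical(ratio_to_pct_increase(2.5), 150)
  expect_equal(pct_increase_to_ratio(ratio_to_pct_increase(1.7)), 1.7)
})

test_that("af_sample computes the late-max / early-mean ratio", {
  # uniform 900 ms AF segment: ratio 1
  s <- af_sample(seq(0, 22500, by = 900))
  expect_equal(s$ratio, 1.0)
  # one 1600 ms pause in the second half, 800 ms otherwise
  rr <- c(rep(800, 13), rep(800, 5), 1600, rep(800, 6))
  s <- af_sample(cumsum(c(0, rr)))
  expect_equal(s$ratio, 2.0)
  expect_error(af_sample(seq(0, 15000, by = 800)), "20 s")
})

test_that("derive_asystole_threshold: quantile, degenerate and oracle", {
  der <- derive_asystole_threshold(c(1.4, 1.6, 1.8, 2.0), tail_mass = 0.01)
  expect_equal(round(der$z, 2), 2.33)

  # zero-variance ratios: threshold equals the common ratio
  der <- derive_asystole_threshold(rep(1.8, 10))
  expect_equal(der$sd_log, 0)
  expect_equal(der$derived_ratio_threshold, 1.8)
  expect_true(is.na(der$normality_p))

  # closed-form log-normal quantile oracle
  set.seed(31)
  ratios <- stats::rlnorm(10000, 0, 0.1)
  der <- derive_asystole_threshold(ratios)
  expect_equal(der$derived_ratio_threshold, exp(stats::qnorm(0.99) * 0.1),
               tolerance = 0.01)
  expect_gt(der$normality_p, 0.001) # log-ratios are genuinely normal here

  expect_error(derive_asystole_threshold(c(1.5, 2)), "at least 3")
  expect_error(derive_asystole_threshold(c(1.5, 2, -1)), "positive")
  expect_error(derive_asystole_threshold(c(1.5, 2, 1), tail_mass = 1.5),
               "tail_mass")
})

test_that("classify_sites joins tables and flags rejections", {
  t1 <- cumsum(c(0, rep(800, 12), 1500, 1700, 1600, 1640, rep(800, 3)))
  beats <- rbind(data.frame(patient_id = "P1", site_id = "S1",
                            r_time_ms = t1),
                 data.frame(patient_id = "P1", site_id = "S2",
                            r_time_ms = cumsum(c(0, rep(700, 4)))))
  sites <- data.frame(patient_id = c("P1", "P1"),
                      site_id = c("S1", "S2"),
                      hfs_start_ms = c(9600, 1000), # R-wave exactly at onset
                      hfs_end_ms = c(15600, 3000))
  out <- classify_sites(beats, sites)
  expect_equal(nrow(out), 2)
  expect_equal(out$label[1], "B_AVD_GP")
  expect_equal(out$hfs_mean_rr[1], 1610)
  expect_equal(out$label[2], "REJECTED")
  expect_match(out$reason[2], "fewer than 11")
  s <- summarize_labels(out)
  expect_equal(s$total_tested, 1)
  expect_equal(unname(s$b_avd_gp["n"]), 1)
})
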