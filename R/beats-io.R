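# CSV interchange for R-peak series and classification reports.
# beats.csv: patient_id, site_id, r_time_ms (one row per beat)
# sites.csv: patient_id, site_id, hfs_start_ms, hfs_end_ms
# labels.csv: patient_id, site_id, baseline_mean_rr, hfs_mean_rr,
#             hfs_max_rr, mean_ratio, max_ratio, label

#' Read beat and site tables and classify every HFS site
#'
#' Joins a per-beat table with a per-site HFS-window table, builds a
#' [beat_series()] per site, computes [hfs_rr_stats()] and
#' [classify_site()] for each, and returns the classification report.
#' Sites whose series fail validation (too few baseline beats, truncated
#' recording) are reported with `label = "REJECTED"` and the reason.
#'
#' @param beats data.frame with columns `patient_id`, `site_id`,
#'   `r_time_ms`, or path to such a CSV.
#' @param sites data.frame with columns `patient_id`, `site_id`,
#'   `hfs_start_ms`, `hfs_end_ms`, or path to such a CSV.
#' @param mean_increase_threshold,asystole_ratio_threshold see
#'   [classify_site()].
#' @return data.frame: one row per site with RR statistics, `label` and
#'   `reason` (NA unless rejected).
#' @export
classify_sites <- function(beats, sites, mean_increase_threshold = 1.5,
                           asystole_ratio_threshold = 2.5) {
  if (is.character(beats)) beats <- utils::read.csv(beats)
  if (is.character(sites)) sites <- utils::read.csv(sites)
  need_b <- c("patient_id", "site_id", "r_time_ms")
  need_s <- c("patient_id", "site_id", "hfs_start_ms", "hfs_end_ms")
  if (!all(need_b %in% names(beats)))
    stop("beats table needs columns: ", paste(need_b, collapse = ", "))
  if (!all(need_s %in% names(sites)))
    stop("sites table needs columns: ", paste(need_s, collapse = ", "))
  key_b <- paste(beats$patient_id, beats$site_id, sep = "\r")
  out <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    tt <- sort(beats$r_time_ms[key_b == paste(s$patient_id, s$site_id,
                                              sep = "\r")])
    row <- data.frame(patient_id = s$patient_id, site_id = s$site_id,
                      baseline_mean_rr = NA_real_, hfs_mean_rr = NA_real_,
                      hfs_max_rr = NA_real_, mean_ratio = NA_real_,
                      max_ratio = NA_real_, label = "REJECTED",
                      reason = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      bs <- beat_series(tt, s$hfs_start_ms, s$hfs_end_ms)
      st <- hfs_rr_stats(bs)
      row$baseline_mean_rr <- st$baseline_mean_rr
      row$hfs_mean_rr <- st$hfs_mean_rr
      row$hfs_max_rr <- st$hfs_max_rr
      row$mean_ratio <- st$mean_ratio
      row$max_ratio <- st$max_ratio
      row$label <- classify_site(st, mean_increase_threshold,
                                 asystole_ratio_threshold)
      row
    }, error = function(e) {
      row$reason <- conditionMessage(e)
      row
    })
    res
  })
  do.call(rbind, out)
}

#' Summarise a classification report
#'
#' Counts tested sites, AVD-GP sites and the A/B split, overall and per
#' patient, mirroring the usual cohort-table layout.
#'
#' @param labels classification report from [classify_sites()] (or path to
#'   its CSV form).
#' @return list with `total`, `avd_gp` (n, fraction), `a_avd_gp`,
#'   `b_avd_gp` (n, fraction of AVD-GPs) and a per-patient data.frame.
#' @export
summarize_labels <- function(labels) {
  if (is.character(labels)) labels <- utils::read.csv(labels)
  ok <- labels[labels$label != "REJECTED", , drop = FALSE]
  is_gp <- ok$label %in% c("A_AVD_GP", "B_AVD_GP")
  n_gp <- sum(is_gp)
  per <- do.call(rbind, lapply(split(ok, ok$patient_id), function(d) {
    data.frame(patient_id = d$patient_id[1], tested = nrow(d),
               avd_gp = sum(d$label != "NEGATIVE"),
               a_avd_gp = sum(d$label == "A_AVD_GP"),
               b_avd_gp = sum(d$label == "B_AVD_GP"))
  }))
  rownames(per) <- NULL
  list(total_tested = nrow(ok),
       avd_gp = c(n = n_gp, fraction = n_gp / max(1, nrow(ok))),
       a_avd_gp = c(n = sum(ok$label == "A_AVD_GP"),
                    fraction_of_gp = if (n_gp) sum(ok$label == "A_AVD_GP") / n_gp else NA),
       b_avd_gp = c(n = sum(ok$label == "B_AVD_GP"),
                    fraction_of_gp = if (n_gp) sum(ok$label == "B_AVD_GP") / n_gp else NA),
       per_patient = per)
}
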