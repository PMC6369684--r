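# Whole-cohort simulation: reference shell + ground truth + per-patient
# deformed anatomies, HFS site layouts and R-wave series, all reproducible
# from one master seed.

#' Cohort simulation configuration
#'
#' Defaults state the emulated clinical world: ~75 HFS sites per patient
#' at a ~6 mm coverage spacing, a ground-truth field with three hotspots
#' over a low background, smooth ~3 mm anatomical deformations, an 80/20
#' asystole/bradycardia split among AVD-GP sites, and log-normal AF RR
#' variability.
#'
#' @param n_patients cohort size (default 20).
#' @param sites_per_patient target HFS sites per patient (default 75).
#' @param min_site_spacing_mm coverage spacing target (default 6).
#' @param hotspots ground-truth hotspot table ([default_hotspots()]).
#' @param background ground-truth background probability (default 0.05).
#' @param field_mean_target optional mean-field target (adjusts the
#'   background; see [ground_truth_field()]).
#' @param deformation_scale_mm RMS patient deformation (default 3).
#' @param rr an [rr_params()] list.
#' @param patient_amp_log_sd log-SD of the per-patient field amplitude
#'   factor (default 0.3), emulating the strong between-patient spread of
#'   AVD-GP counts.
#' @param shell a [shell_params()] list.
#' @param seed master seed; the whole cohort is a deterministic function
#'   of it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 20, sites_per_patient = 75,
                          min_site_spacing_mm = 6,
                          hotspots = default_hotspots(),
                          background = 0.05, field_mean_target = NULL,
                          deformation_scale_mm = 3, rr = rr_params(),
                          patient_amp_log_sd = 0.3,
                          shell = shell_params(), seed = 1) {
  structure(list(n_patients = n_patients,
                 sites_per_patient = sites_per_patient,
                 min_site_spacing_mm = min_site_spacing_mm,
                 hotspots = hotspots, background = background,
                 field_mean_target = field_mean_target,
                 deformation_scale_mm = deformation_scale_mm,
                 rr = rr, patient_amp_log_sd = patient_amp_log_sd,
                 shell = shell, seed = seed),
            class = "cohort_config")
}

#' Simulate a complete synthetic cohort
#'
#' @param config a [cohort_config()].
#' @param reference optional prebuilt reference shell (rebuilt from
#'   `config$shell` otherwise).
#' @return list of class `gp_cohort`: `reference`, `truth`
#'   ([ground_truth_field()]), `patients` (each with `id`, `shell`
#'   ([make_patient_shell()]), `sites` ([sample_sites()]), `labels`
#'   ([assign_true_labels()]), `amp_scale`), `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), reference = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(reference)) reference <- make_reference_shell(config$shell)
  truth <- ground_truth_field(reference, config$hotspots,
                              config$background, config$field_mean_target)
  set.seed(config$seed)
  n <- config$n_patients
  shell_seeds <- sample.int(2^20, n)
  site_seeds <- sample.int(2^20, n)
  label_seeds <- sample.int(2^20, n)
  amp <- exp(stats::rnorm(n, 0, config$patient_amp_log_sd))
  patients <- lapply(seq_len(n), function(i) {
    shell <- make_patient_shell(reference, config$deformation_scale_mm,
                                shell_seeds[i])
    sites <- sample_sites(shell$surface, config$sites_per_patient,
                          config$min_site_spacing_mm, site_seeds[i])
    set.seed(label_seeds[i])
    labels <- assign_true_labels(sites, reference, truth, config$rr,
                                 amp_scale = amp[i])
    list(id = sprintf("P%02d", i), shell = shell, sites = sites,
         labels = labels, amp_scale = amp[i])
  })
  structure(list(reference = reference, truth = truth, patients = patients,
                 config = config),
            class = "gp_cohort")
}

#' @export
print.gp_cohort <- function(x, ...) {
  ns <- vapply(x$patients, function(p) p$sites$n, numeric(1))
  cat(sprintf("<gp_cohort> %d patients, %d HFS sites, seed %d\n",
              length(x$patients), sum(ns), x$config$seed))
  invisible(x)
}

#' Flatten a cohort's beat series into beats/sites tables
#'
#' Produces the CSV-shaped interchange tables consumed by
#' [classify_sites()]: one row per R-wave (`beats`) and one row per HFS
#' site with its window and map-space coordinates (`sites`).
#'
#' @param cohort a [simulate_cohort()] result.
#' @return list of data.frames `beats` and `sites`.
#' @export
cohort_tables <- function(cohort) {
  beats <- list(); sites <- list()
  for (p in cohort$patients) {
    for (j in seq_along(p$labels$series)) {
      s <- p$labels$series[[j]]
      sid <- sprintf("%s_S%03d", p$id, j)
      beats[[length(beats) + 1]] <-
        data.frame(patient_id = p$id, site_id = sid,
                   r_time_ms = s$r_times)
      sites[[length(sites) + 1]] <-
        data.frame(patient_id = p$id, site_id = sid,
                   hfs_start_ms = s$hfs_start, hfs_end_ms = s$hfs_end,
                   x_mm = p$sites$positions[j, 1],
                   y_mm = p$sites$positions[j, 2],
                   z_mm = p$sites$positions[j, 3],
                   true_label = p$labels$label[j])
    }
  }
  list(beats = do.call(rbind, beats), sites = do.call(rbind, sites))
}

#' Write a simulated cohort to disk
#'
#' Writes the reference and patient meshes (ascii PLY with label sidecar
#' CSVs, plus the CSV mesh dialect for the reference), `beats.csv`,
#' `sites.csv` and `truth.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_surface(cohort$reference, file.path(dir, "reference.ply"),
               labels_path = file.path(dir, "reference_labels.csv"))
  save_surface(cohort$reference, file.path(dir, "reference_vertices.csv"))
  for (p in cohort$patients) {
    save_surface(p$shell$surface,
                 file.path(dir, paste0(p$id, ".ply")),
                 labels_path = file.path(dir, paste0(p$id, "_labels.csv")))
  }
  tb <- cohort_tables(cohort)
  utils::write.csv(tb$beats, file.path(dir, "beats.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(tb$sites, file.path(dir, "sites.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(background = cohort$truth$background,
                hotspots = cohort$truth$hotspots,
                centers = cohort$truth$centers,
                field = cohort$truth$values,
                patients = lapply(cohort$patients, function(p)
                  list(id = p$id, amp_scale = p$amp_scale,
                       label = p$labels$label, p_true = p$labels$p_true,
                       ref_positions = p$labels$ref_positions)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
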