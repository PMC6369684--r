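# One-command pipeline: simulate -> classify -> register -> atlas ->
# report, with every threshold surfaced in a single config and all
# randomness derived from one seed.

#' Pipeline configuration
#'
#' Bundles every tunable the pipeline uses, at the defaults the method
#' states: mean-RR AVD-GP threshold 1.5 (+50%), asystole ratio 2.5,
#' kernel scale 5 mm, peak threshold 0.20, calibration tail mass 0.01,
#' 8 landmarks per PV ring, 16 phase grid steps.
#'
#' @param cohort a [cohort_config()].
#' @param mean_increase_threshold,asystole_ratio_threshold classifier
#'   thresholds ([classify_site()]).
#' @param sigma_mm atlas kernel scale ([patient_field()]).
#' @param peak_threshold atlas peak threshold ([find_peaks()]).
#' @param tail_mass calibration tail ([derive_asystole_threshold()]).
#' @param landmarks_per_ring,phase_grid_steps registration settings
#'   ([select_fiducial_phases()]).
#' @param tps_lambda TPS regularisation.
#' @param site_coverage share of AVD-GPs for [area_concentration()].
#' @param seed pipeline master seed (overrides `cohort$seed`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            mean_increase_threshold = 1.5,
                            asystole_ratio_threshold = 2.5,
                            sigma_mm = 5, peak_threshold = 0.20,
                            tail_mass = 0.01, landmarks_per_ring = 8,
                            phase_grid_steps = 16, tps_lambda = 0,
                            site_coverage = 0.90, seed = NULL) {
  if (!is.null(seed)) cohort$seed <- seed
  cfg <- list(cohort = cohort,
              mean_increase_threshold = mean_increase_threshold,
              asystole_ratio_threshold = asystole_ratio_threshold,
              sigma_mm = sigma_mm, peak_threshold = peak_threshold,
              tail_mass = tail_mass,
              landmarks_per_ring = landmarks_per_ring,
              phase_grid_steps = phase_grid_steps,
              tps_lambda = tps_lambda, site_coverage = site_coverage)
  bad <- vapply(cfg[-1], function(x) !is.numeric(x) || any(x <= 0),
                logical(1))
  bad["tps_lambda"] <- !is.numeric(cfg$tps_lambda) || cfg$tps_lambda < 0
  if (any(bad))
    stop("non-positive pipeline settings: ",
         paste(names(bad)[bad], collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (lossless JSON round-trip)
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return Invisibly `path` / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_config <- function(config) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$shell$pv_dirs <-
    as.data.frame(x$cohort$shell$pv_dirs) # keep row labels in JSON
  x
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sh <- x$cohort$shell
  sh$pv_dirs <- as.matrix(sh$pv_dirs)
  dimnames(sh$pv_dirs) <- list(rownames(sh$pv_dirs), NULL)
  shell <- shell_params(body_radii = sh$body_radii,
                        pv_radius = sh$pv_radius,
                        fillet_radius = sh$fillet_radius,
                        pv_length = sh$pv_length,
                        pv_dirs = as.matrix(sh$pv_dirs),
                        mv_dir = sh$mv_dir,
                        mv_angle_deg = sh$mv_angle * 180 / pi,
                        subdiv = sh$subdiv)
  co <- x$cohort
  cohort <- cohort_config(n_patients = co$n_patients,
                          sites_per_patient = co$sites_per_patient,
                          min_site_spacing_mm = co$min_site_spacing_mm,
                          hotspots = co$hotspots,
                          background = co$background,
                          field_mean_target = co$field_mean_target,
                          deformation_scale_mm = co$deformation_scale_mm,
                          rr = do.call(rr_params, co$rr[names(co$rr) %in%
                            names(formals(rr_params))]),
                          patient_amp_log_sd = co$patient_amp_log_sd,
                          shell = shell, seed = co$seed)
  pipeline_config(cohort = cohort,
                  mean_increase_threshold = x$mean_increase_threshold,
                  asystole_ratio_threshold = x$asystole_ratio_threshold,
                  sigma_mm = x$sigma_mm, peak_threshold = x$peak_threshold,
                  tail_mass = x$tail_mass,
                  landmarks_per_ring = x$landmarks_per_ring,
                  phase_grid_steps = x$phase_grid_steps,
                  tps_lambda = x$tps_lambda,
                  site_coverage = x$site_coverage)
}

#' Run the full mapping pipeline on a synthetic cohort
#'
#' Stages: simulate the cohort; classify every HFS site from its R-wave
#' series; register each patient surface onto the reference shell
#' (junction detection, phase selection, similarity + TPS, held-out TRE);
#' transform classified sites onto the reference; build per-patient
#' kernel probability fields and the cohort-averaged atlas; detect peaks
#' and the area-concentration statistic; summarise counts, the A/B split
#' and per-patient TRE.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the report bundle (labels.csv,
#'   per-patient registration JSONs, atlas.vtk/atlas.csv, peaks.json,
#'   summary.json, config.json).
#' @param cohort optional pre-simulated [simulate_cohort()] result
#'   matching `config$cohort` (simulated otherwise).
#' @param progress emit per-stage messages.
#' @return list of class `gp_pipeline_result`: `cohort`, `labels`,
#'   `registrations`, `mapped` (per-patient mapped site coordinates),
#'   `fields`, `atlas`, `peaks`, `area`, `summary`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL, progress = TRUE) {
  say <- function(...) if (progress) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  say("stage simulate")
  if (is.null(cohort))
    cohort <- stage("simulate", simulate_cohort(config$cohort))
  reference <- cohort$reference

  say("stage classify")
  tb <- cohort_tables(cohort)
  labels <- stage("classify",
                  classify_sites(tb$beats, tb$sites,
                                 config$mean_increase_threshold,
                                 config$asystole_ratio_threshold))

  say("stage register")
  curv_r <- vertex_curvature(reference)
  reference_rings <- lapply(PV_LABELS, function(pv)
    find_junction_plane(reference, pv, curvature = curv_r))
  registrations <- stage("register", lapply(cohort$patients, function(p) {
    say("  register ", p$id)
    register_surfaces(p$shell$surface, reference,
                      n_per_ring = config$landmarks_per_ring,
                      grid_steps = config$phase_grid_steps,
                      lambda = config$tps_lambda,
                      source_id = p$id, reference_id = "reference",
                      reference_rings = reference_rings)
  }))

  say("stage map & atlas")
  res <- stage("atlas", {
    fields <- list(); mapped <- list(); gp_positions <- list()
    for (i in seq_along(cohort$patients)) {
      p <- cohort$patients[[i]]
      reg <- registrations[[i]]$registration
      mp <- transform_to_reference(reg, p$sites$positions, reference)
      lab_p <- labels$label[labels$patient_id == p$id]
      ok <- lab_p != "REJECTED"
      pbin <- as.numeric(lab_p[ok] != "NEGATIVE")
      fields[[i]] <- patient_field(mp$points[ok, , drop = FALSE], pbin,
                                   reference, config$sigma_mm)
      mapped[[i]] <- mp
      gp_positions[[i]] <- mp$points[ok, , drop = FALSE][pbin == 1, ,
                                                         drop = FALSE]
    }
    atlas <- cohort_average(fields)
    gp_all <- do.call(rbind, gp_positions)
    peaks <- find_peaks(atlas, config$peak_threshold)
    area <- if (nrow(gp_all)) area_concentration(atlas, gp_all,
                                                 config$site_coverage)
            else NULL
    list(fields = fields, mapped = mapped, atlas = atlas, peaks = peaks,
         area = area, gp_all = gp_all)
  })

  tre <- vapply(registrations, function(r) r$tre_mm, numeric(1))
  summ <- summarize_labels(labels)
  summary <- list(
    n_patients = length(cohort$patients),
    hfs_sites_tested = summ$total_tested,
    avd_gp = summ$avd_gp, a_avd_gp = summ$a_avd_gp,
    b_avd_gp = summ$b_avd_gp,
    tre_mm = c(mean = mean(tre), sd = stats::sd(tre)),
    n_peaks = length(res$peaks),
    peak_probabilities = vapply(res$peaks, function(p) p$peak_probability,
                                numeric(1)),
    area_fraction_for_site_coverage =
      if (!is.null(res$area)) res$area$area_fraction else NA_real_,
    site_coverage = config$site_coverage)

  out <- structure(list(cohort = cohort, labels = labels,
                        registrations = registrations,
                        mapped = res$mapped, fields = res$fields,
                        atlas = res$atlas, peaks = res$peaks,
                        area = res$area, summary = summary,
                        config = config),
                   class = "gp_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_bundle(out, out_dir)
  out
}

#' @export
print.gp_pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gp_pipeline_result> %d patients, %d sites tested\n",
              s$n_patients, s$hfs_sites_tested))
  cat(sprintf("  AVD-GP: %d (%.1f%%); A %d (%.0f%% of GP), B %d (%.0f%%)\n",
              s$avd_gp["n"], 100 * s$avd_gp["fraction"],
              s$a_avd_gp["n"], 100 * s$a_avd_gp["fraction_of_gp"],
              s$b_avd_gp["n"], 100 * s$b_avd_gp["fraction_of_gp"]))
  cat(sprintf("  TRE %.2f +/- %.2f mm; %d atlas peaks (%s)\n",
              s$tre_mm["mean"], s$tre_mm["sd"], s$n_peaks,
              paste(sprintf("%.0f%%", 100 * s$peak_probabilities),
                    collapse = ", ")))
  cat(sprintf("  %.0f%% of surface area contains %.0f%% of AVD-GPs\n",
              100 * s$area_fraction_for_site_coverage,
              100 * s$site_coverage))
  invisible(x)
}

#' Write the pipeline report bundle
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return Invisibly `dir`.
#' @export
write_pipeline_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  regdir <- file.path(dir, "registrations")
  dir.create(regdir, showWarnings = FALSE)
  for (i in seq_along(result$registrations)) {
    r <- result$registrations[[i]]
    write_registration_json(r$registration,
                            file.path(regdir,
                                      paste0(r$registration$source_id,
                                             ".json")),
                            phases = r$phases)
  }
  write_atlas_csv(result$atlas, file.path(dir, "atlas.csv"))
  write_atlas_vtk(result$atlas, file.path(dir, "atlas.vtk"))
  jsonlite::write_json(lapply(result$peaks, function(p)
    list(component = p$component, vertex = p$vertex,
         peak_probability = p$peak_probability,
         n_members = length(p$members), annotation = p$annotation)),
    file.path(dir, "peaks.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_pipeline_config(result$config, file.path(dir, "config.json"))
  invisible(dir)
}
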