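# End-to-end orchestration: simulate a synthetic study directory,
# measure anisotropy over its cores, and run the full statistical
# analysis with reproducible configuration.

#' Pipeline run configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param profile `"tiny"` (default; a small study that runs in seconds,
#'   used throughout the test-suite) or `"full"` (full-size cohort of
#'   192 patients with 5000-px core crops -- hours of compute).
#' @param wavelength Illumination wavelength, nm.
#' @param pixel_size Pixel size, um/pixel.  The default 0.05 keeps the
#'   Gaussian-texture correlation length of the recurrent class's lower
#'   tail (g down to ~0.80, a ~0.28 um) above the 4-pixel resolution
#'   guard.
#' @param g_threshold Anisotropy dichotomization threshold (default
#'   0.93).
#' @param aggregation Patient-level aggregation method (default
#'   `"mean"`).
#' @param n_boot Bootstrap replicates for ROC confidence intervals.
#' @param ... Overrides for profile-derived fields (`n_recurrent`,
#'   `n_nonrecurrent`, `rois_per_patient_range`, `gland_radius`,
#'   `stroma_width`, `min_pixels`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, profile = c("tiny", "full"),
                       wavelength = 552, pixel_size = 0.05,
                       g_threshold = 0.93, aggregation = "mean",
                       n_boot = NULL, ...) {
  profile <- match.arg(profile)
  base <- if (profile == "tiny") {
    list(
      n_recurrent = 3L, n_nonrecurrent = 5L,
      rois_per_patient_range = c(2L, 3L),
      gland_radius = 2.5, stroma_width = 2,
      min_pixels = 1500L, n_boot = n_boot %||% 200L
    )
  } else {
    list(
      n_recurrent = 33L, n_nonrecurrent = 159L,
      rois_per_patient_range = c(6L, 18L),
      gland_radius = 5, stroma_width = 4,
      min_pixels = 10000L, n_boot = n_boot %||% 2000L
    )
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown)) stopf("unknown run_config fields: %s", paste(unknown, collapse = ", "))
  base[names(overrides)] <- overrides
  cfg <- c(
    list(seed = as.integer(seed), profile = profile, wavelength = wavelength,
         pixel_size = pixel_size, g_threshold = g_threshold,
         aggregation = aggregation),
    base
  )
  for (f in c("wavelength", "pixel_size", "g_threshold")) {
    if (cfg[[f]] <= 0) stopf("`%s` must be positive", f)
  }
  structure(cfg, class = "run_config")
}

config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_json(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Simulate a complete synthetic study directory
#'
#' Writes, under `out_dir`: `cohort.csv` (patient table), per-patient
#' core images `cores/<id>.tif` (+ JSON sidecars) whose stromal ROI
#' textures are tuned to the patient's ROI-level anisotropy targets,
#' matching `cores/<id>_rois.json` polygon files, and `config.json`
#' (with the config hash).  A `_INCOMPLETE` marker exists while writing
#' and is removed on success, so interrupted runs are detectable.  The
#' output is a deterministic function of the configuration.
#'
#' @param config A [run_config()].
#' @param out_dir Target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
simulate_study <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stopf("`config` must be a run_config")
  dir.create(file.path(out_dir, "cores"), recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "_INCOMPLETE")
  file.create(marker)

  spec <- cohort_spec(
    n_recurrent = config$n_recurrent, n_nonrecurrent = config$n_nonrecurrent,
    rois_per_patient_range = config$rois_per_patient_range,
    seed = config$seed
  )
  cohort <- generate_cohort(spec)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))

  for (i in seq_len(nrow(cohort$patients))) {
    pid <- cohort$patients$patient_id[i]
    targets <- cohort$rois$g_target[cohort$rois$patient_id == pid]
    # clamp tail draws to the g resolvable at this pixel size (a >= 4 px)
    g_min <- grf_theoretical_g(4.05 * config$pixel_size, config$wavelength)
    targets <- pmax(targets, g_min)
    core <- generate_core_image(
      g_target = targets, n_glands = length(targets),
      pixel_size = config$pixel_size,
      gland_radius = config$gland_radius, stroma_width = config$stroma_width,
      seed = derive_seed(config$seed, i), wavelength = config$wavelength,
      min_roi_pixels = config$min_pixels
    )
    for (k in seq_along(core$rois)) {
      core$rois[[k]]$patient_id <- pid
      core$rois[[k]]$core_id <- pid
    }
    write_phase_tiff(core$image, file.path(out_dir, "cores", paste0(pid, ".tif")))
    write_roi_json(core$rois, file.path(out_dir, "cores", paste0(pid, "_rois.json")))
  }
  writeLines(
    sprintf('{"config": %s, "hash": "%s"}', config_json(config), config_hash(config)),
    file.path(out_dir, "config.json")
  )
  unlink(marker)
  invisible(out_dir)
}

read_study_config <- function(study_dir) {
  path <- file.path(study_dir, "config.json")
  if (!file.exists(path)) stopf("no config.json in %s; not a study directory?", study_dir)
  if (file.exists(file.path(study_dir, "_INCOMPLETE"))) {
    stopf("study directory %s is marked incomplete (interrupted simulate run)", study_dir)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- raw$config
  cfg$rois_per_patient_range <- as.integer(cfg$rois_per_patient_range)
  structure(cfg, class = "run_config")
}

#' Measure every core in a study directory
#'
#' Reads each core TIFF and its ROI file, measures anisotropy per ROI,
#' and writes one CSV row per ROI with seed/config provenance columns.
#'
#' @param study_dir Directory produced by [simulate_study()] (or laid
#'   out the same way).
#' @param out_csv Output CSV path (default
#'   `<study_dir>/measurements.csv`).
#' @return The measurements data.frame, invisibly.
#' @export
measure_study <- function(study_dir, out_csv = file.path(study_dir, "measurements.csv")) {
  config <- read_study_config(study_dir)
  icfg <- imaging_config(wavelength = config$wavelength,
                         min_pixels = config$min_pixels)
  tiffs <- sort(list.files(file.path(study_dir, "cores"), pattern = "\\.tif$",
                           full.names = TRUE))
  if (!length(tiffs)) stopf("no core TIFFs under %s", study_dir)
  rows <- lapply(tiffs, function(tf) {
    image <- read_phase_tiff(tf)
    if (any(!is.finite(image$values))) {
      stopf("core %s contains non-finite phase values", basename(tf))
    }
    rois <- read_roi_json(sub("\\.tif$", "_rois.json", tf))
    measure_rois(image, rois, icfg)
  })
  out <- do.call(rbind, rows)
  out$seed <- config$seed
  out$config_hash <- config_hash(config)
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(out)
}

#' Full statistical analysis of a measured study
#'
#' Aggregates ROI measurements to patient level, appends CAPRA-S, and
#' computes every reported statistic: class histograms (ROI- and
#' patient-level), one-way ANOVA between classes, ROC analyses for
#' anisotropy / PSA / Gleason score / CAPRA-S, the Kaplan-Meier curves
#' split at the anisotropy threshold (with 3- and 5-year recurrence-free
#' probabilities and a log-rank test), and sensitivity/specificity
#' stratified by CAPRA-S group and by Gleason stratum.  Writes
#' `report.json`, `roc_curves.csv`, `km_curves.csv`, and
#' `strata_performance.csv` under `out_dir`.
#'
#' @param measurements Measurements data.frame or CSV path.
#' @param cohort Cohort data.frame or CSV path.
#' @param out_dir Output directory (`NULL` = don't write, just return).
#' @param config A [run_config()].
#' @return List of all computed results (the content of
#'   `report.json`, plus the `roc_result` and `km_curve` objects).
#' @export
analyze_study <- function(measurements, cohort, out_dir = NULL,
                          config = run_config()) {
  if (is.character(measurements)) measurements <- utils::read.csv(measurements)
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  need <- c("patient_id", "recurrent", "time_months", "event", "psa",
            "gleason_primary", "gleason_secondary", "sm", "epe", "svi", "lni")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) stopf("cohort lacks required columns: %s", paste(missing, collapse = ", "))
  if (!all(c("patient_id", "g") %in% names(measurements))) {
    stopf("measurements lack required columns patient_id, g")
  }

  patient_g <- aggregate_patient_g(measurements, method = config$aggregation)
  cohort <- merge(cohort, patient_g, by = "patient_id")
  if (!nrow(cohort)) stopf("no overlap between cohort and measurement patient ids")
  cohort <- add_capra_s(cohort)
  cohort$gleason_group <- gleason_stratum(cohort$gleason_primary, cohort$gleason_secondary)
  cohort$recurrent <- as.logical(cohort$recurrent)
  cohort$event <- as.logical(cohort$event)
  rec <- cohort$recurrent

  anova_res <- one_way_anova(split(cohort$g_patient, rec))

  rocs <- list(
    anisotropy = roc_analysis(cohort$g_patient, rec, "lower",
                              n_boot = config$n_boot, seed = config$seed),
    psa = roc_analysis(cohort$psa, rec, "higher",
                       n_boot = config$n_boot, seed = config$seed),
    gleason = roc_analysis(cohort$gleason_primary + cohort$gleason_secondary, rec,
                           "higher", n_boot = config$n_boot, seed = config$seed),
    capra_s = roc_analysis(cohort$capra_s, rec, "higher",
                           n_boot = config$n_boot, seed = config$seed)
  )

  low <- cohort$g_patient < config$g_threshold
  km <- list(
    low = km_estimate(cohort$time_months[low], cohort$event[low], "low anisotropy"),
    high = km_estimate(cohort$time_months[!low], cohort$event[!low], "high anisotropy")
  )
  km_summary <- lapply(km, function(k) {
    s <- km_survival_at(k, c(36, 60))
    list(rfs_3yr = s[1], rfs_5yr = s[2])
  })
  logrank <- if (length(unique(low)) == 2) {
    logrank_test(cohort$time_months, cohort$event, low)
  } else NULL

  strata <- rbind(
    cbind(split_by = "capra_s_group",
          stratified_performance(cohort, "capra_s_group", config$g_threshold)),
    cbind(split_by = "gleason_group",
          stratified_performance(cohort, "gleason_group", config$g_threshold))
  )

  hist_roi <- histogram_g(measurements$g)
  hist_patient <- histogram_g(cohort$g_patient)

  confusion <- confusion_at_threshold(cohort$g_patient, rec,
                                      config$g_threshold, "lower")

  report <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    n_patients = nrow(cohort),
    n_recurrent = sum(rec),
    class_summary = list(
      g_mean_rec = mean(cohort$g_patient[rec]),
      g_sd_rec = stats::sd(cohort$g_patient[rec]),
      g_mean_nonrec = mean(cohort$g_patient[!rec]),
      g_sd_nonrec = stats::sd(cohort$g_patient[!rec])
    ),
    anova = anova_res,
    roc = lapply(rocs, function(r) list(
      auc = r$auc, auc_ci = r$auc_ci, optimal_cutoff = r$optimal_cutoff,
      sensitivity = r$sensitivity, specificity = r$specificity,
      orientation = r$orientation
    )),
    confusion_at_threshold = confusion,
    km = km_summary,
    logrank = logrank,
    strata = strata,
    histogram_roi = hist_roi,
    histogram_patient = hist_patient
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
    roc_curves <- do.call(rbind, lapply(names(rocs), function(nm) {
      cbind(predictor = nm, rocs[[nm]]$curve)
    }))
    utils::write.csv(roc_curves, file.path(out_dir, "roc_curves.csv"), row.names = FALSE)
    km_curves <- do.call(rbind, lapply(names(km), function(nm) {
      cbind(group = nm, as.data.frame(km[[nm]]))
    }))
    utils::write.csv(km_curves, file.path(out_dir, "km_curves.csv"), row.names = FALSE)
    utils::write.csv(strata, file.path(out_dir, "strata_performance.csv"),
                     row.names = FALSE)
  }
  invisible(c(report, list(roc_objects = rocs, km_objects = km, cohort = cohort)))
}

#' Run simulate + measure + analyze in one call
#'
#' @param config A [run_config()].
#' @param out_dir Study directory to create.
#' @return The [analyze_study()] result, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  simulate_study(config, out_dir)
  measurements <- measure_study(out_dir)
  analyze_study(measurements, file.path(out_dir, "cohort.csv"),
                out_dir = file.path(out_dir, "analysis"), config = config)
}
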