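# End-to-end orchestration: simulate -> per-scan metrics and detection ->
# thresholds/scores -> cohort statistics, with a manifest.

#' Default run configuration
#'
#' @param n_subjects Cohort size.
#' @param seed Top-level seed; every stage derives its own from it.
#' @param out_dir Output directory.
#' @param write_scan_files Write per-scan physio/motion/matrix files
#'   (verbose; default FALSE, tables and results only).
#' @param ... Overrides for [cohort_spec()] fields.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 20L, seed = 1L, out_dir = "respfmri-run",
                       write_scan_files = FALSE, ...) {
  structure(list(n_subjects = n_subjects, seed = seed, out_dir = out_dir,
                 write_scan_files = write_scan_files,
                 cohort = list(...)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(cfg[setdiff(names(cfg), "cohort")],
                        cfg$cohort %||% list()))
}

#' @rdname read_run_config
#' @param config A [run_config()] to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Detect breathing patterns in one realized scan
#'
#' Convenience wrapper: respiratory measures from the belt trace, global
#' signal from the parcel matrix, pattern detection.
#'
#' @param physio A [physio_recording()].
#' @param scan A [scan_data()].
#' @return A [detect_patterns()] result.
#' @export
detect_scan <- function(physio, scan) {
  meas <- respiratory_measures(physio$resp, physio$sample_hz)
  gs <- global_signal(scan)
  detect_patterns(meas, gs$z, scan$tr_s, sample_hz = physio$sample_hz)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: simulate the cohort; compute per-scan respiratory measures,
#' gFC and pattern indices; calibrate thresholds on truth-clean scans and
#' score subjects; run the cohort statistics (sex chi-squared on burst
#' calls, ANCOVA of gFC). Writes TSV results and a JSON manifest recording
#' the configuration hash and per-stage outputs.
#'
#' @param config A [run_config()].
#' @return List with `cohort`, `scan_results`, `scores`, `stats`,
#'   `manifest` (also written under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, c(list(n_subjects = config$n_subjects,
                                      seed = config$seed), config$cohort))
  stages <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    res
  }

  cohort <- run_stage("simulate", {
    co <- generate_cohort(spec)
    readr::write_tsv(co$subjects, file.path(out_dir, "subjects.tsv"))
    readr::write_tsv(co$events, file.path(out_dir, "events.tsv"))
    if (config$write_scan_files) write_cohort(co, file.path(out_dir, "scans"))
    co
  })

  scan_results <- run_stage("metrics_detect", {
    rows <- purrr::map_dfr(seq_len(nrow(cohort$scans)), function(i) {
      sub <- cohort$scans$subject[i]
      sc <- cohort$scans$scan[i]
      real <- realize_scan(cohort, sub, sc)
      det <- detect_scan(real$physio, real$scan)
      tibble::tibble(subject = sub, scan = sc,
                     has_burst = cohort$scans$has_burst[i],
                     has_deep = cohort$scans$has_deep[i],
                     burst_index = det$burst_index,
                     deep_index = det$deep_index,
                     rate_cv = det$rate_cv,
                     gfc = as.numeric(gfc(real$scan)))
    })
    readr::write_tsv(rows, file.path(out_dir, "scan_results.tsv"))
    rows
  })

  scores <- run_stage("score", {
    clean <- scan_results[!scan_results$has_burst & !scan_results$has_deep, ]
    if (nrow(clean) < 5L) clean <- scan_results # tiny cohorts: fall back
    thr <- calibrate_thresholds(clean)
    bs <- binarize_and_score(scan_results, thr)
    subj <- dplyr::left_join(bs$scores,
                             dplyr::summarise(
                               dplyr::group_by(scan_results, .data$subject),
                               gfc = mean(.data$gfc), .groups = "drop"),
                             by = "subject")
    subj <- dplyr::left_join(subj, cohort$subjects, by = "subject")
    readr::write_tsv(bs$calls, file.path(out_dir, "scan_calls.tsv"))
    readr::write_tsv(subj, file.path(out_dir, "subject_scores.tsv"))
    list(thresholds = thr, calls = bs$calls, subjects = subj)
  })

  stats_out <- run_stage("stats", {
    calls <- dplyr::left_join(scores$calls,
                              cohort$subjects[, c("subject", "sex")],
                              by = "subject")
    # demo-sized cohorts trip the small-cell approximation warning
    chi2 <- tryCatch(suppressWarnings(sex_pattern_chi2(calls$burst_call,
                                                       calls$sex)),
                     error = function(e) NULL)
    anc <- tryCatch(
      ancova_gfc(scores$subjects, gfc ~ sex + icv_z + burst_index + deep_index),
      error = function(e) NULL)
    if (!is.null(chi2)) readr::write_tsv(chi2, file.path(out_dir, "sex_chi2.tsv"))
    if (!is.null(anc)) readr::write_tsv(tidy(anc), file.path(out_dir, "ancova.tsv"))
    list(sex_chi2 = chi2, ancova = anc)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("respfmri")),
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    seed = config$seed,
    n_subjects = config$n_subjects,
    stages = stages,
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(cohort = cohort, scan_results = scan_results, scores = scores,
       stats = stats_out, manifest = manifest)
}
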