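# Ground-truth evaluation harnesses for the detector, built on the
# synthetic generator. These power the package's own validation (and the
# acceptance script): they measure how well the pattern indices recover
# implanted truth under the study conditions.

wilcoxon_auc <- function(pos, neg) {
  mean(outer(pos, neg, `>`)) + 0.5 * mean(outer(pos, neg, `==`))
}

#' Scan-level detection benchmark
#'
#' Generates `n_clean` pattern-free scans, `n_burst` scans with one
#' implanted burst train and `n_deep` scans with implanted deep breaths
#' (event parameters drawn from the generator's own distributions), runs
#' the detector on each, and summarizes separability.
#'
#' @param spec A [cohort_spec()] (timing/coupling conditions).
#' @param n_clean,n_burst,n_deep Scans per arm.
#' @param seed Integer seed.
#' @return A tibble (`type`, `burst_index`, `deep_index`, `rate_cv`) with
#'   attributes `auc_burst` (burst vs clean, burst index) and `auc_deep`
#'   (deep vs clean, deep index).
#' @export
detection_benchmark <- function(spec = cohort_spec(), n_clean = 50L,
                                n_burst = 50L, n_deep = 0L, seed = 1L) {
  duration_s <- spec$frames_per_scan * spec$tr_s
  one <- function(type, i) {
    set.seed(derive_seed(seed, i, match(type, c("clean", "burst", "deep"))))
    evs <- switch(type,
      clean = list(),
      burst = sample_scan_events(TRUE, FALSE, duration_s),
      deep = sample_scan_events(FALSE, TRUE, duration_s)
    )
    g <- generate_scan(spec, evs,
                       seed = derive_seed(seed, i, 50L +
                                            match(type,
                                                  c("clean", "burst",
                                                    "deep"))))
    det <- detect_scan(g$physio, g$scan)
    tibble::tibble(type = type, burst_index = det$burst_index,
                   deep_index = det$deep_index, rate_cv = det$rate_cv)
  }
  out <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_clean), function(i) one("clean", i)),
    purrr::map_dfr(seq_len(n_burst), function(i) one("burst", i)),
    purrr::map_dfr(seq_len(n_deep), function(i) one("deep", i))
  )
  clean_idx <- out[out$type == "clean", ]
  attr(out, "auc_burst") <- if (n_burst > 0) {
    wilcoxon_auc(out$burst_index[out$type == "burst"],
                 clean_idx$burst_index)
  } else NA_real_
  attr(out, "auc_deep") <- if (n_deep > 0) {
    wilcoxon_auc(out$deep_index[out$type == "deep"], clean_idx$deep_index)
  } else NA_real_
  out
}

#' Subject-level recovery benchmark
#'
#' Generates a full cohort, detects patterns in every scan, and relates
#' each subject's mean indices to the implanted truth (number of scans
#' carrying each pattern).
#'
#' @param spec A [cohort_spec()] (use `n_subjects` to size the cohort).
#' @param progress Print a dot every 50 scans.
#' @return A tibble per subject (`subject`, `sex`, `true_burst_scans`,
#'   `true_deep_scans`, `burst_index`, `deep_index`, `gfc`, `icv_z`) with
#'   attributes `spearman_burst` and `spearman_deep` and the scan-level
#'   table as attribute `scans`.
#' @export
cohort_recovery_benchmark <- function(spec = cohort_spec(n_subjects = 200L),
                                      progress = FALSE) {
  co <- generate_cohort(spec)
  rows <- purrr::map_dfr(seq_len(nrow(co$scans)), function(i) {
    real <- realize_scan(co, co$scans$subject[i], co$scans$scan[i])
    det <- detect_scan(real$physio, real$scan)
    if (progress && i %% 50 == 0) cat(".")
    tibble::tibble(subject = co$scans$subject[i], scan = co$scans$scan[i],
                   has_burst = co$scans$has_burst[i],
                   has_deep = co$scans$has_deep[i],
                   burst_index = det$burst_index,
                   deep_index = det$deep_index,
                   gfc = as.numeric(gfc(real$scan)))
  })
  subj <- rows |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(true_burst_scans = sum(.data$has_burst),
                     true_deep_scans = sum(.data$has_deep),
                     burst_index = mean(.data$burst_index),
                     deep_index = mean(.data$deep_index),
                     gfc = mean(.data$gfc), .groups = "drop") |>
    dplyr::left_join(co$subjects[, c("subject", "sex", "icv_z")],
                     by = "subject")
  attr(subj, "spearman_burst") <- stats::cor(subj$true_burst_scans,
                                             subj$burst_index,
                                             method = "spearman")
  attr(subj, "spearman_deep") <- stats::cor(subj$true_deep_scans,
                                            subj$deep_index,
                                            method = "spearman")
  attr(subj, "scans") <- rows
  subj
}
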