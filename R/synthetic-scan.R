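# Synthetic scans and cohorts: network-structured parcel signals coupled to
# implanted respiratory events, pulse and motion traces, and sex-structured
# cohorts with ground truth.

#' Specify a synthetic cohort
#'
#' Defaults are the study conditions the pipeline targets: four 14.4-min
#' scans per subject (1200 frames at tr = 0.72 s) with 400 Hz physiology;
#' bursts in 45% of male and 35% of female scans and deep breaths in ~53%
#' of scans; sex-specific head-size (ICV) distributions; respiratory
#' responses loaded more strongly onto sensorimotor networks.
#'
#' @param n_subjects Number of subjects.
#' @param scans_per_subject Scans per subject (default 4).
#' @param frames_per_scan Frames per scan (default 1200).
#' @param tr_s Repetition time in seconds (default 0.72).
#' @param physio_hz Physiology sampling rate (default 400).
#' @param p_burst_scan_male,p_burst_scan_female Per-scan burst prevalence by
#'   sex (defaults 0.45 / 0.35).
#' @param p_deep_scan Per-scan deep-breath prevalence (default 0.53).
#' @param icv_mean_by_sex Named vector `c(M = , F = )` of mean intracranial
#'   volume (cm^3).
#' @param icv_sd ICV standard deviation (cm^3).
#' @param gfc_coupling Loading of the respiratory response onto parcel
#'   signals (dimensionless; 0 disconnects respiration from fMRI).
#' @param sensorimotor_gain Multiplier (> 1) of the respiratory loading on
#'   sensorimotor-network parcels.
#' @param icv_gfc_slope Change in shared-signal SD per ICV z-unit (negative:
#'   smaller heads carry more globally shared signal, hence higher gFC).
#' @param n_networks,parcels_per_network Parcellation size (default 9 x 10).
#' @param resp_scale Amplitude of the respiratory regressor in signal SD
#'   units.
#' @param shared_sd,network_sd,unit_ar SD of the globally shared and
#'   network-common noise components and the AR(1) coefficient of unit
#'   noise.
#' @param seed Integer seed; every random draw in the cohort derives from
#'   it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 20L, scans_per_subject = 4L,
                        frames_per_scan = 1200L, tr_s = 0.72,
                        physio_hz = 400, p_burst_scan_male = 0.45,
                        p_burst_scan_female = 0.35, p_deep_scan = 0.53,
                        icv_mean_by_sex = c(M = 1550, F = 1350),
                        icv_sd = 110, gfc_coupling = 1,
                        sensorimotor_gain = 2, icv_gfc_slope = -0.15,
                        n_networks = 9L, parcels_per_network = 10L,
                        resp_scale = 3, shared_sd = 0.5, network_sd = 0.5,
                        unit_ar = 0.3, seed = 1L) {
  for (p in c(p_burst_scan_male, p_burst_scan_female, p_deep_scan)) {
    assert_scalar_num(p, "prevalence", lower = 0, upper = 1)
  }
  assert_scalar_num(n_subjects, "n_subjects", lower = 1)
  assert_scalar_num(tr_s, "tr_s", lower = 1e-3)
  stopifnot(all(c("M", "F") %in% names(icv_mean_by_sex)))
  structure(list(
    n_subjects = as.integer(n_subjects),
    scans_per_subject = as.integer(scans_per_subject),
    frames_per_scan = as.integer(frames_per_scan), tr_s = tr_s,
    physio_hz = physio_hz, p_burst_scan_male = p_burst_scan_male,
    p_burst_scan_female = p_burst_scan_female, p_deep_scan = p_deep_scan,
    icv_mean_by_sex = icv_mean_by_sex, icv_sd = icv_sd,
    gfc_coupling = gfc_coupling, sensorimotor_gain = sensorimotor_gain,
    icv_gfc_slope = icv_gfc_slope, n_networks = as.integer(n_networks),
    parcels_per_network = as.integer(parcels_per_network),
    resp_scale = resp_scale, shared_sd = shared_sd, network_sd = network_sd,
    unit_ar = unit_ar, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Default synthetic parcellation
#'
#' Nine networks of `parcels_per_network` parcels; the sensorimotor set
#' (Visual, Auditory, SMhand, SMmouth) carries elevated respiratory
#' loading.
#'
#' @param spec A [cohort_spec()] (only the parcellation fields are used).
#' @return A [network_assignment()].
#' @export
default_parcellation <- function(spec = cohort_spec()) {
  nets <- c("Visual", "Auditory", "SMhand", "SMmouth", "CinguloOperc",
            "FrontoParietal", "Default", "DorsalAttn", "Salience")
  nets <- rep(nets, length.out = spec$n_networks)
  network <- rep(nets, each = spec$parcels_per_network)
  network_assignment(sprintf("p%03d", seq_along(network)), network)
}

# z-score head size against the spec's own population (sex mixture), so a
# subject's icv_z does not depend on who else was sampled
icv_population_z <- function(icv, spec) {
  mu <- mean(spec$icv_mean_by_sex)
  sd_pool <- sqrt(spec$icv_sd^2 + (diff(range(spec$icv_mean_by_sex)) / 2)^2)
  (icv - mu) / sd_pool
}

# Event impulse train at the frame grid: deep breaths contribute one impulse
# at onset; burst trains one impulse per cycle start.
event_regressor <- function(events_log, kernel_deep, kernel_burst, tr_s,
                            n_frames) {
  deep <- rep(0, n_frames)
  burst <- rep(0, n_frames)
  if (nrow(events_log) > 0) {
    for (i in seq_len(nrow(events_log))) {
      e <- events_log[i, ]
      amp <- e$amplitude_factor / 2.5
      if (e$kind == "deep_breath") {
        j <- floor(e$onset_s / tr_s) + 1L
        if (j <= n_frames) deep[j] <- deep[j] + amp
      } else {
        onsets <- e$onset_s + (seq_len(e$n_cycles) - 1L) * e$cycle_s
        j <- floor(onsets / tr_s) + 1L
        j <- j[j <= n_frames]
        burst[j] <- burst[j] + amp
      }
    }
  }
  conv1 <- function(x, kern) {
    stats::convolve(x, rev(kern), type = "open")[seq_along(x)]
  }
  kd <- kernel_deep$samples
  kb <- kernel_burst$samples
  list(deep = conv1(deep, kd), burst = conv1(burst, kb))
}

ar1_matrix <- function(n_frames, n_series, rho, sd = 1) {
  innov <- matrix(stats::rnorm(n_frames * n_series, 0,
                               sd * sqrt(1 - rho^2)), n_frames, n_series)
  if (rho != 0) {
    innov <- apply(innov, 2L, function(e)
      as.numeric(stats::filter(e, rho, method = "recursive")))
  }
  t(innov)
}

#' Generate one synthetic scan
#'
#' Builds the belt trace (eupnea plus implanted events), the pulse trace
#' (with a transient heart-rate elevation after each deep breath), motion
#' parameters (with a small spike at each deep-breath onset, plus any
#' requested extra spikes), and a parcel-by-frame signal matrix: AR(1) unit
#' noise plus network-common and globally shared components plus the event
#' train convolved with the matching response kernel, scaled by
#' `gfc_coupling` and by `sensorimotor_gain` on sensorimotor parcels.
#'
#' @param spec A [cohort_spec()].
#' @param events List of [resp_event()]s to implant.
#' @param seed Integer seed for this scan.
#' @param shared_sd Override of the globally shared component SD (used by
#'   [realize_scan()] to encode the head-size link).
#' @param hr_baseline_bpm Baseline heart rate (default drawn from 60-80).
#' @param motion_spikes_s Extra motion-spike onsets in seconds.
#' @param rate_hz,rate_jitter,depth_drift Eupnea parameters (rate drawn
#'   from 0.2-0.33 Hz when `NULL`).
#' @return List with `scan` ([scan_data()]), `physio`
#'   ([physio_recording()]), `truth` (event log tibble), `regressors`
#'   (frame-grid deep/burst response regressors), `hr_baseline_bpm`.
#' @export
generate_scan <- function(spec, events = list(), seed = 1L,
                          shared_sd = NULL, hr_baseline_bpm = NULL,
                          motion_spikes_s = numeric(0), rate_hz = NULL,
                          rate_jitter = 0.06, depth_drift = 0.08) {
  stopifnot(inherits(spec, "cohort_spec"))
  duration_s <- spec$frames_per_scan * spec$tr_s
  n_samples <- round(duration_s * spec$physio_hz)
  if (abs(n_samples / spec$physio_hz - duration_s) > 1e-9) {
    stop("frames_per_scan * tr_s must equal physio samples / physio_hz")
  }
  set.seed(derive_seed(seed, 1L))
  rate_hz <- rate_hz %||% stats::runif(1, 0.2, 0.33)
  belt <- generate_eupnea(duration_s, rate_hz = rate_hz,
                          rate_jitter = rate_jitter,
                          depth_drift = depth_drift,
                          sample_hz = spec$physio_hz,
                          seed = derive_seed(seed, 2L))
  for (e in events) belt <- implant_event(belt, e)
  truth <- attr(belt, "events")
  deep_onsets <- truth$onset_s[truth$kind == "deep_breath"]

  set.seed(derive_seed(seed, 3L))
  hr_baseline_bpm <- hr_baseline_bpm %||% stats::runif(1, 60, 80)
  pulse <- generate_pulse(duration_s, hr_baseline_bpm = hr_baseline_bpm,
                          deep_onsets_s = deep_onsets,
                          sample_hz = spec$physio_hz,
                          seed = derive_seed(seed, 4L))
  physio <- physio_recording(resp = as.numeric(belt),
                             pulse = as.numeric(pulse),
                             trigger = rep(1, n_samples),
                             sample_hz = spec$physio_hz)

  motion <- generate_motion(spec$frames_per_scan, spec$tr_s,
                            spike_onsets_s = c(deep_onsets, motion_spikes_s),
                            spike_mm = 0.3, seed = derive_seed(seed, 5L))

  parc <- default_parcellation(spec)
  n_parcels <- nrow(parc)
  sm <- parc$network %in% attr(parc, "sensorimotor")
  reg <- event_regressor(truth, response_kernel("deep_breath", spec$tr_s),
                         response_kernel("burst", spec$tr_s), spec$tr_s,
                         spec$frames_per_scan)
  resp_sig <- spec$resp_scale * (reg$deep + reg$burst)
  loading <- ifelse(sm, spec$sensorimotor_gain, 1)

  set.seed(derive_seed(seed, 6L))
  g_sd <- shared_sd %||% spec$shared_sd
  shared <- ar1_matrix(spec$frames_per_scan, 1L, spec$unit_ar, g_sd)
  net_ids <- match(parc$network, unique(parc$network))
  net_comp <- ar1_matrix(spec$frames_per_scan, max(net_ids), spec$unit_ar,
                         spec$network_sd)
  unit_noise <- ar1_matrix(spec$frames_per_scan, n_parcels, spec$unit_ar, 1)
  signals <- unit_noise + net_comp[net_ids, , drop = FALSE] +
    matrix(shared[1L, ], n_parcels, spec$frames_per_scan, byrow = TRUE) +
    spec$gfc_coupling * outer(loading, resp_sig)

  scan <- scan_data(signals, tr_s = spec$tr_s, network = parc$network,
                    motion = motion)
  list(scan = scan, physio = physio, truth = truth, regressors = reg,
       hr_baseline_bpm = hr_baseline_bpm)
}

# Sample burst/deep event parameters for one scan; bursts span 2-5 minutes.
sample_scan_events <- function(has_burst, has_deep, duration_s) {
  events <- list()
  burst_span <- c(NA_real_, NA_real_)
  if (has_burst) {
    avail <- duration_s - 150 # onset margin before and after the train
    if (avail < 90) stop("scan too short (", duration_s,
                         " s) to host a burst train")
    cycle_s <- stats::runif(1, 30, 50)
    total <- stats::runif(1, min(120, 0.8 * avail), min(300, avail))
    n_cycles <- max(2L, round(total / cycle_s))
    span <- n_cycles * cycle_s
    onset <- stats::runif(1, 45, duration_s - span - 45)
    events <- c(events, list(resp_event("burst_train", onset_s = onset,
                                        amplitude_factor = stats::runif(1, 2, 3),
                                        n_cycles = n_cycles,
                                        cycle_s = cycle_s)))
    burst_span <- c(onset - 30, onset + span + 30)
  }
  if (has_deep) {
    n_deep <- sample(1:3, 1L)
    placed <- numeric(0)
    for (k in seq_len(n_deep)) {
      for (try in 1:20) {
        on <- stats::runif(1, 45, duration_s - 90)
        clear_burst <- is.na(burst_span[1L]) ||
          on < burst_span[1L] || on > burst_span[2L]
        if (clear_burst && (!length(placed) || all(abs(placed - on) > 60))) {
          placed <- c(placed, on)
          break
        }
      }
    }
    for (on in sort(placed)) {
      events <- c(events, list(resp_event("deep_breath", onset_s = on,
                                          amplitude_factor = stats::runif(1, 2, 3),
                                          apnea_s = stats::runif(1, 0, 15))))
    }
  }
  events
}

#' Generate a ground-truthed cohort
#'
#' Draws subjects (sex, ICV from sex-specific distributions, BMI), assigns
#' each scan burst/deep-breath status by Bernoulli draws at the sex-specific
#' prevalences, and samples event parameters. Scan signal data are not
#' materialized here; use [realize_scan()] to build any scan on demand
#' (deterministically, from the cohort seed).
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort` list: `spec`, `subjects` (tibble: subject, sex, icv,
#'   bmi, icv_z), `scans` (tibble: subject, scan, has_burst, has_deep),
#'   `events` (ground-truth tibble: subject, scan, kind, onset parameters).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(derive_seed(spec$seed, 0L))
  n <- spec$n_subjects
  sex <- ifelse(stats::runif(n) < 0.5, "M", "F")
  subjects <- tibble::tibble(
    subject = sprintf("sub%04d", seq_len(n)),
    sex = sex,
    icv = stats::rnorm(n, spec$icv_mean_by_sex[sex], spec$icv_sd),
    bmi = pmin(pmax(stats::rnorm(n, 26.5, 5), 16.5), 43.9)
  )
  subjects$icv_z <- icv_population_z(subjects$icv, spec)
  duration_s <- spec$frames_per_scan * spec$tr_s
  scans <- tidyr::expand_grid(subject_idx = seq_len(n),
                              scan = seq_len(spec$scans_per_subject))
  p_burst <- ifelse(sex[scans$subject_idx] == "M", spec$p_burst_scan_male,
                    spec$p_burst_scan_female)
  scans$subject <- subjects$subject[scans$subject_idx]
  scans$has_burst <- stats::runif(nrow(scans)) < p_burst
  scans$has_deep <- stats::runif(nrow(scans)) < spec$p_deep_scan
  events <- purrr::map_dfr(seq_len(nrow(scans)), function(i) {
    set.seed(derive_seed(spec$seed, scans$subject_idx[i], scans$scan[i], 7L))
    evs <- sample_scan_events(scans$has_burst[i], scans$has_deep[i],
                              duration_s)
    if (!length(evs)) return(NULL)
    purrr::map_dfr(evs, function(e) tibble::tibble(
      subject = scans$subject[i], scan = scans$scan[i], kind = e$kind,
      onset_s = e$onset_s, amplitude_factor = e$amplitude_factor,
      apnea_s = if (e$kind == "deep_breath") e$apnea_s else NA_real_,
      n_cycles = if (e$kind == "burst_train") e$n_cycles else NA_integer_,
      cycle_s = if (e$kind == "burst_train") e$cycle_s else NA_real_
    ))
  })
  structure(list(spec = spec,
                 subjects = subjects[, c("subject", "sex", "icv", "bmi",
                                         "icv_z")],
                 scans = scans[, c("subject", "scan", "has_burst",
                                   "has_deep")],
                 events = events),
            class = "respfmri_cohort")
}

#' @export
print.respfmri_cohort <- function(x, ...) {
  cat("<respfmri_cohort> ", nrow(x$subjects), " subjects x ",
      x$spec$scans_per_subject, " scans; ", nrow(x$events),
      " implanted events\n", sep = "")
  invisible(x)
}

#' Materialize one scan of a generated cohort
#'
#' Deterministic given the cohort (and hence its seed): rebuilding the same
#' subject/scan yields identical data.
#'
#' @param cohort A [generate_cohort()] result.
#' @param subject Subject id (e.g. `"sub0001"`).
#' @param scan Scan number (1-based).
#' @return As [generate_scan()].
#' @export
realize_scan <- function(cohort, subject, scan) {
  spec <- cohort$spec
  si <- match(subject, cohort$subjects$subject)
  if (is.na(si)) stop("unknown subject: ", subject)
  ev_rows <- cohort$events[cohort$events$subject == subject &
                             cohort$events$scan == scan, ]
  events <- purrr::map(seq_len(nrow(ev_rows)), function(i) {
    e <- ev_rows[i, ]
    if (e$kind == "deep_breath") {
      resp_event("deep_breath", onset_s = e$onset_s,
                 amplitude_factor = e$amplitude_factor, apnea_s = e$apnea_s)
    } else {
      resp_event("burst_train", onset_s = e$onset_s,
                 amplitude_factor = e$amplitude_factor,
                 n_cycles = e$n_cycles, cycle_s = e$cycle_s)
    }
  })
  shared_sd <- spec$shared_sd *
    (1 + spec$icv_gfc_slope * cohort$subjects$icv_z[si])
  generate_scan(spec, events = events,
                seed = derive_seed(spec$seed, si, scan, 11L),
                shared_sd = max(shared_sd, 0.05))
}

#' Write a cohort to a dataset directory
#'
#' Emits `subjects.tsv`, `scans.tsv`, `events.tsv`, `parcels.tsv`, and per
#' scan a physiology log (HCP dialect), a motion file and a parcel-by-frame
#' matrix TSV.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param subjects Optional subset of subject ids to materialize.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, subjects = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$subjects, file.path(out_dir, "subjects.tsv"))
  readr::write_tsv(cohort$scans, file.path(out_dir, "scans.tsv"))
  readr::write_tsv(cohort$events, file.path(out_dir, "events.tsv"))
  write_network_assignment(default_parcellation(cohort$spec),
                           file.path(out_dir, "parcels.tsv"))
  ids <- subjects %||% cohort$subjects$subject
  for (sub in ids) {
    for (sc in seq_len(cohort$spec$scans_per_subject)) {
      real <- realize_scan(cohort, sub, sc)
      stem <- file.path(out_dir, sprintf("%s_scan%d", sub, sc))
      write_physio_log(real$physio, paste0(stem, "_physio.txt"))
      write_motion_params(real$scan$motion, paste0(stem, "_motion.txt"))
      write_matrix_scan(real$scan, paste0(stem, "_parcels.tsv"))
    }
  }
  invisible(out_dir)
}

#' Simulate subject-level summaries under the cohort's structural model
#'
#' A lightweight generator of the subject table alone (no time series):
#' pattern scores are Binomial draws at the sex-specific prevalences,
#' indices are noisy linear readouts of the scores, and gFC depends only on
#' the burst/deep indices and on head size -- the same dependence structure
#' the scan-level generator induces. Used for cohort-statistics calibration
#' at sizes where materializing time series would be wasteful.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [cohort_spec()] supplying prevalences and ICV parameters.
#' @param beta_burst,beta_deep gFC change per unit index.
#' @param beta_icv gFC change per ICV z-unit (negative: smaller heads,
#'   higher gFC).
#' @param index_per_score Mean index increment per score unit.
#' @param index_noise_sd,gfc_noise_sd Residual SDs.
#' @param intercept Baseline gFC (Fisher-Z units).
#' @param seed Integer seed.
#' @return Tibble: subject, sex, icv, icv_z, bmi, burst_score, deep_score,
#'   burst_index, deep_index, gfc.
#' @export
simulate_subject_summaries <- function(n_subjects = 200L,
                                       spec = cohort_spec(),
                                       beta_burst = 1.2, beta_deep = 0.15,
                                       beta_icv = -0.04,
                                       index_per_score = 0.02,
                                       index_noise_sd = 0.006,
                                       gfc_noise_sd = 0.04,
                                       intercept = 0.15, seed = 1L) {
  set.seed(derive_seed(seed, 21L))
  sex <- ifelse(stats::runif(n_subjects) < 0.5, "M", "F")
  icv <- stats::rnorm(n_subjects, spec$icv_mean_by_sex[sex], spec$icv_sd)
  icv_z <- icv_population_z(icv, spec)
  p_burst <- ifelse(sex == "M", spec$p_burst_scan_male,
                    spec$p_burst_scan_female)
  burst_score <- stats::rbinom(n_subjects, spec$scans_per_subject, p_burst)
  deep_score <- stats::rbinom(n_subjects, spec$scans_per_subject,
                              spec$p_deep_scan)
  burst_index <- pmax(0, index_per_score * burst_score +
                        stats::rnorm(n_subjects, 0, index_noise_sd))
  deep_index <- pmax(0, index_per_score * deep_score +
                       stats::rnorm(n_subjects, 0, index_noise_sd))
  gfc <- intercept + beta_burst * burst_index + beta_deep * deep_index +
    beta_icv * icv_z + stats::rnorm(n_subjects, 0, gfc_noise_sd)
  tibble::tibble(subject = sprintf("sub%04d", seq_len(n_subjects)),
                 sex = sex, icv = icv, icv_z = icv_z,
                 bmi = pmin(pmax(stats::rnorm(n_subjects, 26.5, 5), 16.5),
                            43.9),
                 burst_score = burst_score, deep_score = deep_score,
                 burst_index = burst_index, deep_index = deep_index,
                 gfc = gfc)
}
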