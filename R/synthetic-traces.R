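# Ground-truthed synthetic physiological traces.
#
# A belt trace is represented internally as a schedule of segments (breaths
# and apneas); each breath is a raised cosine starting and ending at the
# trough, so segments concatenate continuously and events can be implanted
# by editing the schedule and re-rendering. Rendering is done against
# absolute time, so sample counts never drift.

render_schedule <- function(schedule, sample_hz, baseline, depth_unit,
                            duration_s) {
  n <- round(duration_s * sample_hz)
  t <- (seq_len(n) - 1L) / sample_hz
  starts <- cumsum(c(0, schedule$dur_s))[seq_len(nrow(schedule))]
  total <- starts[length(starts)] + schedule$dur_s[nrow(schedule)]
  if (total < duration_s - 1e-9) {
    stop("schedule covers ", signif(total, 6), " s < requested ", duration_s, " s")
  }
  seg <- findInterval(t, starts)
  u <- (t - starts[seg]) / schedule$dur_s[seg]
  baseline + depth_unit * schedule$depth[seg] * 0.5 * (1 - cos(2 * pi * u))
}

new_belt_trace <- function(schedule, sample_hz, baseline, depth_unit,
                           duration_s, base_period_s, events) {
  values <- render_schedule(schedule, sample_hz, baseline, depth_unit,
                            duration_s)
  structure(values, schedule = schedule, sample_hz = sample_hz,
            baseline = baseline, depth_unit = depth_unit,
            duration_s = duration_s, base_period_s = base_period_s,
            events = events, class = "belt_trace")
}

empty_event_log <- function() {
  tibble::tibble(kind = character(0), onset_s = numeric(0),
                 duration_s = numeric(0), amplitude_factor = numeric(0),
                 apnea_s = numeric(0), n_cycles = integer(0),
                 cycle_s = numeric(0))
}

#' Generate a eupneic (normal tidal breathing) belt trace
#'
#' Quasi-sinusoidal breathing at `rate_hz` with breath-to-breath log-normal
#' period jitter and a slow multiplicative depth drift, rendered as a
#' belt-like trace in arbitrary units with a positive offset. Each breath is
#' a raised cosine from trough to trough, so with no jitter or drift the
#' trace is exactly periodic.
#'
#' @param duration_s Trace duration in seconds (> 0).
#' @param rate_hz Breathing rate in Hz, within `[0.1, 0.5]` (6-30
#'   breaths/min; default 0.25, i.e. 15 breaths/min).
#' @param rate_jitter SD of log inter-breath periods; the coefficient of
#'   variation of inter-peak intervals approximates this value.
#' @param depth_drift Innovation SD of a slow AR(1) log-depth walk.
#' @param sample_hz Sampling rate in Hz (default 400).
#' @param baseline,depth_unit Belt offset and eupneic breath depth in
#'   arbitrary units.
#' @param seed Optional integer seed.
#' @return A `belt_trace`: numeric vector with the breath schedule, event
#'   log and rendering metadata as attributes.
#' @export
generate_eupnea <- function(duration_s, rate_hz = 0.25, rate_jitter = 0,
                            depth_drift = 0, sample_hz = 400,
                            baseline = 5000, depth_unit = 1000, seed = NULL) {
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_num(rate_hz, "rate_hz", lower = 0.1, upper = 0.5)
  assert_scalar_num(rate_jitter, "rate_jitter", lower = 0)
  assert_scalar_num(depth_drift, "depth_drift", lower = 0)
  if (!is.null(seed)) set.seed(seed)
  t0 <- 1 / rate_hz
  n_breaths <- ceiling(duration_s / t0 * (1 + 3 * rate_jitter)) + 3L
  periods <- if (rate_jitter > 0) {
    pmin(pmax(t0 * exp(stats::rnorm(n_breaths, 0, rate_jitter)), 0.4 * t0),
         2.5 * t0)
  } else rep(t0, n_breaths)
  while (sum(periods) < duration_s + t0) periods <- c(periods, t0)
  depths <- if (depth_drift > 0) {
    # AR(1) log-depth walk with stationary SD = depth_drift
    innov_sd <- depth_drift * sqrt(1 - 0.95^2)
    l <- stats::filter(stats::rnorm(length(periods), 0, innov_sd), 0.95,
                       method = "recursive")
    pmin(pmax(exp(as.numeric(l)), 0.4), 2.5)
  } else rep(1, length(periods))
  schedule <- tibble::tibble(type = "breath", dur_s = periods, depth = depths)
  new_belt_trace(schedule, sample_hz, baseline, depth_unit, duration_s,
                 base_period_s = t0, events = empty_event_log())
}

#' @export
print.belt_trace <- function(x, ...) {
  ev <- attr(x, "events")
  cat("<belt_trace> ", signif(attr(x, "duration_s"), 6), " s @ ",
      attr(x, "sample_hz"), " Hz; ", nrow(ev), " implanted event(s)\n",
      sep = "")
  invisible(x)
}

#' Specify a respiratory event for implanting
#'
#' @param kind `"deep_breath"` or `"burst_train"`.
#' @param onset_s Event onset in seconds from trace start (snapped to the
#'   nearest breath boundary when implanted).
#' @param amplitude_factor Breath depth as a multiple of eupneic depth
#'   (> 1).
#' @param apnea_s Deep breaths only: seconds of post-breath flat trace,
#'   in `[0, 20]`.
#' @param n_cycles Burst trains only: number of burst cycles.
#' @param cycle_s Burst trains only: seconds per cycle, `[30, 50]` by
#'   default (override `cycle_range` to relax).
#' @param taper_shape Burst trains only: `"linear"` or `"exponential"`
#'   decay of per-breath depth across each cycle.
#' @param taper_floor Depth multiple the taper decays to (default 0.3).
#' @param cycle_range Allowed `cycle_s` range.
#' @return A `resp_event` list.
#' @export
resp_event <- function(kind = c("deep_breath", "burst_train"), onset_s,
                       amplitude_factor = 2.5, apnea_s = 0, n_cycles = 5L,
                       cycle_s = 40, taper_shape = c("linear", "exponential"),
                       taper_floor = 0.3, cycle_range = c(30, 50)) {
  kind <- match.arg(kind)
  taper_shape <- match.arg(taper_shape)
  assert_scalar_num(onset_s, "onset_s", lower = 0)
  if (!is.numeric(amplitude_factor) || amplitude_factor <= 1) {
    stop("amplitude_factor must exceed 1 (a multiple of eupneic depth)")
  }
  if (kind == "deep_breath") {
    assert_scalar_num(apnea_s, "apnea_s", lower = 0, upper = 20)
  } else {
    assert_scalar_num(n_cycles, "n_cycles", lower = 1)
    assert_scalar_num(cycle_s, "cycle_s", lower = cycle_range[1L],
                      upper = cycle_range[2L])
  }
  structure(list(kind = kind, onset_s = onset_s,
                 amplitude_factor = amplitude_factor, apnea_s = apnea_s,
                 n_cycles = as.integer(n_cycles), cycle_s = cycle_s,
                 taper_shape = taper_shape, taper_floor = taper_floor),
            class = "resp_event")
}

# Replacement segments for one event, given the eupneic base period.
event_segments <- function(event, t0) {
  if (event$kind == "deep_breath") {
    # period stretches with depth, so flow (depth/time) stays near eupneic
    # and RVT barely deflects while ENV and RV rise
    seg <- tibble::tibble(type = "breath", dur_s = t0 * event$amplitude_factor,
                          depth = event$amplitude_factor)
    if (event$apnea_s > 0) {
      seg <- dplyr::bind_rows(seg, tibble::tibble(type = "apnea",
                                                  dur_s = event$apnea_s,
                                                  depth = 0))
    }
    seg
  } else {
    m <- max(3L, floor(event$cycle_s / t0))
    frac <- (seq_len(m) - 1L) / (m - 1L)
    depths <- switch(event$taper_shape,
      linear = event$amplitude_factor +
        frac * (event$taper_floor - event$amplitude_factor),
      exponential = event$amplitude_factor *
        (event$taper_floor / event$amplitude_factor)^frac
    )
    one_cycle <- tibble::tibble(type = "breath",
                                dur_s = rep(event$cycle_s / m, m),
                                depth = depths)
    dplyr::bind_rows(replicate(event$n_cycles, one_cycle, simplify = FALSE))
  }
}

#' Implant a respiratory event into a belt trace
#'
#' The event onset is snapped to the nearest breath boundary (trough), the
#' covered eupneic breaths are replaced by the event's segments (a slow deep
#' breath with optional apnea, or a train of tapering burst cycles), and the
#' trace is re-rendered. The ground-truth log records the actual onset.
#'
#' @param trace A `belt_trace` from [generate_eupnea()].
#' @param event A [resp_event()].
#' @return The modified `belt_trace`; `attr(, "events")` holds the log.
#' @export
implant_event <- function(trace, event) {
  stopifnot(inherits(trace, "belt_trace"), inherits(event, "resp_event"))
  schedule <- attr(trace, "schedule")
  t0 <- attr(trace, "base_period_s")
  duration_s <- attr(trace, "duration_s")
  new_seg <- event_segments(event, t0)
  needed <- sum(new_seg$dur_s)
  starts <- cumsum(c(0, schedule$dur_s))[seq_len(nrow(schedule))]
  i0 <- which.min(abs(starts - event$onset_s))
  onset <- starts[i0]
  if (onset + needed > duration_s + 1e-9) {
    stop("event (", signif(needed, 4), " s at ", signif(onset, 5),
         " s) does not fit within the ", duration_s, " s trace")
  }
  log <- attr(trace, "events")
  if (nrow(log) > 0 &&
      any(onset < log$onset_s + log$duration_s & onset + needed > log$onset_s)) {
    stop("event at ", signif(onset, 5),
         " s overlaps a previously implanted event")
  }
  # remove whole original segments spanning the event; absorb the leftover
  # into the following breath so total duration is preserved
  removed <- 0
  i1 <- i0 - 1L
  while (removed < needed - 1e-9 && i1 < nrow(schedule)) {
    i1 <- i1 + 1L
    removed <- removed + schedule$dur_s[i1]
  }
  if (removed < needed - 1e-9) stop("event extends past the end of the schedule")
  leftover <- removed - needed
  after <- if (i1 < nrow(schedule)) schedule[(i1 + 1L):nrow(schedule), ] else
    schedule[0, ]
  if (leftover > 1e-9) {
    if (nrow(after) > 0) {
      after$dur_s[1L] <- after$dur_s[1L] + leftover
    } else {
      after <- tibble::tibble(type = "breath", dur_s = leftover, depth = 1)
    }
  }
  schedule <- dplyr::bind_rows(
    if (i0 > 1L) schedule[seq_len(i0 - 1L), ] else schedule[0, ],
    new_seg, after
  )
  log <- dplyr::bind_rows(log, tibble::tibble(
    kind = event$kind, onset_s = onset, duration_s = needed,
    amplitude_factor = event$amplitude_factor,
    apnea_s = if (event$kind == "deep_breath") event$apnea_s else NA_real_,
    n_cycles = if (event$kind == "burst_train") event$n_cycles else NA_integer_,
    cycle_s = if (event$kind == "burst_train") event$cycle_s else NA_real_
  ))
  new_belt_trace(schedule, attr(trace, "sample_hz"), attr(trace, "baseline"),
                 attr(trace, "depth_unit"), duration_s, t0, log)
}

#' Generate a pulse-oximetry trace with optional post-sigh HR elevation
#'
#' A pseudo-plethysmographic waveform (fundamental plus second harmonic) at
#' an instantaneous heart rate of `hr_baseline_bpm`, transiently elevated by
#' `bump_bpm` decaying over `decay_s` seconds after each deep-breath onset
#' (sighs reliably raise heart rate for several seconds; bursts get no bump
#' by default).
#'
#' @param duration_s Duration in seconds.
#' @param hr_baseline_bpm Baseline heart rate (default 70).
#' @param deep_onsets_s Deep-breath onsets in seconds.
#' @param bump_bpm Peak HR elevation after a deep breath (default 8).
#' @param decay_s Exponential decay constant of the elevation (default 5).
#' @param sample_hz Sampling rate (default 400).
#' @param baseline,amp_unit Offset and amplitude in arbitrary units.
#' @param noise_sd Additive white noise SD in arbitrary units.
#' @param seed Optional integer seed.
#' @return Numeric pulse trace with attribute `sample_hz`.
#' @export
generate_pulse <- function(duration_s, hr_baseline_bpm = 70,
                           deep_onsets_s = numeric(0), bump_bpm = 8,
                           decay_s = 5, sample_hz = 400, baseline = 2000,
                           amp_unit = 500, noise_sd = 10, seed = NULL) {
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_num(hr_baseline_bpm, "hr_baseline_bpm", lower = 20, upper = 133)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sample_hz)
  t <- (seq_len(n) - 1L) / sample_hz
  rate_hz <- rep(hr_baseline_bpm / 60, n)
  for (on in deep_onsets_s) {
    after <- t >= on
    rate_hz[after] <- rate_hz[after] +
      (bump_bpm / 60) * exp(-(t[after] - on) / decay_s)
  }
  phase <- cumsum(rate_hz) / sample_hz
  wave <- sin(2 * pi * phase) + 0.3 * sin(4 * pi * phase)
  y <- baseline + amp_unit * wave
  if (noise_sd > 0) y <- y + stats::rnorm(n, 0, noise_sd)
  structure(y, sample_hz = sample_hz)
}

#' Generate per-frame head-motion parameters with optional spikes
#'
#' Gaussian jitter plus a slow drift on each of the six rigid-body
#' parameters; each spike adds a single-frame displacement (translation in
#' mm) at the frame containing its onset.
#'
#' @param n_frames Number of frames.
#' @param tr_s Repetition time in seconds.
#' @param spike_onsets_s Spike onsets in seconds.
#' @param spike_mm Spike displacement in mm (default 0.5).
#' @param jitter_mm Per-frame jitter SD (default 0.01).
#' @param seed Optional integer seed.
#' @return A [motion_params()] object (rotations in radians).
#' @export
generate_motion <- function(n_frames, tr_s, spike_onsets_s = numeric(0),
                            spike_mm = 0.5, jitter_mm = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n_frames * 6L, 0, jitter_mm), n_frames, 6L)
  m[, 4:6] <- m[, 4:6] / 50 # comparable arc scale at 50 mm radius
  drift <- outer(seq_len(n_frames) / n_frames, stats::rnorm(6L, 0, 0.1))
  m <- m + drift
  for (on in spike_onsets_s) {
    j <- min(n_frames, floor(on / tr_s) + 1L)
    m[j, 1L] <- m[j, 1L] + spike_mm
  }
  motion_params(m, tr_s = tr_s, angle_unit = "radians")
}
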