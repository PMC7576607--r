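# Pulse-oximetry peak detection, heart rate, pulse amplitude, and an
# automated reliability flag.

#' Detect beats in a cleaned pulse-oximetry trace
#'
#' Peaks with prominence of at least `min_prominence` z-units and spacing of
#' at least `min_spacing_samples` samples. The default spacing of 180
#' samples at 400 Hz (0.45 s) presumes heart rates under 133 beats per
#' minute.
#'
#' @param pulse z-scored pulse trace (a [clean_trace()]; pulse traces are
#'   typically cleaned with `smooth_window_s = NULL`).
#' @param sample_hz Sampling rate; defaults to the trace attribute.
#' @param min_spacing_samples Minimum spacing in samples (default 180).
#' @param min_prominence Minimum prominence in z-units (default 0.5).
#' @return Tibble with `time_s` and `value`; empty with attribute
#'   `degenerate = TRUE` for a constant trace.
#' @export
detect_beats <- function(pulse, sample_hz = NULL, min_spacing_samples = 180L,
                         min_prominence = 0.5) {
  sample_hz <- sample_hz %||% attr(pulse, "sample_hz") %||% 400
  x <- as.numeric(pulse)
  if (isTRUE(attr(pulse, "degenerate")) || stats::sd(x) == 0) {
    return(structure(tibble::tibble(time_s = numeric(0), value = numeric(0)),
                     degenerate = TRUE))
  }
  idx <- find_peaks(x, min_spacing = as.integer(min_spacing_samples),
                    min_prominence = min_prominence)
  structure(tibble::tibble(time_s = (idx - 1L) / sample_hz, value = x[idx]),
            degenerate = FALSE)
}

#' Heart rate from beat times
#'
#' HR at beat k (k >= 2) is 60 / (t_k - t_{k-1}), assigned at t_k.
#'
#' @param beat_times Numeric vector of beat times in seconds (ascending).
#' @return Tibble with `time_s`, `hr_bpm`; attribute `degenerate = TRUE`
#'   when fewer than 2 beats.
#' @export
heart_rate <- function(beat_times) {
  if (length(beat_times) < 2L) {
    return(structure(tibble::tibble(time_s = numeric(0), hr_bpm = numeric(0)),
                     degenerate = TRUE))
  }
  structure(tibble::tibble(time_s = beat_times[-1L],
                           hr_bpm = 60 / diff(beat_times)),
            degenerate = FALSE)
}

#' Pulse amplitude per beat
#'
#' Height of each detected peak relative to the lowest point of the trace
#' since the previous peak (the previous trough).
#'
#' @param pulse z-scored pulse trace.
#' @param beats A [detect_beats()] tibble.
#' @param sample_hz Sampling rate; defaults to the trace attribute.
#' @return Tibble with `time_s`, `amplitude` (z-units), one row per beat
#'   after the first.
#' @export
pulse_amplitude <- function(pulse, beats, sample_hz = NULL) {
  sample_hz <- sample_hz %||% attr(pulse, "sample_hz") %||% 400
  x <- as.numeric(pulse)
  if (nrow(beats) < 2L) {
    return(tibble::tibble(time_s = numeric(0), amplitude = numeric(0)))
  }
  idx <- round(beats$time_s * sample_hz) + 1L
  amp <- vapply(2:length(idx), function(k) {
    x[idx[k]] - min(x[idx[k - 1L]:idx[k]])
  }, numeric(1))
  tibble::tibble(time_s = beats$time_s[-1L], amplitude = amp)
}

#' Interpolate an HR (or amplitude) series onto an arbitrary time grid
#'
#' Linear interpolation between beats, constant-extended at the ends.
#'
#' @param series Tibble with `time_s` and one value column.
#' @param grid_s Target times in seconds.
#' @return Numeric vector on `grid_s`.
#' @export
interp_to_grid <- function(series, grid_s) {
  if (nrow(series) == 0L) return(rep(NA_real_, length(grid_s)))
  if (nrow(series) == 1L) return(rep(series[[2L]][1L], length(grid_s)))
  stats::approx(series$time_s, series[[2L]], xout = grid_s, rule = 2)$y
}

#' Cardiac series with automated reliability flag
#'
#' Pulse traces are fragile (finger movement corrupts segments). Where the
#' original workflow relied on visual checks, this wrapper flags a scan as
#' unreliable when more than `max_bad_frac` of inter-beat intervals fall
#' outside `plausible_ibi_s` (defaults: 5% outside 0.33-2 s, i.e. 30-180
#' bpm).
#'
#' @param pulse Raw or cleaned pulse trace.
#' @param sample_hz Sampling rate in Hz (default 400).
#' @param min_spacing_samples,min_prominence See [detect_beats()].
#' @param plausible_ibi_s Plausible inter-beat interval range in seconds.
#' @param max_bad_frac Maximum tolerated fraction of implausible intervals.
#' @return A `cardiac_series` object: list with `beats`, `hr`, `amplitude`,
#'   `bad_fraction`, `reliable`, `sample_hz`.
#' @export
cardiac_series <- function(pulse, sample_hz = 400, min_spacing_samples = 180L,
                           min_prominence = 0.5,
                           plausible_ibi_s = c(0.33, 2), max_bad_frac = 0.05) {
  ct <- if (inherits(pulse, "clean_trace")) pulse else
    clean_trace(pulse, sample_hz, smooth_window_s = NULL)
  sample_hz <- attr(ct, "sample_hz")
  beats <- detect_beats(ct, sample_hz, min_spacing_samples, min_prominence)
  hr <- heart_rate(beats$time_s)
  amp <- pulse_amplitude(ct, beats, sample_hz)
  ibi <- diff(beats$time_s)
  bad <- if (length(ibi)) {
    mean(ibi < plausible_ibi_s[1L] | ibi > plausible_ibi_s[2L])
  } else NA_real_
  structure(list(beats = beats, hr = hr, amplitude = amp,
                 bad_fraction = bad,
                 reliable = isTRUE(bad <= max_bad_frac),
                 sample_hz = sample_hz),
            class = "cardiac_series")
}

#' @export
print.cardiac_series <- function(x, ...) {
  cat("<cardiac_series> ", nrow(x$beats), " beats; mean HR ",
      signif(mean(x$hr$hr_bpm), 4), " bpm; ",
      if (isTRUE(x$reliable)) "reliable" else "UNRELIABLE", "\n", sep = "")
  invisible(x)
}
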