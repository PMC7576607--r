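# Breath detection and the three respiratory measures (ENV, RV, RVT).

#' Detect breath peaks and troughs in a cleaned respiratory trace
#'
#' Local maxima with topographic prominence of at least `min_prominence`
#' z-units and pairwise spacing of at least `min_spacing_s` (breaths are
#' assumed more than 2 s apart); troughs are detected on the inverted trace
#' under the same rule.
#'
#' @param trace A [clean_trace()] (z-scored respiratory trace).
#' @param sample_hz Sampling rate; defaults to the trace attribute.
#' @param min_spacing_s Minimum inter-peak spacing in seconds (default 2).
#' @param min_prominence Minimum prominence in z-units (default 0.5).
#' @return A `breath_extrema` object: list of tibbles `peaks` and `troughs`
#'   (`time_s`, `value`, `prominence`) plus `sample_hz` and `degenerate`.
#' @export
detect_breaths <- function(trace, sample_hz = NULL, min_spacing_s = 2,
                           min_prominence = 0.5) {
  sample_hz <- sample_hz %||% attr(trace, "sample_hz") %||% 400
  x <- as.numeric(trace)
  degen <- isTRUE(attr(trace, "degenerate")) || stats::sd(x) == 0
  empty <- tibble::tibble(time_s = numeric(0), value = numeric(0),
                          prominence = numeric(0))
  if (degen) {
    return(structure(list(peaks = empty, troughs = empty,
                          sample_hz = sample_hz, degenerate = TRUE),
                     class = "breath_extrema"))
  }
  spacing <- round(min_spacing_s * sample_hz)
  one_side <- function(v) {
    idx <- find_peaks(v, min_spacing = spacing, min_prominence = min_prominence)
    tibble::tibble(time_s = (idx - 1L) / sample_hz, value = x[idx],
                   prominence = peak_prominence(v, idx))
  }
  pk <- one_side(x)
  tr <- one_side(-x) # `value` is the true trace value at the trough
  structure(list(peaks = pk, troughs = tr, sample_hz = sample_hz,
                 degenerate = FALSE),
            class = "breath_extrema")
}

#' @export
print.breath_extrema <- function(x, ...) {
  cat("<breath_extrema> ", nrow(x$peaks), " peaks / ", nrow(x$troughs),
      " troughs @ ", x$sample_hz, " Hz\n", sep = "")
  invisible(x)
}

#' Respiratory envelope (ENV): sliding-window RMS
#'
#' Root-mean-square of the z-scored trace over a centered window (10 s by
#' default), shrinking at the endpoints. For a stationary unit-variance
#' trace ENV is approximately 1 throughout.
#'
#' @param trace z-scored respiratory trace.
#' @param sample_hz Sampling rate; defaults to the trace attribute.
#' @param window_s Window length in seconds (default 10).
#' @return Numeric series, same length as the trace.
#' @export
compute_env <- function(trace, sample_hz = NULL, window_s = 10) {
  sample_hz <- sample_hz %||% attr(trace, "sample_hz") %||% 400
  w <- round(window_s * sample_hz)
  if (w > length(trace)) stop("ENV window longer than trace")
  slide_rms(as.numeric(trace), w)
}

#' Respiration variance (RV): sliding-window standard deviation
#'
#' Standard deviation of the treated respiratory trace within a centered
#' window (6 s by default), endpoints shrinking.
#'
#' @inheritParams compute_env
#' @param window_s Window length in seconds (default 6).
#' @return Numeric series, same length as the trace.
#' @export
compute_rv <- function(trace, sample_hz = NULL, window_s = 6) {
  sample_hz <- sample_hz %||% attr(trace, "sample_hz") %||% 400
  w <- round(window_s * sample_hz)
  if (w > length(trace)) stop("RV window longer than trace")
  slide_sd(as.numeric(trace), w)
}

#' Respiration volume per time (RVT)
#'
#' For each peak after the first that has a trough between it and the
#' previous peak: RVT = (peak value - prior trough value) / (time between
#' the two peaks). Peaks lacking an interceding trough are skipped (no value
#' is scored at that peak). A continuous series is produced by linear
#' interpolation between scored peaks, constant-extended at the ends.
#'
#' RVT is a depth-per-time measure: co-scaling breath amplitude and period
#' leaves it unchanged, which is why slow deep breaths barely deflect RVT
#' while ENV and RV rise -- the dissociation that separates sighs from
#' bursts across the three measures.
#'
#' @param trace z-scored respiratory trace (used for series length/grid).
#' @param extrema A [detect_breaths()] result.
#' @param sample_hz Sampling rate; defaults to the trace attribute.
#' @return List with `peaks` (tibble: `time_s`, `value`, `rvt`; `rvt` is NA
#'   where unscored), `series` (numeric, trace grid), and `degenerate`.
#' @export
compute_rvt <- function(trace, extrema, sample_hz = NULL) {
  sample_hz <- sample_hz %||% attr(trace, "sample_hz") %||% 400
  n <- length(trace)
  pk <- extrema$peaks
  if (nrow(pk) < 2L) {
    return(list(peaks = tibble::tibble(time_s = pk$time_s, value = pk$value,
                                       rvt = rep(NA_real_, nrow(pk))),
                series = rep(NA_real_, n), degenerate = TRUE))
  }
  tt <- extrema$troughs$time_s
  tv <- extrema$troughs$value
  rvt <- rep(NA_real_, nrow(pk))
  # last trough strictly before each peak; scored only if it also falls
  # after the previous peak (otherwise no interceding trough)
  last_before <- findInterval(pk$time_s - 1e-12, tt)
  for (k in 2:nrow(pk)) {
    j <- last_before[k]
    if (j < 1L || tt[j] <= pk$time_s[k - 1L]) next # not scored
    rvt[k] <- (pk$value[k] - tv[j]) /
      (pk$time_s[k] - pk$time_s[k - 1L])
  }
  scored <- which(!is.na(rvt))
  series <- rep(NA_real_, n)
  if (length(scored) >= 1L) {
    grid <- (seq_len(n) - 1L) / sample_hz
    if (length(scored) == 1L) {
      series <- rep(rvt[scored], n)
    } else {
      series <- stats::approx(pk$time_s[scored], rvt[scored], xout = grid,
                              rule = 2)$y
    }
  }
  list(peaks = tibble::tibble(time_s = pk$time_s, value = pk$value, rvt = rvt),
       series = series, degenerate = length(scored) == 0L)
}

#' Breathing-rate series and rate variability
#'
#' Instantaneous rate is 60 / inter-peak interval, assigned at the later
#' peak; `rate_cv` is the coefficient of variation (SD/mean) of the
#' inter-peak intervals and is the pattern index's haphazard-breathing
#' downweighting input.
#'
#' @param extrema A [detect_breaths()] result.
#' @return List with `rate` (tibble: `time_s`, `rate_bpm`), `rate_cv`, and
#'   `degenerate` (TRUE when fewer than 3 peaks).
#' @export
breathing_rate_stats <- function(extrema) {
  pk <- extrema$peaks$time_s
  if (length(pk) < 3L) {
    return(list(rate = tibble::tibble(time_s = numeric(0), rate_bpm = numeric(0)),
                rate_cv = NA_real_, degenerate = TRUE))
  }
  ipi <- diff(pk)
  list(rate = tibble::tibble(time_s = pk[-1L], rate_bpm = 60 / ipi),
       rate_cv = stats::sd(ipi) / mean(ipi), degenerate = FALSE)
}

#' All respiratory measures for one scan
#'
#' Cleans the raw belt trace (unless already a `clean_trace`) and computes
#' breath extrema, ENV, RV, RVT and rate statistics in one pass.
#'
#' @param resp Raw belt trace in arbitrary units, or a [clean_trace()].
#' @param sample_hz Sampling rate in Hz (default 400).
#' @param env_window_s,rv_window_s ENV and RV windows in seconds.
#' @param min_spacing_s,min_prominence Peak-detection parameters, see
#'   [detect_breaths()].
#' @return A `resp_measures` object: list with `trace` (clean),
#'   `extrema`, `env`, `rv`, `rvt` (list from [compute_rvt()]), `rate`,
#'   `rate_cv`, `sample_hz`.
#' @export
respiratory_measures <- function(resp, sample_hz = 400, env_window_s = 10,
                                 rv_window_s = 6, min_spacing_s = 2,
                                 min_prominence = 0.5) {
  ct <- if (inherits(resp, "clean_trace")) resp else clean_trace(resp, sample_hz)
  sample_hz <- attr(ct, "sample_hz")
  ex <- detect_breaths(ct, sample_hz, min_spacing_s, min_prominence)
  rvt <- compute_rvt(ct, ex, sample_hz)
  rs <- breathing_rate_stats(ex)
  structure(list(trace = ct, extrema = ex,
                 env = compute_env(ct, sample_hz, env_window_s),
                 rv = compute_rv(ct, sample_hz, rv_window_s),
                 rvt = rvt, rate = rs$rate, rate_cv = rs$rate_cv,
                 sample_hz = sample_hz),
            class = "resp_measures")
}

#' @export
print.resp_measures <- function(x, ...) {
  cat("<resp_measures> ", length(x$trace), " samples @ ", x$sample_hz, " Hz; ",
      nrow(x$extrema$peaks), " breaths; rate_cv = ",
      signif(x$rate_cv, 3), "\n", sep = "")
  invisible(x)
}

#' Tabulate respiratory measure series
#'
#' @param x A `resp_measures` object.
#' @param ... Unused.
#' @return Tibble with `time_s`, `trace`, `env`, `rv`, `rvt_interp`.
#' @export
tidy.resp_measures <- function(x, ...) {
  n <- length(x$trace)
  tibble::tibble(time_s = (seq_len(n) - 1L) / x$sample_hz,
                 trace = as.numeric(x$trace), env = x$env, rv = x$rv,
                 rvt_interp = x$rvt$series)
}
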