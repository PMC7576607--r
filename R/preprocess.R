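# Cleaning of raw physiological traces. The pipeline order is fixed:
# outlier replacement -> smoothing -> z-scoring; clean_trace() enforces it and
# records provenance.

#' Replace spike artifacts in a physiological trace
#'
#' Pressure-belt and pulse-oximetry recordings carry occasional spurious
#' spikes (connector noise, subject movement against the belt). Samples
#' deviating more than `n_mad` scaled median absolute deviations from the
#' moving median over `window` samples are replaced by linear interpolation
#' between the nearest non-outlier neighbors; outlying runs at either end
#' extend the nearest valid value.
#'
#' @param x Numeric trace.
#' @param window Moving-median window in samples (default 100, i.e. 0.25 s at
#'   400 Hz). Must span at least 3 samples.
#' @param n_mad Outlier threshold in scaled (consistent-for-normal) median
#'   absolute deviations (default 3).
#' @return The trace with outliers replaced; the number of replacements is
#'   attached as attribute `n_replaced`.
#' @details Detection and replacement are iterated to a fixed point (a
#'   replaced spike slightly shifts the local median/MAD, which can expose
#'   secondary outliers), so applying the filter to its own output changes
#'   nothing.
#' @export
replace_outliers <- function(x, window = 100L, n_mad = 3) {
  if (window < 3L) stop("outlier window must span at least 3 samples")
  assert_scalar_num(n_mad, "n_mad", lower = 0)
  n <- length(x)
  k <- as.integer(window)
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 0L) n - 1L else n)
  y <- x
  total <- 0L
  for (iter in seq_len(20L)) {
    med <- moving_median_shrink(y, k)
    dev <- abs(y - med)
    smad <- 1.4826 * moving_median_shrink(dev, k)
    out <- dev > n_mad * smad & smad > 0
    if (!any(out)) break
    good <- which(!out)
    if (!length(good)) {
      stop("every sample flagged as outlier; cannot interpolate")
    }
    y[out] <- stats::approx(good, y[good], xout = which(out), rule = 2)$y
    total <- total + sum(out)
  }
  structure(y, n_replaced = total)
}

# Moving median over a centered window that shrinks symmetrically at the
# endpoints: fast C path for the interior, explicit truncated windows for
# the first/last half-window.
moving_median_shrink <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  mm <- stats::runmed(x, k, endrule = "keep")
  for (i in seq_len(min(h, n))) {
    mm[i] <- stats::median(x[seq_len(min(n, i + h))])
  }
  for (i in seq.int(max(1L, n - h + 1L), n)) {
    mm[i] <- stats::median(x[max(1L, i - h):n])
  }
  mm
}

#' Smooth a trace with a local quadratic (Savitzky-Golay) filter
#'
#' Gentle blurring ahead of peak detection: each sample is replaced by the
#' value at that sample of a least-squares quadratic fitted over a centered
#' window (1 s, i.e. 400 samples at 400 Hz, by default). Polynomials of
#' order <= 2 pass through unchanged; breath peak positions move by less
#' than the window curvature allows.
#'
#' @param x Numeric trace.
#' @param sample_hz Sampling rate in Hz.
#' @param window_s Smoothing window in seconds (default 1).
#' @param order Polynomial order (default 2).
#' @return Smoothed trace, same length.
#' @export
smooth_trace <- function(x, sample_hz = 400, window_s = 1, order = 2L) {
  assert_scalar_num(sample_hz, "sample_hz", lower = 1e-9)
  assert_scalar_num(window_s, "window_s", lower = 1e-9)
  n_w <- round(window_s * sample_hz)
  if (n_w < 5) stop("smoothing window must span at least 5 samples (window_s * sample_hz >= 5)")
  sg_smooth(x, n_w, p = order)
}

#' z-score a trace
#'
#' Centers and scales to unit standard deviation. A constant trace cannot be
#' scaled; it returns all zeros with the `degenerate` attribute set, and
#' downstream detectors treat it as empty rather than erroring.
#'
#' @param x Numeric trace of length >= 2.
#' @return Numeric trace with attribute `degenerate` (logical).
#' @export
zscore_trace <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples to z-score")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(structure(rep(0, length(x)), degenerate = TRUE))
  }
  structure((x - mean(x)) / s, degenerate = FALSE)
}

#' Clean a raw belt or pulse trace
#'
#' Applies the fixed cleaning order -- outlier replacement, quadratic
#' smoothing, z-scoring -- and records each step with its parameters.
#'
#' @param x Raw trace in arbitrary units.
#' @param sample_hz Sampling rate in Hz (default 400).
#' @param outlier_window,outlier_nmad Passed to [replace_outliers()].
#' @param smooth_window_s Passed to [smooth_trace()]; `NULL` skips smoothing
#'   (pulse traces are peak-picked unsmoothed).
#' @return A `clean_trace`: numeric vector with attributes `sample_hz`,
#'   `degenerate` and `provenance` (list of applied steps).
#' @examples
#' raw <- 1000 + 200 * sin(2 * pi * 0.25 * seq(0, 60, by = 1 / 50))
#' ct <- clean_trace(raw, sample_hz = 50)
#' round(c(mean(ct), sd(ct)), 10)
#' @export
clean_trace <- function(x, sample_hz = 400, outlier_window = 100L,
                        outlier_nmad = 3, smooth_window_s = 1) {
  prov <- list()
  y <- replace_outliers(x, window = outlier_window, n_mad = outlier_nmad)
  prov$replace_outliers <- list(window = outlier_window, n_mad = outlier_nmad,
                                n_replaced = attr(y, "n_replaced"))
  if (!is.null(smooth_window_s)) {
    y <- smooth_trace(as.numeric(y), sample_hz = sample_hz, window_s = smooth_window_s)
    prov$smooth_trace <- list(window_s = smooth_window_s, order = 2L)
  }
  z <- zscore_trace(as.numeric(y))
  prov$zscore <- list()
  structure(as.numeric(z), sample_hz = sample_hz,
            degenerate = attr(z, "degenerate"), provenance = prov,
            class = "clean_trace")
}

#' @export
print.clean_trace <- function(x, ...) {
  cat("<clean_trace> ", length(x), " samples @ ", attr(x, "sample_hz"), " Hz",
      if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}
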