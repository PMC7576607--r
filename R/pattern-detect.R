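# Automated indexing of breathing patterns. Architecture: probability-like
# priors derived from the respiratory belt trace are multiplied by the
# rectified fit of pattern templates to the global fMRI signal, time-averaged
# over the scan, and downweighted by breathing-rate variability; per-subject
# indices are means over scans. The prior/template/downweighting forms below
# are this package's concrete realization of that architecture, with every
# constant exposed as an argument.

#' Deep-breath prior from the respiratory trace
#'
#' High where an isolated breath's prominence exceeds `k` times the local
#' median prominence while its immediate neighbors stay near-eupneic; flat
#' from `lead_s` before the breath peak, decaying exponentially over
#' `support_s` after it. Serial large breaths (bursts) are damped by the
#' isolation term, which is what keeps the two patterns' priors apart.
#'
#' @param measures A [respiratory_measures()] result.
#' @param tr_s Frame interval in seconds.
#' @param n_frames Number of frames in the prior series.
#' @param k Prominence multiple of the local median at which the prior
#'   saturates to 0.5 (default 2).
#' @param local_window_s Window (s) for the local median prominence.
#' @param lead_s Seconds before the breath peak the prior switches on
#'   (covers the breath onset itself).
#' @param support_s Decay support after the peak (default 10 s).
#' @param decay_s Exponential decay constant (default 4 s).
#' @return Numeric series in `[0, 1]` at the frame grid; attribute
#'   `degenerate` when no breaths were detected.
#' @export
deep_breath_prior <- function(measures, tr_s, n_frames, k = 2,
                              local_window_s = 90, lead_s = 6,
                              support_s = 10, decay_s = 4) {
  pk <- measures$extrema$peaks
  out <- rep(0, n_frames)
  if (nrow(pk) < 3L) return(structure(out, degenerate = TRUE))
  tt <- pk$time_s
  prom <- pk$prominence
  local_med <- vapply(seq_along(tt), function(i) {
    nb <- abs(tt - tt[i]) <= local_window_s
    stats::median(prom[nb])
  }, numeric(1))
  ratio <- prom / pmax(local_med, 1e-12)
  raw <- pmax(0, ratio - 1)
  # quartic saturation: 0.5 at ratio k, near 0 for eupneic fluctuations
  score <- raw^4 / (raw^4 + (k - 1)^4)
  # isolation: damp when adjacent breaths are themselves enlarged
  n_pk <- length(tt)
  nb_ratio <- pmax(c(ratio[-1L], 0), c(0, ratio[-n_pk]))
  score <- score * exp(-pmax(0, nb_ratio - 1.5))
  t_frame <- (seq_len(n_frames) - 0.5) * tr_s
  for (i in which(score > 1e-3)) {
    dt <- t_frame - tt[i]
    shape <- ifelse(dt < -lead_s | dt > support_s, 0,
                    ifelse(dt <= 0, 1, exp(-dt / decay_s)))
    out <- pmax(out, score[i] * shape)
  }
  structure(pmin(out, 1), degenerate = FALSE)
}

# Sliding variance-balanced correlation between x and its lagged copy,
# window of w samples centered on the midpoint of each sample pair;
# constant-padded. Normalizing by the larger of the two window variances
# (rather than their geometric mean) damps windows where one side's
# variance is a single transient -- a lone bump must not probe the other
# window's noise at full Pearson scale.
slide_corr_lag <- function(x, lag, w) {
  n <- length(x)
  if (lag >= n - 2L) return(rep(0, n))
  a <- x[seq_len(n - lag)]
  b <- x[(lag + 1L):n]
  sa <- slide_sums(a, w)
  sb <- slide_sums(b, w)
  csab <- c(0, cumsum(a * b))
  bnd <- slide_bounds(length(a), w)
  sab <- csab[bnd$hi + 1L] - csab[bnd$lo]
  m <- sa$m
  cov_ab <- sab - sa$s1 * sb$s1 / m
  va <- sa$s2 - sa$s1^2 / m
  vb <- sb$s2 - sb$s1^2 / m
  r <- ifelse(va > 1e-12 & vb > 1e-12, cov_ab / pmax(va, vb), 0)
  # stamp at the pair midpoint, extend ends
  out <- rep(0, n)
  pos <- seq_len(n - lag) + lag %/% 2L
  out[pos] <- r
  out[seq_len(lag %/% 2L)] <- r[1L]
  if (max(pos) < n) out[(max(pos) + 1L):n] <- r[length(r)]
  out
}

#' Burst prior from the respiratory trace
#'
#' High where the breathing-depth envelope (ENV) shows deep, slow,
#' *repeating* modulation at burst timescales. Two windowed statistics are
#' combined: the modulation depth (local ENV SD over local ENV mean) and
#' the peak positive autocorrelation of the ENV over lags spanning
#' `period_range_s` (25-70 s), i.e. evidence for a dominant modulation
#' period in the burst-cycle band. Their product is mapped through a
#' saturating function. A lone deep breath modulates ENV once but not
#' periodically, so its autocorrelation at burst lags stays low.
#'
#' @param measures A [respiratory_measures()] result.
#' @param tr_s Frame interval in seconds.
#' @param n_frames Number of frames.
#' @param window_s Analysis window in seconds (default 150; scans shorter
#'   than this are an error).
#' @param period_range_s Modulation-period (lag) range in seconds.
#' @param lag_step_s Lag grid step (default 5 s).
#' @param m0 Modulation statistic at which the prior reaches 0.5.
#' @return Numeric series in `[0, 1]` at the frame grid.
#' @export
burst_prior <- function(measures, tr_s, n_frames, window_s = 150,
                        period_range_s = c(25, 70), lag_step_s = 5,
                        m0 = 0.15) {
  scan_s <- n_frames * tr_s
  if (scan_s < window_s) {
    stop("scan (", signif(scan_s, 5), " s) shorter than the burst analysis ",
         "window (", window_s, " s)")
  }
  env_f <- frame_average(measures$env, measures$sample_hz, tr_s, n_frames)
  w <- round(window_s / tr_s)
  m <- slide_sd(env_f, w) / pmax(slide_mean(env_f, w), 1e-6)
  lags <- unique(round(seq(period_range_s[1L], period_range_s[2L],
                           by = lag_step_s) / tr_s))
  # periodicity comb: autocorrelation at the period minus at the half
  # period -- near zero for slow drifts and one-off bumps, large for
  # genuine cycling at that period
  half <- unique(lags %/% 2L)
  r_at <- lapply(stats::setNames(nm = c(lags, half)), function(l)
    slide_corr_lag(env_f, l, w))
  # require both repetition (positive r at the full lag) and a trough at
  # the half lag; a lone sigh-plus-apnea pair passes the comb but not the
  # repetition requirement
  period_score <- rep(0, n_frames)
  for (l in lags) {
    r_l <- r_at[[as.character(l)]]
    comb <- pmin(r_l, r_l - r_at[[as.character(l %/% 2L)]])
    period_score <- pmax(period_score, comb)
  }
  raw <- period_score * m
  pmin(raw^2 / (raw^2 + m0^2), 1)
}

#' Rectified template fit to the global fMRI signal
#'
#' Sliding Pearson correlation between the kernel and the signal window
#' starting at each frame (so the match is time-stamped at the response
#' onset); negative correlations are clamped to zero. The tail (frames with
#' incomplete windows) is zero-padded.
#'
#' @param global_z z-scored global signal at the frame grid.
#' @param kernel A [response_kernel()]; resampled internally to `tr_s`.
#' @param tr_s Frame interval in seconds.
#' @return Numeric match series in `[0, 1]`, same length as `global_z`.
#' @export
template_match <- function(global_z, kernel, tr_s) {
  k <- if (abs(kernel$dt_s - tr_s) < 1e-12) kernel$samples else
    stats::approx(kernel$time_s, kernel$samples,
                  xout = seq(0, kernel$support_s, by = tr_s), rule = 2)$y
  x <- as.numeric(global_z)
  n <- length(x)
  L <- length(k)
  if (n < L) stop("signal (", n, " frames) shorter than template (", L, ")")
  kc <- k - mean(k)
  ks <- sqrt(sum(kc^2))
  # window sums via cumsum; cross term via one-sided linear filter
  cs1 <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n - L + 1L)
  s1 <- cs1[i + L] - cs1[i]
  s2 <- cs2[i + L] - cs2[i]
  cross <- stats::filter(x, rev(kc), sides = 1L)[i + L - 1L]
  sx <- sqrt(pmax(s2 - s1^2 / L, 0))
  r <- ifelse(sx > 1e-12, cross / (sx * ks), 0)
  c(pmax(r, 0), rep(0, L - 1L))
}

#' Stretch a response kernel's time axis
#'
#' Used to test detection robustness to template mis-specification: a
#' stretch of 1.2 delays every timing landmark (peak, nadir, resolution) by
#' 20%.
#'
#' @param kernel A [response_kernel()].
#' @param stretch Multiplicative time-axis factor.
#' @return A `response_kernel` with resampled values.
#' @export
perturb_kernel <- function(kernel, stretch) {
  t_new <- kernel$time_s
  y <- stats::approx(kernel$time_s * stretch, kernel$samples, xout = t_new,
                     rule = 2)$y
  out <- kernel
  out$samples <- y / max(abs(y))
  out
}

#' Haphazard-breathing downweighting factor
#'
#' `exp(-lambda * max(0, rate_cv - c0))`: scans with breathing-rate
#' coefficient of variation beyond `c0` are discounted to dampen outliers
#' from erratic breathing.
#'
#' @param rate_cv Coefficient of variation of inter-breath intervals.
#' @param lambda Decay rate (default 5).
#' @param c0 Tolerated rate CV (default 0.15).
#' @return Scalar weight in `(0, 1]`.
#' @export
rate_cv_weight <- function(rate_cv, lambda = 5, c0 = 0.15) {
  if (is.na(rate_cv)) return(1)
  exp(-lambda * max(0, rate_cv - c0))
}

#' Scan-level pattern index
#'
#' Time-averaged product of the prior and match series, downweighted by the
#' breathing-rate variability factor. Wherever the prior is zero the scan
#' contributes nothing, regardless of the template fit.
#'
#' @param prior_series,match_series Aligned frame-grid series.
#' @param rate_cv Breathing-rate CV of the scan.
#' @param lambda,c0 See [rate_cv_weight()].
#' @return Nonnegative scalar.
#' @export
pattern_index <- function(prior_series, match_series, rate_cv = NA_real_,
                          lambda = 5, c0 = 0.15) {
  if (length(prior_series) != length(match_series)) {
    stop("prior (", length(prior_series), ") and match (",
         length(match_series), ") series lengths differ")
  }
  mean(prior_series * match_series) * rate_cv_weight(rate_cv, lambda, c0)
}

#' Run the full pattern detector on one scan
#'
#' @param resp Raw belt trace (arbitrary units) or [clean_trace()].
#' @param global_z z-scored global fMRI signal at the frame grid.
#' @param tr_s Frame interval in seconds.
#' @param sample_hz Belt sampling rate (default 400).
#' @param lambda,c0 Downweighting parameters, see [rate_cv_weight()].
#' @param kernels List with `deep_breath` and `burst` [response_kernel()]s
#'   (defaults built at `tr_s`).
#' @param ... Further arguments to [deep_breath_prior()] / [burst_prior()].
#' @return A `pattern_detection` object: scalars `burst_index`,
#'   `deep_index`, `rate_cv`, and the underlying `prior`/`match` series.
#' @export
detect_patterns <- function(resp, global_z, tr_s, sample_hz = 400,
                            lambda = 5, c0 = 0.15, kernels = NULL, ...) {
  n_frames <- length(global_z)
  meas <- if (inherits(resp, "resp_measures")) resp else
    respiratory_measures(resp, sample_hz)
  kernels <- kernels %||% list(deep_breath = response_kernel("deep_breath", tr_s),
                               burst = response_kernel("burst", tr_s))
  dp <- deep_breath_prior(meas, tr_s, n_frames, ...)
  bp <- burst_prior(meas, tr_s, n_frames)
  # cross-pattern exclusion: a deep breath is an *isolated* large breath,
  # so frames explained by an ongoing burst train do not feed the sigh
  # index (cycle-start breaths tower over the taper-depressed local median
  # and would otherwise leak into the sigh prior and template fit). The
  # burst prior is dilated by a running max to cover train edges, and the
  # sigh prior is gated linearly to zero at dilated prior >= 0.5.
  bp_dil <- slide_max(bp, round(90 / tr_s))
  dp <- dp * pmax(0, 1 - 2 * bp_dil)
  dm <- template_match(global_z, kernels$deep_breath, tr_s)
  bm <- template_match(global_z, kernels$burst, tr_s)
  structure(list(
    burst_index = pattern_index(bp, bm, meas$rate_cv, lambda, c0),
    deep_index = pattern_index(dp, dm, meas$rate_cv, lambda, c0),
    rate_cv = meas$rate_cv,
    prior = list(deep = as.numeric(dp), burst = as.numeric(bp)),
    match = list(deep = dm, burst = bm),
    tr_s = tr_s, n_frames = n_frames,
    weight = rate_cv_weight(meas$rate_cv, lambda, c0)
  ), class = "pattern_detection")
}

#' @export
print.pattern_detection <- function(x, ...) {
  cat("<pattern_detection> burst ", signif(x$burst_index, 3), ", deep ",
      signif(x$deep_index, 3), " (rate_cv ", signif(x$rate_cv, 3), ")\n",
      sep = "")
  invisible(x)
}

#' @describeIn detect_patterns One-row tibble of the scan-level indices.
#' @param x A `pattern_detection`.
#' @export
tidy.pattern_detection <- function(x, ...) {
  tibble::tibble(burst_index = x$burst_index, deep_index = x$deep_index,
                 rate_cv = x$rate_cv, weight = x$weight)
}

#' Per-minute decomposition of a pattern index
#'
#' Mean of prior x match within each scan minute (same downweighting
#' factor applied), for the time-in-scan trend analysis.
#'
#' @param detection A [detect_patterns()] result.
#' @param pattern `"burst"` or `"deep"`.
#' @return Tibble with `minute` (1-based) and `index`.
#' @export
pattern_index_by_minute <- function(detection,
                                    pattern = c("burst", "deep")) {
  pattern <- match.arg(pattern)
  pm <- detection$prior[[pattern]] * detection$match[[pattern]]
  frame_minute <- floor((seq_along(pm) - 0.5) * detection$tr_s / 60) + 1L
  idx <- as.numeric(tapply(pm, frame_minute, mean)) * detection$weight
  tibble::tibble(minute = sort(unique(frame_minute)), index = idx)
}

#' Calibrate binarization thresholds from clean-scan indices
#'
#' The threshold for each pattern is set where the index distribution of
#' pattern-free scans has `exceedance` probability mass above it (default
#' 5%).
#'
#' @param clean_indices Tibble with `burst_index` and `deep_index` columns
#'   from pattern-free scans.
#' @param exceedance Target false-call rate on clean scans.
#' @return Named numeric `c(burst = , deep = )`.
#' @export
calibrate_thresholds <- function(clean_indices, exceedance = 0.05) {
  c(burst = stats::quantile(clean_indices$burst_index, 1 - exceedance,
                            names = FALSE),
    deep = stats::quantile(clean_indices$deep_index, 1 - exceedance,
                           names = FALSE))
}

#' Binary calls per scan and pattern scores per subject
#'
#' A scan is called positive when its index reaches the pattern's
#' threshold; a subject's pattern score is the count of positive calls over
#' their scans (0-4 for four scans). Subjects with a scan count other than
#' `expected_scans` are scored over the available scans and flagged.
#'
#' @param index_tbl Tibble with `subject`, `scan`, `burst_index`,
#'   `deep_index`.
#' @param thresholds Named numeric `c(burst = , deep = )`, from
#'   [calibrate_thresholds()].
#' @param expected_scans Expected scans per subject (default 4).
#' @return List with `calls` (scan-level tibble adding `burst_call`,
#'   `deep_call`) and `scores` (subject-level tibble: `burst_score`,
#'   `deep_score`, `burst_index`, `deep_index` subject means,
#'   `incomplete`).
#' @export
binarize_and_score <- function(index_tbl, thresholds, expected_scans = 4L) {
  calls <- dplyr::mutate(index_tbl,
                         burst_call = as.integer(.data$burst_index >=
                                                   thresholds[["burst"]]),
                         deep_call = as.integer(.data$deep_index >=
                                                  thresholds[["deep"]]))
  scores <- calls |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(burst_score = sum(.data$burst_call),
                     deep_score = sum(.data$deep_call),
                     burst_index = mean(.data$burst_index),
                     deep_index = mean(.data$deep_index),
                     n_scans = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(incomplete = .data$n_scans != expected_scans)
  list(calls = calls, scores = scores)
}
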