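# Event-locked extraction and statistics around labeled onsets.

#' Extract event-locked windows from a sampled signal
#'
#' Windows span the half-open interval `[-pre_s, post_s)` about each onset
#' (defaults 30/60 s, i.e. 90-s segments of `90 / dt` samples). Onsets are
#' snapped to the nearest sample (ties toward earlier); onsets too close to
#' either end of the record are dropped and reported via the `dropped`
#' attribute.
#'
#' @param x Numeric series.
#' @param rate_hz Sampling rate of `x` in Hz (for frame-rate signals pass
#'   `1/tr_s`).
#' @param onsets_s Event onsets in seconds.
#' @param pre_s,post_s Window extent in seconds (defaults 30 and 60).
#' @param label Event-type label carried on the result.
#' @return An `event_windows` object: matrix (events x samples) with
#'   `time_s` (0 at onset), `label`, `rate_hz`, and attribute `dropped`.
#' @export
extract_windows <- function(x, rate_hz, onsets_s, pre_s = 30, post_s = 60,
                            label = "event") {
  n <- length(x)
  n_pre <- round(pre_s * rate_hz)
  n_post <- round(post_s * rate_hz)
  centers <- floor(onsets_s * rate_hz + 0.5 - 1e-9) + 1L # nearest, ties earlier
  ok <- centers - n_pre >= 1L & centers + n_post - 1L <= n
  if (!any(ok)) stop("no onset admits a full [", -pre_s, ", ", post_s,
                     ") s window within the record")
  dropped <- onsets_s[!ok]
  if (length(dropped)) {
    message(length(dropped), " onset(s) dropped (window exceeds record): ",
            paste(signif(dropped, 5), collapse = ", "))
  }
  offs <- seq.int(-n_pre, n_post - 1L)
  idx <- outer(centers[ok], offs, `+`)
  w <- matrix(x[idx], nrow = sum(ok))
  structure(list(windows = w, time_s = offs / rate_hz,
                 label = label, rate_hz = rate_hz, onsets_s = onsets_s[ok]),
            dropped = dropped, class = "event_windows")
}

#' @export
print.event_windows <- function(x, ...) {
  cat("<event_windows> '", x$label, "': ", nrow(x$windows), " events x ",
      ncol(x$windows), " samples (", min(x$time_s), " to ", max(x$time_s),
      " s)\n", sep = "")
  invisible(x)
}

#' Pointwise mean and SD across event windows
#'
#' @param ws An [extract_windows()] result with at least 2 events.
#' @return Tibble: `time_s`, `mean`, `sd`, `n`, `label`.
#' @export
event_mean_sd <- function(ws) {
  if (nrow(ws$windows) < 2L) stop("need at least 2 events")
  tibble::tibble(time_s = ws$time_s,
                 mean = colMeans(ws$windows),
                 sd = apply(ws$windows, 2L, stats::sd),
                 n = nrow(ws$windows), label = ws$label)
}

#' Pointwise two-sample t-test between two event-window sets
#'
#' Welch two-sided t-test at every timepoint; the display band colors
#' p < 0.001 on a log scale capped at 1e-10. Timepoints where both sets
#' have zero variance get p = 1 and are flagged.
#'
#' @param ws_a,ws_b [extract_windows()] results on the same time axis.
#' @param p_color Band coloring threshold (default 1e-3).
#' @param p_cap Lower cap for the log-scale display (default 1e-10).
#' @return Tibble: `time_s`, `t`, `p`, `p_display` (capped), `significant`,
#'   `degenerate`.
#' @export
pointwise_ttest <- function(ws_a, ws_b, p_color = 1e-3, p_cap = 1e-10) {
  if (nrow(ws_a$windows) < 2L || nrow(ws_b$windows) < 2L) {
    stop("need at least 2 events per set")
  }
  if (!isTRUE(all.equal(ws_a$time_s, ws_b$time_s))) {
    stop("window sets are on different time axes")
  }
  a <- ws_a$windows
  b <- ws_b$windows
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  degen <- va == 0 & vb == 0
  se2 <- va / na + vb / nb
  tt <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)), 1)
  p <- ifelse(degen, 1, 2 * stats::pt(-abs(tt), df))
  tibble::tibble(time_s = ws_a$time_s, t = tt, p = p,
                 p_display = pmax(p, p_cap),
                 significant = p < p_color, degenerate = degen)
}

#' Event-window connectivity matrices
#'
#' For each onset, Pearson correlations among parcel time series over the
#' span (default -10 to +40 s about onset), Fisher-Z transformed; the mean
#' across events is computed in Z and reported in r. Events whose span
#' leaves the scan are dropped.
#'
#' @param parcel_ts Parcel-by-frame matrix.
#' @param tr_s Frame interval in seconds.
#' @param onsets_s Event onsets in seconds.
#' @param span_s Two-element span about onset (default `c(-10, 40)`).
#' @return List: `mean_z` (parcel x parcel Fisher-Z), `mean_r`, `n_events`,
#'   `per_event` (list of Z matrices).
#' @export
event_connectivity <- function(parcel_ts, tr_s, onsets_s,
                               span_s = c(-10, 40)) {
  n <- ncol(parcel_ts)
  n_pre <- round(-span_s[1L] / tr_s)
  n_post <- round(span_s[2L] / tr_s)
  centers <- floor(onsets_s / tr_s + 0.5 - 1e-9) + 1L
  ok <- centers - n_pre >= 1L & centers + n_post <= n
  if (!any(ok)) stop("no event span fits within the scan")
  zs <- lapply(centers[ok], function(cf) {
    seg <- t(parcel_ts[, (cf - n_pre):(cf + n_post), drop = FALSE])
    fisher_z(stats::cor(seg))
  })
  mean_z <- Reduce(`+`, zs) / length(zs)
  diag(mean_z) <- 0
  list(mean_z = mean_z, mean_r = z_to_r(mean_z), n_events = length(zs),
       per_event = zs)
}

#' Mean correlation within and between network blocks
#'
#' Convenience summary of a parcel matrix: the mean off-diagonal value of
#' each network-pair block.
#'
#' @param mat Parcel x parcel matrix (r or Z).
#' @param network Per-parcel network labels.
#' @return Tibble: `network_a`, `network_b`, `mean_value`.
#' @export
network_block_means <- function(mat, network) {
  nets <- unique(network)
  purrr::map_dfr(seq_along(nets), function(i) {
    purrr::map_dfr(seq.int(i, length(nets)), function(j) {
      rows <- network == nets[i]
      cols <- network == nets[j]
      block <- mat[rows, cols, drop = FALSE]
      if (i == j) {
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.numeric(block)
      }
      tibble::tibble(network_a = nets[i], network_b = nets[j],
                     mean_value = mean(vals))
    })
  })
}
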