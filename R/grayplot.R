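# Carpet/gray-plot construction and ggplot2 display helpers.

#' Gray-plot matrix: compartment-ordered, row-standardized signals
#'
#' Rows are z-scored per unit and stably sorted by compartment (gray block
#' first, then white, then csf), the order used for carpet displays; the
#' display limits are symmetric about 0.
#'
#' @param scan A [scan_data()].
#' @param limits Symmetric display clip in z-units (default 2).
#' @return List: `matrix` (ordered units x frames, clipped), `order`
#'   (original row indices), `compartment` (ordered labels), `separator`
#'   (row count of the gray block, NULL when no white/csf rows), `limits`.
#' @export
grayplot_matrix <- function(scan, limits = 2) {
  comp <- factor(scan$compartment, levels = c("gray", "white", "csf"))
  ord <- order(comp) # stable
  m <- scan$signals[ord, , drop = FALSE]
  m <- t(apply(m, 1L, zscore_vec))
  m <- pmin(pmax(m, -limits), limits)
  n_gray <- sum(scan$compartment == "gray")
  list(matrix = m, order = ord,
       compartment = as.character(comp[ord]),
       separator = if (n_gray < nrow(m)) n_gray else NULL,
       limits = limits)
}

#' Render a gray plot with its physiological panel stack
#'
#' Writes a figure stacking the z-scored respiratory trace, the three
#' respiratory measures (ENV/RV/RVT at fixed vertical offsets), the global
#' signal, FD and DVARS above the compartment-ordered heat map (green line
#' separating gray matter when white/csf rows exist). Deterministic given
#' its inputs.
#'
#' @param scan A [scan_data()] with motion.
#' @param measures A [respiratory_measures()] for the scan's belt trace.
#' @param path Output file (.png or .svg).
#' @param metrics Optional precomputed [scan_metrics()] tibble.
#' @param width,height Figure size in inches.
#' @return `path`, invisibly; the underlying matrix is attached as
#'   attribute `grayplot`.
#' @export
render_grayplot <- function(scan, measures, path, metrics = NULL,
                            width = 8, height = 6) {
  missing_panels <- character(0)
  if (is.null(scan$motion)) missing_panels <- c(missing_panels, "FD (motion)")
  if (!inherits(measures, "resp_measures")) {
    missing_panels <- c(missing_panels, "respiratory measures")
  }
  if (length(missing_panels)) {
    stop("cannot render gray plot; missing panels: ",
         paste(missing_panels, collapse = ", "))
  }
  metrics <- metrics %||% scan_metrics(scan)
  gp <- grayplot_matrix(scan)
  n_frames <- ncol(scan$signals)
  tgrid <- (seq_len(n_frames) - 1L) * scan$tr_s
  env_f <- frame_average(measures$env, measures$sample_hz, scan$tr_s, n_frames)
  rv_f <- frame_average(measures$rv, measures$sample_hz, scan$tr_s, n_frames)
  rvt_f <- frame_average(ifelse(is.na(measures$rvt$series), 0,
                                measures$rvt$series),
                         measures$sample_hz, scan$tr_s, n_frames)
  resp_f <- frame_average(as.numeric(measures$trace), measures$sample_hz,
                          scan$tr_s, n_frames)
  traces <- dplyr::bind_rows(
    tibble::tibble(time_s = tgrid, value = resp_f, panel = "resp",
                   series = "resp"),
    tibble::tibble(time_s = tgrid, value = env_f + 0, panel = "measures",
                   series = "ENV"),
    tibble::tibble(time_s = tgrid, value = rv_f + 3, panel = "measures",
                   series = "RV"),
    tibble::tibble(time_s = tgrid, value = rvt_f + 6, panel = "measures",
                   series = "RVT"),
    tibble::tibble(time_s = tgrid, value = metrics$global_z, panel = "global",
                   series = "global"),
    tibble::tibble(time_s = tgrid, value = metrics$fd_filtered, panel = "FD",
                   series = "FD"),
    tibble::tibble(time_s = tgrid, value = metrics$dvars_z, panel = "DVARS",
                   series = "DVARS")
  )
  traces$panel <- factor(traces$panel,
                         levels = c("resp", "measures", "global", "FD",
                                    "DVARS"))
  heat <- tidyr::expand_grid(row = seq_len(nrow(gp$matrix)),
                             frame = seq_len(n_frames))
  heat$time_s <- (heat$frame - 1L) * scan$tr_s
  heat$value <- as.numeric(t(gp$matrix))[
    (heat$row - 1L) * n_frames + heat$frame]
  p_traces <- ggplot2::ggplot(traces,
                              ggplot2::aes(x = .data$time_s,
                                           y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25, ggplot2::aes(group = .data$series)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 8)
  p_heat <- ggplot2::ggplot(heat, ggplot2::aes(x = .data$time_s,
                                               y = .data$row,
                                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "gray50",
                                  high = "white",
                                  limits = c(-gp$limits, gp$limits)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "units") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(legend.position = "none")
  if (!is.null(gp$separator)) {
    p_heat <- p_heat + ggplot2::geom_hline(yintercept = gp$separator + 0.5,
                                           color = "green", linewidth = 0.4)
  }
  if (requireNamespace("patchwork", quietly = TRUE)) {
    combined <- patchwork::wrap_plots(p_traces, p_heat, ncol = 1L,
                                      heights = c(1.2, 1))
  } else {
    combined <- p_heat
  }
  ggplot2::ggsave(path, combined, width = width, height = height, dpi = 150)
  invisible(structure(path, grayplot = gp))
}

#' Plot event-locked mean traces with a mean +/- SD shade
#'
#' @param mean_sd Tibble from [event_mean_sd()] (rows from several labels
#'   can be stacked).
#' @return A ggplot.
#' @export
plot_event_response <- function(mean_sd) {
  ggplot2::ggplot(mean_sd, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                        color = .data$label,
                                        fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "time from onset (s)", y = "signal") +
    ggplot2::theme_minimal()
}

#' Heat-map display of a connectivity (or contrast) matrix
#'
#' @param mat Parcel x parcel matrix.
#' @param network Optional per-parcel network labels for axis ordering.
#' @param mask Optional logical matrix; unmasked cells are grayed.
#' @return A ggplot.
#' @export
plot_connectivity_matrix <- function(mat, network = NULL, mask = NULL) {
  p <- nrow(mat)
  ord <- if (is.null(network)) seq_len(p) else order(network)
  m <- mat[ord, ord]
  df <- tidyr::expand_grid(row = seq_len(p), col = seq_len(p))
  df$value <- as.numeric(m)[(df$col - 1L) * p + df$row]
  if (!is.null(mask)) {
    mm <- mask[ord, ord]
    df$value[!as.logical(mm)[(df$col - 1L) * p + df$row]] <- NA
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(na.value = "gray70") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the prior, match and product series of a pattern detection
#'
#' @param object A [detect_patterns()] result.
#' @param ... Unused.
#' @return A ggplot faceted by pattern and series.
#' @export
autoplot.pattern_detection <- function(object, ...) {
  tgrid <- (seq_len(object$n_frames) - 0.5) * object$tr_s
  df <- dplyr::bind_rows(
    tibble::tibble(time_s = tgrid, value = object$prior$burst,
                   pattern = "burst", series = "prior"),
    tibble::tibble(time_s = tgrid, value = object$match$burst,
                   pattern = "burst", series = "match"),
    tibble::tibble(time_s = tgrid, value = object$prior$deep,
                   pattern = "deep_breath", series = "prior"),
    tibble::tibble(time_s = tgrid, value = object$match$deep,
                   pattern = "deep_breath", series = "match")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$pattern, ncol = 1L) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
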