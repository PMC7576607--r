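# Scan container and fMRI-side quality/summary series: global signal, DVARS,
# framewise displacement (original / respiration-filtered / 4-TR), and
# alignment of 400 Hz physiology onto the frame grid.

#' Construct a scan object
#'
#' Holds a unit-by-frame signal matrix (voxels or parcels) with its
#' repetition time, tissue-compartment or network labels, and optional
#' motion parameters.
#'
#' @param signals Numeric matrix, units x frames.
#' @param tr_s Repetition time in seconds.
#' @param compartment Per-unit labels in `{gray, white, csf}`. Defaults to
#'   all-gray, which is the parcel-mode convention (cortical parcels).
#' @param network Optional per-unit network labels (parcel mode).
#' @param motion Optional [motion_params()] with matching frame count.
#' @return A `scan_data` object.
#' @export
scan_data <- function(signals, tr_s, compartment = NULL, network = NULL,
                      motion = NULL) {
  signals <- as.matrix(signals)
  assert_scalar_num(tr_s, "tr_s", lower = 1e-9)
  n_units <- nrow(signals)
  compartment <- compartment %||% rep("gray", n_units)
  if (length(compartment) != n_units) {
    stop("compartment labels (", length(compartment),
         ") do not match signal rows (", n_units, ")")
  }
  if (!all(compartment %in% c("gray", "white", "csf"))) {
    stop("compartment labels must be in {gray, white, csf}")
  }
  if (!is.null(network) && length(network) != n_units) {
    stop("network labels (", length(network),
         ") do not match signal rows (", n_units, ")")
  }
  if (!is.null(motion) && nrow(motion) != ncol(signals)) {
    stop("motion frames (", nrow(motion), ") do not match signal frames (",
         ncol(signals), ")")
  }
  structure(list(signals = signals, tr_s = tr_s,
                 compartment = compartment, network = network,
                 motion = motion),
            class = "scan_data")
}

#' @export
print.scan_data <- function(x, ...) {
  cat("<scan_data> ", nrow(x$signals), " units x ", ncol(x$signals),
      " frames, tr ", x$tr_s, " s\n", sep = "")
  invisible(x)
}

#' Global (gray-matter mean) fMRI signal
#'
#' @param scan A [scan_data()].
#' @return List with `series` (mean over gray units per frame) and `z`
#'   (z-scored copy).
#' @export
global_signal <- function(scan) {
  gray <- scan$compartment == "gray"
  if (!any(gray)) stop("no gray-labeled units; global signal undefined")
  s <- colMeans(scan$signals[gray, , drop = FALSE])
  list(series = s, z = zscore_vec(s))
}

#' DVARS: framewise RMS of the backward temporal difference
#'
#' DVARS at frame t is the root-mean-square over units of
#' `x[t] - x[t-1]`; by convention DVARS is 0 at the first frame.
#'
#' @param scan A [scan_data()] (or bare matrix, units x frames).
#' @return List with `series` and `z` (z-scored over frames, for censoring).
#' @export
dvars <- function(scan) {
  m <- if (inherits(scan, "scan_data")) scan$signals else as.matrix(scan)
  if (ncol(m) < 2L) stop("DVARS needs at least 2 frames")
  d <- m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  series <- c(0, sqrt(colMeans(d^2)))
  list(series = series, z = zscore_vec(series))
}

#' Framewise displacement
#'
#' Sum of absolute framewise changes in the six rigid-body position
#' parameters, with rotations expressed as arc displacement at
#' `radius_mm` (50 mm). Variants:
#' \describe{
#'   \item{original}{backward difference to the preceding frame; FD[1] = 0.}
#'   \item{filtered}{each position trace is band-stop filtered over
#'     `stopband_hz` (0.2-0.5 Hz, the tidal-breathing band) with a
#'     zero-phase Butterworth filter before differencing.}
#'   \item{filtered_4tr}{as `filtered`, but differenced over four frames
#'     (effective interval 4 x tr; 2.88 s at tr = 0.72 s), for comparability
#'     with legacy slow-TR FD.}
#' }
#'
#' @param motion A [motion_params()] object (rotations in radians).
#' @param variant One of `"original"`, `"filtered"`, `"filtered_4tr"`.
#' @param radius_mm Head radius for the arc conversion (default 50).
#' @param stopband_hz Stopband edges in Hz (default `c(0.2, 0.5)`).
#' @param filter_order Butterworth order per pass (default 5; the zero-phase
#'   forward-backward application doubles the effective order).
#' @return Numeric FD series in mm, one value per frame (leading values 0).
#' @export
framewise_displacement <- function(motion, variant = c("original", "filtered",
                                                       "filtered_4tr"),
                                   radius_mm = 50, stopband_hz = c(0.2, 0.5),
                                   filter_order = 5L) {
  variant <- match.arg(variant)
  pos <- as.matrix(motion[, 1:6])
  pos[, 4:6] <- pos[, 4:6] * radius_mm # radians -> arc mm
  tr_s <- attr(motion, "tr_s")
  n <- nrow(pos)
  lag <- if (variant == "filtered_4tr") 4L else 1L
  if (n < lag + 1L) stop("need at least ", lag + 1L, " frames for variant ", variant)
  if (variant != "original") {
    fs <- 1 / tr_s
    wn <- stopband_hz / (fs / 2)
    if (any(wn >= 1)) {
      stop("stopband [", stopband_hz[1L], ", ", stopband_hz[2L],
           "] Hz exceeds the Nyquist rate ", signif(fs / 2, 4), " Hz")
    }
    bf <- signal::butter(filter_order, wn, type = "stop")
    pos <- apply(pos, 2L, function(p) signal::filtfilt(bf, p))
  }
  d <- abs(pos[-seq_len(lag), , drop = FALSE] -
             pos[seq_len(n - lag), , drop = FALSE])
  c(rep(0, lag), rowSums(d))
}

#' Average a physiological series onto the fMRI frame grid
#'
#' Frame j (0-based) covers the half-open interval `[j*tr, (j+1)*tr)`; the
#' frame value is the mean of the physio samples falling inside it.
#'
#' @param x Physiological series at `sample_hz`.
#' @param sample_hz Sampling rate in Hz.
#' @param tr_s Repetition time in seconds.
#' @param n_frames Number of frames.
#' @return Numeric vector of length `n_frames`.
#' @export
align_physio_to_frames <- function(x, sample_hz, tr_s, n_frames) {
  frame_average(as.numeric(x), sample_hz, tr_s, n_frames)
}

#' All derived fMRI metrics for one scan
#'
#' @param scan A [scan_data()] with motion parameters.
#' @return Tibble with one row per frame: `frame`, `time_s`, `global`,
#'   `global_z`, `dvars`, `dvars_z`, and FD variants where motion is
#'   available.
#' @export
scan_metrics <- function(scan) {
  gs <- global_signal(scan)
  dv <- dvars(scan)
  n <- ncol(scan$signals)
  out <- tibble::tibble(frame = seq_len(n) - 1L,
                        time_s = (seq_len(n) - 1L) * scan$tr_s,
                        global = gs$series, global_z = gs$z,
                        dvars = dv$series, dvars_z = dv$z)
  if (!is.null(scan$motion)) {
    out$fd_original <- framewise_displacement(scan$motion, "original")
    out$fd_filtered <- framewise_displacement(scan$motion, "filtered")
    out$fd_filtered_4tr <- framewise_displacement(scan$motion, "filtered_4tr")
  }
  out
}
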