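# Readers and writers for every on-disk format the pipeline touches.
# Physiology logs follow the Siemens PMU dialect used by HCP: plain text,
# whitespace-delimited integer columns at 400 Hz, default column order
# trigger / respiratory / pulse.

#' Construct a physiological recording
#'
#' @param resp Respiratory-belt trace (arbitrary units).
#' @param pulse Pulse-oximetry trace (arbitrary units).
#' @param trigger Optional scanner-trigger channel.
#' @param sample_hz Sampling rate in Hz (default 400).
#' @return A `physio_recording` object.
#' @export
physio_recording <- function(resp, pulse, trigger = NULL, sample_hz = 400) {
  assert_scalar_num(sample_hz, "sample_hz", lower = 1e-9)
  n <- length(resp)
  if (length(pulse) != n || (!is.null(trigger) && length(trigger) != n)) {
    stop("all physio channels must have equal length")
  }
  if (anyNA(resp) || anyNA(pulse) || (!is.null(trigger) && anyNA(trigger))) {
    stop("physio channels contain missing samples; gaps are an error")
  }
  structure(list(resp = as.numeric(resp), pulse = as.numeric(pulse),
                 trigger = if (is.null(trigger)) NULL else as.numeric(trigger),
                 sample_hz = sample_hz, n_samples = n),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat("<physio_recording> ", x$n_samples, " samples @ ", x$sample_hz,
      " Hz (", signif(x$n_samples / x$sample_hz, 6), " s)\n", sep = "")
  invisible(x)
}

#' Read an HCP-style physiology log
#'
#' @param path Path to a whitespace-delimited text log.
#' @param column_map Named integer vector mapping channels to columns;
#'   default HCP order `c(trigger = 1, resp = 2, pulse = 3)`. At least the
#'   `resp` and `pulse` entries must be present.
#' @param sample_hz Sampling rate in Hz (default 400).
#' @return A [physio_recording()].
#' @export
read_physio_log <- function(path, column_map = c(trigger = 1L, resp = 2L,
                                                 pulse = 3L),
                            sample_hz = 400) {
  if (!file.exists(path)) stop("physio log not found: ", path)
  if (!all(c("resp", "pulse") %in% names(column_map))) {
    stop("column_map must name at least the resp and pulse columns")
  }
  nf <- utils::count.fields(path)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != stats::median(nf))[1L]
    stop("ragged physio log: row ", bad, " has ", nf[bad],
         " fields (expected ", stats::median(nf), ")")
  }
  ncol <- nf[1L]
  if (ncol < max(column_map)) {
    stop("physio log has ", ncol, " columns but column_map needs ",
         max(column_map))
  }
  vals <- tryCatch(scan(path, what = numeric(), quiet = TRUE),
                   error = function(e) stop("non-numeric token in physio log ",
                                            path, ": ", conditionMessage(e),
                                            call. = FALSE))
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  physio_recording(
    resp = m[, column_map[["resp"]]],
    pulse = m[, column_map[["pulse"]]],
    trigger = if ("trigger" %in% names(column_map))
      m[, column_map[["trigger"]]] else NULL,
    sample_hz = sample_hz
  )
}

#' Write a physiology log in the HCP dialect
#'
#' Channels are rounded to integers (the PMU emits integer arbitrary
#' units) and written whitespace-delimited in trigger / resp / pulse order.
#'
#' @param rec A [physio_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_physio_log <- function(rec, path) {
  trig <- rec$trigger %||% rep(0, rec$n_samples)
  m <- cbind(round(trig), round(rec$resp), round(rec$pulse))
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct motion parameters
#'
#' Six rigid-body parameters per frame: three translations in mm and three
#' rotations stored in radians (converted from the declared unit).
#'
#' @param m Matrix or data frame with at least 6 columns; when 12 columns
#'   are present (parameters plus file-side derivatives) only the first 6
#'   are used and differences are recomputed internally.
#' @param tr_s Repetition time in seconds.
#' @param angle_unit Unit of the rotation columns as given: `"degrees"`
#'   (HCP convention, default) or `"radians"`.
#' @return A `motion_params` tibble (`trans_x/y/z` mm, `rot_x/y/z` rad)
#'   with attributes `tr_s` and `angle_unit` (always `"radians"` after
#'   construction).
#' @export
motion_params <- function(m, tr_s, angle_unit = c("degrees", "radians")) {
  angle_unit <- match.arg(angle_unit)
  m <- as.matrix(m)
  if (ncol(m) < 6L) {
    stop("motion file must have at least 6 columns, found ", ncol(m))
  }
  m <- m[, 1:6, drop = FALSE]
  if (angle_unit == "degrees") m[, 4:6] <- m[, 4:6] * pi / 180
  out <- tibble::as_tibble(as.data.frame(m),
                           .name_repair = ~ c("trans_x", "trans_y", "trans_z",
                                              "rot_x", "rot_y", "rot_z"))
  structure(out, tr_s = tr_s, angle_unit = "radians",
            class = c("motion_params", class(out)))
}

#' Read a motion-parameter file
#'
#' @param path Whitespace-delimited text file, one row per frame, >= 6
#'   columns (12-column HCP files carry derivatives in columns 7-12, which
#'   are ignored).
#' @param tr_s Repetition time in seconds.
#' @param angle_unit Declared unit of rotations in the file (default
#'   degrees, the HCP convention).
#' @return A [motion_params()] object.
#' @export
read_motion_params <- function(path, tr_s, angle_unit = "degrees") {
  if (!file.exists(path)) stop("motion file not found: ", path)
  m <- as.matrix(utils::read.table(path))
  motion_params(m, tr_s = tr_s, angle_unit = angle_unit)
}

#' Write motion parameters
#'
#' Rotations are written in the requested unit (degrees by default, the
#' HCP convention).
#'
#' @param motion A [motion_params()] object.
#' @param path Output path.
#' @param angle_unit Unit for the written rotation columns.
#' @return `path`, invisibly.
#' @export
write_motion_params <- function(motion, path,
                                angle_unit = c("degrees", "radians")) {
  angle_unit <- match.arg(angle_unit)
  m <- as.matrix(motion[, 1:6])
  if (angle_unit == "degrees") m[, 4:6] <- m[, 4:6] * 180 / pi
  utils::write.table(format(m, digits = 15, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Parcel-to-network assignment
#'
#' @param parcel_id Character or integer parcel identifiers (ordered; the
#'   order is recorded and stable).
#' @param network Network name per parcel.
#' @param sensorimotor Networks forming the sensorimotor set (visual,
#'   auditory, motor and somatosensory cortex carry the strongest
#'   respiratory loading).
#' @return A `network_assignment` tibble with attribute `sensorimotor`.
#' @export
network_assignment <- function(parcel_id, network,
                               sensorimotor = c("Visual", "Auditory",
                                                "SMhand", "SMmouth")) {
  if (length(parcel_id) != length(network)) {
    stop("parcel_id and network lengths differ")
  }
  if (anyDuplicated(parcel_id)) stop("duplicated parcel_id")
  out <- tibble::tibble(parcel_id = as.character(parcel_id),
                        network = as.character(network))
  structure(out, sensorimotor = sensorimotor,
            class = c("network_assignment", class(out)))
}

#' Read / write a parcel-network table (TSV: parcel_id, network)
#'
#' @param path TSV path.
#' @param sensorimotor Passed to [network_assignment()].
#' @return A [network_assignment()].
#' @export
read_network_assignment <- function(path, sensorimotor = c("Visual",
                                                           "Auditory",
                                                           "SMhand",
                                                           "SMmouth")) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  network_assignment(tb$parcel_id, tb$network, sensorimotor = sensorimotor)
}

#' @rdname read_network_assignment
#' @param networks A [network_assignment()] to write.
#' @export
write_network_assignment <- function(networks, path) {
  readr::write_tsv(tibble::as_tibble(networks), path)
  invisible(path)
}

#' Read a unit-by-frame signal matrix into a scan
#'
#' Accepts a TSV matrix (rows are units) or a 4-D NIfTI volume flattened
#' against a 3-D mask (requires the RNifti package).
#'
#' @param path Matrix TSV or NIfTI file.
#' @param tr_s Repetition time in seconds.
#' @param labels Optional per-unit labels: a [network_assignment()] (parcel
#'   mode) or a character vector of compartments (voxel mode).
#' @param mask For NIfTI input: logical/numeric 3-D array or NIfTI path;
#'   nonzero voxels are retained in array order.
#' @param motion Optional [motion_params()].
#' @return A [scan_data()].
#' @export
read_matrix_scan <- function(path, tr_s, labels = NULL, mask = NULL,
                             motion = NULL) {
  is_nifti <- grepl("\\.nii(\\.gz)?$", path)
  if (is_nifti) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package")
    }
    vol <- as.array(RNifti::readNifti(path))
    if (length(dim(vol)) != 4L) stop("expected a 4-D NIfTI volume")
    if (is.null(mask)) stop("NIfTI input requires a mask")
    if (is.character(mask)) mask <- RNifti::readNifti(mask)
    keep <- which(as.array(mask) != 0)
    m <- matrix(vol, prod(dim(vol)[1:3]), dim(vol)[4L])[keep, , drop = FALSE]
  } else {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
  }
  network <- NULL
  compartment <- NULL
  if (inherits(labels, "network_assignment")) {
    if (nrow(labels) != nrow(m)) {
      stop("label table has ", nrow(labels), " rows but matrix has ",
           nrow(m), " units")
    }
    network <- labels$network
  } else if (!is.null(labels)) {
    if (length(labels) != nrow(m)) {
      stop("labels have length ", length(labels), " but matrix has ",
           nrow(m), " units")
    }
    compartment <- labels
  }
  scan_data(m, tr_s = tr_s, compartment = compartment, network = network,
            motion = motion)
}

#' Write a scan's signal matrix as TSV
#'
#' @param scan A [scan_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_scan <- function(scan, path) {
  utils::write.table(format(scan$signals, digits = 10, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(path)
}

#' Read / write an event-onset table (TSV: subject, scan, kind, onset_s)
#'
#' @param path TSV path.
#' @return Tibble of events.
#' @export
read_events <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_events
#' @param events Events tibble to write.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(events, path)
  invisible(path)
}
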