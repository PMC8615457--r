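#' Read marker trajectories from a TRC motion-capture file
#'
#' Minimal reader for the standard tab-separated TRC layout: a five-line
#' header (file type, field names, field values including `DataRate` and
#' `NumMarkers`, marker names, per-marker X/Y/Z labels) followed by
#' frame/time/coordinate rows.  Coordinates are returned in the file's
#' units (convert to metres before building segments if the header says
#' mm).
#'
#' @param file Path to the TRC file.
#' @return List with `fs` (Hz), `units` (string) and `markers`, a named
#'   list of n-by-3 coordinate matrices.
#' @export
read_trc <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 6L) stop_wbam("wbam_domain_error", "not a TRC file: too short")
  fields <- strsplit(lines[2L], "\t")[[1L]]
  values <- strsplit(lines[3L], "\t")[[1L]]
  hdr <- setNames(as.list(values), fields)
  fs <- as.numeric(hdr[["DataRate"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  units <- if (!is.null(hdr[["Units"]])) hdr[["Units"]] else "m"
  names_row <- strsplit(lines[4L], "\t")[[1L]]
  marker_names <- names_row[seq(3L, by = 3L, length.out = n_markers)]
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  mat <- do.call(rbind, lapply(strsplit(data_lines, "\t"), function(p) {
    as.numeric(p[seq_len(2L + 3L * n_markers)])
  }))
  markers <- lapply(seq_len(n_markers), function(k) {
    mat[, 2L + (3L * (k - 1L) + 1L):(3L * k), drop = FALSE]
  })
  names(markers) <- marker_names
  list(fs = fs, units = units, markers = markers)
}

#' Build segment kinematics from marker endpoints
#'
#' Converts marker trajectories into segment CoM trajectories by the
#' proximal/distal endpoint convention: the CoM of each segment lies at
#' `com_ratio` of the way from its proximal to its distal marker, with
#' the ratio taken from the inertial parameter table.  Angular velocity
#' is not recoverable from two points and is set to zero (the local spin
#' term then vanishes; for walking this term is small relative to the
#' transfer term).
#'
#' @param markers Named list of n-by-3 marker matrices in m (e.g. from
#'   [read_trc()]).
#' @param endpoints Data frame with columns `segment`, `proximal`,
#'   `distal` naming one marker pair per model segment.
#' @param bsip Relative inertial table (for `com_ratio`).
#' @param fs Sampling rate in Hz.
#' @return Named list of [segment_kinematics()].
#' @export
segments_from_markers <- function(markers, endpoints, bsip = default_bsip(),
                                  fs = 120) {
  validate_bsip(bsip)
  missing <- setdiff(segment_names(), endpoints$segment)
  if (length(missing)) {
    stop_wbam("wbam_model_incomplete", "endpoint table is missing segments: %s",
              paste(missing, collapse = ", "))
  }
  ratio <- setNames(bsip$com_ratio, bsip$segment)
  segs <- lapply(segment_names(), function(s) {
    row <- endpoints[endpoints$segment == s, , drop = FALSE][1L, ]
    for (mk in c(row$proximal, row$distal)) {
      if (is.null(markers[[mk]])) {
        stop_wbam("wbam_model_incomplete", "marker '%s' for segment '%s' not found",
                  mk, s)
      }
    }
    prox <- markers[[row$proximal]]
    dist <- markers[[row$distal]]
    segment_kinematics(pos = prox + ratio[[s]] * (dist - prox), fs = fs)
  })
  names(segs) <- segment_names()
  segs
}
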