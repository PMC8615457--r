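#' Segment kinematics container
#'
#' Holds the centre-of-mass trajectory of one body segment in the lab
#' frame, together with its CoM velocity and angular velocity.  The lab
#' frame is right-handed with X anterior (walking direction), Y to the
#' subject's left and Z up; the frontal-plane component of an angular
#' momentum vector is therefore its X component.
#'
#' @param pos n-by-3 matrix of CoM positions in m.
#' @param vel Optional n-by-3 matrix of CoM velocities in m/s; derived by
#'   central finite differences of `pos` at `fs` when omitted.
#' @param omega Optional n-by-3 matrix of segment angular velocities in
#'   rad/s; zero when omitted (no local spin term).
#' @param fs Sampling rate in Hz.
#' @return An object of class `segment_kinematics`.
#' @export
segment_kinematics <- function(pos, vel = NULL, omega = NULL, fs = 120) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3L) stop_wbam("wbam_domain_error", "pos must have 3 columns")
  n <- nrow(pos)
  if (n < 2L) stop_wbam("wbam_length_error", "need at least 2 samples per segment")
  if (is.null(vel)) vel <- finite_diff(pos, fs) else vel <- as.matrix(vel)
  if (is.null(omega)) omega <- matrix(0, n, 3L) else omega <- as.matrix(omega)
  if (nrow(vel) != n || nrow(omega) != n || ncol(vel) != 3L || ncol(omega) != 3L) {
    stop_wbam("wbam_alignment_error",
              "pos, vel and omega must all be n-by-3 with the same n")
  }
  structure(list(pos = pos, vel = vel, omega = omega, fs = fs),
            class = "segment_kinematics")
}

#' Assemble a gait trial
#'
#' Bundles the 12 segment trajectories with subject anthropometry,
#' optional vertical ground-reaction force, and the paretic side, which
#' fixes the sign convention (positive frontal WBAM points toward the
#' non-paretic side).
#'
#' @param segments Named list of [segment_kinematics()] objects covering
#'   all labels in [segment_names()].
#' @param subject_mass Body mass in kg.
#' @param subject_height Stature in m.
#' @param walking_speed Mean walking speed in m/s (used for
#'   normalization).
#' @param paretic_side `"left"` or `"right"`.
#' @param grf Optional list with elements `fz` (vertical force, N) and
#'   `fs` (sampling rate, Hz) for gait-event detection.
#' @param fs Kinematic sampling rate in Hz.
#' @param inertial Subject-scaled inertial table; defaults to
#'   [segment_inertial_table()] with the packaged anthropometrics.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(segments, subject_mass, subject_height, walking_speed,
                       paretic_side = c("left", "right"), grf = NULL, fs = 120,
                       inertial = segment_inertial_table(subject_mass, subject_height)) {
  paretic_side <- match.arg(paretic_side)
  missing <- setdiff(segment_names(), names(segments))
  if (length(missing)) {
    stop_wbam("wbam_model_incomplete", "missing segments: %s",
              paste(missing, collapse = ", "))
  }
  if (!is.numeric(walking_speed) || walking_speed <= 0) {
    stop_wbam("wbam_domain_error", "walking_speed must be positive")
  }
  if (subject_mass <= 0 || subject_height <= 0) {
    stop_wbam("wbam_domain_error", "subject mass and height must be positive")
  }
  ns <- vapply(segments[segment_names()], function(s) nrow(s$pos), integer(1))
  if (length(unique(ns)) != 1L) {
    stop_wbam("wbam_alignment_error", "all segments must have the same length")
  }
  if (!is.null(grf) && (is.null(grf$fz) || is.null(grf$fs))) {
    stop_wbam("wbam_domain_error", "grf must be a list with elements fz and fs")
  }
  structure(list(
    segments = segments[segment_names()], grf = grf,
    paretic_side = paretic_side, subject_mass = subject_mass,
    subject_height = subject_height, walking_speed = walking_speed,
    fs = fs, inertial = inertial
  ), class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  n <- nrow(x$segments[[1L]]$pos)
  cat(sprintf(
    "<gait_trial> 12 segments, %d samples @ %g Hz (%.2f s), paretic side: %s\n",
    n, x$fs, n / x$fs, x$paretic_side))
  cat(sprintf("  subject: %.1f kg, %.2f m, walking speed %.2f m/s; GRF: %s\n",
              x$subject_mass, x$subject_height, x$walking_speed,
              if (is.null(x$grf)) "absent" else sprintf("%g Hz", x$grf$fs)))
  invisible(x)
}

#' Apply the standard smoothing to a gait trial
#'
#' Low-pass filters every kinematic series (bidirectional fourth-order
#' Butterworth, default cut-off 6 Hz) and, when present, the vertical
#' ground-reaction force (default cut-off 80 Hz), the usual pre-processing
#' for motion-capture and force-plate data.
#'
#' @param trial A [gait_trial()].
#' @param fc_kin Kinematic cut-off frequency in Hz.
#' @param fc_grf Force cut-off frequency in Hz.
#' @return The trial with all series filtered.
#' @export
filter_trial <- function(trial, fc_kin = 6, fc_grf = 80) {
  stopifnot(inherits(trial, "gait_trial"))
  filt_mat <- function(m, fs, fc) apply(m, 2L, butterworth_lowpass, fs = fs, fc = fc)
  trial$segments <- lapply(trial$segments, function(s) {
    s$pos <- filt_mat(s$pos, s$fs, fc_kin)
    s$vel <- filt_mat(s$vel, s$fs, fc_kin)
    s$omega <- filt_mat(s$omega, s$fs, fc_kin)
    s
  })
  if (!is.null(trial$grf)) {
    trial$grf$fz <- butterworth_lowpass(trial$grf$fz, trial$grf$fs, fc_grf)
  }
  trial
}

#' Read segment-level kinematics from a long-format CSV
#'
#' Expects columns `time_s`, `segment`, `px`, `py`, `pz` and optionally
#' `wx`, `wy`, `wz` (segment angular velocity in rad/s).  Positions are in
#' metres in the lab frame (X anterior, Y left, Z up).  The sampling rate
#' is taken from a `# sample_rate: <Hz>` header comment when present, and
#' assumed to be 120 Hz otherwise.
#'
#' @param file Path to the CSV file.
#' @return Named list of [segment_kinematics()] plus an `fs` attribute.
#' @export
read_segment_kinematics <- function(file) {
  fs <- scan_rate_comment(file, default = 120)
  d <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("time_s", "segment", "px", "py", "pz")
  if (!all(need %in% names(d))) {
    stop_wbam("wbam_domain_error", "kinematics CSV must have columns %s",
              paste(need, collapse = ", "))
  }
  has_omega <- all(c("wx", "wy", "wz") %in% names(d))
  segs <- lapply(split(d, d$segment), function(g) {
    g <- g[order(g$time_s), ]
    segment_kinematics(
      pos = as.matrix(g[, c("px", "py", "pz")]),
      omega = if (has_omega) as.matrix(g[, c("wx", "wy", "wz")]) else NULL,
      fs = fs
    )
  })
  attr(segs, "fs") <- fs
  segs
}

#' Read a vertical ground-reaction-force CSV
#'
#' Expects columns `time_s` and `fz` (N); sampling rate from a
#' `# sample_rate: <Hz>` header comment, default 1200 Hz.
#'
#' @param file Path to the CSV file.
#' @return List with elements `fz` and `fs`, suitable for the `grf`
#'   argument of [gait_trial()].
#' @export
read_grf <- function(file) {
  fs <- scan_rate_comment(file, default = 1200)
  d <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("time_s", "fz") %in% names(d))) {
    stop_wbam("wbam_domain_error", "GRF CSV must have columns time_s, fz")
  }
  list(fz = d$fz[order(d$time_s)], fs = fs)
}

scan_rate_comment <- function(file, default) {
  head_lines <- readLines(file, n = 10L)
  m <- grep("^#\\s*sample_rate\\s*:", head_lines, value = TRUE)
  if (length(m)) as.numeric(sub("^#\\s*sample_rate\\s*:\\s*", "", m[1L])) else default
}
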