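#' Angular momentum of one segment about the body centre of mass
#'
#' Computes, per sample, the transfer term
#' `(r_i - r_CM) x m_i (v_i - v_CM)` plus the local spin term `I_i w_i`.
#' The moment of inertia may be a scalar (treated as isotropic) or a
#' length-3 vector of lab-frame diagonal components.
#'
#' @param seg A [segment_kinematics()] object.
#' @param mass Segment mass in kg.
#' @param inertia Segment moment of inertia in kg m^2 (scalar or length 3).
#' @param body_pos n-by-3 matrix, body CoM position in m.
#' @param body_vel n-by-3 matrix, body CoM velocity in m/s.
#' @return n-by-3 matrix of angular momentum in kg m^2/s.
#' @export
segment_angular_momentum <- function(seg, mass, inertia, body_pos, body_vel) {
  n <- nrow(seg$pos)
  if (nrow(body_pos) != n || nrow(body_vel) != n) {
    stop_wbam("wbam_alignment_error",
              "body CoM series must match the segment series length")
  }
  if (mass <= 0) stop_wbam("wbam_domain_error", "segment mass must be positive")
  if (length(inertia) == 1L) inertia <- rep(inertia, 3L)
  transfer <- mass * cross3(seg$pos - body_pos, seg$vel - body_vel)
  local <- sweep(seg$omega, 2L, inertia, `*`)
  transfer + local
}

#' Body centre-of-mass trajectory of a gait trial
#'
#' Mass-weighted mean of the segment CoM positions and velocities.
#'
#' @param trial A [gait_trial()].
#' @return List with n-by-3 matrices `pos` and `vel`.
#' @export
body_com <- function(trial) {
  masses <- setNames(trial$inertial$mass, trial$inertial$segment)
  total <- sum(masses[segment_names()])
  n <- nrow(trial$segments[[1L]]$pos)
  pos <- matrix(0, n, 3L)
  vel <- matrix(0, n, 3L)
  for (s in segment_names()) {
    pos <- pos + masses[[s]] * trial$segments[[s]]$pos
    vel <- vel + masses[[s]] * trial$segments[[s]]$vel
  }
  list(pos = pos / total, vel = vel / total)
}

#' Frontal whole-body angular momentum of a gait trial
#'
#' Sums the 12 segment angular momenta about the body centre of mass and
#' returns the frontal-plane component (about the anterior-posterior lab
#' axis, X).  The sign is mirrored for right-paretic subjects so that
#' positive values always indicate angular momentum toward the
#' non-paretic side.
#'
#' @param trial A [gait_trial()].
#' @return Numeric vector, raw frontal WBAM in kg m^2/s at the kinematic
#'   sampling rate.
#' @export
whole_body_angular_momentum <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  com <- body_com(trial)
  masses <- setNames(trial$inertial$mass, trial$inertial$segment)
  inertias <- setNames(trial$inertial$inertia, trial$inertial$segment)
  total <- matrix(0, nrow(com$pos), 3L)
  for (s in segment_names()) {
    total <- total + segment_angular_momentum(
      trial$segments[[s]], masses[[s]], inertias[[s]], com$pos, com$vel)
  }
  lx <- total[, 1L]
  if (trial$paretic_side == "right") lx <- -lx
  lx
}

#' Time-normalize one gait cycle to a 101-point grid
#'
#' Linearly interpolates the samples between two successive paretic foot
#' contacts onto 0, 1, ..., 100 percent of the gait cycle.  Endpoint
#' values are preserved exactly.
#'
#' @param series Numeric vector sampled at the kinematic rate.
#' @param cycle_start,cycle_end Sample indices delimiting the cycle
#'   (`cycle_end > cycle_start + 1`).
#' @return A [wbam_series()] of length 101.
#' @export
time_normalize_cycle <- function(series, cycle_start, cycle_end) {
  if (cycle_end <= cycle_start + 1) {
    stop_wbam("wbam_length_error", "degenerate cycle: end must exceed start + 1")
  }
  if (cycle_end > length(series) || cycle_start < 1) {
    stop_wbam("wbam_length_error", "cycle indices outside the series")
  }
  xout <- seq(cycle_start, cycle_end, length.out = 101L)
  wbam_series(approx(seq_along(series), series, xout = xout)$y)
}

#' Cycle-normalized WBAM series
#'
#' A length-101 frontal WBAM series over 0-100 percent of one gait cycle.
#' Positive values point toward the non-paretic side.
#'
#' @param values Numeric vector of length 101, all finite.
#' @param normalized Logical: `TRUE` once divided by mass x height x speed
#'   (dimensionless), `FALSE` while still in kg m^2/s.
#' @return Object of class `wbam_series`.
#' @export
wbam_series <- function(values, normalized = FALSE) {
  values <- as.numeric(values)
  if (length(values) != 101L) {
    stop_wbam("wbam_length_error", "a cycle-normalized WBAM series has 101 samples, got %d",
              length(values))
  }
  if (!all(is.finite(values))) {
    stop_wbam("wbam_domain_error", "WBAM series contains non-finite values")
  }
  structure(values, class = "wbam_series", normalized = normalized,
            sign_convention = "positive = toward non-paretic side")
}

#' @export
print.wbam_series <- function(x, ...) {
  cat(sprintf("<wbam_series> 101 samples over the gait cycle (%s), range %.4g\n",
              if (isTRUE(attr(x, "normalized"))) "dimensionless" else "kg m^2/s",
              max(x) - min(x)))
  invisible(x)
}

#' Dimensionless normalization of a WBAM series
#'
#' Divides every sample by body mass (kg) x height (m) x walking speed
#' (m/s), the standard scaling that removes the dependence of WBAM
#' magnitude on stature and speed.
#'
#' @param series Numeric vector or [wbam_series()].
#' @param mass Body mass in kg.
#' @param height Stature in m.
#' @param speed Walking speed in m/s.
#' @return Series of the same shape, dimensionless.
#' @export
normalize_wbam <- function(series, mass, height, speed) {
  if (!all(c(mass, height, speed) > 0)) {
    stop_wbam("wbam_domain_error", "mass, height and speed must all be positive")
  }
  out <- as.numeric(series) / (mass * height * speed)
  if (inherits(series, "wbam_series")) out <- wbam_series(out, normalized = TRUE)
  out
}

#' Range of the frontal WBAM over one gait cycle
#'
#' The difference between the maximum and the minimum of the series, the
#' balance outcome of the analysis.  Always non-negative and invariant
#' under adding a constant.
#'
#' @param series Numeric vector of length at least 2 (typically a
#'   [wbam_series()]).
#' @return Non-negative scalar.
#' @export
wbam_range <- function(series) {
  x <- as.numeric(series)
  if (length(x) < 2L) {
    stop_wbam("wbam_length_error", "need at least 2 samples to take a range")
  }
  max(x) - min(x)
}

#' Per-cycle normalized WBAM ranges of a trial
#'
#' End-to-end per-trial computation: optional smoothing, raw frontal WBAM,
#' paretic-contact detection, time normalization of each full cycle to 101
#' points, dimensionless normalization, and the per-cycle range.
#'
#' @param trial A [gait_trial()].
#' @param smooth Apply [filter_trial()] first (default `TRUE`).
#' @param threshold Vertical-force contact threshold in N.
#' @param fc_kin,fc_grf Filter cut-offs passed to [filter_trial()].
#' @return List with `ranges` (one dimensionless range per cycle),
#'   `cycles` (list of normalized [wbam_series()]), and `events`
#'   (contact sample indices).
#' @export
trial_wbam_ranges <- function(trial, smooth = TRUE, threshold = 20,
                              fc_kin = 6, fc_grf = 80) {
  if (smooth) trial <- filter_trial(trial, fc_kin = fc_kin, fc_grf = fc_grf)
  lx <- whole_body_angular_momentum(trial)
  events <- detect_paretic_contacts(trial, threshold = threshold)
  if (length(events) < 2L) {
    stop_wbam("wbam_no_cycle", "fewer than two paretic contacts: no full gait cycle")
  }
  cycles <- lapply(seq_len(length(events) - 1L), function(k) {
    raw <- time_normalize_cycle(lx, events[k], events[k + 1L])
    normalize_wbam(raw, trial$subject_mass, trial$subject_height,
                   trial$walking_speed)
  })
  list(ranges = vapply(cycles, wbam_range, numeric(1)),
       cycles = cycles, events = events)
}
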