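# Builders for small, fully controlled gait trials used across tests.

# Inertial table with hand-chosen masses/inertias (bypasses the packaged
# anthropometrics so closed-form oracles are exact).
make_inertial <- function(masses, inertias = rep(0, 12)) {
  data.frame(segment = segment_names(), mass = masses, length = 1,
             com_ratio = 0.5, inertia = inertias, stringsAsFactors = FALSE)
}

static_segment <- function(n, at = c(0, 0, 0), fs = 120) {
  segment_kinematics(pos = matrix(rep(at, each = n), n, 3),
                     vel = matrix(0, n, 3), fs = fs)
}

# Trial of 12 segments, all static at distinct spots unless overridden.
# Irrelevant segments get negligible mass so oracles only involve the
# overridden ones.
make_trial <- function(overrides = list(), masses = NULL, inertias = NULL,
                       n = 240, fs = 120, paretic_side = "left",
                       mass = 70, height = 1.7, speed = 1, grf = NULL) {
  base_at <- lapply(seq_len(12), function(k) c(0, 0.1 * k, 1))
  segs <- lapply(base_at, function(at) static_segment(n, at, fs))
  names(segs) <- segment_names()
  for (nm in names(overrides)) segs[[nm]] <- overrides[[nm]]
  if (is.null(masses)) {
    masses <- ifelse(segment_names() %in% names(overrides), 1, 1e-12)
  }
  if (is.null(inertias)) inertias <- rep(0, 12)
  gait_trial(segs, subject_mass = mass, subject_height = height,
             walking_speed = speed, paretic_side = paretic_side, grf = grf,
             fs = fs, inertial = make_inertial(masses, inertias))
}

# Segment whose CoM moves on a circle in the frontal (y-z) plane, with
# exact analytic velocities.
circle_segment <- function(n, radius, omega_rate, centre = c(0, 0, 0),
                           phase = 0, fs = 120) {
  t <- (seq_len(n) - 1) / fs
  a <- omega_rate * t + phase
  segment_kinematics(
    pos = cbind(centre[1], centre[2] + radius * cos(a), centre[3] + radius * sin(a)),
    vel = cbind(0, -radius * omega_rate * sin(a), radius * omega_rate * cos(a)),
    fs = fs)
}
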