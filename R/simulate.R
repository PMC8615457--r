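#' Stratified block randomization into AF and CT groups
#'
#' Assigns patients to the auditory-feedback (AF) and control (CT) arms
#' so that within every stratum (e.g. a paresis-level by sensory-level
#' block) the two group counts differ by at most one.  The assignment is
#' a pure function of the patient order, the strata and the seed.
#'
#' @param patients Character vector of patient ids.
#' @param strata Optional factor/vector of stratum labels, one per
#'   patient (single stratum when omitted).
#' @param seed Integer seed.
#' @return Data frame with columns `patient_id`, `stratum`, `group`.
#' @export
block_randomize <- function(patients, strata = NULL, seed = 1L) {
  if (!length(patients)) stop_wbam("wbam_domain_error", "empty patient list")
  if (is.null(strata)) strata <- rep("all", length(patients))
  if (length(strata) != length(patients)) {
    stop_wbam("wbam_domain_error", "strata must match patients in length")
  }
  rng <- local_rng(seed)
  out <- lapply(split(seq_along(patients), strata), function(idx) {
    perm <- idx[rng$sample_idx(length(idx))]
    grp <- rep(c("AF", "CT"), length.out = length(perm))
    data.frame(patient_id = patients[perm], stratum = strata[perm][1L],
               group = grp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[match(patients, out$patient_id), ]
  rownames(out) <- NULL
  out
}

#' Isolated RNG stream (does not disturb the global .Random.seed)
#' @noRd
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  })
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    runif = with_state(runif),
    rnorm = with_state(rnorm),
    rlnorm = with_state(rlnorm),
    sample_idx = with_state(function(n) sample.int(n))
  )
}

#' Configuration of a synthetic pre/post cohort
#'
#' Describes the generative law of a trial-level WBAM-range dataset:
#' per-patient pre-rehabilitation "bias" (a log-normal baseline range),
#' trial-level multiplicative noise on the pre value, patient-level
#' treadmill and auditory-feedback effects drawn around population
#' truths, and additive observation noise on the post value.  Defaults
#' mirror the study layout: 8 AF + 8 CT patients, 5 paired trials each,
#' population effects `beta_ct = 1.046` and `beta_af = -0.209`, no
#' patient-level effect variation, and pre biases spanning roughly
#' 0.01-0.1 dimensionless units.
#'
#' @param n_af,n_ct Patients per group.
#' @param trials_per_patient Paired trials per patient.
#' @param true_beta_ct,true_beta_af Population effect truths.
#' @param sigma_ct,sigma_af Patient-level effect scales (0 = none).
#' @param sigma_obs Observation noise S.D. on the post value.
#' @param pre_meanlog,pre_sdlog Log-normal parameters of the per-patient
#'   pre bias.
#' @param trial_noise Multiplicative S.D. of trial-level pre variation.
#' @param seed Integer seed.
#' @param strata Optional per-patient stratum labels for
#'   [block_randomize()]; when supplied, group sizes come from the
#'   randomization of `n_af + n_ct` patients instead of fixed counts.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_af = 8L, n_ct = 8L, trials_per_patient = 5L,
                          true_beta_ct = 1.046, true_beta_af = -0.209,
                          sigma_ct = 0, sigma_af = 0, sigma_obs = 0.005,
                          pre_meanlog = log(0.03), pre_sdlog = 0.5,
                          trial_noise = 0.05, seed = 1L, strata = NULL) {
  if (n_af < 1L || n_ct < 1L) stop_wbam("wbam_domain_error", "need >= 1 patient per group")
  if (trials_per_patient < 1L) stop_wbam("wbam_domain_error", "need >= 1 trial")
  if (sigma_obs <= 0) stop_wbam("wbam_domain_error", "sigma_obs must be positive")
  if (sigma_ct < 0 || sigma_af < 0) {
    stop_wbam("wbam_domain_error", "effect scales must be non-negative")
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic pre/post WBAM-range cohort
#'
#' Draws a trial-level dataset from the hierarchical generative law of
#' the effect models: per patient j a pre bias `b_j` (log-normal) and
#' effects `beta_ct_j ~ Normal(true_beta_ct, sigma_ct)` and, for AF
#' patients, `beta_af_j ~ Normal(true_beta_af, sigma_af)`; per trial i a
#' pre value `b_j (1 + trial_noise * z)` and a post value
#' `(beta_ct_j + g beta_af_j) pre + Normal(0, sigma_obs)`.  Negative
#' post values (possible only in the extreme noise tail) are redrawn so
#' the dataset satisfies the non-negativity invariant of WBAM ranges.
#' The generator is a pure function of the configuration (including its
#' seed); the underlying truths are attached as a "truth ledger".
#'
#' @param config A [cohort_config()].
#' @return A [range_dataset()] with attribute `truth` (list of the
#'   population truths, per-patient biases and effects, and the seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rng <- local_rng(config$seed)
  if (is.null(config$strata)) {
    ids <- c(sprintf("AF%02d", seq_len(config$n_af)),
             sprintf("CT%02d", seq_len(config$n_ct)))
    groups <- c(rep("AF", config$n_af), rep("CT", config$n_ct))
  } else {
    ids <- sprintf("PS%02d", seq_len(config$n_af + config$n_ct))
    assign <- block_randomize(ids, config$strata, seed = config$seed)
    groups <- assign$group[match(ids, assign$patient_id)]
  }
  n_pat <- length(ids)
  bias <- rng$rlnorm(n_pat, config$pre_meanlog, config$pre_sdlog)
  bct <- rng$rnorm(n_pat, config$true_beta_ct, config$sigma_ct)
  baf <- ifelse(groups == "AF",
                rng$rnorm(n_pat, config$true_beta_af, config$sigma_af), 0)
  obs <- list()
  for (j in seq_len(n_pat)) {
    for (i in seq_len(config$trials_per_patient)) {
      pre <- bias[j] * (1 + config$trial_noise * rng$rnorm(1))
      pre <- max(pre, 1e-6)
      post <- -1
      while (post < 0) {
        post <- (bct[j] + baf[j]) * pre + config$sigma_obs * rng$rnorm(1)
      }
      obs[[length(obs) + 1L]] <- data.frame(
        patient_id = ids[j], group = groups[j],
        phase = c("pre", "post"), trial = i,
        range_value = c(pre, post), stringsAsFactors = FALSE)
    }
  }
  out <- range_dataset(do.call(rbind, obs))
  attr(out, "truth") <- list(
    true_beta_ct = config$true_beta_ct, true_beta_af = config$true_beta_af,
    sigma_ct = config$sigma_ct, sigma_af = config$sigma_af,
    sigma_obs = config$sigma_obs, seed = config$seed,
    patients = data.frame(patient_id = ids, group = groups, pre_bias = bias,
                          beta_ct_j = bct, beta_af_j = baf,
                          stringsAsFactors = FALSE))
  out
}

#' Write a cohort and its truth ledger
#'
#' @param dataset A [generate_cohort()] result.
#' @param file CSV output path; the truth ledger is written next to it as
#'   `<file>.truth.json`.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(dataset, file) {
  write_range_csv(dataset, file)
  truth <- attr(dataset, "truth")
  truth_file <- paste0(file, ".truth.json")
  jsonlite::write_json(truth, truth_file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(data = file, truth = truth_file))
}

#' Configuration of a synthetic gait trial
#'
#' Each segment's CoM oscillates sinusoidally in the frontal plane around
#' a fixed offset: lateral position
#' `y_i(t) = cy_i + A_i sin(2 pi f t + phi_i)` and vertical position
#' `z_i(t) = cz_i + B_i cos(2 pi f t + psi_i)`, with a shared forward
#' drift at the walking speed.  Analytic velocities accompany the
#' sampled positions, so the trial's frontal WBAM has a closed form.
#' Paretic-side segments have their lateral amplitudes scaled by
#' `asymmetry_factor`, emulating the asymmetric momentum of hemiparetic
#' gait.  A square-pulse vertical GRF marks paretic foot contacts at the
#' start of every cycle.
#'
#' @param cycle_duration Gait cycle duration in s.
#' @param n_cycles Number of cycles in the trial.
#' @param sample_rate Kinematic sampling rate in Hz.
#' @param amplitude Base lateral amplitude in m: a scalar (per-segment
#'   amplitudes are jittered around it) or a length-12 vector of exact
#'   per-segment amplitudes in [segment_names()] order.
#' @param vert_amplitude Base vertical amplitude in m (scalar or
#'   length-12, as for `amplitude`).
#' @param asymmetry_factor Paretic-side lateral amplitude multiplier.
#' @param seed Integer seed (randomizes per-segment phase offsets).
#' @param subject_mass,subject_height,walking_speed Subject constants.
#' @param spin_inertia,spin_rate Optional constant-rate frontal spin of
#'   the trunk (rad/s) exercising the local `I w` term.
#' @return List of class `gait_config`.
#' @export
gait_config <- function(cycle_duration = 1.0, n_cycles = 4L, sample_rate = 120,
                        amplitude = 0.02, vert_amplitude = 0.01,
                        asymmetry_factor = 1.5, seed = 1L,
                        subject_mass = 68.7, subject_height = 1.69,
                        walking_speed = 1.0, spin_inertia = 0,
                        spin_rate = 0) {
  if (cycle_duration <= 0) stop_wbam("wbam_domain_error", "cycle_duration must be > 0")
  if (sample_rate < 2 / cycle_duration) {
    stop_wbam("wbam_domain_error",
              "sample_rate %g Hz violates the Nyquist limit for cycle frequency %g Hz",
              sample_rate, 1 / cycle_duration)
  }
  structure(as.list(environment()), class = "gait_config")
}

#' Generate a synthetic gait trial with closed-form WBAM
#'
#' Builds a [gait_trial()] from a [gait_config()]: sinusoidal frontal
#' CoM trajectories per segment with exact analytic velocities, zero
#' angular velocity except an optional trunk spin, a pulse-train GRF
#' marking cycle starts, and an attached function `analytic_wbam(t)`
#' evaluating the exact raw frontal WBAM at arbitrary times directly
#' from the analytic positions and velocities.
#'
#' @param config A [gait_config()].
#' @return A `gait_trial` with attributes `analytic_wbam` (function of
#'   time in s) and `times` (sample times).
#' @export
generate_synthetic_gait <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  rng <- local_rng(config$seed)
  segs <- segment_names()
  n_seg <- length(segs)
  f <- 1 / config$cycle_duration
  paretic <- grepl("^p_", segs)
  amp_y <- if (length(config$amplitude) == n_seg) config$amplitude else
    config$amplitude * (0.5 + rng$runif(n_seg))
  amp_z <- if (length(config$vert_amplitude) == n_seg) config$vert_amplitude else
    config$vert_amplitude * (0.5 + rng$runif(n_seg))
  phi <- 2 * pi * rng$runif(n_seg)
  psi <- 2 * pi * rng$runif(n_seg)
  # left/right limb pairs share a base amplitude and move laterally in
  # antiphase (alternating gait); vertical phases are kept common so the
  # two sides circulate oppositely and their frontal angular momenta
  # cancel when the gait is symmetric.  The paretic side is then scaled.
  for (k in which(paretic)) {
    twin <- match(sub("^p_", "n_", segs[k]), segs)
    amp_y[twin] <- amp_y[k]
    amp_z[twin] <- amp_z[k]
    phi[twin] <- phi[k] + pi
    psi[twin] <- psi[k]
  }
  amp_y[paretic] <- amp_y[paretic] * config$asymmetry_factor
  # static offsets: rough standing posture (x anterior, y left, z up)
  cy <- c(0, 0, -0.2, 0.2, -0.22, 0.22, -0.1, 0.1, -0.1, 0.1, -0.1, 0.1)
  cz <- c(1.2, 0.95, 1.25, 1.25, 1.0, 1.0, 0.7, 0.7, 0.3, 0.3, 0.05, 0.05) *
    config$subject_height / 1.7
  times <- seq(0, config$n_cycles * config$cycle_duration, by = 1 / config$sample_rate)
  inertial <- segment_inertial_table(config$subject_mass, config$subject_height)
  masses <- setNames(inertial$mass, inertial$segment)
  pos_fun <- function(t, k) {
    cbind(config$walking_speed * t,
          cy[k] + amp_y[k] * sin(2 * pi * f * t + phi[k]),
          cz[k] + amp_z[k] * cos(2 * pi * f * t + psi[k]))
  }
  vel_fun <- function(t, k) {
    cbind(rep(config$walking_speed, length(t)),
          amp_y[k] * 2 * pi * f * cos(2 * pi * f * t + phi[k]),
          -amp_z[k] * 2 * pi * f * sin(2 * pi * f * t + psi[k]))
  }
  seg_list <- lapply(seq_len(n_seg), function(k) {
    omega <- NULL
    if (segs[k] == "trunk" && config$spin_rate != 0) {
      omega <- cbind(rep(config$spin_rate, length(times)), 0, 0)
    }
    segment_kinematics(pos = pos_fun(times, k), vel = vel_fun(times, k),
                       omega = omega, fs = config$sample_rate)
  })
  names(seg_list) <- segs
  # trunk spin uses an isotropic inertia override so the analytic form is exact
  if (config$spin_rate != 0 && config$spin_inertia > 0) {
    inertial$inertia[inertial$segment == "trunk"] <- config$spin_inertia
  }
  grf_fs <- 1200
  grf_t <- seq(0, max(times), by = 1 / grf_fs)
  stance <- (grf_t %% config$cycle_duration) < 0.6 * config$cycle_duration
  fz <- ifelse(stance, 0.6 * config$subject_mass * 9.81, 0)
  fz[1L] <- 0  # ensure the first contact is a rising edge
  trial <- gait_trial(seg_list, subject_mass = config$subject_mass,
                      subject_height = config$subject_height,
                      walking_speed = config$walking_speed,
                      paretic_side = "left",
                      grf = list(fz = fz, fs = grf_fs),
                      fs = config$sample_rate, inertial = inertial)
  total_mass <- sum(masses[segs])
  analytic <- function(t) {
    t <- as.numeric(t)
    com_p <- matrix(0, length(t), 3L)
    com_v <- matrix(0, length(t), 3L)
    for (k in seq_len(n_seg)) {
      com_p <- com_p + masses[[segs[k]]] * pos_fun(t, k)
      com_v <- com_v + masses[[segs[k]]] * vel_fun(t, k)
    }
    com_p <- com_p / total_mass
    com_v <- com_v / total_mass
    lx <- numeric(length(t))
    for (k in seq_len(n_seg)) {
      rel_r <- pos_fun(t, k) - com_p
      rel_v <- vel_fun(t, k) - com_v
      lx <- lx + masses[[segs[k]]] *
        (rel_r[, 2L] * rel_v[, 3L] - rel_r[, 3L] * rel_v[, 2L])
    }
    if (config$spin_rate != 0) {
      i_trunk <- inertial$inertia[inertial$segment == "trunk"]
      lx <- lx + i_trunk * config$spin_rate
    }
    lx  # paretic side is "left": no sign mirroring
  }
  attr(trial, "analytic_wbam") <- analytic
  attr(trial, "times") <- times
  trial
}
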