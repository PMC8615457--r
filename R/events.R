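#' Rising-edge threshold crossings of a vertical force series
#'
#' Returns the sample indices at which `fz` rises to or above the
#' threshold, having been below it at the previous sample — the standard
#' force-plate definition of initial ground contact.
#'
#' @param fz Vertical force in N.
#' @param threshold Contact threshold in N (gait-lab default 20 N).
#' @return Strictly increasing integer sample indices.
#' @export
detect_contacts <- function(fz, threshold = 20) {
  fz <- as.numeric(fz)
  if (length(fz) < 2L) stop_wbam("wbam_length_error", "force series too short")
  above <- fz >= threshold
  which(above[-1L] & !above[-length(above)]) + 1L
}

#' Local minima of a series with a minimum separation
#' @noRd
local_minima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] < x[1:(n - 2L)] & x[2:(n - 1L)] <= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  keep <- cand[1L]
  for (i in cand[-1L]) {
    if (i - keep[length(keep)] >= min_sep) keep <- c(keep, i)
  }
  keep
}

#' Paretic foot-contact events of a gait trial
#'
#' Uses the vertical ground-reaction force when available (rising edge
#' through `threshold`, mapped from the force-plate to the kinematic
#' sampling rate); otherwise falls back on local minima of the paretic
#' foot CoM height.  Successive events delimit one gait cycle (0 and 100
#' percent at paretic foot contact).
#'
#' @param trial A [gait_trial()].
#' @param threshold Vertical-force contact threshold in N.
#' @param min_cycle_s Shortest plausible gait cycle in s, used to merge
#'   spurious kinematic minima.
#' @return Strictly increasing kinematic sample indices.
#' @export
detect_paretic_contacts <- function(trial, threshold = 20, min_cycle_s = 0.5) {
  stopifnot(inherits(trial, "gait_trial"))
  n_kin <- nrow(trial$segments[[1L]]$pos)
  if (!is.null(trial$grf)) {
    idx_grf <- detect_contacts(trial$grf$fz, threshold)
    if (!length(idx_grf)) {
      stop_wbam("wbam_no_cycle", "no contact found in the force signal")
    }
    idx <- round((idx_grf - 1L) * trial$fs / trial$grf$fs) + 1L
    idx <- unique(pmin(pmax(idx, 1L), n_kin))
  } else {
    z <- trial$segments$p_foot$pos[, 3L]
    idx <- local_minima(z, min_sep = as.integer(min_cycle_s * trial$fs))
    if (!length(idx)) {
      stop_wbam("wbam_no_cycle", "no contact found from paretic foot height")
    }
  }
  sort(idx)
}
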