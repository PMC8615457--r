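#' Canonical segment labels of the 12-segment walking model
#'
#' The body model comprises the trunk (thorax), pelvis, and the paretic
#' (`p_`) and non-paretic (`n_`) upper arms, forearms, thighs, shanks and
#' feet.  Head and hands are excluded.
#'
#' @return Character vector of the 12 segment labels.
#' @export
segment_names <- function() {
  c("trunk", "pelvis",
    "p_upperarm", "n_upperarm", "p_forearm", "n_forearm",
    "p_thigh", "n_thigh", "p_shank", "n_shank", "p_foot", "n_foot")
}

#' Default body-segment inertial parameter table
#'
#' Loads the packaged anthropometric table (approximate adult-male values
#' after the Dumas et al. 2007 compilation): per-segment mass fraction of
#' body mass, segment length as a fraction of stature, centre-of-mass
#' position ratio along the proximal-distal axis, and radius of gyration
#' about the frontal (anterior-posterior) axis as a fraction of segment
#' length.
#'
#' @return A data frame with columns `segment`, `mass_fraction`,
#'   `length_fraction`, `com_ratio`, `rgyr_frontal`.
#' @export
default_bsip <- function() {
  path <- system.file("extdata", "bsip_dumas2007.csv", package = "wbam")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Scale an inertial parameter table to a subject
#'
#' Converts the relative anthropometric table into absolute segment masses
#' (kg) and moments of inertia about the frontal axis (kg m^2) for a
#' subject of given mass and stature, with `I_i = m_i (k_i l_i)^2` from
#' the radius-of-gyration ratio `k_i` and segment length `l_i`.
#'
#' @param mass Subject body mass in kg.
#' @param height Subject stature in m.
#' @param bsip Relative parameter table as returned by [default_bsip()].
#' @return Data frame with columns `segment`, `mass` (kg), `length` (m),
#'   `com_ratio` and `inertia` (kg m^2), one row per model segment.
#' @export
segment_inertial_table <- function(mass, height, bsip = default_bsip()) {
  if (!is.numeric(mass) || mass <= 0 || !is.numeric(height) || height <= 0) {
    stop_wbam("wbam_domain_error", "mass and height must be positive")
  }
  validate_bsip(bsip)
  data.frame(
    segment = bsip$segment,
    mass = mass * bsip$mass_fraction,
    length = height * bsip$length_fraction,
    com_ratio = bsip$com_ratio,
    inertia = mass * bsip$mass_fraction *
      (bsip$rgyr_frontal * height * bsip$length_fraction)^2,
    stringsAsFactors = FALSE
  )
}

validate_bsip <- function(bsip) {
  need <- c("segment", "mass_fraction", "length_fraction", "com_ratio", "rgyr_frontal")
  if (!all(need %in% names(bsip))) {
    stop_wbam("wbam_model_incomplete", "inertial table must have columns %s",
              paste(need, collapse = ", "))
  }
  missing <- setdiff(segment_names(), bsip$segment)
  if (length(missing)) {
    stop_wbam("wbam_model_incomplete", "inertial table is missing segments: %s",
              paste(missing, collapse = ", "))
  }
  if (anyDuplicated(bsip$segment)) {
    stop_wbam("wbam_model_incomplete", "duplicated segment rows in inertial table")
  }
  if (any(bsip$mass_fraction <= 0)) {
    stop_wbam("wbam_domain_error", "segment mass fractions must be positive")
  }
  if (any(bsip$rgyr_frontal < 0)) {
    stop_wbam("wbam_domain_error", "radii of gyration must be non-negative")
  }
  invisible(bsip)
}
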