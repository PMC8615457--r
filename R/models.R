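#' Specification of one pre/post effect model
#'
#' The four candidate models share the observation law
#' `post ~ Normal(beta_effective * pre, sigma)` where `beta_effective`
#' combines a treadmill-training effect (`beta_ct`, both groups) and an
#' additional auditory-feedback effect (`beta_af`, AF group only), and
#' differ in whether each effect is a single population value or varies
#' by patient around population hyperparameters:
#'
#' * model 1 — neither effect varies by patient (non-hierarchical);
#' * model 2 — patient-level `beta_ct_j ~ Normal(mu_ct, sigma_ct)`;
#' * model 3 — patient-level `beta_af_j ~ Normal(mu_af, sigma_af)`;
#' * model 4 — both effects patient-level.
#'
#' Priors are non-informative uniforms: `Uniform(-5, 5)` for all
#' effect-type parameters and `Uniform(0, prior_sigma_factor * sd(post))`
#' for all scale-type parameters (scale-aware, weakly restrictive).
#'
#' @param model_id 1, 2, 3 or 4.
#' @param prior_beta Length-2 uniform prior bounds for effect parameters.
#' @param prior_sigma_factor Multiplier of `sd(post)` setting the upper
#'   uniform bound for scale parameters.
#' @return Object of class `wbam_model_spec`.
#' @export
model_spec <- function(model_id, prior_beta = c(-5, 5), prior_sigma_factor = 10) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:4) stop_wbam("wbam_domain_error", "model_id must be 1..4")
  structure(list(
    model_id = model_id,
    hierarchical_ct = model_id %in% c(2L, 4L),
    hierarchical_af = model_id %in% c(3L, 4L),
    prior_beta = prior_beta,
    prior_sigma_factor = prior_sigma_factor
  ), class = "wbam_model_spec")
}

#' @export
print.wbam_model_spec <- function(x, ...) {
  ind <- c("none", "beta_ct_j", "beta_af_j", "beta_ct_j, beta_af_j")[x$model_id]
  cat(sprintf("<wbam_model_spec> model %d (patient-level effects: %s)\n",
              x$model_id, ind))
  invisible(x)
}

#' Conditional log likelihood of paired observations
#'
#' Log of `Normal(post | beta_effective * pre, sigma)` given all
#' (possibly patient-level) effect parameters.  The auditory-feedback
#' effect enters only for AF-group pairs.
#'
#' @param spec A [model_spec()].
#' @param params Named list with `sigma` (> 0), `beta_ct` and `beta_af`.
#'   For hierarchical effects, supply a named vector (by `patient_id`) of
#'   patient-level values.
#' @param pairs A `paired_ranges` data frame (see [pair_trials()]).
#' @return Numeric vector of log densities, one per pair.
#' @export
conditional_loglik <- function(spec, params, pairs) {
  if (!is.numeric(params$sigma) || params$sigma <= 0) {
    stop_wbam("wbam_domain_error", "sigma must be positive")
  }
  bct <- expand_effect(params$beta_ct, pairs$patient_id, "beta_ct")
  baf <- expand_effect(params$beta_af, pairs$patient_id, "beta_af")
  g <- as.numeric(pairs$group == "AF")
  dnorm(pairs$post, (bct + g * baf) * pairs$pre, params$sigma, log = TRUE)
}

expand_effect <- function(value, patient_id, what) {
  if (length(value) == 1L) return(rep(as.numeric(value), length(patient_id)))
  if (is.null(names(value))) {
    stop_wbam("wbam_domain_error", "patient-level %s must be a named vector", what)
  }
  missing <- setdiff(unique(patient_id), names(value))
  if (length(missing)) {
    stop_wbam("wbam_domain_error", "%s missing for patients: %s", what,
              paste(missing, collapse = ", "))
  }
  as.numeric(value[patient_id])
}

#' Marginalized (new-patient) log likelihood
#'
#' Integrates the patient-level effects out of the conditional likelihood
#' against their population distributions, giving the predictive density
#' of an observation from a new, unseen patient.  Because both the
#' likelihood and the hierarchies are normal and enter linearly, the
#' integral is available in closed form: with `g = 1` for AF pairs and 0
#' otherwise,
#' `post ~ Normal((m_ct + g m_af) pre, sqrt((s_ct^2 + g s_af^2) pre^2 + sigma^2))`,
#' where `(m, s)` are the population mean and scale of each effect
#' (`s = 0` for non-hierarchical effects).  For model 1 this reduces to
#' [conditional_loglik()].
#'
#' @param spec A [model_spec()].
#' @param hyper Named list of top-level parameters: `sigma` plus, per
#'   effect, either `beta_ct` (non-hierarchical) or `mu_ct`/`sigma_ct`
#'   (hierarchical), and likewise `beta_af` or `mu_af`/`sigma_af`.
#' @param pairs A `paired_ranges` data frame.
#' @return Numeric vector of log predictive densities, one per pair.
#' @export
marginal_loglik <- function(spec, hyper, pairs) {
  if (!is.numeric(hyper$sigma) || hyper$sigma <= 0) {
    stop_wbam("wbam_domain_error", "sigma must be positive")
  }
  m_ct <- if (spec$hierarchical_ct) hyper$mu_ct else hyper$beta_ct
  m_af <- if (spec$hierarchical_af) hyper$mu_af else hyper$beta_af
  s_ct <- if (spec$hierarchical_ct) hyper$sigma_ct else 0
  s_af <- if (spec$hierarchical_af) hyper$sigma_af else 0
  if (any(c(s_ct, s_af) < 0)) {
    stop_wbam("wbam_domain_error", "hierarchy scales must be non-negative")
  }
  g <- as.numeric(pairs$group == "AF")
  mu <- (m_ct + g * m_af) * pairs$pre
  sd_marg <- sqrt((s_ct^2 + g * s_af^2) * pairs$pre^2 + hyper$sigma^2)
  dnorm(pairs$post, mu, sd_marg, log = TRUE)
}
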