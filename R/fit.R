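#' MCMC sampler configuration
#'
#' @param chains Number of chains (at least 2; 4 for reported fits).
#' @param iter Total iterations per chain, including warm-up.
#' @param warmup Warm-up (adaptation + burn-in) iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return List of class `wbam_mcmc_config`.
#' @export
mcmc_config <- function(chains = 4L, iter = 2000L, warmup = 1000L, seed = 1L) {
  if (iter <= warmup) stop_wbam("wbam_domain_error", "iter must exceed warmup")
  if (chains < 2L) stop_wbam("wbam_insufficient_chains", "need at least 2 chains")
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "wbam_mcmc_config")
}

jags_model_string <- function(spec) {
  bct_term <- if (spec$hierarchical_ct) "bct[pat[k]]" else "beta_ct"
  baf_term <- if (spec$hierarchical_af) "baf[paf[k]]" else "beta_af"
  lik <- sprintf(
    "  for (k in 1:N) {\n    post[k] ~ dnorm((%s + g[k] * %s) * pre[k], tau)\n  }\n",
    bct_term, baf_term)
  # non-centered hierarchies: bct_j = mu + sigma * eta_j avoids the
  # funnel geometry when the effect variation is near zero
  ct_prior <- if (spec$hierarchical_ct) {
    paste0("  for (j in 1:J) {\n",
           "    eta_ct[j] ~ dnorm(0, 1)\n",
           "    bct[j] <- mu_ct + sigma_ct * eta_ct[j]\n  }\n",
           "  mu_ct ~ dunif(blb, bub)\n",
           "  sigma_ct ~ dunif(0, sub)\n")
  } else {
    "  beta_ct ~ dunif(blb, bub)\n"
  }
  af_prior <- if (spec$hierarchical_af) {
    paste0("  for (j in 1:JAF) {\n",
           "    eta_af[j] ~ dnorm(0, 1)\n",
           "    baf[j] <- mu_af + sigma_af * eta_af[j]\n  }\n",
           "  mu_af ~ dunif(blb, bub)\n",
           "  sigma_af ~ dunif(0, sub)\n")
  } else {
    "  beta_af ~ dunif(blb, bub)\n"
  }
  paste0("model {\n", lik, ct_prior, af_prior,
         "  sigma ~ dunif(0, sub)\n  tau <- pow(sigma, -2)\n}\n")
}

monitored_params <- function(spec) {
  c(if (spec$hierarchical_ct) c("mu_ct", "sigma_ct", "bct") else "beta_ct",
    if (spec$hierarchical_af) c("mu_af", "sigma_af", "baf") else "beta_af",
    "sigma")
}

#' Fit one pre/post effect model by MCMC
#'
#' Samples the joint posterior of the chosen model (see [model_spec()])
#' under its uniform priors with JAGS (Gibbs/slice sampling; the model is
#' conjugate-friendly and mixes well).  Chains are seeded
#' deterministically from `mcmc$seed` with over-dispersed initial values.
#' Convergence is assessed per parameter with the split Gelman-Rubin
#' statistic ([compute_rhat()]); any value at or above 1.10 flags the fit
#' as non-converged (the fit is still returned, marked).  The matrix of
#' pointwise log predictive densities used for WAIC is filled with the
#' marginalized new-patient density ([marginal_loglik()]) evaluated at
#' every saved draw.
#'
#' @param spec A [model_spec()].
#' @param pairs A `paired_ranges` data frame from [pair_trials()].
#' @param mcmc A [mcmc_config()].
#' @return Object of class `wbam_fit` with elements `draws` (saved draws,
#'   chains stacked, named columns), `draws_array` (iterations x chains x
#'   parameters), `rhat`, `converged`, `pointwise_loglik` (draws x
#'   observations), `spec`, `pairs`, `mcmc`.
#' @export
fit_model <- function(spec, pairs, mcmc = mcmc_config()) {
  stopifnot(inherits(spec, "wbam_model_spec"), inherits(pairs, "paired_ranges"))
  if (!any(pairs$group == "AF")) {
    stop_wbam("wbam_identifiability_error",
              "beta_af is not identifiable without AF-group pairs")
  }
  patients <- unique(pairs$patient_id)
  af_patients <- unique(pairs$patient_id[pairs$group == "AF"])
  pat <- match(pairs$patient_id, patients)
  paf <- match(pairs$patient_id, af_patients)
  paf[is.na(paf)] <- 1L  # dummy index, multiplied by g = 0
  sub <- spec$prior_sigma_factor * sd(pairs$post)
  data <- list(N = nrow(pairs), pre = pairs$pre, post = pairs$post,
               g = as.numeric(pairs$group == "AF"),
               blb = spec$prior_beta[1L], bub = spec$prior_beta[2L], sub = sub)
  if (spec$hierarchical_ct) {
    data$J <- length(patients)
    data$pat <- pat
  }
  if (spec$hierarchical_af) {
    data$JAF <- length(af_patients)
    data$paf <- paf
  }
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    set.seed(mcmc$seed + 7919L * ch)
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = mcmc$seed + ch)
    ct0 <- runif(1, 0.7, 1.3)
    af0 <- runif(1, -0.5, 0.1)
    if (spec$hierarchical_ct) {
      ini$mu_ct <- ct0
      ini$sigma_ct <- runif(1, 0.02, 0.5) * sub / 10
    } else ini$beta_ct <- ct0
    if (spec$hierarchical_af) {
      ini$mu_af <- af0
      ini$sigma_af <- runif(1, 0.02, 0.5) * sub / 10
    } else ini$beta_af <- af0
    ini$sigma <- runif(1, 0.05, 0.9) * sub / 10
    ini
  })
  n_adapt <- min(500L, mcmc$warmup %/% 2L)
  jm <- rjags::jags.model(textConnection(jags_model_string(spec)), data = data,
                          inits = inits, n.chains = mcmc$chains, quiet = TRUE,
                          n.adapt = n_adapt)
  update(jm, mcmc$warmup - n_adapt, progress.bar = "none")
  samp <- rjags::coda.samples(jm, monitored_params(spec),
                              n.iter = mcmc$iter - mcmc$warmup,
                              progress.bar = "none")
  pnames <- colnames(samp[[1L]])
  n_iter <- nrow(samp[[1L]])
  arr <- array(NA_real_, c(n_iter, mcmc$chains, length(pnames)),
               dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(mcmc$chains)) arr[, ch, ] <- as.matrix(samp[[ch]])
  draws <- do.call(rbind, lapply(seq_len(mcmc$chains), function(ch) arr[, ch, ]))
  colnames(draws) <- pnames
  rhat <- apply(arr, 3L, compute_rhat)
  converged <- all(is.finite(rhat)) && all(rhat < 1.10)
  if (!converged) {
    warning(sprintf("model %d: split R-hat >= 1.10 for %s; fit flagged non-converged",
                    spec$model_id,
                    paste(names(rhat)[!is.finite(rhat) | rhat >= 1.10], collapse = ", ")),
            call. = FALSE)
  }
  fit <- structure(list(
    spec = spec, pairs = pairs, mcmc = mcmc, draws = draws, draws_array = arr,
    n_chains = mcmc$chains, rhat = rhat, converged = converged,
    patients = patients, af_patients = af_patients, sigma_upper = sub
  ), class = "wbam_fit")
  fit$pointwise_loglik <- pointwise_loglik(fit, type = "marginal")
  fit
}

#' @export
print.wbam_fit <- function(x, ...) {
  cat(sprintf("<wbam_fit> model %d: %d chains x %d saved draws, %d pairs\n",
              x$spec$model_id, x$n_chains, nrow(x$draws) / x$n_chains,
              nrow(x$pairs)))
  cat(sprintf("  max split R-hat %.4f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT converged"))
  eff <- effect_draws(x)
  cat(sprintf("  beta_ct %.4f, beta_af %.4f (posterior means)\n",
              mean(eff$ct), mean(eff$af)))
  invisible(x)
}

#' Population-level effect draws of a fit
#'
#' Returns the draws of the population treadmill effect (`beta_ct` or
#' `mu_ct`), the population auditory-feedback effect (`beta_af` or
#' `mu_af`) and the observation scale `sigma`.
#'
#' @param fit A `wbam_fit`.
#' @return List with numeric vectors `ct`, `af`, `sigma` (and `sigma_ct`,
#'   `sigma_af` when hierarchical).
#' @export
effect_draws <- function(fit) {
  d <- fit$draws
  list(
    ct = d[, if (fit$spec$hierarchical_ct) "mu_ct" else "beta_ct"],
    af = d[, if (fit$spec$hierarchical_af) "mu_af" else "beta_af"],
    sigma = d[, "sigma"],
    sigma_ct = if (fit$spec$hierarchical_ct) d[, "sigma_ct"],
    sigma_af = if (fit$spec$hierarchical_af) d[, "sigma_af"]
  )
}

draw_hyper <- function(fit, s) {
  d <- fit$draws
  spec <- fit$spec
  h <- list(sigma = d[s, "sigma"])
  if (spec$hierarchical_ct) {
    h$mu_ct <- d[s, "mu_ct"]; h$sigma_ct <- d[s, "sigma_ct"]
  } else h$beta_ct <- d[s, "beta_ct"]
  if (spec$hierarchical_af) {
    h$mu_af <- d[s, "mu_af"]; h$sigma_af <- d[s, "sigma_af"]
  } else h$beta_af <- d[s, "beta_af"]
  h
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Evaluates, for every saved draw and every paired observation, either
#' the marginalized new-patient predictive log density (default; the
#' basis of the model comparison) or the conditional log density given
#' the sampled patient-level effects.
#'
#' @param fit A `wbam_fit`.
#' @param type `"marginal"` (default) or `"conditional"`.
#' @return Matrix draws x observations.
#' @export
pointwise_loglik <- function(fit, type = c("marginal", "conditional")) {
  type <- match.arg(type)
  d <- fit$draws
  pairs <- fit$pairs
  spec <- fit$spec
  S <- nrow(d)
  g <- as.numeric(pairs$group == "AF")
  if (type == "marginal") {
    m_ct <- d[, if (spec$hierarchical_ct) "mu_ct" else "beta_ct"]
    m_af <- d[, if (spec$hierarchical_af) "mu_af" else "beta_af"]
    s_ct <- if (spec$hierarchical_ct) d[, "sigma_ct"] else rep(0, S)
    s_af <- if (spec$hierarchical_af) d[, "sigma_af"] else rep(0, S)
    sig <- d[, "sigma"]
    mu <- (outer(m_ct, rep(1, nrow(pairs))) + outer(m_af, g)) *
      outer(rep(1, S), pairs$pre)
    var_m <- (outer(s_ct^2, rep(1, nrow(pairs))) + outer(s_af^2, g)) *
      outer(rep(1, S), pairs$pre^2) + outer(sig^2, rep(1, nrow(pairs)))
    y <- outer(rep(1, S), pairs$post)
    -0.5 * log(2 * pi * var_m) - (y - mu)^2 / (2 * var_m)
  } else {
    pat <- match(pairs$patient_id, fit$patients)
    paf <- match(pairs$patient_id, fit$af_patients)
    bct <- if (spec$hierarchical_ct) {
      d[, paste0("bct[", pat, "]"), drop = FALSE]
    } else matrix(d[, "beta_ct"], S, nrow(pairs))
    baf <- matrix(0, S, nrow(pairs))
    if (spec$hierarchical_af) {
      af_cols <- paste0("baf[", paf[!is.na(paf)], "]")
      baf[, !is.na(paf)] <- d[, af_cols, drop = FALSE]
    } else baf[] <- d[, "beta_af"]
    mu <- sweep(bct + sweep(baf, 2L, g, `*`), 2L, pairs$pre, `*`)
    y <- outer(rep(1, S), pairs$post)
    dnorm(y, mu, d[, "sigma"], log = TRUE)
  }
}

#' Split Gelman-Rubin convergence statistic
#'
#' Potential scale reduction factor computed after splitting every chain
#' in half, so that within-chain trends are detected as well as
#' between-chain disagreement.  By convention the statistic is 1 when the
#' draws have zero total variance (a constant parameter).
#'
#' @param chains Matrix of draws, iterations x chains (at least 2 chains
#'   of equal length, at least 4 iterations).
#' @return Scalar R-hat.
#' @export
compute_rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) {
    stop_wbam("wbam_insufficient_chains", "R-hat needs at least 2 chains")
  }
  if (nrow(chains) < 4L) {
    stop_wbam("wbam_length_error", "R-hat needs chains of length >= 4")
  }
  half <- nrow(chains) %/% 2L
  split <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j) {
    cbind(chains[seq_len(half), j], chains[nrow(chains) - half + seq_len(half), j])
  }))
  if (all(split == split[1L])) return(1.0)
  n <- nrow(split)
  means <- colMeans(split)
  w <- mean(apply(split, 2L, var))
  b_over_n <- var(means)
  if (w == 0) return(Inf)
  sqrt(((n - 1) / n * w + b_over_n) / w)
}
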