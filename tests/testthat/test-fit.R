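test_that("split R-hat behaves on iid, separated and constant chains", {
  set.seed(12)
  iid <- matrix(rnorm(4000), 1000, 4)
  expect_equal(compute_rhat(iid), 1.0, tolerance = 0.05)

  sep <- cbind(rnorm(200, 0, 1), rnorm(200, 10, 1))
  expect_gt(compute_rhat(sep), 1.10)

  expect_equal(compute_rhat(matrix(2.5, 100, 4)), 1.0)
  expect_error(compute_rhat(matrix(rnorm(100), 100, 1)),
               class = "wbam_insufficient_chains")
})

test_that("split R-hat equals the brute-force split formula", {
  brute <- function(chains) {
    half <- nrow(chains) %/% 2
    seqs <- list()
    for (j in seq_len(ncol(chains))) {
      seqs <- c(seqs, list(chains[1:half, j]),
                list(chains[(nrow(chains) - half + 1):nrow(chains), j]))
    }
    n <- half
    m <- length(seqs)
    means <- vapply(seqs, mean, numeric(1))
    vars <- vapply(seqs, var, numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  set.seed(77)
  for (rep in 1:5) {
    ch <- matrix(rnorm(600, sd = runif(1, 0.5, 2)), 150, 4) +
      rep(rnorm(4, sd = 0.2), each = 150)
    expect_equal(compute_rhat(ch), brute(ch), tolerance = 1e-12)
  }
})

test_that("model 1 recovers known effects from a synthetic cohort", {
  ds <- generate_cohort(cohort_config(true_beta_ct = 1.05, true_beta_af = -0.21,
                                      sigma_obs = 0.005, seed = 21))
  fit <- fit_model(model_spec(1), pair_trials(ds), mcmc_config(seed = 21))
  expect_true(fit$converged)
  es <- effect_summary(fit)
  ct <- es[es$effect == "beta_ct", ]
  af <- es[es$effect == "beta_af", ]
  expect_lt(abs(ct$mean - 1.05), 0.05)
  expect_lt(abs(af$mean - (-0.21)), 0.05)
  expect_true(ct$lower <= 1.05 && 1.05 <= ct$upper)
  expect_true(af$lower <= -0.21 && -0.21 <= af$upper)
})

test_that("with near-zero noise the posterior pins the exact post/pre ratio", {
  ds <- generate_cohort(cohort_config(sigma_obs = 1e-6, trial_noise = 0,
                                      true_beta_ct = 1.046,
                                      true_beta_af = -0.209, seed = 8))
  pairs <- pair_trials(ds)
  ct_ratio <- mean(pairs$post[pairs$group == "CT"] / pairs$pre[pairs$group == "CT"])
  fit <- fit_model(model_spec(1), pairs, mcmc_config(seed = 8))
  expect_lt(abs(mean(fit$draws[, "beta_ct"]) - ct_ratio), 1e-3)
})

test_that("a CT-only dataset leaves the feedback effect unidentifiable", {
  ds <- generate_cohort(cohort_config(seed = 3))
  ds_ct <- range_dataset(as.data.frame(ds)[ds$group == "CT", ])
  expect_error(fit_model(model_spec(1), pair_trials(ds_ct)),
               class = "wbam_identifiability_error")
})

test_that("hierarchical fits expose hypermeans and converge on default data", {
  ds <- generate_cohort(cohort_config(sigma_ct = 0.05, seed = 14))
  fit <- fit_model(model_spec(2), pair_trials(ds), mcmc_config(seed = 14))
  expect_true(all(c("mu_ct", "sigma_ct", "beta_af", "sigma") %in%
                  colnames(fit$draws)))
  expect_true(fit$converged)
  expect_true(all(fit$draws[, "sigma"] > 0))
  expect_true(all(fit$draws[, "sigma_ct"] >= 0))
  # marginal pointwise log-likelihood agrees with direct evaluation on a draw
  s <- 17L
  ll_direct <- marginal_loglik(fit$spec, wbam:::draw_hyper(fit, s), fit$pairs)
  expect_equal(fit$pointwise_loglik[s, ], ll_direct, tolerance = 1e-10)
})

test_that("conditional pointwise log-likelihood uses the sampled patient effects", {
  ds <- generate_cohort(cohort_config(n_af = 3, n_ct = 3, sigma_af = 0.05,
                                      seed = 15))
  fit <- fit_model(model_spec(3), pair_trials(ds),
                   mcmc_config(chains = 2, iter = 600, warmup = 300, seed = 15))
  ll <- pointwise_loglik(fit, type = "conditional")
  s <- 5L
  pairs <- fit$pairs
  baf <- setNames(rep(0, length(fit$patients)), fit$patients)
  baf[fit$af_patients] <- fit$draws[s, paste0("baf[", seq_along(fit$af_patients), "]")]
  params <- list(beta_ct = fit$draws[s, "beta_ct"], beta_af = baf,
                 sigma = fit$draws[s, "sigma"])
  expect_equal(ll[s, ], conditional_loglik(fit$spec, params, pairs),
               tolerance = 1e-10)
})

test_that("sampling is reproducible under a fixed seed", {
  ds <- generate_cohort(cohort_config(n_af = 3, n_ct = 3, seed = 2))
  pairs <- pair_trials(ds)
  cfg <- mcmc_config(chains = 2, iter = 400, warmup = 200, seed = 9)
  f1 <- fit_model(model_spec(1), pairs, cfg)
  f2 <- fit_model(model_spec(1), pairs, cfg)
  expect_identical(f1$draws, f2$draws)
})
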