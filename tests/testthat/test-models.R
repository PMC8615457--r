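test_that("model ids map to their hierarchy flags", {
  flags <- t(vapply(1:4, function(m) {
    s <- model_spec(m)
    c(ct = s$hierarchical_ct, af = s$hierarchical_af)
  }, logical(2)))
  expect_equal(flags, cbind(ct = c(FALSE, TRUE, FALSE, TRUE),
                            af = c(FALSE, FALSE, TRUE, TRUE)))
  expect_error(model_spec(5), class = "wbam_domain_error")
})

test_that("conditional log likelihood equals the normal density formula", {
  spec <- model_spec(1)
  pairs <- make_pairs("A", "AF", pre = 0.05, post = 0.05 * 0.84)
  # exact mean, sigma = 1: density is 1/sqrt(2 pi)
  ll <- conditional_loglik(spec, list(beta_ct = 1.05, beta_af = -0.21, sigma = 1),
                           pairs)
  expect_equal(ll, log(1 / sqrt(2 * pi)))
  # arbitrary inputs match an independent evaluation of the formula
  set.seed(42)
  for (rep in 1:20) {
    p <- make_pairs("A", sample(c("AF", "CT"), 1), pre = runif(1, 0.01, 0.1),
                    post = runif(1, 0.005, 0.1))
    bct <- runif(1, 0.5, 1.5); baf <- runif(1, -0.5, 0.2); sg <- runif(1, 1e-3, 0.05)
    g <- as.numeric(p$group == "AF")
    mu <- (bct + g * baf) * p$pre
    expect_equal(
      conditional_loglik(model_spec(1), list(beta_ct = bct, beta_af = baf,
                                             sigma = sg), p),
      -0.5 * log(2 * pi * sg^2) - (p$post - mu)^2 / (2 * sg^2),
      tolerance = 1e-12)
  }
  expect_error(conditional_loglik(spec, list(beta_ct = 1, beta_af = 0,
                                             sigma = -1), pairs),
               class = "wbam_domain_error")
})

test_that("the auditory-feedback effect is gated off for control pairs", {
  pairs <- make_pairs("A", "CT", pre = 0.05, post = 0.052)
  l1 <- conditional_loglik(model_spec(1),
                           list(beta_ct = 1.0, beta_af = -0.2, sigma = 0.01), pairs)
  l2 <- conditional_loglik(model_spec(1),
                           list(beta_ct = 1.0, beta_af = 3.0, sigma = 0.01), pairs)
  expect_equal(l1, l2)
})

test_that("a zero hierarchy scale collapses the marginal onto the conditional", {
  pairs <- make_pairs(c("A", "B"), c("AF", "CT"), pre = c(0.05, 0.03),
                      post = c(0.042, 0.031))
  cond <- conditional_loglik(model_spec(1),
                             list(beta_ct = 1.02, beta_af = -0.2, sigma = 0.004),
                             pairs)
  marg <- marginal_loglik(model_spec(2),
                          list(mu_ct = 1.02, sigma_ct = 0, beta_af = -0.2,
                               sigma = 0.004), pairs)
  expect_equal(marg, cond, tolerance = 1e-12)
})

test_that("marginal densities match numeric quadrature of the conditional", {
  # integrate Normal(post | (b_ct + g b_af) pre, sigma) against the
  # population law(s) of the patient-level effects, by brute force
  quad_marginal <- function(model, hyper, pre, post, g) {
    if (model == 2) {
      integrate(function(b) {
        dnorm(post, (b + g * hyper$beta_af) * pre, hyper$sigma) *
          dnorm(b, hyper$mu_ct, hyper$sigma_ct)
      }, -Inf, Inf, rel.tol = 1e-10)$value
    } else if (model == 3) {
      if (g == 0) return(dnorm(post, hyper$beta_ct * pre, hyper$sigma))
      integrate(function(b) {
        dnorm(post, (hyper$beta_ct + b) * pre, hyper$sigma) *
          dnorm(b, hyper$mu_af, hyper$sigma_af)
      }, -Inf, Inf, rel.tol = 1e-10)$value
    } else {
      inner <- function(bct) {
        vapply(bct, function(bc) {
          if (g == 0) {
            dnorm(post, bc * pre, hyper$sigma)
          } else {
            integrate(function(ba) {
              dnorm(post, (bc + ba) * pre, hyper$sigma) *
                dnorm(ba, hyper$mu_af, hyper$sigma_af)
            }, -Inf, Inf, rel.tol = 1e-10)$value
          }
        }, numeric(1))
      }
      integrate(function(bct) inner(bct) * dnorm(bct, hyper$mu_ct, hyper$sigma_ct),
                -Inf, Inf, rel.tol = 1e-8)$value
    }
  }
  set.seed(7)
  for (k in 1:34) {
    model <- sample(2:4, 1)
    g <- sample(0:1, 1)
    pre <- runif(1, 0.01, 0.1)
    hyper <- list(mu_ct = runif(1, 0.8, 1.2), sigma_ct = runif(1, 0.01, 0.3),
                  beta_ct = runif(1, 0.8, 1.2),
                  mu_af = runif(1, -0.4, 0), sigma_af = runif(1, 0.01, 0.3),
                  beta_af = runif(1, -0.4, 0), sigma = runif(1, 0.002, 0.02))
    post <- (hyper$mu_ct + g * -0.2) * pre + rnorm(1, 0, 0.01)
    pairs <- make_pairs("A", if (g == 1) "AF" else "CT", pre, post)
    got <- exp(marginal_loglik(model_spec(model), hyper, pairs))
    want <- quad_marginal(model, hyper, pre, post, g)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the marginal density integrates to one over the post value", {
  pairs_at <- function(post) make_pairs("A", "AF", 0.05, post)
  hyper <- list(mu_ct = 1.0, sigma_ct = 0.2, mu_af = -0.2, sigma_af = 0.1,
                sigma = 0.01)
  total <- integrate(function(y) {
    vapply(y, function(yy) {
      exp(marginal_loglik(model_spec(4), hyper, pairs_at(yy)))
    }, numeric(1))
  }, -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
})

test_that("Monte-Carlo averaging of the conditional recovers the marginal", {
  set.seed(99)
  n_mc <- 1e5
  pairs <- make_pairs("A", "AF", 0.06, 0.048)
  hyper <- list(mu_ct = 1.05, sigma_ct = 0.15, beta_ct = 1.05,
                mu_af = -0.2, sigma_af = 0.1, beta_af = -0.2, sigma = 0.008)
  for (model in 2:4) {
    spec <- model_spec(model)
    bct <- if (spec$hierarchical_ct) rnorm(n_mc, hyper$mu_ct, hyper$sigma_ct)
           else rep(hyper$beta_ct, n_mc)
    baf <- if (spec$hierarchical_af) rnorm(n_mc, hyper$mu_af, hyper$sigma_af)
           else rep(hyper$beta_af, n_mc)
    dens <- dnorm(pairs$post, (bct + baf) * pairs$pre, hyper$sigma)
    mc <- mean(dens)
    se <- sd(dens) / sqrt(n_mc)
    marg <- exp(marginal_loglik(spec, hyper, pairs))
    expect_lt(abs(mc - marg), 3 * se)
  }
})
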