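#' Posterior effect summary
#'
#' Summarises the population treadmill effect (`beta_ct`), the additional
#' auditory-feedback effect (`beta_af`) and their drawwise combination
#' `beta_ct + beta_af` (the total AF-group effect) as empirical posterior
#' means and central 95 percent percentile intervals (2.5 and 97.5
#' percent quantiles of the draws).  For hierarchical models the
#' population hyper-means are summarised.
#'
#' @param fit A `wbam_fit`, or a list with numeric draw vectors `ct` and
#'   `af` (scalars allowed, giving degenerate intervals).
#' @param level Central interval mass (default 0.95).
#' @param force Summarise a non-converged fit anyway (default `FALSE`).
#' @return Data frame of class `effect_summary` with columns `effect`,
#'   `mean`, `lower`, `upper`.
#' @export
effect_summary <- function(fit, level = 0.95, force = FALSE) {
  if (inherits(fit, "wbam_fit")) {
    if (!fit$converged && !force) {
      stop_wbam("wbam_not_converged",
                "fit is flagged non-converged; pass force = TRUE to summarise anyway")
    }
    eff <- effect_draws(fit)
  } else {
    eff <- fit
    stopifnot(is.numeric(eff$ct), is.numeric(eff$af))
  }
  combined <- eff$ct + eff$af
  a <- (1 - level) / 2
  one <- function(name, x) {
    if (length(x) == 1L) {
      data.frame(effect = name, mean = x, lower = x, upper = x,
                 stringsAsFactors = FALSE)
    } else {
      q <- quantile(x, c(a, 1 - a), names = FALSE)
      data.frame(effect = name, mean = mean(x), lower = q[1L], upper = q[2L],
                 stringsAsFactors = FALSE)
    }
  }
  out <- rbind(one("beta_ct", eff$ct), one("beta_af", eff$af),
               one("combined", combined))
  class(out) <- c("effect_summary", "data.frame")
  out
}

#' Percent reduction of the WBAM range attributable to auditory feedback
#'
#' Maps the auditory-feedback effect to a percentage: a multiplicative
#' effect `beta_af` changes the post/pre ratio by `100 * beta_af`
#' percent, so the reduction is `-100 * beta_af`, applied drawwise.
#'
#' @param beta_af Numeric vector of posterior draws (or a scalar).
#' @param level Central interval mass (default 0.95).
#' @return List with `mean`, `lower`, `upper` in percent.
#' @export
percent_reduction <- function(beta_af, level = 0.95) {
  pct <- -100 * as.numeric(beta_af)
  if (length(pct) == 1L) return(list(mean = pct, lower = pct, upper = pct))
  a <- (1 - level) / 2
  q <- quantile(pct, c(a, 1 - a), names = FALSE)
  list(mean = mean(pct), lower = q[1L], upper = q[2L])
}

#' Standardized effect size (Cohen's d) between group-effect posteriors
#'
#' Computes a drawwise standardized difference between the CT-group
#' effect draws and the AF-group effect draws: the pooled scale is
#' `sqrt((s_ct^2 + s_af^2) / 2)` with `s` the empirical standard
#' deviation of each draw set, and `d_s = |ct_s - af_s| / pooled`.
#' Reported are the mean and central 95 percent interval of the `d`
#' draws, plus the standardized difference of the two means
#' (`d_at_means`), which equals the drawwise mean when the difference is
#' constant across draws.
#'
#' @param ct_draws,af_draws Numeric draw vectors of equal length.
#' @param level Central interval mass (default 0.95).
#' @return List with `mean`, `lower`, `upper`, `d_at_means`,
#'   `pooled_scale`.
#' @export
cohen_d <- function(ct_draws, af_draws, level = 0.95) {
  ct_draws <- as.numeric(ct_draws)
  af_draws <- as.numeric(af_draws)
  if (!length(ct_draws) || !length(af_draws)) {
    stop_wbam("wbam_domain_error", "draw sets must be non-empty")
  }
  pooled <- sqrt((sd(ct_draws)^2 + sd(af_draws)^2) / 2)
  if (!is.finite(pooled) || pooled == 0) {
    stop_wbam("wbam_undefined_d", "pooled scale is zero; d is undefined")
  }
  d <- abs(ct_draws - af_draws) / pooled
  a <- (1 - level) / 2
  q <- quantile(d, c(a, 1 - a), names = FALSE)
  list(mean = mean(d), lower = q[1L], upper = q[2L],
       d_at_means = abs(mean(ct_draws) - mean(af_draws)) / pooled,
       pooled_scale = pooled)
}

#' Posterior predictive bands over a grid of pre values
#'
#' For each group and each pre-rehabilitation WBAM range on the grid,
#' pools the per-draw marginal (new-patient) predictive normal
#' `Normal((m_ct + g m_af) pre, sqrt((s_ct^2 + g s_af^2) pre^2 + sigma^2))`
#' into its exact mixture, and returns the mean line and the central
#' interval bounds at the requested levels.  Mixture quantiles are found
#' by root-finding on the pooled CDF, so they are exact up to the root
#' tolerance (no extra simulation noise).  At `pre = 0` the mean line
#' passes through 0.
#'
#' @param fit A `wbam_fit`.
#' @param pre_grid Non-negative pre values (default 40 points spanning
#'   the observed pre range from 0).
#' @param levels Central interval masses (default 50 and 95 percent).
#' @param max_draws Thin to at most this many draws for speed.
#' @return Data frame with columns `group`, `pre`, `mean` and `lo`/`hi`
#'   per level (e.g. `lo50`, `hi50`, `lo95`, `hi95`).
#' @export
predictive_interval_curve <- function(fit, pre_grid = NULL,
                                      levels = c(0.5, 0.95),
                                      max_draws = 1000L) {
  stopifnot(inherits(fit, "wbam_fit"))
  if (is.null(pre_grid)) {
    pre_grid <- seq(0, max(fit$pairs$pre) * 1.05, length.out = 40L)
  }
  if (any(pre_grid < 0)) stop_wbam("wbam_domain_error", "pre values must be >= 0")
  d <- fit$draws
  S <- nrow(d)
  keep <- if (S > max_draws) round(seq(1L, S, length.out = max_draws)) else seq_len(S)
  spec <- fit$spec
  m_ct <- d[keep, if (spec$hierarchical_ct) "mu_ct" else "beta_ct"]
  m_af <- d[keep, if (spec$hierarchical_af) "mu_af" else "beta_af"]
  s_ct2 <- if (spec$hierarchical_ct) d[keep, "sigma_ct"]^2 else 0
  s_af2 <- if (spec$hierarchical_af) d[keep, "sigma_af"]^2 else 0
  sig2 <- d[keep, "sigma"]^2
  rows <- list()
  for (grp in c("AF", "CT")) {
    g <- as.numeric(grp == "AF")
    slope <- m_ct + g * m_af
    var_slope <- s_ct2 + g * s_af2
    for (pre in pre_grid) {
      mu_s <- slope * pre
      sd_s <- sqrt(var_slope * pre^2 + sig2)
      row <- list(group = grp, pre = pre, mean = mean(mu_s))
      for (lv in levels) {
        a <- (1 - lv) / 2
        tag <- sprintf("%.0f", 100 * lv)
        row[[paste0("lo", tag)]] <- mixture_normal_quantile(a, mu_s, sd_s)
        row[[paste0("hi", tag)]] <- mixture_normal_quantile(1 - a, mu_s, sd_s)
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact quantile of an equally weighted normal mixture
#' @noRd
mixture_normal_quantile <- function(p, mu, sd) {
  lo <- min(mu - 10 * max(sd))
  hi <- max(mu + 10 * max(sd))
  uniroot(function(q) mean(pnorm(q, mu, sd)) - p, c(lo, hi),
          tol = 1e-10)$root
}
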