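#' Widely applicable information criterion from pointwise log likelihoods
#'
#' Given a draws-by-observations matrix of log predictive densities,
#' computes the log pointwise predictive density
#' `lppd = sum_n log mean_s exp(ll_sn)` (via a numerically stable
#' log-sum-exp), the effective-parameter penalty
#' `p_waic = sum_n var_s(ll_sn)`, and `waic = -2 (lppd - p_waic)`
#' (deviance scale; smaller is better).
#'
#' @param ll Matrix of log likelihoods, draws x observations, all finite,
#'   with at least 2 draws.
#' @return List with `lppd`, `p_waic`, `waic`.
#' @export
compute_waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2L) {
    stop_wbam("wbam_length_error", "p_waic needs at least 2 draws")
  }
  if (!all(is.finite(ll))) {
    stop_wbam("wbam_domain_error", "log-likelihood matrix must be finite")
  }
  lppd <- sum(apply(ll, 2L, log_sum_exp) - log(nrow(ll)))
  p_waic <- sum(apply(ll, 2L, var))
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

#' Rank candidate models by WAIC
#'
#' Sorts models by ascending WAIC (best first) and reports the difference
#' `d_waic` from the best model.  Ties are broken by ascending model id.
#'
#' @param waics Named numeric vector of WAIC values (names are model
#'   ids), or a list of `compute_waic()` results.
#' @param lppd,p_waic Optional vectors aligned with `waics` for
#'   reporting.
#' @return Data frame of class `waic_table` with columns `model`,
#'   `waic`, `d_waic`, `rank` (plus `lppd`, `p_waic` when supplied),
#'   ordered by rank.
#' @export
rank_models <- function(waics, lppd = NULL, p_waic = NULL) {
  if (is.list(waics) && !is.null(waics[[1L]]$waic)) {
    lppd <- vapply(waics, `[[`, numeric(1), "lppd")
    p_waic <- vapply(waics, `[[`, numeric(1), "p_waic")
    waics <- vapply(waics, `[[`, numeric(1), "waic")
  }
  if (!length(waics)) stop_wbam("wbam_domain_error", "need at least one model")
  ids <- if (is.null(names(waics))) as.character(seq_along(waics)) else names(waics)
  out <- data.frame(model = ids, waic = as.numeric(waics),
                    stringsAsFactors = FALSE)
  if (!is.null(lppd)) out$lppd <- as.numeric(lppd)
  if (!is.null(p_waic)) out$p_waic <- as.numeric(p_waic)
  out$d_waic <- out$waic - min(out$waic)
  ord <- order(out$waic, out$model)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("waic_table", "data.frame")
  out
}
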