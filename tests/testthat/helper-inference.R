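# Minimal paired dataset and hand-built fit objects for inference tests.

make_pairs <- function(patient, group, pre, post) {
  structure(data.frame(patient_id = patient, group = group,
                       pair = seq_along(pre), pre = pre, post = post,
                       stringsAsFactors = FALSE),
            class = c("paired_ranges", "data.frame"))
}

# A wbam_fit with draws fixed by hand (bypassing MCMC), for closed-form
# checks of the summaries and predictive bands.
fake_fit <- function(draws, spec = model_spec(1),
                     pairs = make_pairs(c("A", "B"), c("AF", "CT"),
                                        pre = c(0.05, 0.04),
                                        post = c(0.042, 0.041)),
                     converged = TRUE) {
  structure(list(spec = spec, pairs = pairs, draws = draws,
                 n_chains = 1L, rhat = setNames(rep(1, ncol(draws)),
                                                colnames(draws)),
                 converged = converged,
                 patients = unique(pairs$patient_id),
                 af_patients = unique(pairs$patient_id[pairs$group == "AF"])),
            class = "wbam_fit")
}
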