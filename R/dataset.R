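#' Trial-level WBAM-range dataset
#'
#' Validates and classes a long-format data frame of per-trial normalized
#' WBAM ranges: one row per (patient, phase, trial), with treatment group
#' `AF` (auditory feedback) or `CT` (control) and phase `pre` or `post`
#' relative to the two-week rehabilitation.
#'
#' @param df Data frame with columns `patient_id`, `group`, `phase`,
#'   `trial`, `range_value`.
#' @return The validated data frame with class `range_dataset`.
#' @export
range_dataset <- function(df) {
  need <- c("patient_id", "group", "phase", "trial", "range_value")
  if (!all(need %in% names(df))) {
    stop_wbam("wbam_domain_error", "range dataset needs columns %s",
              paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  if (!all(df$group %in% c("AF", "CT"))) {
    stop_wbam("wbam_domain_error", "group must be 'AF' or 'CT'")
  }
  if (!all(df$phase %in% c("pre", "post"))) {
    stop_wbam("wbam_domain_error", "phase must be 'pre' or 'post'")
  }
  if (any(df$range_value < 0)) {
    stop_wbam("wbam_domain_error", "range values must be non-negative")
  }
  if (any(df$trial < 1)) stop_wbam("wbam_domain_error", "trial indices start at 1")
  key <- paste(df$patient_id, df$phase, df$trial)
  if (anyDuplicated(key)) {
    stop_wbam("wbam_domain_error", "(patient, phase, trial) must be unique")
  }
  g <- tapply(df$group, df$patient_id, function(x) length(unique(x)))
  if (any(g > 1L)) {
    stop_wbam("wbam_domain_error", "a patient cannot belong to both groups")
  }
  class(df) <- c("range_dataset", "data.frame")
  df
}

#' Read a trial-level range dataset from CSV
#' @param file Path to a CSV with columns `patient_id`, `group`, `phase`,
#'   `trial`, `range_value`.
#' @return A [range_dataset()].
#' @export
read_range_csv <- function(file) {
  range_dataset(read.csv(file, comment.char = "#", stringsAsFactors = FALSE))
}

#' Write a range dataset to CSV
#' @param dataset A [range_dataset()].
#' @param file Output path.
#' @export
write_range_csv <- function(dataset, file) {
  write.csv(as.data.frame(dataset), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Pair pre and post trials within each patient
#'
#' The effect models relate the i-th post-rehabilitation trial of patient
#' j to a pre-rehabilitation value of the same patient.  Two pairing
#' modes are provided: `"index"` pairs the i-th pre trial with the i-th
#' post trial in ascending trial order, truncating to the smaller count
#' (a warning reports dropped trials); `"pre_mean"` pairs every post
#' trial against the patient's mean pre value.
#'
#' @param dataset A [range_dataset()].
#' @param mode Pairing rule, `"index"` (default) or `"pre_mean"`.
#' @return Data frame of class `paired_ranges` with columns `patient_id`,
#'   `group`, `pair`, `pre`, `post`.
#' @export
pair_trials <- function(dataset, mode = c("index", "pre_mean")) {
  mode <- match.arg(mode)
  dataset <- range_dataset(dataset)
  out <- lapply(split(dataset, dataset$patient_id), function(d) {
    pre <- d[d$phase == "pre", ]
    post <- d[d$phase == "post", ]
    if (!nrow(pre) || !nrow(post)) {
      stop_wbam("wbam_pairing_error",
                "patient '%s' lacks %s trials", d$patient_id[1L],
                if (nrow(pre)) "post" else "pre")
    }
    pre <- pre[order(pre$trial), ]
    post <- post[order(post$trial), ]
    if (mode == "index") {
      k <- min(nrow(pre), nrow(post))
      if (nrow(pre) != nrow(post)) {
        warning(sprintf("patient '%s': %d unpaired %s trial(s) dropped",
                        d$patient_id[1L], abs(nrow(pre) - nrow(post)),
                        if (nrow(pre) > nrow(post)) "pre" else "post"),
                call. = FALSE)
      }
      data.frame(patient_id = d$patient_id[1L], group = d$group[1L],
                 pair = seq_len(k), pre = pre$range_value[seq_len(k)],
                 post = post$range_value[seq_len(k)],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(patient_id = d$patient_id[1L], group = d$group[1L],
                 pair = seq_len(nrow(post)), pre = mean(pre$range_value),
                 post = post$range_value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (any(out$pre <= 0)) {
    stop_wbam("wbam_pairing_error", "paired pre values must be positive")
  }
  class(out) <- c("paired_ranges", "data.frame")
  out
}
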