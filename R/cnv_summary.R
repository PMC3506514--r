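#' Summarize CNV calls per tissue and LBF threshold
#'
#' Table-style characteristics of the retained calls at each LBF threshold:
#' mean calls per subject (subjects with zero calls count in the
#' denominator), and the mean and quartiles of call size in kb (inclusive bp
#' span / 1000) and in probes. Quartiles use linear interpolation between
#' order statistics. A tissue/threshold cell with no calls reports a zero
#' count and `NA` size statistics.
#'
#' @param calls Call tibble (all samples pooled; must carry `sample_id`).
#' @param metadata Cohort metadata, used to map samples to subjects/tissues.
#' @param thresholds LBF thresholds to report.
#' @return Tibble with one row per (tissue, threshold): `tissue, lbf_threshold,
#'   n_subjects, mean_calls_per_subject, kb_mean, kb_q25, kb_median, kb_q75,
#'   probes_mean, probes_q25, probes_median, probes_q75`.
#' @export
summarize_cnvs <- function(calls, metadata, thresholds = c(10, 30, 50)) {
  md <- as_tibble(metadata)
  calls <- as_tibble(calls) |>
    left_join(select(md, "sample_id", "tissue"), by = "sample_id")
  rows <- list()
  for (tis in sort(unique(md$tissue))) for (thr in thresholds) {
    subj <- unique(md$subject_id[md$tissue == tis])
    f <- calls[calls$tissue == tis & calls$lbf >= thr, , drop = FALSE]
    kb <- (f$end_bp - f$start_bp + 1) / 1000
    pr <- f$n_probes
    q <- function(v, p) if (nrow(f) == 0) NA_real_ else
      unname(quantile(v, p, type = 7))
    rows[[length(rows) + 1]] <- tibble(
      tissue = tis, lbf_threshold = thr, n_subjects = length(subj),
      mean_calls_per_subject = nrow(f) / length(subj),
      kb_mean = if (nrow(f) == 0) NA_real_ else mean(kb),
      kb_q25 = q(kb, 0.25), kb_median = q(kb, 0.5), kb_q75 = q(kb, 0.75),
      probes_mean = if (nrow(f) == 0) NA_real_ else mean(pr),
      probes_q25 = q(pr, 0.25), probes_median = q(pr, 0.5),
      probes_q75 = q(pr, 0.75))
  }
  bind_rows(rows)
}

#' Per-subject call counts at a threshold
#'
#' @param calls Pooled call tibble.
#' @param metadata Cohort metadata.
#' @param tissue Tissue to count.
#' @param threshold LBF threshold.
#' @return Named integer vector, one count per subject with that tissue
#'   (zero-call subjects included), in metadata order.
#' @export
calls_per_subject <- function(calls, metadata, tissue, threshold) {
  md <- as_tibble(metadata)
  md <- md[md$tissue == tissue, , drop = FALSE]
  f <- as_tibble(calls)
  f <- f[f$lbf >= threshold & f$sample_id %in% md$sample_id, , drop = FALSE]
  counts <- table(factor(f$sample_id, levels = md$sample_id))
  setNames(as.integer(counts), md$subject_id)
}

#' Compare per-subject CNV counts between tissues
#'
#' Two-sided paired test of equal mean CNV count per subject between blood
#' and buccal samples (paired t test on the per-subject counts by default,
#' sign-flip permutation as an alternative).
#'
#' @param blood_counts,buccal_counts Per-subject counts in matched subject
#'   order.
#' @param method `"t"` or `"permutation"`.
#' @param n_perm Number of sign-flip permutations.
#' @return Two-sided p-value.
#' @export
compare_call_counts <- function(blood_counts, buccal_counts,
                                method = c("t", "permutation"),
                                n_perm = 1999) {
  method <- match.arg(method)
  if (length(blood_counts) != length(buccal_counts))
    stop_arg("count vectors must have equal length")
  if (length(blood_counts) < 2) stop_arg("need at least 2 subjects")
  d <- as.numeric(blood_counts) - as.numeric(buccal_counts)
  if (method == "t") {
    if (all(d == 0)) return(1)
    if (sd(d) == 0) return(0)
    return(unname(t.test(d)$p.value))
  }
  obs <- mean(d)
  flips <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE), n_perm)
  stat <- as.numeric(flips %*% d) / length(d)
  (1 + sum(abs(stat) >= abs(obs))) / (n_perm + 1)
}
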