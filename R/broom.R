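#' Tidy a concordance report
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return The per-cell summary tibble (`method, relatedness, tissue_combo,
#'   mean_r, n_pairs`).
#' @exportS3Method generics::tidy
tidy.concordance_report <- function(x, ...) {
  x$summary
}

#' One-row overview of a concordance report
#'
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of methods and pairs, and for each
#'   method present the self-minus-unrelated correlation gap (the headline
#'   contrast: large gaps mean pairs from the same person agree far better
#'   than pairs from different people).
#' @exportS3Method generics::glance
glance.concordance_report <- function(x, ...) {
  gap <- function(m) {
    s <- x$summary[x$summary$method == m, , drop = FALSE]
    self <- s$mean_r[s$relatedness == "self"]
    unrel <- s$mean_r[s$relatedness == "unrelated" &
                        s$tissue_combo == "blood_buccal"]
    if (length(self) && length(unrel)) self - unrel else NA_real_
  }
  out <- tibble(n_methods = length(x$methods), n_pairs = nrow(x$pairs))
  for (m in x$methods) out[[paste0("gap_", m)]] <- gap(m)
  out
}

#' Tidy a cohort truth object
#'
#' @param x A `cohort_truth`.
#' @param ... Unused.
#' @return The flattened truth-set table (see [truth_table()]).
#' @exportS3Method generics::tidy
tidy.cohort_truth <- function(x, ...) {
  truth_table(x)
}

#' One-row overview of a cohort truth object
#'
#' @param x A `cohort_truth`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cohort_truth <- function(x, ...) {
  tt <- truth_table(x)
  tibble(n_subjects = nrow(x$subjects),
         n_dyads = sum(x$subjects$role == "mother"),
         n_samples = nrow(x$metadata),
         n_loci = nrow(x$manifest),
         n_regions = nrow(x$regions),
         n_aberrant_intervals = nrow(tt))
}
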