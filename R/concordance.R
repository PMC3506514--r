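#' Genotype call rate of a sample
#'
#' Fraction of SNP loci with a genotype other than no-call (`"NC"`).
#'
#' @param sample A sample series tibble.
#' @return A single fraction in [0, 1].
#' @export
genotype_call_rate <- function(sample) {
  g <- sample$genotype[sample$kind == "SNP"]
  if (length(g) == 0) stop_arg("sample has no SNP loci")
  mean(g != "NC", na.rm = TRUE)
}

co_called <- function(a, b) {
  ga <- a$genotype[a$kind == "SNP"]
  gb <- b$genotype[b$kind == "SNP"]
  if (length(ga) != length(gb))
    stop_arg("samples must share a manifest")
  ok <- !is.na(ga) & !is.na(gb) & ga != "NC" & gb != "NC"
  list(ga = ga[ok], gb = gb[ok], n = sum(ok))
}

#' SNP genotype concordance between two samples
#'
#' Over the SNP loci called (not `"NC"`) in *both* samples, the fraction with
#' identical genotype.
#'
#' @param a,b Sample series tibbles on the same manifest.
#' @return A single fraction in [0, 1].
#' @export
snp_concordance <- function(a, b) {
  cc <- co_called(a, b)
  if (cc$n == 0) stop_undefined("no co-called SNP loci; concordance undefined")
  mean(cc$ga == cc$gb)
}

#' Mendelian consistency of a mother-child sample pair
#'
#' A violation is a co-called SNP locus at which the two samples carry
#' opposite homozygous genotypes (`AA` vs `BB`) — impossible for a true
#' mother-child pair under Mendelian inheritance (barring genotyping error).
#' The pair is flagged when the violation rate exceeds `threshold`, the
#' signature of a mislabeled or miscollected sample.
#'
#' @param mother,child Sample series tibbles on the same manifest.
#' @param threshold Flag the pair when the violation rate exceeds this.
#' @return A list: `violation_rate`, `n_co_called`, `flagged`.
#' @export
mendelian_consistency <- function(mother, child, threshold = 0.01) {
  cc <- co_called(mother, child)
  if (cc$n == 0) stop_undefined("no co-called SNP loci; rate undefined")
  viol <- (cc$ga == "AA" & cc$gb == "BB") | (cc$ga == "BB" & cc$gb == "AA")
  rate <- mean(viol)
  list(violation_rate = rate, n_co_called = cc$n, flagged = rate > threshold)
}

#' Pearson correlation between two per-locus series
#'
#' Standard Pearson correlation on the genome-wide concatenated series, after
#' dropping loci missing in either member of the pair.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Pearson's r.
#' @export
pair_correlation <- function(a, b) {
  if (length(a) != length(b)) stop_arg("series lengths differ")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop_arg("fewer than 3 jointly observed loci")
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0)
    stop_undefined("zero variance; correlation undefined")
  cor(a, b)
}

#' Enumerate sample pairs by relatedness and tissue combination
#'
#' Classifies every comparable pair of samples into the categories used for
#' concordance reporting: `self` (one subject's blood vs their buccal —
#' always cross-tissue), `mother_child` (one dyad, per tissue combination),
#' and `unrelated` (cross-subject pairs excluding a subject's own dyad
#' partner). Within-tissue pairs are unordered; cross-tissue pairs enumerate
#' both assignments (mother-blood/child-buccal and mother-buccal/child-blood
#' are distinct pairs, as are both directions of an unrelated blood-buccal
#' pair), with `sample_a` always the blood sample.
#'
#' @param metadata Cohort metadata tibble (`sample_id, subject_id, tissue,
#'   dyad_id, role`), at most one sample per subject and tissue.
#' @return Tibble: `sample_a, sample_b, subject_a, subject_b, relatedness,
#'   tissue_combo`.
#' @export
classify_pairs <- function(metadata) {
  md <- as_tibble(metadata)
  if (anyDuplicated(md[c("subject_id", "tissue")]))
    stop_structural("duplicate subject/tissue in metadata")
  kids <- md[md$role == "child", , drop = FALSE]
  for (d in unique(kids$dyad_id))
    if (!any(md$role == "mother" & md$dyad_id == d, na.rm = TRUE))
      stop_structural(sprintf("dyad '%s' has a child but no mother", d))

  sid <- function(subj, tis) {
    i <- which(md$subject_id == subj & md$tissue == tis)
    if (length(i)) md$sample_id[i] else NA_character_
  }
  subjects <- unique(md$subject_id)
  dyad_of <- setNames(md$dyad_id[!duplicated(md$subject_id)], subjects)
  role_of <- setNames(md$role[!duplicated(md$subject_id)], subjects)
  acc <- list(sa = character(), sb = character(), ja = character(),
              jb = character(), rel = character(), combo = character())
  add <- function(sa, sb, ja, jb, rel, combo) {
    if (is.na(sa) || is.na(sb)) return()
    acc$sa[[length(acc$sa) + 1]] <<- sa
    acc$sb[[length(acc$sb) + 1]] <<- sb
    acc$ja[[length(acc$ja) + 1]] <<- ja
    acc$jb[[length(acc$jb) + 1]] <<- jb
    acc$rel[[length(acc$rel) + 1]] <<- rel
    acc$combo[[length(acc$combo) + 1]] <<- combo
  }
  # self: blood vs buccal of the same subject
  for (s in subjects) add(sid(s, "blood"), sid(s, "buccal"), s, s, "self",
                          "blood_buccal")
  # mother-child, per dyad and tissue combination
  for (d in unique(stats::na.omit(md$dyad_id))) {
    mo <- subjects[role_of == "mother" & !is.na(dyad_of) & dyad_of == d]
    ch <- subjects[role_of == "child" & !is.na(dyad_of) & dyad_of == d]
    if (length(mo) != 1 || length(ch) != 1) next
    add(sid(mo, "blood"), sid(ch, "blood"), mo, ch, "mother_child",
        "blood_blood")
    add(sid(mo, "buccal"), sid(ch, "buccal"), mo, ch, "mother_child",
        "buccal_buccal")
    add(sid(mo, "blood"), sid(ch, "buccal"), mo, ch, "mother_child",
        "blood_buccal")
    add(sid(ch, "blood"), sid(mo, "buccal"), ch, mo, "mother_child",
        "blood_buccal")
  }
  same_dyad <- function(i, j) {
    !is.na(dyad_of[i]) && !is.na(dyad_of[j]) && dyad_of[i] == dyad_of[j]
  }
  # unrelated within-tissue: unordered subject pairs
  ns <- length(subjects)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    si <- subjects[i]; sj <- subjects[j]
    if (i < j && !same_dyad(si, sj)) {
      add(sid(si, "blood"), sid(sj, "blood"), si, sj, "unrelated",
          "blood_blood")
      add(sid(si, "buccal"), sid(sj, "buccal"), si, sj, "unrelated",
          "buccal_buccal")
    }
    if (i != j && !same_dyad(si, sj))
      add(sid(si, "blood"), sid(sj, "buccal"), si, sj, "unrelated",
          "blood_buccal")
  }
  tibble(sample_a = acc$sa, sample_b = acc$sb, subject_a = acc$ja,
         subject_b = acc$jb, relatedness = acc$rel, tissue_combo = acc$combo)
}

#' Concordance of paired series across methods and pair categories
#'
#' The study's core statistic: for each method, build a per-locus series per
#' sample (raw LRR, change-point segment-mean projection, or the
#' segment-mean series implied by HMM calls at each LBF threshold), compute
#' the Pearson correlation of every classified pair on the genome-wide
#' concatenated series, and average within (method, relatedness, tissue
#' combination). Pairs whose correlation is undefined (zero variance, too
#' few joint loci) are dropped with a warning, never silently.
#'
#' @param samples Named list of sample series tibbles (names = sample ids).
#' @param metadata Cohort metadata (see [classify_pairs()]).
#' @param methods Any of `"raw"`, `"segmentation"`, `"hmm"`.
#' @param penalty,min_seg Segmentation settings (see [segment_sample()]).
#' @param params HMM parameters (see [hmm_params()]).
#' @param lbf_thresholds LBF thresholds; `"hmm"` yields one method row per
#'   threshold (`hmm_bf10`, ...).
#' @param segmentations,hmm_calls Optional pre-computed per-sample
#'   segmentations / unfiltered call tibbles (named lists), to avoid
#'   recomputation in a pipeline.
#' @return A `concordance_report`: list with `pairs` (per-pair long tibble:
#'   `sample_a, sample_b, relatedness, tissue_combo, method, r`) and
#'   `summary` (mean r and pair count per cell). [tidy()] returns the
#'   summary, [glance()] a one-row overview, [autoplot()] a category plot.
#' @export
concordance_table <- function(samples, metadata,
                              methods = c("raw", "segmentation", "hmm"),
                              penalty = NULL, min_seg = 1,
                              params = hmm_params(),
                              lbf_thresholds = c(10, 30, 50),
                              segmentations = NULL, hmm_calls = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  pairs <- classify_pairs(metadata)
  used <- unique(c(pairs$sample_a, pairs$sample_b))
  missing <- setdiff(used, names(samples))
  if (length(missing))
    stop_arg(paste("samples missing from `samples`:",
                   paste(missing, collapse = ", ")))

  series <- list()
  if ("raw" %in% methods)
    series$raw <- lapply(samples[used], function(s) s$lrr)
  if ("segmentation" %in% methods) {
    series$segmentation <- lapply(used, function(id) {
      seg <- segmentations[[id]] %||%
        segment_sample(samples[[id]], penalty = penalty, min_seg = min_seg)
      segment_mean_series(samples[[id]], seg)
    })
    names(series$segmentation) <- used
  }
  if ("hmm" %in% methods) {
    calls <- hmm_calls[used]
    if (is.null(hmm_calls))
      calls <- setNames(lapply(used, function(id)
        call_cnvs(samples[[id]], params)), used)
    for (thr in lbf_thresholds) {
      nm <- sprintf("hmm_bf%g", thr)
      series[[nm]] <- setNames(lapply(used, function(id)
        hmm_segment_mean_series(filter_by_lbf(calls[[id]], thr),
                                samples[[id]])), used)
    }
  }

  res <- list()
  n_dropped <- 0L
  for (m in names(series)) {
    M <- do.call(cbind, series[[m]][used])
    if (!anyNA(M)) {
      # complete data: every pairwise r in one pass
      cm <- suppressWarnings(cor(M))
      r <- cm[cbind(match(pairs$sample_a, used), match(pairs$sample_b, used))]
      r[!is.finite(r)] <- NA_real_ # zero-variance series
    } else {
      r <- rep(NA_real_, nrow(pairs))
      for (i in seq_len(nrow(pairs))) {
        r[i] <- tryCatch(
          pair_correlation(series[[m]][[pairs$sample_a[i]]],
                           series[[m]][[pairs$sample_b[i]]]),
          cnvconcord_undefined = function(e) NA_real_,
          cnvconcord_argument_error = function(e) NA_real_)
      }
    }
    n_dropped <- n_dropped + sum(is.na(r))
    res[[m]] <- mutate(pairs, method = m, r = r)
  }
  long <- bind_rows(res) |> select("sample_a", "sample_b", "relatedness",
                                   "tissue_combo", "method", "r")
  if (n_dropped > 0)
    warn(sprintf("%d pair correlation(s) undefined and dropped", n_dropped))
  long <- long[!is.na(long$r), , drop = FALSE]
  summary <- long |>
    group_by(.data$method, .data$relatedness, .data$tissue_combo) |>
    summarise(mean_r = mean(.data$r), n_pairs = n(), .groups = "drop")
  structure(list(pairs = long, summary = summary,
                 methods = names(series)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  wide <- tidyr::pivot_wider(x$summary,
                             id_cols = "method",
                             names_from = c("relatedness", "tissue_combo"),
                             values_from = "mean_r")
  print(as.data.frame(wide), digits = 3, row.names = FALSE)
  cat(sprintf("  (%d pairs retained)\n", nrow(x$pairs)))
  invisible(x)
}

#' Compare two sets of pair correlations
#'
#' Two-sided test of equal mean correlation between two groups of pairs
#' (e.g. per-dyad correlations of buccal samples versus blood samples), on
#' Fisher z-transformed values. The default is a (paired) t test on the z
#' scale — a pragmatic stand-in, since small dyad counts leave little power
#' either way — with a permutation alternative (sign flips when paired,
#' label shuffles otherwise).
#'
#' @param group_a,group_b Numeric vectors of correlations; equal length and
#'   matched order when `paired`.
#' @param paired Are the two groups matched (e.g. same dyads, two tissues)?
#' @param method `"t"` or `"permutation"`.
#' @param n_perm Number of permutations.
#' @return Two-sided p-value.
#' @export
compare_dyad_correlations <- function(group_a, group_b, paired = TRUE,
                                      method = c("t", "permutation"),
                                      n_perm = 1999) {
  method <- match.arg(method)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_arg("need at least 2 values per group")
  if (paired && length(group_a) != length(group_b))
    stop_arg("paired groups must have equal length")
  z <- function(r) atanh(clamp(r, -1 + 1e-12, 1 - 1e-12))
  za <- z(group_a); zb <- z(group_b)
  if (paired) {
    d <- za - zb
    if (method == "t") {
      if (all(d == 0)) return(1)
      if (sd(d) == 0) return(0)
      return(unname(t.test(d)$p.value))
    }
    obs <- mean(d)
    flips <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm)
    stat <- as.numeric(flips %*% d) / length(d)
    return((1 + sum(abs(stat) >= abs(obs))) / (n_perm + 1))
  }
  if (method == "t") {
    if (sd(c(za, zb)) == 0) return(1)
    return(unname(t.test(za, zb)$p.value))
  }
  obs <- mean(za) - mean(zb)
  pool <- c(za, zb); na <- length(za)
  stat <- replicate(n_perm, {
    p <- sample(pool)
    mean(p[seq_len(na)]) - mean(p[-seq_len(na)])
  })
  (1 + sum(abs(stat) >= abs(obs))) / (n_perm + 1)
}

#' Detect mislabeled or swapped samples in a cohort
#'
#' Runs the two identity QC checks used for mail-in sample collections:
#' blood-buccal SNP concordance within each subject (a swapped tissue sample
#' collapses concordance to the unrelated-pair background), and Mendelian duo
#' consistency between mother and child samples per tissue combination. Each
#' check row carries its statistic and a flag.
#'
#' @param samples Named list of sample series tibbles.
#' @param metadata Cohort metadata.
#' @param concordance_flag Flag a self pair when concordance falls below this.
#' @param mendel_flag Flag a duo when the violation rate exceeds this.
#' @return Tibble: `check, sample_a, sample_b, value, flagged`.
#' @export
detect_sample_swaps <- function(samples, metadata, concordance_flag = 0.95,
                                mendel_flag = 0.01) {
  md <- as_tibble(metadata)
  rows <- list()
  for (s in unique(md$subject_id)) {
    bl <- md$sample_id[md$subject_id == s & md$tissue == "blood"]
    bu <- md$sample_id[md$subject_id == s & md$tissue == "buccal"]
    if (length(bl) != 1 || length(bu) != 1) next
    conc <- snp_concordance(samples[[bl]], samples[[bu]])
    rows[[length(rows) + 1]] <- tibble(
      check = "self_concordance", sample_a = bl, sample_b = bu, value = conc,
      flagged = conc < concordance_flag)
  }
  for (d in unique(stats::na.omit(md$dyad_id))) {
    mo <- md[md$dyad_id == d & md$role == "mother", , drop = FALSE]
    ch <- md[md$dyad_id == d & md$role == "child", , drop = FALSE]
    for (i in seq_len(nrow(mo))) for (j in seq_len(nrow(ch))) {
      mc <- mendelian_consistency(samples[[mo$sample_id[i]]],
                                  samples[[ch$sample_id[j]]],
                                  threshold = mendel_flag)
      rows[[length(rows) + 1]] <- tibble(
        check = "mendelian", sample_a = mo$sample_id[i],
        sample_b = ch$sample_id[j], value = mc$violation_rate,
        flagged = mc$flagged)
    }
  }
  bind_rows(rows)
}
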