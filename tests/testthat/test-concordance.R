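test_that("call rate and SNP concordance follow their definitions", {
  s <- genotype_sample(c("AA", "AB", "NC", "BB"))
  expect_equal(genotype_call_rate(s), 0.75)
  expect_equal(genotype_call_rate(genotype_sample(rep("NC", 4))), 0)
  expect_equal(genotype_call_rate(genotype_sample(c("AA", "BB"))), 1)
  expect_error(genotype_call_rate(toy_sample(rnorm(3))),
               class = "cnvconcord_argument_error")

  a <- genotype_sample(c("AA", "AB", "BB"))
  expect_equal(snp_concordance(a, a), 1)
  b <- genotype_sample(c("AA", "NC", "BB"))
  expect_equal(snp_concordance(b, a), 1) # over the 2 co-called loci
  expect_equal(snp_concordance(genotype_sample(c("AA", "AB")),
                               genotype_sample(c("BB", "AB"))), 0.5)
  expect_error(snp_concordance(genotype_sample(c("NC", "NC")),
                               genotype_sample(c("AA", "AB"))),
               class = "cnvconcord_undefined")
})

test_that("Mendelian violations are opposite homozygotes over co-called loci", {
  a <- genotype_sample(c("AA", "AB", "BB"))
  mc <- mendelian_consistency(a, a)
  expect_equal(mc$violation_rate, 0)
  expect_false(mc$flagged)

  mo <- genotype_sample(c(rep("AA", 9), "AA"))
  ch <- genotype_sample(c(rep("AA", 9), "BB"))
  mc <- mendelian_consistency(mo, ch)
  expect_equal(mc$violation_rate, 0.1)
  expect_true(mc$flagged)
})

test_that("unrelated-pair violation rate converges to the HWE closed form", {
  # at MAF 0.5 under HWE: P(AA, BB) + P(BB, AA) = 2 * (1/4)^2 = 0.125
  set.seed(61)
  man <- build_manifest(20000, 0, n_chromosomes = 4)
  truth <- simulate_cohort(man, simulate_population_cnvs(man, 0),
                           n_dyads = 0, n_singletons = 2,
                           de_novo_rate = 0, somatic_discordance_rate = 0,
                           snp_maf_range = c(0.5, 0.5))
  a <- render_sample(truth, "s01", "blood")
  b <- render_sample(truth, "s02", "blood")
  mc <- mendelian_consistency(a, b)
  se <- sqrt(0.125 * 0.875 / mc$n_co_called)
  expect_lt(abs(mc$violation_rate - 0.125), 3 * se)
  expect_true(mc$flagged)
})

test_that("pair correlation handles identity, inversion, and degeneracy", {
  x <- rnorm(50)
  expect_equal(pair_correlation(x, x), 1)
  expect_equal(pair_correlation(x, -x), -1)
  expect_error(pair_correlation(x, rep(1, 50)),
               class = "cnvconcord_undefined")
  expect_error(pair_correlation(x, rnorm(49)),
               class = "cnvconcord_argument_error")
  # pairwise deletion of missing loci
  y <- x + rnorm(50, 0, 0.1)
  y[1:5] <- NA
  expect_equal(pair_correlation(x, y), cor(x[-(1:5)], y[-(1:5)]))
})

test_that("pair classification enumerates the expected category counts", {
  md2 <- tibble::tibble(
    sample_id = c("a_blood", "a_buccal", "b_blood", "b_buccal"),
    subject_id = rep(c("a", "b"), each = 2),
    tissue = rep(c("blood", "buccal"), 2),
    dyad_id = NA_character_, role = "singleton")
  pairs <- classify_pairs(md2)
  counts <- table(pairs$relatedness, pairs$tissue_combo)
  expect_equal(sum(pairs$relatedness == "self"), 2)
  expect_equal(sum(pairs$relatedness == "mother_child"), 0)
  expect_equal(unname(counts["unrelated", "blood_buccal"]), 2)
  expect_equal(unname(counts["unrelated", "blood_blood"]), 1)
  expect_equal(unname(counts["unrelated", "buccal_buccal"]), 1)

  md1 <- tibble::tibble(
    sample_id = c("m_blood", "m_buccal", "c_blood", "c_buccal"),
    subject_id = rep(c("m", "c"), each = 2),
    tissue = rep(c("blood", "buccal"), 2),
    dyad_id = "d01", role = rep(c("mother", "child"), each = 2))
  pairs <- classify_pairs(md1)
  counts <- table(pairs$relatedness, pairs$tissue_combo)
  expect_equal(sum(pairs$relatedness == "self"), 2)
  expect_equal(unname(counts["mother_child", "blood_blood"]), 1)
  expect_equal(unname(counts["mother_child", "buccal_buccal"]), 1)
  expect_equal(unname(counts["mother_child", "blood_buccal"]), 2)
  expect_equal(sum(pairs$relatedness == "unrelated"), 0)
})

test_that("a study-shaped cohort yields 39 self pairs and 16 dyad pairs per combo", {
  set.seed(62)
  man <- build_manifest(50, 0, n_chromosomes = 1)
  truth <- simulate_cohort(man, simulate_population_cnvs(man, 0),
                           n_dyads = 16, n_singletons = 7)
  pairs <- classify_pairs(truth$metadata)
  expect_equal(sum(pairs$relatedness == "self"), 39)
  mc <- pairs[pairs$relatedness == "mother_child", ]
  expect_equal(sum(mc$tissue_combo == "blood_blood"), 16)
  expect_equal(sum(mc$tissue_combo == "buccal_buccal"), 16)
  expect_equal(sum(mc$tissue_combo == "blood_buccal"), 32)
  # unrelated blood-buccal: ordered subject pairs minus own dyad partners
  expect_equal(sum(pairs$relatedness == "unrelated" &
                     pairs$tissue_combo == "blood_buccal"), 39 * 38 - 32)
})

test_that("pair classification rejects malformed metadata", {
  md <- tibble::tibble(
    sample_id = c("x1", "x2"), subject_id = c("a", "a"),
    tissue = c("blood", "blood"), dyad_id = NA_character_,
    role = "singleton")
  expect_error(classify_pairs(md), class = "cnvconcord_structural_error")
  md2 <- tibble::tibble(
    sample_id = "c1", subject_id = "c", tissue = "blood", dyad_id = "d01",
    role = "child")
  expect_error(classify_pairs(md2), class = "cnvconcord_structural_error")
})

test_that("duplicate samples correlate perfectly in every method", {
  set.seed(63)
  man <- build_manifest(400, 60, n_chromosomes = 2)
  reg <- simulate_population_cnvs(man, 4)
  truth <- simulate_cohort(man, reg, n_dyads = 0, n_singletons = 1)
  s <- render_sample(truth, "s01", "blood")
  samples <- list(s01_blood = s, s01_buccal = s) # identical duplicates
  ct <- concordance_table(samples, truth$metadata)
  self_rows <- ct$summary[ct$summary$relatedness == "self", ]
  expect_equal(self_rows$mean_r, rep(1, nrow(self_rows)), tolerance = 1e-12)
  expect_setequal(ct$summary$relatedness, "self")
  # report averages reproduce from retained per-pair values
  for (i in seq_len(nrow(ct$summary))) {
    sub <- ct$pairs[ct$pairs$method == ct$summary$method[i] &
                      ct$pairs$relatedness == ct$summary$relatedness[i] &
                      ct$pairs$tissue_combo == ct$summary$tissue_combo[i], ]
    expect_equal(mean(sub$r), ct$summary$mean_r[i])
  }
})

test_that("synthetic cohorts order self above dyad above unrelated", {
  cc <- fixture_cohort()
  ct <- concordance_table(cc$samples, cc$truth$metadata,
                          lbf_thresholds = 30)
  agg <- dplyr::group_by(ct$pairs, .data$method, .data$relatedness)
  agg <- dplyr::summarise(agg, r = mean(.data$r), .groups = "drop")
  for (m in c("segmentation", "hmm_bf30")) {
    r <- setNames(agg$r[agg$method == m], agg$relatedness[agg$method == m])
    expect_gt(r["self"], r["mother_child"])
    expect_gt(r["mother_child"], r["unrelated"])
  }
  # tidy/glance accessors agree with the underlying tables
  expect_identical(tidy(ct), ct$summary)
  g <- glance(ct)
  expect_equal(g$n_pairs, nrow(ct$pairs))
  expect_gt(g$gap_segmentation, 0)
})

test_that("paired correlation comparisons behave under null and shift", {
  set.seed(64)
  r <- runif(16, 0.3, 0.7)
  expect_equal(compare_dyad_correlations(r, r, paired = TRUE), 1)
  shifted <- pmin(0.99, r + 0.25)
  expect_lt(compare_dyad_correlations(r, shifted, paired = TRUE), 0.01)
  expect_error(compare_dyad_correlations(0.5, 0.5),
               class = "cnvconcord_argument_error")
  # permutation agrees with t on clear effects
  p_t <- compare_dyad_correlations(r, shifted, paired = TRUE)
  p_perm <- compare_dyad_correlations(r, shifted, paired = TRUE,
                                      method = "permutation")
  expect_lt(p_perm, 0.05)
  expect_lt(abs(log10(max(p_t, 5e-4)) - log10(max(p_perm, 5e-4))), 2)
})

test_that("a swapped buccal sample is flagged by exactly the affected checks", {
  set.seed(65)
  man <- build_manifest(1500, 200, n_chromosomes = 4)
  reg <- simulate_population_cnvs(man, 8)
  truth <- simulate_cohort(man, reg, n_dyads = 2, n_singletons = 1)
  samples <- simulate_samples(truth)
  # exchange the buccal samples of the two (unrelated) mothers
  tmp <- samples[["d01m_buccal"]]
  samples[["d01m_buccal"]] <- samples[["d02m_buccal"]]
  samples[["d02m_buccal"]] <- tmp
  qc <- detect_sample_swaps(samples, truth$metadata)
  flagged <- qc[qc$flagged, ]
  # self concordance: both swapped subjects, nobody else
  self <- qc[qc$check == "self_concordance", ]
  expect_setequal(self$sample_a[self$flagged],
                  c("d01m_blood", "d02m_blood"))
  # mendelian: exactly the duo checks touching a swapped buccal sample
  mend <- qc[qc$check == "mendelian", ]
  expect_setequal(mend$sample_a[mend$flagged],
                  c("d01m_buccal", "d02m_buccal"))
  expect_true(all(!mend$flagged[!(mend$sample_a %in%
                                    c("d01m_buccal", "d02m_buccal"))]))
})
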