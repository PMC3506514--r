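test_that("population CNV regions respect counts, ranges, and spacing", {
  set.seed(11)
  man <- build_manifest(3000, 500, n_chromosomes = 8)
  expect_equal(nrow(simulate_population_cnvs(man, 0)), 0)

  reg <- simulate_population_cnvs(man, 5, frequency_range = c(0.2, 0.2))
  expect_equal(reg$frequency, rep(0.2, 5))

  reg <- simulate_population_cnvs(man, 15)
  expect_equal(nrow(reg), 15)
  expect_true(all(reg$start_bp < reg$end_bp))
  # every region covers at least one locus
  for (j in seq_len(nrow(reg)))
    expect_gt(length(loci_covered <- which(
      man$chrom == reg$chrom[j] & man$pos >= reg$start_bp[j] &
        man$pos <= reg$end_bp[j])), 0)
  # non-overlap within chromosome
  for (c_ in unique(reg$chrom)) {
    rc <- reg[reg$chrom == c_, ]
    rc <- rc[order(rc$start_bp), ]
    if (nrow(rc) > 1)
      expect_true(all(rc$start_bp[-1] > rc$end_bp[-nrow(rc)]))
  }
})

test_that("realized carrier fractions match binomial sampling at the region frequency", {
  # carrier = subject with >= 1 variant haplotype; expectation 1 - (1 - f)^2
  set.seed(12)
  man <- build_manifest(200, 0, n_chromosomes = 2)
  reg <- simulate_population_cnvs(man, 4, frequency_range = c(0.1, 0.35))
  truth <- simulate_cohort(man, reg, n_dyads = 0, n_singletons = 500,
                           de_novo_rate = 0, somatic_discordance_rate = 0)
  for (j in seq_len(nrow(reg))) {
    carriers <- sum(truth$reg_h1[, j] == 1L | truth$reg_h2[, j] == 1L)
    p <- 1 - (1 - reg$frequency[j])^2
    ci <- qbinom(c(0.005, 0.995), 500, p)
    expect_gte(carriers, ci[1])
    expect_lte(carriers, ci[2])
  }
})

test_that("children inherit one maternal haplotype per chromosome, exactly", {
  cc <- fixture_cohort()
  truth <- cc$truth
  man <- truth$manifest
  snp_chrom <- man$chrom[man$kind == "SNP"]
  for (d in unique(stats::na.omit(truth$subjects$dyad_id))) {
    mo <- paste0(d, "m"); ch <- paste0(d, "c")
    for (c_ in unique(man$chrom)) {
      sel <- snp_chrom == c_
      child_mat <- unname(truth$snp_h1[ch, sel])
      ok <- identical(child_mat, unname(truth$snp_h1[mo, sel])) ||
        identical(child_mat, unname(truth$snp_h2[mo, sel]))
      expect_true(ok)
      rsel <- truth$regions$chrom == c_
      if (any(rsel)) {
        child_reg <- unname(truth$reg_h1[ch, rsel])
        expect_true(identical(child_reg, unname(truth$reg_h1[mo, rsel])) ||
                      identical(child_reg, unname(truth$reg_h2[mo, rsel])))
      }
    }
  }
})

test_that("a homozygous-carrier mother always transmits the deletion", {
  set.seed(13)
  man <- build_manifest(300, 50, n_chromosomes = 3)
  reg <- simulate_population_cnvs(man, 3, frequency_range = c(0.3, 0.5))
  for (rep in 1:20) {
    truth <- simulate_cohort(man, reg, n_dyads = 2, n_singletons = 0,
                             de_novo_rate = 0, somatic_discordance_rate = 0)
    for (d in c("d01", "d02")) {
      mo <- paste0(d, "m"); ch <- paste0(d, "c")
      hom <- truth$reg_h1[mo, ] == 1L & truth$reg_h2[mo, ] == 1L
      if (any(hom)) expect_true(all(truth$reg_h1[ch, hom] == 1L))
    }
  }
})

test_that("child carrier probability matches the Mendelian/HWE closed form", {
  # region frequency f: maternal transmitted haplotype carries with prob f
  # (a uniformly chosen maternal haplotype is a population haplotype),
  # paternal with prob f; P(child carries >= 1) = 1 - (1 - f)^2
  set.seed(14)
  f <- 0.3
  man <- build_manifest(60, 0, n_chromosomes = 1)
  reg <- simulate_population_cnvs(man, 1, frequency_range = c(f, f))
  n_rep <- 400
  carrier <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    truth <- simulate_cohort(man, reg, n_dyads = 1, n_singletons = 0,
                             de_novo_rate = 0, somatic_discordance_rate = 0)
    carrier[i] <- truth$reg_h1["d01c", 1] == 1L || truth$reg_h2["d01c", 1] == 1L
  }
  p_exact <- 1 - (1 - f)^2
  se <- sqrt(p_exact * (1 - p_exact) / n_rep)
  expect_lt(abs(mean(carrier) - p_exact), 3 * se)
})

test_that("zero rates and zero frequencies give an all-diploid cohort", {
  set.seed(15)
  man <- build_manifest(200, 40, n_chromosomes = 2)
  truth <- simulate_cohort(man, simulate_population_cnvs(man, 0),
                           n_dyads = 1, n_singletons = 1,
                           de_novo_rate = 0, somatic_discordance_rate = 0)
  expect_equal(nrow(truth_table(truth)), 0)
  s <- render_sample(truth, "s01", "blood")
  expect_true(all(s$cn_true == 2L))
})

test_that("somatic discordance is tissue-private and absent at rate zero", {
  set.seed(16)
  man <- build_manifest(300, 50, n_chromosomes = 3)
  reg <- simulate_population_cnvs(man, 5)
  truth0 <- simulate_cohort(man, reg, n_dyads = 2, n_singletons = 2,
                            de_novo_rate = 0, somatic_discordance_rate = 0)
  for (id in truth0$subjects$subject_id) {
    bl <- render_sample(truth0, id, "blood", noise = default_noise(lrr_sd = 1e-12))
    bu <- render_sample(truth0, id, "buccal", noise = default_noise(lrr_sd = 1e-12))
    expect_identical(bl$cn_true, bu$cn_true)
  }
  truth1 <- simulate_cohort(man, reg, n_dyads = 0, n_singletons = 30,
                            de_novo_rate = 0, somatic_discordance_rate = 1)
  som <- truth1$extra_cnvs[truth1$extra_cnvs$origin == "somatic", ]
  expect_equal(nrow(som), 60) # one per sample at rate 1
  expect_true(all(som$tissue %in% c("blood", "buccal")))
})

test_that("truth tables round-trip through TSV", {
  cc <- fixture_cohort()
  tab <- truth_table(cc$truth)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(cc$truth, path)
  back <- read_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # empty truth: header-only file
  set.seed(20)
  man <- build_manifest(100, 0, n_chromosomes = 1)
  t0 <- simulate_cohort(man, simulate_population_cnvs(man, 0), n_dyads = 0,
                        n_singletons = 1, de_novo_rate = 0,
                        somatic_discordance_rate = 0)
  write_truth(t0, path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_truth(path)), 0)
})

test_that("cohort simulation is deterministic under a fixed seed", {
  man <- withr::with_seed(21, build_manifest(200, 30, n_chromosomes = 2))
  reg <- withr::with_seed(22, simulate_population_cnvs(man, 4))
  a <- withr::with_seed(23, simulate_cohort(man, reg, 2, 1))
  b <- withr::with_seed(23, simulate_cohort(man, reg, 2, 1))
  expect_identical(a, b)
  sa <- withr::with_seed(24, render_sample(a, "d01m", "blood"))
  sb <- withr::with_seed(24, render_sample(b, "d01m", "blood"))
  expect_identical(sa, sb)
})
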