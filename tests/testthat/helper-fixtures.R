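# Shared fixtures, built once per test run (everything generated in code).

.fixtures <- new.env(parent = emptyenv())

# small paired-tissue cohort: 3 dyads + 2 singletons on a 6-chromosome,
# 2,340-locus manifest
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    set.seed(4242)
    man <- build_manifest(2000, 340, n_chromosomes = 6)
    reg <- simulate_population_cnvs(man, 12)
    truth <- simulate_cohort(man, reg, n_dyads = 3, n_singletons = 2)
    samples <- simulate_samples(truth)
    .fixtures$cohort <- list(manifest = man, regions = reg, truth = truth,
                             samples = samples)
  }
  .fixtures$cohort
}

# minimal hand-built sample series on one or more chromosomes;
# intensity-only probes by default so the HMM sees the LRR term alone
toy_sample <- function(lrr, pos = seq_along(lrr) * 4500, chrom = 1L,
                       kind = "intensity_only", baf = NA_real_,
                       genotype = NA_character_, quality = NA_real_) {
  n <- length(lrr)
  s <- tibble::tibble(probe = sprintf("p%04d", seq_len(n)),
                      chrom = as.integer(rep_len(chrom, n)),
                      pos = as.numeric(pos),
                      kind = rep_len(kind, n), lrr = lrr,
                      baf = rep_len(baf, n),
                      genotype = rep_len(genotype, n),
                      quality = rep_len(quality, n))
  attr(s, "sample_id") <- "toy"
  s
}

# sample series carrying explicit genotypes (for concordance / QC tests)
genotype_sample <- function(genotypes, kind = "SNP") {
  n <- length(genotypes)
  toy_sample(lrr = rep(0, n), kind = kind, genotype = genotypes,
             quality = rep(0.9, n))
}

# brute-force forward-backward over all K^n state paths, independent of the
# package's recursion: transition A(d) = (1-p) I + p 1 pi'
enum_forward_backward <- function(E, pl, pi) {
  n <- nrow(E); K <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  np <- nrow(paths)
  prob <- pi[paths[, 1]] * E[cbind(rep(1L, np), paths[, 1])]
  if (n > 1) for (t in 2:n) {
    same <- paths[, t - 1] == paths[, t]
    a <- pl[t - 1] * pi[paths[, t]] + ifelse(same, 1 - pl[t - 1], 0)
    prob <- prob * a * E[cbind(rep(t, np), paths[, t])]
  }
  lik <- sum(prob)
  gamma <- matrix(NA_real_, n, K)
  for (t in seq_len(n)) for (k in seq_len(K))
    gamma[t, k] <- sum(prob[paths[, t] == k]) / lik
  list(loglik = log(lik), posterior = gamma,
       best_path = paths[which.max(prob), ])
}

# random emission chain for HMM oracle tests
random_chain <- function(n = 6, K = 6) {
  E <- matrix(runif(n * K, 0.05, 1), n, K)
  pos <- cumsum(round(runif(n, 1000, 2e5)))
  pi <- runif(K); pi <- pi / sum(pi)
  p <- hmm_params()
  pl <- p$leave_prob * (1 - exp(-diff(pos) / p$trans_scale_bp))
  list(E = E, pl = pl, pi = pi)
}
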