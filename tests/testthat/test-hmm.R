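test_that("forward-backward matches brute-force path summation on short chains", {
  set.seed(51)
  for (i in 1:12) {
    ch <- random_chain(n = sample(3:6, 1))
    res <- cnvconcord:::cpp_forward_backward(ch$E, ch$pl, ch$pi)
    oracle <- enum_forward_backward(ch$E, ch$pl, ch$pi)
    expect_equal(res$loglik, oracle$loglik, tolerance = 1e-9)
    expect_equal(res$posterior, oracle$posterior, tolerance = 1e-9)
  }
})

test_that("posteriors are normalized and flat emissions return the prior", {
  cc <- fixture_cohort()
  s <- cc$samples[[1]]
  fb <- forward_backward(s)
  expect_true(all(abs(rowSums(fb$posterior) - 1) < 1e-9))
  expect_true(is.finite(fb$loglik))

  # emissions identical across states: posterior equals the stationary prior
  p <- hmm_params()
  E <- matrix(0.3, 20, 6)
  pl <- rep(5e-5, 19)
  res <- cnvconcord:::cpp_forward_backward(E, pl, unname(p$prior))
  expect_equal(res$posterior,
               matrix(rep(unname(p$prior), each = 20), 20, 6),
               tolerance = 1e-12)

  # single locus: posterior proportional to prior x emission
  E1 <- matrix(runif(6), 1, 6)
  res1 <- cnvconcord:::cpp_forward_backward(E1, numeric(0), unname(p$prior))
  expect_equal(as.numeric(res1$posterior),
               unname(p$prior) * E1[1, ] / sum(unname(p$prior) * E1[1, ]))
})

test_that("viterbi matches the enumerated best path and prefers normal on noise", {
  set.seed(52)
  for (i in 1:10) {
    ch <- random_chain(n = 5)
    path <- cnvconcord:::cpp_viterbi(ch$E, ch$pl, ch$pi, 3L)
    oracle <- enum_forward_backward(ch$E, ch$pl, ch$pi)
    expect_equal(as.integer(path), as.integer(oracle$best_path))
  }
  # diploid noise decodes as all-normal
  s <- toy_sample(rnorm(500, 0, 0.15))
  expect_true(all(viterbi(s) == "2"))
})

test_that("non-monotone positions are rejected", {
  s <- toy_sample(rnorm(5), pos = c(1000, 2000, 1500, 3000, 4000))
  expect_error(forward_backward(s), class = "cnvconcord_argument_error")
  expect_error(viterbi(s), class = "cnvconcord_argument_error")
})

test_that("calls are maximal aberrant runs with sane Bayes factors", {
  set.seed(53)
  # all-normal path: no calls
  s <- toy_sample(rnorm(300, 0, 0.15))
  expect_equal(nrow(call_cnvs(s)), 0)

  # one deletion over a known run
  lrr <- rnorm(300, 0, 0.2)
  lrr[101:130] <- rnorm(30, -0.66, 0.2)
  s <- toy_sample(lrr)
  calls <- call_cnvs(s)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$state, "1")
  expect_equal(calls$n_probes, calls$end_index - calls$start_index + 1L)
  expect_gte(calls$start_index, 99L)
  expect_lte(calls$end_index, 132L)

  # independent check: the LBF should be near the plain emission
  # log-likelihood ratio of the forced CN1 vs CN2 path over the run,
  # which lower-bounds the free numerator up to transition terms
  p <- hmm_params()
  run <- calls$start_index:calls$end_index
  direct <- sum(dnorm(lrr[run], p$lrr_mean["1"], p$lrr_sd["1"], log = TRUE) -
                  dnorm(lrr[run], 0, p$lrr_sd["2"], log = TRUE)) / log(10)
  expect_gt(calls$lbf, 30)
  expect_lt(abs(calls$lbf - direct), 8) # transition + mixing terms only
})

test_that("a strong deletion's LBF exceeds 30", {
  set.seed(54)
  lrr <- c(rnorm(100, 0, 0.2), rnorm(30, -0.66, 0.2), rnorm(100, 0, 0.2))
  calls <- call_cnvs(toy_sample(lrr))
  del <- calls[calls$state == "1", ]
  expect_equal(nrow(del), 1)
  expect_gt(del$lbf, 30)
})

test_that("LBF filtering is nested and order preserving", {
  calls <- tibble::tibble(sample_id = "x", chrom = 1L,
                          start_bp = c(1, 100, 200) * 1e3,
                          end_bp = c(50, 150, 250) * 1e3,
                          start_index = c(1L, 10L, 20L),
                          end_index = c(5L, 15L, 25L),
                          state = c("1", "3", "1"), cn = c(1L, 3L, 1L),
                          n_probes = c(5L, 6L, 6L), lbf = c(5, 15, 35))
  expect_equal(nrow(filter_by_lbf(calls, 30)), 1)
  expect_equal(nrow(filter_by_lbf(calls, 10)), 2)
  f10 <- filter_by_lbf(calls, 10)
  expect_equal(f10$lbf, c(15, 35))
  for (thr in c(10, 30, 50))
    expect_true(all(filter_by_lbf(calls, thr)$lbf %in%
                      filter_by_lbf(calls, thr - 5)$lbf))
})

test_that("HMM segment-mean series follows calls and normal stretches", {
  set.seed(55)
  lrr <- c(rnorm(50, 0, 0.1), rnorm(20, -0.66, 0.1), rnorm(50, 0, 0.1))
  s <- toy_sample(lrr)
  calls <- call_cnvs(s)
  expect_equal(nrow(calls), 1)
  v <- hmm_segment_mean_series(calls, s)
  run <- calls$start_index:calls$end_index
  expect_equal(unique(v[run]), mean(lrr[run]))
  expect_equal(length(unique(v)), 3) # left stretch, call, right stretch
  # no calls: constant at the chromosome mean
  v0 <- hmm_segment_mean_series(calls[0, ], s)
  expect_equal(unique(v0), mean(lrr))
  # idempotence under re-projection
  s2 <- s; s2$lrr <- v
  expect_equal(hmm_segment_mean_series(calls, s2), v)
})

test_that("detection power and false-positive rate meet the design targets", {
  set.seed(56)
  # 200 replicated 20-probe deletions, shift -0.66, noise sd 0.2, with the
  # BAF pattern of a heterozygous deletion (remaining allele A or B)
  hits <- logical(200)
  for (i in 1:200) {
    lrr <- rnorm(240, 0, 0.2)
    lrr[111:130] <- lrr[111:130] - 0.66
    geno2 <- sample(c(0, 0.5, 1), 240, replace = TRUE, prob = c(1, 2, 1) / 4)
    baf <- pmin(1, pmax(0, geno2 + rnorm(240, 0, 0.04)))
    baf[111:130] <- pmin(1, pmax(0, rbinom(20, 1, 0.5) +
                                   rnorm(20, 0, 0.04)))
    s <- toy_sample(lrr, kind = "SNP")
    s$baf <- baf
    calls <- filter_by_lbf(call_cnvs(s), 30)
    hits[i] <- any(calls$state %in% c("0", "1") &
                     calls$start_index <= 130 & calls$end_index >= 111)
  }
  expect_gte(mean(hits), 0.95)

  # pure-noise false calls at LBF >= 30: < 0.1 per 1e4 probes on average
  n_fp <- 0
  for (i in 1:10) {
    s <- toy_sample(rnorm(2e4, 0, 0.2))
    n_fp <- n_fp + nrow(filter_by_lbf(call_cnvs(s), 30))
  }
  expect_lt(n_fp / 20, 0.1) # 2e5 probes total
})
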