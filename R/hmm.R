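#' Parameters of the copy-number HMM
#'
#' A six-state Bayesian hidden Markov model over log R ratio and B allele
#' frequency, in the style of HMM-based array CNV callers: total copy numbers
#' 0-4 plus a copy-neutral loss-of-heterozygosity state ("2-LOH", diploid
#' intensity but homozygous BAF bands only).
#'
#' Emissions are independent given the state: LRR is Gaussian per state; BAF
#' at SNP probes is an equal-weight mixture of Gaussian bands at the allelic
#' ratios the state permits (e.g. \{0, 1/2, 1\} at two copies,
#' \{0, 1/3, 2/3, 1\} at three), plus a uniform outlier component of mass
#' `outlier_mass`; at copy number zero the BAF is uniform. Intensity-only
#' probes contribute the LRR term only.
#'
#' Transitions are distance dependent: over a gap of `d` bp the chain leaves
#' its current state with probability `p(d) = leave_prob * (1 - exp(-d /
#' trans_scale_bp))`, and leave mass is distributed over states in proportion
#' to the stationary weights `prior` (so `prior` is exactly the stationary
#' distribution of the chain, and every transition row sums to one).
#'
#' @param lrr_mean,lrr_sd Per-state Gaussian LRR emission parameters.
#' @param baf_sd Band standard deviation for the BAF emission.
#' @param outlier_mass Uniform outlier mass in the BAF mixture.
#' @param prior Stationary state weights (must sum to 1).
#' @param trans_scale_bp Transition length scale L (bp).
#' @param leave_prob Asymptotic leave probability cap.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(lrr_mean = c(-3, -0.66, 0, 0, 0.4, 0.75),
                       lrr_sd = rep(0.2, 6),
                       baf_sd = 0.04, outlier_mass = 0.01,
                       prior = c(0.001, 0.01, 0.972, 0.002, 0.01, 0.005),
                       trans_scale_bp = 1e5, leave_prob = 1e-3) {
  states <- c("0", "1", "2", "2-LOH", "3", "4")
  stopifnot(length(lrr_mean) == 6, length(lrr_sd) == 6, length(prior) == 6)
  if (any(lrr_sd <= 0) || baf_sd <= 0) stop_arg("emission sds must be > 0")
  if (abs(sum(prior) - 1) > 1e-8 || any(prior <= 0))
    stop_arg("`prior` must be positive and sum to 1")
  if (leave_prob <= 0 || leave_prob >= 1)
    stop_arg("`leave_prob` must be in (0, 1)")
  structure(list(
    states = states,
    cn = c(0L, 1L, 2L, 2L, 3L, 4L),
    normal = 3L,
    lrr_mean = setNames(lrr_mean, states),
    lrr_sd = setNames(lrr_sd, states),
    baf_bands = list(`0` = NULL, `1` = c(0, 1), `2` = c(0, 0.5, 1),
                     `2-LOH` = c(0, 1), `3` = c(0, 1 / 3, 2 / 3, 1),
                     `4` = c(0, 0.25, 0.5, 0.75, 1)),
    baf_sd = baf_sd, outlier_mass = outlier_mass,
    prior = setNames(prior, states),
    trans_scale_bp = trans_scale_bp, leave_prob = leave_prob),
    class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> 6-state copy-number HMM\n")
  print(tibble(state = x$states, cn = x$cn, lrr_mean = unname(x$lrr_mean),
               lrr_sd = unname(x$lrr_sd), prior = unname(x$prior)))
  cat(sprintf("  transitions: p(d) = %g * (1 - exp(-d / %g bp))\n",
              x$leave_prob, x$trans_scale_bp))
  invisible(x)
}

# n x 6 linear emission likelihoods
hmm_emissions <- function(lrr, baf, is_snp, params) {
  n <- length(lrr)
  E <- matrix(1, n, 6, dimnames = list(NULL, params$states))
  ok_lrr <- is.finite(lrr)
  ok_baf <- is_snp & is.finite(baf)
  m <- params$outlier_mass
  for (k in seq_len(6)) {
    e <- rep(1, n)
    e[ok_lrr] <- dnorm(lrr[ok_lrr], params$lrr_mean[k], params$lrr_sd[k])
    bands <- params$baf_bands[[k]]
    if (is.null(bands)) {
      # copy number zero: BAF carries no band structure (uniform on [0, 1])
      eb <- rep(1, n)
    } else {
      eb <- rep(1, n)
      bd <- 0
      for (b in bands) bd <- bd + dnorm(baf[ok_baf], b, params$baf_sd)
      eb[ok_baf] <- (1 - m) * bd / length(bands) + m
    }
    E[, k] <- e * eb
  }
  E
}

# per-step leave probabilities from positions
hmm_pleave <- function(pos, params) {
  params$leave_prob * (1 - exp(-diff(pos) / params$trans_scale_bp))
}

check_positions <- function(sample) {
  for (c_ in unique(sample$chrom)) {
    p <- sample$pos[sample$chrom == c_]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop_arg(sprintf("positions not strictly increasing on chromosome %s",
                       c_))
  }
}

#' Forward-backward posterior state probabilities
#'
#' Runs the scaled forward-backward algorithm independently on each
#' chromosome of a sample (chains restart at the stationary prior at every
#' chromosome start). Computation is performed in scaled space, so series of
#' 1e5+ loci do not underflow.
#'
#' @param sample A sample series tibble (loci sorted by position within
#'   chromosome).
#' @param params An [hmm_params()] object.
#' @return A list: `posterior` (n x 6 matrix, rows sum to 1) and `loglik`
#'   (total log-likelihood over all chromosomes).
#' @export
forward_backward <- function(sample, params = hmm_params()) {
  check_positions(sample)
  n <- nrow(sample)
  gamma <- matrix(NA_real_, n, 6, dimnames = list(NULL, params$states))
  ll <- 0
  for (c_ in unique(sample$chrom)) {
    idx <- which(sample$chrom == c_)
    E <- hmm_emissions(sample$lrr[idx], sample$baf[idx],
                       sample$kind[idx] == "SNP", params)
    pl <- hmm_pleave(sample$pos[idx], params)
    res <- cpp_forward_backward(E, pl, unname(params$prior))
    gamma[idx, ] <- res$posterior
    ll <- ll + res$loglik
  }
  list(posterior = gamma, loglik = ll)
}

#' Most probable copy-number state path
#'
#' Viterbi decoding of the same model as [forward_backward()], per
#' chromosome, with ties broken toward the normal (two-copy) state.
#'
#' @inheritParams forward_backward
#' @return Character vector of state labels, one per locus.
#' @export
viterbi <- function(sample, params = hmm_params()) {
  check_positions(sample)
  path <- integer(nrow(sample))
  for (c_ in unique(sample$chrom)) {
    idx <- which(sample$chrom == c_)
    E <- hmm_emissions(sample$lrr[idx], sample$baf[idx],
                       sample$kind[idx] == "SNP", params)
    pl <- hmm_pleave(sample$pos[idx], params)
    path[idx] <- cpp_viterbi(E, pl, unname(params$prior), params$normal)
  }
  params$states[path]
}

# log10 Bayes factor of one aberrant run versus forced normal copy number.
# Both terms are restricted forward sums over the run, started from the
# posterior at the locus preceding the run (propagated one transition step),
# or from the stationary prior at a chromosome start. The numerator sums over
# all state paths; the denominator forces the normal state throughout.
run_lbf <- function(E, pl, w, prior, normal) {
  m <- nrow(E)
  la <- log(w) + log(E[1, ])
  lforced <- log(w[normal]) + log(E[1, normal])
  if (m > 1) for (t in 2:m) {
    p <- pl[t - 1]
    mx <- max(la)
    tot <- sum(exp(la - mx))
    pred <- (1 - p) * exp(la - mx) + p * prior * tot
    la <- mx + log(pred) + log(E[t, ])
    lforced <- lforced + log((1 - p) + p * prior[normal]) + log(E[t, normal])
  }
  (logsumexp(la) - lforced) / log(10)
}

#' Call CNVs from the decoded state path
#'
#' Decodes the sample with [viterbi()] (or uses a supplied path), turns every
#' maximal run of a non-normal state into one call, and attaches to each call
#' a log10 Bayes factor: the evidence for the data over the run under the
#' unrestricted model versus the same model with every locus forced to the
#' normal two-copy state, both conditioned on the posterior at the flanking
#' locus. Calls never span chromosome boundaries; adjacent runs of different
#' aberrant states are reported separately.
#'
#' @inheritParams forward_backward
#' @param path Optional pre-computed state-label path (as from [viterbi()]).
#' @return Tibble of calls: `sample_id, chrom, start_bp, end_bp, start_index,
#'   end_index, state, cn, n_probes, lbf` (empty when the path is all
#'   normal).
#' @export
call_cnvs <- function(sample, params = hmm_params(), path = NULL) {
  check_positions(sample)
  sid <- attr(sample, "sample_id") %||% NA_character_
  acc <- list(chrom = integer(), s = integer(), e = integer(),
              state = integer(), lbf = numeric())
  for (c_ in unique(sample$chrom)) {
    idx <- which(sample$chrom == c_)
    E <- hmm_emissions(sample$lrr[idx], sample$baf[idx],
                       sample$kind[idx] == "SNP", params)
    pl <- hmm_pleave(sample$pos[idx], params)
    pr <- unname(params$prior)
    if (is.null(path)) {
      cpath <- cpp_viterbi(E, pl, pr, params$normal)
    } else {
      cpath <- match(path[idx], params$states)
    }
    gamma <- NULL
    r <- rle(cpath)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values != params$normal)) {
      s <- starts[j]; e <- ends[j]
      if (s == 1L) {
        w <- pr
      } else {
        if (is.null(gamma))
          gamma <- cpp_forward_backward(E, pl, pr)$posterior
        p0 <- pl[s - 1]
        w <- (1 - p0) * gamma[s - 1, ] + p0 * pr
      }
      lbf <- run_lbf(E[s:e, , drop = FALSE],
                     if (e > s) pl[s:(e - 1)] else numeric(0),
                     w, pr, params$normal)
      k <- length(acc$s) + 1L
      acc$chrom[[k]] <- c_; acc$s[[k]] <- idx[s]; acc$e[[k]] <- idx[e]
      acc$state[[k]] <- r$values[j]; acc$lbf[[k]] <- lbf
    }
  }
  tibble(sample_id = rep(sid, length(acc$s)), chrom = acc$chrom,
         start_bp = sample$pos[acc$s], end_bp = sample$pos[acc$e],
         start_index = acc$s, end_index = acc$e,
         state = params$states[acc$state], cn = params$cn[acc$state],
         n_probes = acc$e - acc$s + 1L, lbf = acc$lbf)
}

#' Filter CNV calls by log10 Bayes factor
#'
#' @param calls A call tibble from [call_cnvs()].
#' @param threshold Minimum LBF to retain.
#' @return The retained calls, order preserved. Filters are nested: the call
#'   set at a higher threshold is a subset of the set at any lower one.
#' @export
filter_by_lbf <- function(calls, threshold) {
  calls[calls$lbf >= threshold, , drop = FALSE]
}

#' Segment-mean series implied by a set of CNV calls
#'
#' Builds a per-locus piecewise-constant series from filtered calls: loci
#' inside a retained call get the mean LRR over the call's loci; loci outside
#' any call get the mean LRR of their maximal surrounding non-call stretch on
#' the chromosome. With no calls the series is constant per chromosome at
#' the chromosome mean.
#'
#' @param calls Filtered calls (see [filter_by_lbf()]).
#' @param sample The sample the calls were made on.
#' @return Numeric vector, one value per locus.
#' @export
hmm_segment_mean_series <- function(calls, sample) {
  n <- nrow(sample)
  v <- numeric(n)
  for (c_ in unique(sample$chrom)) {
    idx <- which(sample$chrom == c_)
    in_call <- rep(FALSE, length(idx))
    cc <- calls[calls$chrom == c_, , drop = FALSE]
    for (j in seq_len(nrow(cc))) {
      rel <- (cc$start_index[j]:cc$end_index[j]) - idx[1] + 1L
      in_call[rel] <- TRUE
      v[cc$start_index[j]:cc$end_index[j]] <-
        mean(sample$lrr[cc$start_index[j]:cc$end_index[j]], na.rm = TRUE)
    }
    r <- rle(in_call)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(!r$values)) {
      gi <- idx[starts[j]:ends[j]]
      v[gi] <- mean(sample$lrr[gi], na.rm = TRUE)
    }
  }
  v
}
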