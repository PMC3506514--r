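#' Default segmentation penalty (BIC-style)
#'
#' `2 * sigma^2 * log(n)`, with `sigma` estimated robustly from first
#' differences of the series (`mad(diff(x)) / sqrt(2)`), so that isolated
#' copy-number steps do not inflate the noise estimate.
#'
#' @param x Numeric LRR series.
#' @return A single penalty value.
#' @export
bic_penalty <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  sigma <- mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- sd(x)
  if (!is.finite(sigma) || sigma == 0) return(0)
  2 * sigma^2 * log(n)
}

segmentation_tibble <- function(x, ends) {
  starts <- c(1L, head(ends, -1) + 1L)
  cs <- c(0, cumsum(x))
  tibble::new_tibble(list(
    segment = seq_along(ends), start = as.integer(starts),
    end = as.integer(ends), n_loci = as.integer(ends - starts + 1L),
    mean = (cs[ends + 1] - cs[starts]) / (ends - starts + 1)),
    nrow = length(ends))
}

#' Exact penalized optimal segmentation of an LRR series
#'
#' Partitions a series into contiguous constant-mean segments by minimizing
#' the total within-segment sum of squared deviations plus `penalty` per
#' segment. The global optimum of this objective is found by dynamic
#' programming (O(n^2)); ties are broken toward fewer segments, then toward
#' the earliest admissible rightmost breakpoint, applied recursively.
#'
#' @param x Numeric series (one chromosome); must be finite — impute or drop
#'   missing values upstream (see [segment_sample()]).
#' @param penalty Non-negative penalty per segment; default [bic_penalty()].
#' @param min_seg Minimum loci per segment (series shorter than `min_seg`
#'   yield a single segment).
#' @param max_lookback Optional cap on segment length in loci (windowed
#'   approximation for very long series); `Inf` (the default) is the exact,
#'   tested contract.
#' @return Tibble with one row per segment: `segment, start, end, n_loci,
#'   mean` (indices 1-based, inclusive; `mean` is the arithmetic mean of the
#'   member loci).
#' @examples
#' optimal_segmentation(c(1, 1, 1, 9, 9, 9), penalty = 1)
#' @seealso [brute_force_segmentation()] for the exhaustive reference
#'   implementation used in tests.
#' @export
optimal_segmentation <- function(x, penalty = NULL, min_seg = 1,
                                 max_lookback = Inf) {
  if (length(x) == 0) stop_arg("`x` must be non-empty")
  if (any(!is.finite(x)))
    stop_arg("`x` must be finite; handle missing values upstream")
  min_seg <- check_count(min_seg, "min_seg", min = 1)
  penalty <- penalty %||% bic_penalty(x)
  if (!is.finite(penalty) || penalty < 0) stop_arg("`penalty` must be >= 0")
  lb <- if (is.finite(max_lookback)) as.integer(max_lookback) else 0L
  ends <- cpp_dp_segment(as.numeric(x), penalty, min_seg, lb)
  segmentation_tibble(x, ends)
}

#' Exhaustive-enumeration segmentation (testing oracle)
#'
#' Minimizes the same objective as [optimal_segmentation()] by enumerating
#' all 2^(n-1) partitions of the series, with the same tie-breaking rule.
#' Exposed as an independent reference implementation for short series.
#'
#' @inheritParams optimal_segmentation
#' @param max_n Enumeration bound on `length(x)`.
#' @return Same shape as [optimal_segmentation()].
#' @export
brute_force_segmentation <- function(x, penalty = NULL, min_seg = 1,
                                     max_n = 14) {
  n <- length(x)
  if (n == 0) stop_arg("`x` must be non-empty")
  if (n > max_n)
    stop_arg(sprintf("series length %d exceeds enumeration bound %d", n, max_n))
  if (any(!is.finite(x))) stop_arg("`x` must be finite")
  penalty <- penalty %||% bic_penalty(x)
  if (n < min_seg) return(segmentation_tibble(x, n))

  # cost of every [a, b] segment, computed directly (no shared code with DP)
  costm <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in a:n) {
    xs <- x[a:b]
    costm[a, b] <- sum((xs - mean(xs))^2)
  }
  bits <- 2^(0:(n - 2))
  best_cost <- Inf; best_ends <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    breaks <- if (n > 1) which(bitwAnd(mask, bits) != 0) else integer(0)
    ends <- c(breaks, n)
    starts <- c(1L, breaks + 1L)
    if (any(ends - starts + 1L < min_seg)) next
    cost <- sum(costm[cbind(starts, ends)]) + penalty * length(ends)
    take <- FALSE
    if (cost < best_cost) take <- TRUE
    else if (cost == best_cost) {
      if (length(ends) < length(best_ends)) take <- TRUE
      else if (length(ends) == length(best_ends)) {
        # earliest rightmost breakpoint, recursively
        d <- rev(ends) - rev(best_ends)
        nz <- which(d != 0)
        if (length(nz) && d[nz[1]] < 0) take <- TRUE
      }
    }
    if (take) { best_cost <- cost; best_ends <- ends }
  }
  if (is.null(best_ends)) return(segmentation_tibble(x, n))
  segmentation_tibble(x, best_ends)
}

#' Objective value of a segmentation
#'
#' @param x Numeric series.
#' @param seg Segmentation tibble.
#' @param penalty Penalty per segment.
#' @return Total within-segment SSE plus `penalty * nrow(seg)`.
#' @export
segmentation_objective <- function(x, seg, penalty) {
  sse <- sum(vapply(seq_len(nrow(seg)), function(i) {
    xs <- x[seg$start[i]:seg$end[i]]
    sum((xs - mean(xs))^2)
  }, numeric(1)))
  sse + penalty * nrow(seg)
}

#' Project segment means back onto loci
#'
#' @param seg Segmentation tibble (columns `start`, `end`, `mean`) that tiles
#'   `1:n_loci` without gaps or overlaps.
#' @param n_loci Series length.
#' @return Numeric vector of length `n_loci`; `out[i]` is the mean of the
#'   segment containing locus `i`.
#' @export
project_segment_means <- function(seg, n_loci) {
  seg <- arrange(seg, .data$start)
  if (nrow(seg) == 0 || seg$start[1] != 1 || seg$end[nrow(seg)] != n_loci ||
      (nrow(seg) > 1 && any(seg$start[-1] != seg$end[-nrow(seg)] + 1)))
    stop_structural("segmentation does not tile 1:n_loci")
  rep(seg$mean, seg$end - seg$start + 1)
}

#' Segment every chromosome of a sample
#'
#' Applies [optimal_segmentation()] independently to each chromosome of a
#' sample's LRR series (each sample, and each chromosome, is segmented on its
#' own). Loci with missing LRR are dropped for fitting and assigned the
#' enclosing segment's mean at projection, so series lengths stay aligned
#' across samples.
#'
#' @param sample A sample series tibble (see [render_sample()] /
#'   [read_final_report()]).
#' @inheritParams optimal_segmentation
#' @return Tibble with one row per segment: `chrom, start_idx, end_idx`
#'   (global row indices into the sample), `start_bp, end_bp, n_probes,
#'   seg_mean`.
#' @export
segment_sample <- function(sample, penalty = NULL, min_seg = 1,
                           max_lookback = Inf) {
  out <- list()
  for (c_ in unique(sample$chrom)) {
    idx <- which(sample$chrom == c_)
    xs <- sample$lrr[idx]
    keep <- which(is.finite(xs))
    if (length(keep) == 0) {
      out[[length(out) + 1]] <- tibble(
        chrom = c_, start_idx = idx[1], end_idx = idx[length(idx)],
        start_bp = sample$pos[idx[1]], end_bp = sample$pos[idx[length(idx)]],
        n_probes = length(idx), seg_mean = NA_real_)
      next
    }
    seg <- optimal_segmentation(xs[keep], penalty = penalty,
                                min_seg = min_seg,
                                max_lookback = max_lookback)
    # map kept-space segment ends back to the full locus range; loci dropped
    # between segments attach to the segment on their left
    ends_full <- keep[seg$end]
    ends_full[nrow(seg)] <- length(idx)
    starts_full <- c(1L, head(ends_full, -1) + 1L)
    out[[length(out) + 1]] <- tibble::new_tibble(list(
      chrom = rep(c_, nrow(seg)), start_idx = idx[starts_full],
      end_idx = idx[ends_full],
      start_bp = sample$pos[idx[starts_full]],
      end_bp = sample$pos[idx[ends_full]],
      n_probes = as.integer(ends_full - starts_full + 1L),
      seg_mean = seg$mean), nrow = nrow(seg))
  }
  bind_rows(out)
}

#' Segment-mean series for a whole sample
#'
#' @param sample A sample series tibble.
#' @param segments Output of [segment_sample()] for that sample.
#' @return Numeric vector, one value per locus of the sample, piecewise
#'   constant on the segments.
#' @export
segment_mean_series <- function(sample, segments) {
  n <- nrow(sample)
  v <- rep(NA_real_, n)
  for (i in seq_len(nrow(segments)))
    v[segments$start_idx[i]:segments$end_idx[i]] <- segments$seg_mean[i]
  if (anyNA(v)) stop_structural("segments do not cover every locus")
  v
}
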