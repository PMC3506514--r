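#' Default per-sample noise model
#'
#' `lrr_sd` is the per-locus Gaussian standard deviation of the log R ratio
#' (log2 units) for blood samples; buccal samples are rendered with
#' `lrr_sd * buccal_multiplier`, reflecting the somewhat lower and more
#' variable DNA quality of swab samples while defaulting near parity.
#' `wave_amplitude` adds an optional long-range sinusoidal "genomic wave"
#' (period `wave_period_bp`), off by default. `batch_offset_sd`, also off by
#' default, adds a per-sample constant LRR offset standing in for chip/batch
#' effects.
#'
#' @param lrr_sd,baf_sd,wave_amplitude,wave_period_bp,buccal_multiplier,batch_offset_sd
#'   Noise parameters; see Details.
#' @return A named list of noise parameters.
#' @export
default_noise <- function(lrr_sd = 0.18, baf_sd = 0.04, wave_amplitude = 0,
                          wave_period_bp = 5e5, buccal_multiplier = 1.25,
                          batch_offset_sd = 0) {
  list(lrr_sd = lrr_sd, baf_sd = baf_sd, wave_amplitude = wave_amplitude,
       wave_period_bp = wave_period_bp, buccal_multiplier = buccal_multiplier,
       batch_offset_sd = batch_offset_sd)
}

#' Default genotype-quality model
#'
#' GenCall-like per-genotype confidence scores are drawn from a
#' Beta(alpha, beta) distribution, independent of genotype; genotypes with a
#' score at or below `nocall_threshold` are masked to no-calls. The default
#' Beta(3.2, 1) puts about 0.23% of its mass at or below 0.15, so genotype
#' call rates sit near 99.8%, typical of a high-quality array run.
#'
#' @param alpha,beta Beta distribution parameters (> 0).
#' @param nocall_threshold Scores at or below this value become no-calls.
#' @return A named list of quality-model parameters.
#' @export
default_quality_model <- function(alpha = 3.2, beta = 1,
                                  nocall_threshold = 0.15) {
  list(alpha = alpha, beta = beta, nocall_threshold = nocall_threshold)
}

#' Default LRR state means
#'
#' Mean log R ratio per total copy number 0-4: 0 at two copies, and
#' `0.55 * log2(cn / 2)` for one to four copies — a bounded, monotone
#' attenuation of the ideal log2 response resembling the compressed dynamic
#' range of array intensities. Copy number zero is floored at -3 (the ideal
#' value is minus infinity).
#'
#' @return Named numeric vector of length 5 (names `"0"` to `"4"`).
#' @export
default_lrr_means <- function() {
  c(`0` = -3, `1` = 0.55 * log2(1 / 2), `2` = 0,
    `3` = 0.55 * log2(3 / 2), `4` = 0.55 * log2(4 / 2))
}

# per-locus total copy number and per-haplotype copies for one sample
sample_copy_state <- function(truth, subject_id, tissue) {
  man <- truth$manifest
  n <- nrow(man)
  h1 <- rep(1L, n); h2 <- rep(1L, n)
  n_reg <- nrow(truth$regions)
  if (n_reg > 0) {
    hc <- hap_copies_of(truth$regions$variant_copy)
    for (j in seq_len(n_reg)) {
      idx <- loci_in_interval(man, truth$regions$chrom[j],
                              truth$regions$start_bp[j],
                              truth$regions$end_bp[j])
      if (truth$reg_h1[subject_id, j] == 1L) h1[idx] <- hc[j]
      if (truth$reg_h2[subject_id, j] == 1L) h2[idx] <- hc[j]
    }
  }
  ex <- truth$extra_cnvs
  ex <- ex[ex$subject_id == subject_id & ex$tissue %in% c("both", tissue), ,
           drop = FALSE]
  if (nrow(ex) > 0) {
    for (j in seq_len(nrow(ex))) {
      idx <- loci_in_interval(man, ex$chrom[j], ex$start_bp[j], ex$end_bp[j])
      h1[idx] <- as.integer(ceiling(ex$cn[j] / 2))
      h2[idx] <- as.integer(floor(ex$cn[j] / 2))
    }
  }
  cn <- clamp(h1 + h2, 0L, 4L)
  list(h1 = h1, h2 = h2, cn = cn)
}

#' Render one array sample from the cohort truth
#'
#' Produces a per-locus sample series — log R ratio, B allele frequency,
#' genotype, and quality score — for one subject and tissue. The LRR at each
#' locus is the state mean for the locus's true total copy number plus
#' Gaussian noise (plus optional wave/batch terms). The BAF is drawn around
#' the band implied by the B-allele dosage at the locus's copy number (e.g.
#' \{0, 1/2, 1\} at two copies, \{0, 1\} at one copy, \{0, 1/3, 2/3, 1\} at
#' three), truncated to [0, 1]; at copy number zero the BAF is uniform.
#' Genotypes are the true germline genotypes, masked to `"NC"` where the
#' quality score falls at or below the no-call threshold. Intensity-only
#' probes carry an LRR but no genotype, quality, or BAF.
#'
#' @param truth A `cohort_truth` object.
#' @param subject_id,tissue Which sample to render.
#' @param noise See [default_noise()].
#' @param quality_model See [default_quality_model()].
#' @param lrr_means State mean LRRs, see [default_lrr_means()].
#' @return A tibble with one row per manifest locus: `probe, chrom, pos,
#'   kind, cn_true, lrr, baf, genotype, quality`, with attributes
#'   `sample_id`, `subject_id`, `tissue`.
#' @examples
#' set.seed(1)
#' man <- build_manifest(400, 60, n_chromosomes = 2)
#' truth <- simulate_cohort(man, simulate_population_cnvs(man, 3),
#'                          n_dyads = 1, n_singletons = 0)
#' s <- render_sample(truth, "d01m", "blood")
#' head(s)
#' @export
render_sample <- function(truth, subject_id, tissue,
                          noise = default_noise(),
                          quality_model = default_quality_model(),
                          lrr_means = default_lrr_means()) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!any(truth$metadata$subject_id == subject_id &
             truth$metadata$tissue == tissue))
    abort(sprintf("no sample for subject '%s', tissue '%s'", subject_id,
                  tissue),
          class = "cnvconcord_lookup_error")
  if (!is.finite(noise$lrr_sd) || noise$lrr_sd < 0)
    stop_arg("`noise$lrr_sd` must be >= 0")

  man <- truth$manifest
  n <- nrow(man)
  st <- sample_copy_state(truth, subject_id, tissue)
  mult <- if (tissue == "buccal") noise$buccal_multiplier else 1
  mu <- unname(lrr_means[as.character(st$cn)])
  lrr <- mu + rnorm(n, 0, noise$lrr_sd * mult)
  if (noise$wave_amplitude > 0)
    lrr <- lrr + noise$wave_amplitude *
      sin(2 * pi * man$pos / noise$wave_period_bp)
  if (noise$batch_offset_sd > 0) lrr <- lrr + rnorm(1, 0, noise$batch_offset_sd)

  is_snp <- man$kind == "SNP"
  snp_pos <- which(is_snp)
  # B-allele dosage from phased alleles and per-haplotype copies
  a1 <- a2 <- integer(n)
  a1[snp_pos] <- truth$snp_h1[subject_id, ]
  a2[snp_pos] <- truth$snp_h2[subject_id, ]
  bcop <- a1 * st$h1 + a2 * st$h2
  bfrac <- ifelse(st$cn > 0, bcop / st$cn, NA_real_)
  baf <- rep(NA_real_, n)
  u <- runif(n) # uniform BAF at copy-number zero
  eps <- rnorm(n, 0, noise$baf_sd)
  baf[is_snp] <- ifelse(st$cn[is_snp] == 0, u[is_snp],
                        clamp(bfrac[is_snp] + eps[is_snp], 0, 1))

  quality <- rep(NA_real_, n)
  quality[is_snp] <- rbeta(sum(is_snp), quality_model$alpha,
                           quality_model$beta)
  geno <- rep(NA_character_, n)
  geno[is_snp] <- c("AA", "AB", "BB")[a1[is_snp] + a2[is_snp] + 1L]
  geno[which(is_snp & quality <= quality_model$nocall_threshold)] <- "NC"

  out <- tibble(probe = man$probe, chrom = man$chrom, pos = man$pos,
                kind = man$kind, cn_true = as.integer(st$cn), lrr = lrr,
                baf = baf, genotype = geno, quality = quality)
  attr(out, "sample_id") <- paste0(subject_id, "_", tissue)
  attr(out, "subject_id") <- subject_id
  attr(out, "tissue") <- tissue
  out
}

#' Render every sample of a cohort
#'
#' @inheritParams render_sample
#' @return A named list of sample tibbles (names are `sample_id`s, in
#'   `truth$metadata` order).
#' @export
simulate_samples <- function(truth, noise = default_noise(),
                             quality_model = default_quality_model(),
                             lrr_means = default_lrr_means()) {
  md <- truth$metadata
  out <- vector("list", nrow(md))
  for (i in seq_len(nrow(md)))
    out[[i]] <- render_sample(truth, md$subject_id[i], md$tissue[i],
                              noise = noise, quality_model = quality_model,
                              lrr_means = lrr_means)
  names(out) <- md$sample_id
  out
}
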