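#' Simulate common population CNV regions
#'
#' Places non-overlapping copy-number-variable regions on the manifest, each
#' with a population (per-haplotype) frequency, emulating the common CNVs that
#' are shared by multiple individuals in a population and that drive the
#' positive correlation observed even between unrelated samples.
#'
#' Region sizes (kb) are log-normal with the requested mean and dispersion
#' (sdlog). Each region is anchored at a manifest locus so it always spans at
#' least one probe. `variant_copy` is the total copy number of a typical
#' aberrant carrier: values below 2 mark deletion haplotypes (0 copies on the
#' variant haplotype), values above 2 mark duplication haplotypes
#' (`variant_copy - 1` copies).
#'
#' @param manifest Probe manifest.
#' @param n_regions Number of regions (>= 0).
#' @param frequency_range Length-2 vector, per-haplotype frequency bounds in
#'   (0, 1); frequencies are drawn uniformly.
#' @param size_distribution Length-2 vector `c(mean_kb, dispersion)`: mean
#'   region size in kb and log-normal sdlog.
#' @param variant_copy_probs Named probabilities over variant copy classes
#'   `"0"`, `"1"`, `"3"`, `"4"` (unnamed classes get probability 0).
#' @return Tibble: `region_id, chrom, start_bp, end_bp, variant_copy,
#'   frequency`, sorted by position; zero-row tibble when `n_regions = 0`.
#' @examples
#' set.seed(1)
#' man <- build_manifest(2000, 300, n_chromosomes = 6)
#' simulate_population_cnvs(man, n_regions = 10)
#' @export
simulate_population_cnvs <- function(manifest, n_regions,
                                     frequency_range = c(0.05, 0.4),
                                     size_distribution = c(100, 0.6),
                                     variant_copy_probs = c("1" = 0.6,
                                                            "3" = 0.3,
                                                            "4" = 0.1)) {
  n_regions <- check_count(n_regions, "n_regions", min = 0)
  if (nrow(manifest) == 0) stop_arg("`manifest` must be non-empty")
  if (length(frequency_range) != 2 || any(frequency_range <= 0) ||
      any(frequency_range >= 1) || frequency_range[1] > frequency_range[2])
    stop_arg("`frequency_range` must be increasing within (0, 1)")
  empty <- tibble(region_id = character(), chrom = integer(),
                  start_bp = numeric(), end_bp = numeric(),
                  variant_copy = integer(), frequency = numeric())
  if (n_regions == 0) return(empty)

  mean_kb <- size_distribution[1]
  disp <- size_distribution[2]
  meanlog <- log(mean_kb) - disp^2 / 2
  copy_classes <- as.integer(names(variant_copy_probs))

  chrom_tab <- table(factor(manifest$chrom, levels = sort(unique(manifest$chrom))))
  chroms <- as.integer(names(chrom_tab))
  placed <- vector("list", n_regions)
  taken <- list() # per chromosome: matrix of (start, end)
  tries <- 0L
  max_tries <- 200L * n_regions
  i <- 1L
  while (i <= n_regions) {
    tries <- tries + 1L
    if (tries > max_tries)
      abort("could not place non-overlapping CNV regions (infeasible packing)",
            class = "cnvconcord_generation_error")
    chrom <- chroms[sample.int(length(chroms), 1, prob = as.numeric(chrom_tab))]
    loci <- manifest$pos[manifest$chrom == chrom]
    start <- loci[sample.int(length(loci), 1)]
    size_bp <- max(1000, round(rlnorm(1, meanlog, disp) * 1000))
    end <- start + size_bp - 1
    prev <- taken[[as.character(chrom)]]
    if (!is.null(prev) && any(start <= prev[, 2] & end >= prev[, 1])) next
    taken[[as.character(chrom)]] <- rbind(prev, c(start, end))
    placed[[i]] <- tibble(
      chrom = chrom, start_bp = start, end_bp = end,
      variant_copy = sample(copy_classes, 1, prob = variant_copy_probs),
      frequency = runif(1, frequency_range[1], frequency_range[2]))
    i <- i + 1L
  }
  out <- bind_rows(placed) |> arrange(.data$chrom, .data$start_bp)
  out$region_id <- sprintf("cnvr%03d", seq_len(n_regions))
  select(out, "region_id", "chrom", "start_bp", "end_bp", "variant_copy",
         "frequency")
}

# copies carried by a variant haplotype of a region
hap_copies_of <- function(variant_copy) {
  ifelse(variant_copy < 2, 0L, as.integer(variant_copy) - 1L)
}

#' Simulate a paired-tissue, dyad-structured cohort
#'
#' Builds the genetic truth for a cohort of mother-infant dyads and unrelated
#' singletons where every subject contributes both a blood and a buccal
#' sample. Each subject receives two haplotypes: CNV-region carrier indicators
#' drawn under Hardy-Weinberg equilibrium at each region's frequency, and SNP
#' alleles drawn at per-SNP minor-allele frequencies. A child's maternal
#' haplotype is copied from one of its mother's two haplotypes, chosen with
#' probability 1/2 independently per chromosome (no intra-chromosome
#' recombination); the paternal haplotype is drawn from the population.
#' De novo CNVs (shared by both tissues) and tissue-private somatic CNVs are
#' appended at the stated per-subject / per-sample rates.
#'
#' @param manifest Probe manifest.
#' @param regions Population CNV regions from [simulate_population_cnvs()].
#' @param n_dyads Number of mother-infant dyads.
#' @param n_singletons Number of unrelated singleton subjects.
#' @param de_novo_rate Per-subject probability of one de novo CNV.
#' @param somatic_discordance_rate Per-sample probability of one
#'   tissue-private somatic CNV.
#' @param snp_maf_range Uniform bounds for per-SNP B-allele frequencies.
#' @param extra_cnv_size `c(mean_kb, dispersion)` for de novo / somatic CNV
#'   sizes (log-normal, as in [simulate_population_cnvs()]).
#' @return A `cohort_truth` object: list with `manifest`, `regions`,
#'   `subjects`, `metadata` (one row per sample: `sample_id, subject_id,
#'   tissue, dyad_id, role`), per-subject haplotype matrices, `extra_cnvs`,
#'   and `maf`.
#' @examples
#' set.seed(1)
#' man <- build_manifest(1000, 150, n_chromosomes = 4)
#' reg <- simulate_population_cnvs(man, 6)
#' truth <- simulate_cohort(man, reg, n_dyads = 2, n_singletons = 1)
#' truth$metadata
#' @export
simulate_cohort <- function(manifest, regions, n_dyads = 16, n_singletons = 7,
                            de_novo_rate = 0.05,
                            somatic_discordance_rate = 0.05,
                            snp_maf_range = c(0.05, 0.5),
                            extra_cnv_size = c(100, 0.6)) {
  n_dyads <- check_count(n_dyads, "n_dyads", min = 0)
  n_singletons <- check_count(n_singletons, "n_singletons", min = 0)
  check_fraction(de_novo_rate, "de_novo_rate")
  check_fraction(somatic_discordance_rate, "somatic_discordance_rate")
  if (n_dyads + n_singletons == 0) stop_arg("cohort must contain >= 1 subject")

  subjects <- bind_rows(
    if (n_dyads > 0) tibble(
      subject_id = sprintf("d%02dm", seq_len(n_dyads)),
      dyad_id = sprintf("d%02d", seq_len(n_dyads)), role = "mother"),
    if (n_dyads > 0) tibble(
      subject_id = sprintf("d%02dc", seq_len(n_dyads)),
      dyad_id = sprintf("d%02d", seq_len(n_dyads)), role = "child"),
    if (n_singletons > 0) tibble(
      subject_id = sprintf("s%02d", seq_len(n_singletons)),
      dyad_id = NA_character_, role = "singleton"))
  subjects$sex <- ifelse(subjects$role == "mother", "F",
                         sample(c("F", "M"), nrow(subjects), replace = TRUE))
  ns <- nrow(subjects)
  snp_idx <- which(manifest$kind == "SNP")
  n_snp <- length(snp_idx)
  snp_chrom <- manifest$chrom[snp_idx]
  n_reg <- nrow(regions)
  maf <- runif(n_snp, snp_maf_range[1], snp_maf_range[2])

  snp_h1 <- matrix(0L, ns, n_snp); snp_h2 <- matrix(0L, ns, n_snp)
  reg_h1 <- matrix(0L, ns, max(1, n_reg))[, seq_len(n_reg), drop = FALSE]
  reg_h2 <- reg_h1
  rownames(snp_h1) <- rownames(snp_h2) <- subjects$subject_id
  if (n_reg > 0) rownames(reg_h1) <- rownames(reg_h2) <- subjects$subject_id

  draw_hap <- function() {
    list(snp = rbinom(n_snp, 1L, maf),
         reg = if (n_reg > 0) rbinom(n_reg, 1L, regions$frequency) else integer(0))
  }
  founders <- subjects$subject_id[subjects$role != "child"]
  for (id in founders) {
    h1 <- draw_hap(); h2 <- draw_hap()
    snp_h1[id, ] <- h1$snp; snp_h2[id, ] <- h2$snp
    if (n_reg > 0) { reg_h1[id, ] <- h1$reg; reg_h2[id, ] <- h2$reg }
  }
  chroms <- sort(unique(manifest$chrom))
  for (d in seq_len(n_dyads)) {
    mo <- sprintf("d%02dm", d); ch <- sprintf("d%02dc", d)
    transmit <- sample(1:2, length(chroms), replace = TRUE)
    mo_snp <- rbind(snp_h1[mo, ], snp_h2[mo, ])
    mo_reg <- if (n_reg > 0) rbind(reg_h1[mo, ], reg_h2[mo, ]) else NULL
    maternal_snp <- integer(n_snp)
    maternal_reg <- integer(n_reg)
    for (ci in seq_along(chroms)) {
      s_sel <- snp_chrom == chroms[ci]
      maternal_snp[s_sel] <- mo_snp[transmit[ci], s_sel]
      if (n_reg > 0) {
        r_sel <- regions$chrom == chroms[ci]
        maternal_reg[r_sel] <- mo_reg[transmit[ci], r_sel]
      }
    }
    pat <- draw_hap()
    snp_h1[ch, ] <- maternal_snp
    snp_h2[ch, ] <- pat$snp
    if (n_reg > 0) { reg_h1[ch, ] <- maternal_reg; reg_h2[ch, ] <- pat$reg }
  }

  metadata <- tidyr::expand_grid(subjects, tissue = c("blood", "buccal")) |>
    mutate(sample_id = paste0(.data$subject_id, "_", .data$tissue)) |>
    select("sample_id", "subject_id", "tissue", "dyad_id", "role", "sex")

  # de novo (germline, both tissues) and somatic (tissue-private) extras
  draw_interval <- function() {
    chrom_tab <- table(manifest$chrom)
    chrom <- as.integer(names(chrom_tab))[
      sample.int(length(chrom_tab), 1, prob = as.numeric(chrom_tab))]
    loci <- manifest$pos[manifest$chrom == chrom]
    start <- loci[sample.int(length(loci), 1)]
    size_bp <- max(1000, round(rlnorm(1, log(extra_cnv_size[1]) -
                                        extra_cnv_size[2]^2 / 2,
                                      extra_cnv_size[2]) * 1000))
    tibble(chrom = chrom, start_bp = start, end_bp = start + size_bp - 1,
           cn = sample(c(1L, 3L), 1))
  }
  extras <- list()
  for (id in subjects$subject_id) {
    if (rbinom(1, 1, de_novo_rate) == 1)
      extras[[length(extras) + 1]] <-
        mutate(draw_interval(), subject_id = id, tissue = "both",
               origin = "de_novo")
  }
  for (j in seq_len(nrow(metadata))) {
    if (rbinom(1, 1, somatic_discordance_rate) == 1)
      extras[[length(extras) + 1]] <-
        mutate(draw_interval(), subject_id = metadata$subject_id[j],
               tissue = metadata$tissue[j], origin = "somatic")
  }
  extra_cnvs <- if (length(extras)) {
    bind_rows(extras) |>
      select("subject_id", "tissue", "chrom", "start_bp", "end_bp", "cn",
             "origin")
  } else {
    tibble(subject_id = character(), tissue = character(), chrom = integer(),
           start_bp = numeric(), end_bp = numeric(), cn = integer(),
           origin = character())
  }

  structure(list(manifest = manifest, regions = regions,
                 subjects = select(subjects, "subject_id", "sex", "dyad_id",
                                   "role"),
                 metadata = metadata, maf = maf,
                 snp_h1 = snp_h1, snp_h2 = snp_h2,
                 reg_h1 = reg_h1, reg_h2 = reg_h2,
                 extra_cnvs = extra_cnvs),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("<cohort_truth>\n")
  cat(sprintf("  %d subjects (%d dyads, %d singletons), %d samples\n",
              nrow(x$subjects), sum(x$subjects$role == "mother"),
              sum(x$subjects$role == "singleton"), nrow(x$metadata)))
  cat(sprintf("  manifest: %d loci (%d SNP, %d intensity-only) on %d chromosomes\n",
              nrow(x$manifest), sum(x$manifest$kind == "SNP"),
              sum(x$manifest$kind == "intensity_only"),
              length(unique(x$manifest$chrom))))
  cat(sprintf("  %d population CNV regions; %d de novo / somatic extras\n",
              nrow(x$regions), nrow(x$extra_cnvs)))
  invisible(x)
}

#' Tabulate the CNV truth set of a cohort
#'
#' Flattens a `cohort_truth` object into one row per aberrant interval per
#' subject: germline region genotypes that deviate from two copies
#' (`origin = "germline"`, `tissue = "both"`), de novo events, and
#' tissue-private somatic events.
#'
#' @param truth A `cohort_truth` object.
#' @return Tibble: `subject_id, tissue, chrom, start_bp, end_bp, cn, origin`.
#' @export
truth_table <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  rows <- list()
  n_reg <- nrow(truth$regions)
  if (n_reg > 0) {
    hc <- hap_copies_of(truth$regions$variant_copy)
    for (j in seq_len(n_reg)) {
      c1 <- ifelse(truth$reg_h1[, j] == 1L, hc[j], 1L)
      c2 <- ifelse(truth$reg_h2[, j] == 1L, hc[j], 1L)
      cn <- clamp(c1 + c2, 0L, 4L)
      hit <- which(cn != 2L)
      if (length(hit))
        rows[[length(rows) + 1]] <- tibble(
          subject_id = rownames(truth$reg_h1)[hit], tissue = "both",
          chrom = truth$regions$chrom[j],
          start_bp = truth$regions$start_bp[j],
          end_bp = truth$regions$end_bp[j],
          cn = as.integer(cn[hit]), origin = "germline")
    }
  }
  bind_rows(c(rows, list(truth$extra_cnvs))) |>
    arrange(.data$subject_id, .data$tissue, .data$chrom, .data$start_bp)
}

#' Write / read a CNV truth-set table
#'
#' @param truth A `cohort_truth` object (or a truth table tibble).
#' @param path File path for the tab-separated truth table.
#' @return `write_truth()` invisibly returns the table written;
#'   `read_truth()` returns the tibble.
#' @export
write_truth <- function(truth, path) {
  tab <- if (inherits(truth, "cohort_truth")) truth_table(truth) else
    as_tibble(truth)
  readr::write_tsv(tab, path)
  invisible(tab)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(), tissue = readr::col_character(),
    chrom = readr::col_integer(), start_bp = readr::col_double(),
    end_bp = readr::col_double(), cn = readr::col_integer(),
    origin = readr::col_character()))
}
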