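#' Build a synthetic SNP-array probe manifest
#'
#' Creates an ordered table of array loci on the autosomes, mixing polymorphic
#' SNP probes with non-polymorphic intensity-only probes (informative for copy
#' number but carrying no genotype). Loci are distributed across chromosomes in
#' proportion to the physical lengths of the human autosomes, with inter-locus
#' gaps drawn from an exponential distribution, so probe density resembles a
#' genotyping array at a reduced scale.
#'
#' @param n_snp Number of SNP probes (> 0).
#' @param n_intensity_only Number of intensity-only probes (>= 0).
#' @param n_chromosomes Number of autosomes to place loci on (1-22).
#' @param mean_spacing_bp Mean inter-locus gap in base pairs.
#' @return A tibble with one row per locus, ordered by chromosome then
#'   position: `probe` (unique name), `chrom` (integer), `pos` (1-based bp),
#'   `kind` (`"SNP"` or `"intensity_only"`).
#' @examples
#' set.seed(1)
#' man <- build_manifest(n_snp = 500, n_intensity_only = 80, n_chromosomes = 4)
#' dplyr::count(man, chrom, kind)
#' @export
build_manifest <- function(n_snp, n_intensity_only = 0, n_chromosomes = 22,
                           mean_spacing_bp = 4500) {
  n_snp <- check_count(n_snp, "n_snp", min = 1)
  n_intensity_only <- check_count(n_intensity_only, "n_intensity_only", min = 0)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", min = 1)
  if (n_chromosomes > 22) stop_arg("`n_chromosomes` must be <= 22 (autosomes only)")
  if (!is.finite(mean_spacing_bp) || mean_spacing_bp <= 0)
    stop_arg("`mean_spacing_bp` must be > 0")

  n <- n_snp + n_intensity_only
  per_chrom <- proportional_counts(n, autosome_mb[seq_len(n_chromosomes)])
  # with few loci some chromosomes may get 0; drop them silently
  chrom <- rep.int(seq_len(n_chromosomes), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k) {
    if (k == 0) return(numeric(0))
    cumsum(pmax(1, round(rexp(k, rate = 1 / mean_spacing_bp))))
  }), use.names = FALSE)
  kind <- sample(rep(c("SNP", "intensity_only"), c(n_snp, n_intensity_only)))
  probe <- ifelse(kind == "SNP",
                  sprintf("rs%07d", seq_len(n)),
                  sprintf("cnvi%07d", seq_len(n)))
  tibble(probe = probe, chrom = as.integer(chrom), pos = as.numeric(pos),
         kind = kind)
}

#' Locus indices covered by a genomic interval
#'
#' @param manifest Probe manifest (see [build_manifest()]).
#' @param chrom,start_bp,end_bp Interval (1-based, inclusive).
#' @return Integer row indices into `manifest`.
#' @keywords internal
loci_in_interval <- function(manifest, chrom, start_bp, end_bp) {
  which(manifest$chrom == chrom & manifest$pos >= start_bp &
          manifest$pos <= end_bp)
}
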