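#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline in one validated,
#' serializable object. The defaults describe the reference study design at
#' reduced array scale: 16 mother-infant dyads plus 7 singletons (39
#' subjects, 78 samples, blood and buccal each), and a manifest of 5,479 SNP
#' plus 927 intensity-only loci on the 22 autosomes (1/100 of a 660k-class
#' array).
#'
#' @param n_snp,n_intensity_only,n_chromosomes,mean_spacing_bp Manifest
#'   (see [build_manifest()]).
#' @param n_regions,frequency_range,size_mean_kb,size_dispersion Population
#'   CNV regions (see [simulate_population_cnvs()]).
#' @param n_dyads,n_singletons,de_novo_rate,somatic_discordance_rate,snp_maf_range
#'   Cohort (see [simulate_cohort()]).
#' @param lrr_sd,baf_sd,wave_amplitude,buccal_noise_multiplier,batch_offset_sd
#'   Noise (see [default_noise()]).
#' @param quality_alpha,quality_beta,nocall_threshold Quality model (see
#'   [default_quality_model()]).
#' @param penalty,min_seg Segmentation (`NULL` penalty = BIC default).
#' @param lbf_thresholds LBF filtering thresholds.
#' @param seed Master seed; per-stage sub-seeds are derived from it
#'   deterministically so stages can be re-run in isolation.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(n_snp = 5479, n_intensity_only = 927,
                            n_chromosomes = 22, mean_spacing_bp = 4500,
                            n_regions = 40, frequency_range = c(0.05, 0.4),
                            size_mean_kb = 100, size_dispersion = 0.6,
                            n_dyads = 16, n_singletons = 7,
                            de_novo_rate = 0.05,
                            somatic_discordance_rate = 0.05,
                            snp_maf_range = c(0.05, 0.5),
                            lrr_sd = 0.18, baf_sd = 0.04,
                            wave_amplitude = 0,
                            buccal_noise_multiplier = 1.25,
                            batch_offset_sd = 0,
                            quality_alpha = 3.2, quality_beta = 1,
                            nocall_threshold = 0.15,
                            penalty = NULL, min_seg = 1,
                            lbf_thresholds = c(10, 30, 50), seed = 1) {
  cfg <- as.list(environment())
  if (any(cfg$lbf_thresholds <= 0)) stop_arg("LBF thresholds must be positive")
  if (cfg$nocall_threshold <= 0) stop_arg("`nocall_threshold` must be positive")
  check_count(cfg$seed, "seed", min = 0)
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else
                  paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

noise_from_config <- function(cfg) {
  default_noise(lrr_sd = cfg$lrr_sd, baf_sd = cfg$baf_sd,
                wave_amplitude = cfg$wave_amplitude,
                buccal_multiplier = cfg$buccal_noise_multiplier,
                batch_offset_sd = cfg$batch_offset_sd)
}

quality_from_config <- function(cfg) {
  default_quality_model(alpha = cfg$quality_alpha, beta = cfg$quality_beta,
                        nocall_threshold = cfg$nocall_threshold)
}

# calls vs truth: per threshold, how many retained calls overlap a true
# aberrant interval of the same sample and direction, and how many truth
# intervals are recovered
truth_comparison <- function(calls, truth_tab, metadata, thresholds) {
  md <- as_tibble(metadata)
  truth_s <- truth_tab |>
    left_join(md, by = "subject_id", relationship = "many-to-many") |>
    filter(.data$tissue.x == "both" | .data$tissue.x == .data$tissue.y) |>
    transmute(sample_id = .data$sample_id, chrom = .data$chrom,
              start_bp = .data$start_bp, end_bp = .data$end_bp,
              dir = sign(.data$cn - 2))
  rows <- list()
  for (thr in thresholds) {
    f <- calls[calls$lbf >= thr, , drop = FALSE]
    call_hit <- logical(nrow(f))
    truth_hit <- logical(nrow(truth_s))
    if (nrow(f) > 0 && nrow(truth_s) > 0) {
      for (i in seq_len(nrow(f))) {
        m <- truth_s$sample_id == f$sample_id[i] &
          truth_s$chrom == f$chrom[i] &
          truth_s$start_bp <= f$end_bp[i] & truth_s$end_bp >= f$start_bp[i] &
          truth_s$dir == sign(f$cn[i] - 2)
        call_hit[i] <- any(m)
        truth_hit <- truth_hit | m
      }
    }
    rows[[length(rows) + 1]] <- tibble(
      lbf_threshold = thr, n_calls = nrow(f),
      n_calls_matching_truth = sum(call_hit),
      precision = if (nrow(f)) sum(call_hit) / nrow(f) else NA_real_,
      n_truth_intervals = nrow(truth_s),
      n_truth_recovered = sum(truth_hit),
      recall = if (nrow(truth_s)) sum(truth_hit) / nrow(truth_s) else
        NA_real_)
  }
  bind_rows(rows)
}

#' Run the full in-silico pipeline
#'
#' Simulates a cohort, renders every sample, segments, calls CNVs, and
#' writes every report: per-sample Final-Report TSVs, metadata, the CNV
#' truth set, segment and call tables (TSV + BED), the concordance report,
#' SNP QC with swap detection, CNV count/size summaries with the
#' blood-vs-buccal count comparison, a calls-versus-truth comparison, and a
#' JSON run manifest (package version, seed, parameters, stage counts; no
#' timestamps, so identical configurations produce byte-identical output
#' trees). Each stage reseeds from a sub-seed derived from `config$seed`.
#'
#' @param config A [pipeline_config()] object.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory stage results (`truth`,
#'   `samples`, `segments`, `calls`, `concordance`, `summary`, ...).
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "final_reports"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  # stage 1: cohort truth
  set.seed(stage_seed(config$seed, 1))
  manifest <- build_manifest(config$n_snp, config$n_intensity_only,
                             config$n_chromosomes, config$mean_spacing_bp)
  regions <- simulate_population_cnvs(
    manifest, config$n_regions, config$frequency_range,
    c(config$size_mean_kb, config$size_dispersion))
  truth <- simulate_cohort(manifest, regions, config$n_dyads,
                           config$n_singletons, config$de_novo_rate,
                           config$somatic_discordance_rate,
                           config$snp_maf_range,
                           c(config$size_mean_kb, config$size_dispersion))
  truth_tab <- write_truth(truth, file.path(outdir, "truth.tsv"))
  write_metadata(truth$metadata, file.path(outdir, "metadata.tsv"))
  say("stage 1: %d loci, %d regions, %d subjects, %d samples",
      nrow(manifest), nrow(regions), nrow(truth$subjects),
      nrow(truth$metadata))

  # stage 2: render samples
  set.seed(stage_seed(config$seed, 2))
  samples <- simulate_samples(truth, noise_from_config(config),
                              quality_from_config(config))
  for (id in names(samples))
    write_final_report(samples[[id]],
                       file.path(outdir, "final_reports",
                                 paste0(id, ".txt")))
  say("stage 2: rendered %d samples", length(samples))

  # stage 3: segmentation
  set.seed(stage_seed(config$seed, 3))
  segmentations <- lapply(samples, segment_sample, penalty = config$penalty,
                          min_seg = config$min_seg)
  seg_tab <- bind_rows(lapply(names(segmentations), function(id)
    mutate(segmentations[[id]], sample_id = id)))
  write_segments(seg_tab, file.path(outdir, "segments.tsv"))
  export_bed(seg_tab, file.path(outdir, "segments.bed"))
  say("stage 3: %d segments", nrow(seg_tab))

  # stage 4: HMM calls
  set.seed(stage_seed(config$seed, 4))
  params <- hmm_params()
  hmm_calls <- lapply(names(samples), function(id) {
    calls <- call_cnvs(samples[[id]], params)
    calls$sample_id <- id
    calls
  })
  names(hmm_calls) <- names(samples)
  call_tab <- bind_rows(hmm_calls)
  write_calls(call_tab, file.path(outdir, "cnv_calls.tsv"))
  export_bed(call_tab, file.path(outdir, "cnv_calls.bed"))
  say("stage 4: %d raw calls (%s at LBF >= %s)",
      nrow(call_tab),
      paste(vapply(config$lbf_thresholds,
                   function(t) sum(call_tab$lbf >= t), numeric(1)),
            collapse = "/"),
      paste(config$lbf_thresholds, collapse = "/"))

  # stage 5: concordance + SNP QC
  set.seed(stage_seed(config$seed, 5))
  conc <- concordance_table(samples, truth$metadata,
                            methods = c("raw", "segmentation", "hmm"),
                            penalty = config$penalty,
                            min_seg = config$min_seg, params = params,
                            lbf_thresholds = config$lbf_thresholds,
                            segmentations = segmentations,
                            hmm_calls = hmm_calls)
  readr::write_tsv(conc$summary, file.path(outdir, "concordance_summary.tsv"))
  readr::write_tsv(conc$pairs, file.path(outdir, "concordance_pairs.tsv"))
  qc <- detect_sample_swaps(samples, truth$metadata)
  call_rates <- tibble(check = "call_rate",
                       sample_a = names(samples), sample_b = NA_character_,
                       value = vapply(samples, genotype_call_rate,
                                      numeric(1)),
                       flagged = vapply(samples, genotype_call_rate,
                                        numeric(1)) < 0.97)
  readr::write_tsv(bind_rows(call_rates, qc),
                   file.path(outdir, "snp_qc.tsv"))
  say("stage 5: %d pair correlations, %d QC checks (%d flagged)",
      nrow(conc$pairs), nrow(qc) + nrow(call_rates),
      sum(qc$flagged) + sum(call_rates$flagged))

  # stage 6: CNV summaries + truth comparison
  set.seed(stage_seed(config$seed, 6))
  cnv_sum <- summarize_cnvs(call_tab, truth$metadata,
                            config$lbf_thresholds)
  readr::write_tsv(cnv_sum, file.path(outdir, "cnv_summary.tsv"))
  tc <- truth_comparison(call_tab, truth_tab, truth$metadata,
                         config$lbf_thresholds)
  readr::write_tsv(tc, file.path(outdir, "truth_comparison.tsv"))
  say("stage 6: summaries written")

  manifest_json <- list(
    package = "cnvconcord",
    version = as.character(utils::packageVersion("cnvconcord")),
    seed = config$seed,
    config = unclass(config),
    counts = list(loci = nrow(manifest), regions = nrow(regions),
                  subjects = nrow(truth$subjects),
                  samples = length(samples), segments = nrow(seg_tab),
                  calls = nrow(call_tab)))
  jsonlite::write_json(manifest_json,
                       file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(truth = truth, samples = samples,
                 segmentations = segmentations, segments = seg_tab,
                 calls = call_tab, hmm_calls = hmm_calls,
                 concordance = conc, cnv_summary = cnv_sum,
                 truth_comparison = tc, qc = bind_rows(call_rates, qc),
                 outdir = outdir))
}
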