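final_report_cols <- c("SNP Name", "Chr", "Position", "GType", "GC Score",
                       "Log R Ratio", "B Allele Freq")

#' Write a sample as a Final-Report-style TSV
#'
#' Tab-separated per-sample table with the seven columns `SNP Name, Chr,
#' Position, GType, GC Score, Log R Ratio, B Allele Freq`. Intensity-only
#' probes have empty `GType`, `GC Score`, and `B Allele Freq` fields.
#'
#' @param sample A sample series tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_final_report <- function(sample, path) {
  out <- tibble(`SNP Name` = sample$probe, Chr = sample$chrom,
                Position = sample$pos, GType = sample$genotype,
                `GC Score` = sample$quality, `Log R Ratio` = sample$lrr,
                `B Allele Freq` = sample$baf)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a Final-Report-style TSV into a sample series
#'
#' Parses and validates a per-sample table written by [write_final_report()]
#' (or exported by array software in the same dialect), aligning it to the
#' probe manifest. Rows with a blank genotype field are intensity-only
#' probes. Malformed rows and probe names absent from the manifest are
#' errors, reported with their line number where available.
#'
#' @param path Input path.
#' @param manifest Probe manifest the series must align to.
#' @return A sample series tibble in manifest order (columns as in
#'   [render_sample()], without `cn_true`), with the file's base name as the
#'   `sample_id` attribute.
#' @export
read_final_report <- function(path, manifest) {
  # parse issues are converted to errors below via problems()
  dat <- suppressWarnings(readr::read_tsv(path, na = character(),
                                          col_types = readr::cols(
    `SNP Name` = readr::col_character(), Chr = readr::col_integer(),
    Position = readr::col_double(), GType = readr::col_character(),
    `GC Score` = readr::col_character(),
    `Log R Ratio` = readr::col_double(),
    `B Allele Freq` = readr::col_character())))
  if (!identical(names(dat), final_report_cols))
    stop_arg(paste("unexpected columns; expected:",
                   paste(final_report_cols, collapse = ", ")))
  probs <- readr::problems(dat)
  if (nrow(probs) > 0)
    stop_arg(sprintf("malformed row at line %d of %s: expected %s",
                     probs$row[1], path, probs$expected[1]))
  if (nrow(dat) == 0) stop_arg(sprintf("no data rows in %s", path))
  unknown <- setdiff(dat$`SNP Name`, manifest$probe)
  if (length(unknown))
    stop_arg(sprintf("unknown probe name(s) in %s: %s", path,
                     paste(head(unknown, 3), collapse = ", ")))
  if (nrow(dat) != nrow(manifest))
    stop_arg(sprintf("%s has %d rows; manifest has %d loci", path,
                     nrow(dat), nrow(manifest)))
  ord <- match(manifest$probe, dat$`SNP Name`)
  dat <- dat[ord, ]
  blank <- dat$GType == ""
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == "",
                                                              NA, x)))
  out <- tibble(probe = manifest$probe, chrom = manifest$chrom,
                pos = manifest$pos, kind = manifest$kind,
                lrr = dat$`Log R Ratio`,
                baf = num_or_na(dat$`B Allele Freq`),
                genotype = ifelse(blank, NA_character_, dat$GType),
                quality = num_or_na(dat$`GC Score`))
  attr(out, "sample_id") <- sub("\\.[^.]*$", "", basename(path))
  out
}

#' Write / read cohort metadata
#'
#' @param metadata Metadata tibble (`sample_id, subject_id, tissue, dyad_id,
#'   role`, optionally `sex`).
#' @param path File path.
#' @export
write_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, na = "")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, na = "", col_types = readr::cols(
    .default = readr::col_character()))
}

#' Write / read a segment table
#'
#' Columns: `sample_id, chrom, start_bp, end_bp, n_probes, seg_mean`.
#'
#' @param segments Segment tibble (with `sample_id`).
#' @param path File path.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(select(segments, "sample_id", "chrom", "start_bp",
                          "end_bp", "n_probes", "seg_mean"), path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), chrom = readr::col_integer(),
    start_bp = readr::col_double(), end_bp = readr::col_double(),
    n_probes = readr::col_integer(), seg_mean = readr::col_double()))
}

#' Write / read a CNV call table
#'
#' Columns: `sample_id, chrom, start_bp, end_bp, n_probes, state, lbf`.
#'
#' @param calls Call tibble.
#' @param path File path.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(select(calls, "sample_id", "chrom", "start_bp", "end_bp",
                          "n_probes", "state", "lbf"), path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), chrom = readr::col_integer(),
    start_bp = readr::col_double(), end_bp = readr::col_double(),
    n_probes = readr::col_integer(), state = readr::col_character(),
    lbf = readr::col_double()))
}

#' Export intervals as BED
#'
#' Converts a table with 1-based inclusive `chrom, start_bp, end_bp`
#' coordinates to 0-based half-open BED. The `name` column is `sample_id`
#' where present; the score column is `seg_mean` or `lbf` where present.
#'
#' @param x Segment or call tibble.
#' @param path Output path.
#' @export
export_bed <- function(x, path) {
  score <- if ("lbf" %in% names(x)) x$lbf else
    if ("seg_mean" %in% names(x)) x$seg_mean else 0
  bed <- tibble(chrom = paste0("chr", x$chrom),
                start = as.integer(x$start_bp - 1),
                end = as.integer(x$end_bp),
                name = if ("sample_id" %in% names(x)) x$sample_id else ".",
                score = score)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
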