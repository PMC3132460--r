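# Plain-text writers/readers for the standard exchange formats: BED
# (0-based half-open) for intervals, TSV for matrices and sample sheets.

#' Write a probe design as BED
#'
#' Columns: chrom, start, end, probe_id, score (GC fraction x 1000).
#'
#' @param design A probe design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(design, path) {
  readr::write_tsv(
    tibble(
      chrom = design$chrom, start = design$start, end = design$end,
      name = design$probe_id, score = round(design$gc * 1000)
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Read a probe design from BED
#'
#' @param path BED path written by [write_probe_bed()].
#' @param platform Platform tag to attach.
#' @return A probe design tibble.
#' @export
read_probe_bed <- function(path, platform = "tiling") {
  b <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                           "name", "score"),
                       show_col_types = FALSE)
  tibble(
    probe_id = b$name, chrom = b$chrom, start = b$start, end = b$end,
    gc = b$score / 1000, platform = platform
  )
}

#' Write per-sample copy-number segments as BED
#'
#' One BED row per segment: name = class, score = supporting probes;
#' sample id in column 7.
#'
#' @param segments A segment tibble (`sample_id`, `start`, `end`,
#'   `class`, `n_probes`).
#' @param path Output path.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path, chrom = "chr4") {
  readr::write_tsv(
    tibble(
      chrom = chrom, start = segments$start, end = segments$end,
      name = segments$class, score = segments$n_probes,
      sample_id = segments$sample_id
    ),
    path, col_names = FALSE
  )
  invisible(path)
}

#' Write / read a log2-ratio matrix as TSV
#'
#' First column `probe_id`, one numeric column per sample.
#'
#' @param mat A wide log2-ratio tibble.
#' @param path TSV path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a sample sheet as TSV
#'
#' Columns: `sample_id`, `status`, `batch`.
#'
#' @param samples Sample sheet tibble.
#' @param path TSV path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples[, c("sample_id", "status", "batch")], path)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write truth profiles as per-sample BED
#'
#' One row per carrier deletion: chrom, start, end, sample_id, copy
#' number.
#'
#' @param truths A [simulate_cohort()] tibble.
#' @param path Output path.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truths, path, chrom = "chr4") {
  tc <- truths[truths$carrier, , drop = FALSE]
  readr::write_tsv(
    tibble(
      chrom = chrom, start = tc$del_start, end = tc$del_end,
      name = tc$sample_id, score = tc$cn
    ),
    path, col_names = FALSE
  )
  invisible(path)
}
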