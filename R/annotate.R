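#' Load the 4p16.3 subtelomere gene annotation table
#'
#' Reads the packaged gene table for the 1.3-Mb subtelomeric region (34
#' putative genes from PDE6B to LETM1, including hypothetical LOC
#' entries), or any TSV with the same five annotation columns. Printed
#' 1-based inclusive coordinates are converted to internal 0-based
#' half-open on load; records are sorted by start.
#'
#' @param path Path to a TSV with columns `start`, `end`, `cytoband`,
#'   `symbol`, `description`, `model_evidence` (coordinates printed
#'   1-based inclusive). Defaults to the packaged table.
#' @return A tibble of gene records with half-open `start`/`end`.
#' @examples
#' genes <- load_gene_table()
#' nrow(genes)
#' genes$symbol[1]
#' @export
load_gene_table <- function(path = system.file("extdata", "genes_4p16_3.tsv",
                                               package = "subtelcnv")) {
  if (!file.exists(path)) abort(sprintf("gene table not found: %s", path))
  g <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!nrow(g)) return(tibble(
    start = double(), end = double(), cytoband = character(),
    symbol = character(), description = character(),
    model_evidence = character()
  ))
  need <- c("start", "end", "cytoband", "symbol", "description",
            "model_evidence")
  if (!all(need %in% names(g))) {
    abort(sprintf("gene table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(g$start) | !is.finite(g$end) |
                 g$start >= g$end | !nzchar(g$symbol))
  if (length(bad)) {
    abort(sprintf("malformed gene record at line %d (start >= end or empty symbol)",
                  bad[1] + 1L))
  }
  conv <- printed_to_halfopen(g$start, g$end)
  g |>
    mutate(start = conv$start, end = conv$end) |>
    arrange(.data$start) |>
    select(dplyr::all_of(need))
}

#' Genes overlapping an interval
#'
#' Returns the gene records whose interval overlaps the half-open query
#' by at least 1 bp.
#'
#' @param genes A gene tibble from [load_gene_table()].
#' @param start,end Half-open query interval.
#' @return The overlapping subset, in positional order.
#' @examples
#' genes_in_region(load_gene_table(), 550000, 1850000) # all 34
#' @export
genes_in_region <- function(genes, start, end) {
  check_interval(start, end, "query")
  genes[genes$end > start & genes$start < end, , drop = FALSE]
}

#' HbA1c conversion from JDS to NGSP standard
#'
#' `NGSP (%) = JDS (%) + 0.4` — the relation between the two
#' glycated-hemoglobin reporting standards used when screening control
#' subjects.
#'
#' @param value_jds HbA1c percentage on the JDS standard (>= 0).
#' @return HbA1c percentage on the NGSP standard.
#' @examples
#' hba1c_jds_to_ngsp(6.0) # 6.4 -- fails the strict < 6.4 control cut
#' @export
hba1c_jds_to_ngsp <- function(value_jds) {
  if (any(value_jds < 0)) abort("HbA1c cannot be negative")
  value_jds + 0.4
}

#' Control-eligibility predicate on NGSP HbA1c
#'
#' Nondiabetic control screening requires HbA1c strictly below 6.4%
#' (NGSP).
#'
#' @param value_ngsp HbA1c percentage on the NGSP standard.
#' @return Logical eligibility.
#' @export
control_eligible <- function(value_ngsp) {
  value_ngsp < 6.4
}

#' Cohort segment report with gene and gap annotation
#'
#' One row per sample per segment with its class, span, probe support,
#' overlap with the assembly gap, and the symbols of overlapped genes;
#' plus a cohort summary of carrier counts by case/control status.
#'
#' @param validation A [validate_samples()] result (or any segment tibble
#'   with `sample_id`, `start`, `end`, `class`, `n_probes`).
#' @param samples Sample sheet (`sample_id`, `status`).
#' @param region The [region_model()].
#' @param genes Gene table (default: the packaged 4p16.3 table).
#' @return A list with tibbles `segments` (annotated) and `summary`
#'   (carrier counts by status).
#' @export
render_cohort_report <- function(validation, samples,
                                 region = region_model(),
                                 genes = load_gene_table()) {
  segs <- if (inherits(validation, "cnv_validation")) {
    validation$segments[validation$segments$group == "test", , drop = FALSE]
  } else {
    as_tibble(validation)
  }
  if (!nrow(segs)) {
    return(list(
      segments = tibble(
        sample_id = character(), start = double(), end = double(),
        class = character(), span_bp = double(), n_probes = integer(),
        gap_overlap_bp = double(), genes = character()
      ),
      summary = tibble(status = character(), n = integer(),
                       carriers = integer())
    ))
  }
  ann <- segs |>
    mutate(
      span_bp = .data$end - .data$start,
      gap_overlap_bp = overlap_bp(.data$start, .data$end,
                                  region$gap_start, region$gap_end),
      genes = vapply(seq_len(dplyr::n()), function(i) {
        hit <- genes_in_region(genes, segs$start[i], segs$end[i])
        paste(hit$symbol, collapse = ",")
      }, character(1))
    ) |>
    select("sample_id", "start", "end", "class", "span_bp", "n_probes",
           "gap_overlap_bp", "genes")

  carriers <- ann |>
    group_by(.data$sample_id) |>
    summarise(carrier = any(.data$class == "loss"), .groups = "drop") |>
    left_join(samples[, c("sample_id", "status")], by = "sample_id")
  summary <- carriers |>
    group_by(.data$status) |>
    summarise(n = dplyr::n(), carriers = sum(.data$carrier),
              .groups = "drop")

  list(segments = ann, summary = summary)
}
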