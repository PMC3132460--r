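#' Per-sample mean log2 ratio over a locus
#'
#' Averages the log2 ratio over all probes whose interval midpoint lies in
#' the half-open locus, for every sample column.
#'
#' @param mat A wide log2-ratio tibble.
#' @param design The matching probe design.
#' @param locus_start,locus_end Half-open locus bounds (bp).
#' @return A tibble with columns `sample_id`, `mean_log2`, `n_probes`.
#' @export
summarize_locus <- function(mat, design, locus_start, locus_end) {
  check_interval(locus_start, locus_end, "locus")
  mid <- (design$start + design$end) / 2
  hit <- mid >= locus_start & mid < locus_end
  if (!any(hit)) {
    abort(sprintf("no probes in locus [%s, %s)",
                  format(locus_start, big.mark = ","),
                  format(locus_end, big.mark = ",")))
  }
  v <- ratio_matrix(mat)[hit, , drop = FALSE]
  tibble(
    sample_id = colnames(v),
    mean_log2 = unname(colMeans(v)),
    n_probes = sum(hit)
  )
}

#' Collapse per-probe loss classes into loss intervals
#'
#' Implements the consecutive-marker evidence rule: only maximal runs of
#' at least `min_run` consecutive loss-classed probes are accepted as
#' loss intervals (a single deviant marker is not evidence of a CNV);
#' shorter runs are discarded. Intervals span from the first probe's
#' start to the last probe's end.
#'
#' @param classes Character vector of per-probe classes (`"loss"` /
#'   anything else), aligned to `design` rows.
#' @param design The probe design.
#' @param min_run Minimum run length in probes (default 2: more than one
#'   consecutive abnormal marker).
#' @return A tibble of loss intervals: `start`, `end`, `n_probes`.
#' @export
apply_consecutive_constraint <- function(classes, design, min_run = 2) {
  if (length(classes) != nrow(design)) {
    abort("classes are not aligned to design probes")
  }
  r <- rle(classes == "loss")
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  tibble(
    start = design$start[starts_idx[keep]],
    end = design$end[ends_idx[keep]],
    n_probes = r$lengths[keep]
  )
}

#' Reliability screen for candidate CNVs
#'
#' Retains candidates that satisfy the screening reliability criterion:
#' at least `min_probes` consecutive supporting probes and a span of at
#' least `min_span` bp (both thresholds read inclusively).
#'
#' @param candidates A tibble with columns `n_probes` and `span_bp` (or
#'   `start`/`end` from which the span is derived).
#' @param min_probes Minimum supporting probe count (default 50).
#' @param min_span Minimum span in bp (default 50,000).
#' @return The tibble with a logical `passed_screen` column; rows failing
#'   the screen are kept but flagged.
#' @export
screen_candidates <- function(candidates, min_probes = 50,
                              min_span = 50000) {
  if (!"span_bp" %in% names(candidates)) {
    candidates <- mutate(candidates, span_bp = .data$end - .data$start)
  }
  mutate(
    candidates,
    passed_screen = .data$n_probes >= min_probes & .data$span_bp >= min_span
  )
}

#' Stage-1 screening caller over candidate loci
#'
#' For each candidate locus: summarises every sample to its mean log2
#' ratio over the locus, fits a Gaussian-mixture classifier
#' ([fit_gmm_classes()]) to the summaries, tabulates per-status loss
#' calls, and applies the reliability screen ([screen_candidates()]).
#'
#' @param mat A (normalized) wide log2-ratio tibble.
#' @param design The matching probe design.
#' @param loci A tibble of candidate loci with columns `start`, `end`
#'   (and optionally `locus_id`).
#' @param samples Sample sheet: `sample_id`, `status` (`"case"` /
#'   `"control"`), `batch`.
#' @param min_probes,min_span Reliability screen thresholds.
#' @param max_k,min_separation Passed to [fit_gmm_classes()].
#' @return An object of class `cnv_screen`: `$candidates` (one row per
#'   locus: coordinates, probe count, span, loss counts by status,
#'   `passed_screen`) and `$calls` (one row per locus x sample with the
#'   mixture class).
#' @export
screen_cohort <- function(mat, design, loci, samples,
                          min_probes = 50, min_span = 50000,
                          max_k = 3, min_separation = 0.3) {
  if (!all(c("start", "end") %in% names(loci))) {
    abort("loci must have start and end columns")
  }
  loci <- as_tibble(loci)
  if (!"locus_id" %in% names(loci)) {
    loci$locus_id <- sprintf("locus_%02d", seq_len(nrow(loci)))
  }

  calls <- purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    sm <- summarize_locus(mat, design, loci$start[i], loci$end[i])
    fit <- fit_gmm_classes(sm$mean_log2, max_k = max_k,
                           min_separation = min_separation)
    mutate(sm, locus_id = loci$locus_id[i], class = fit$class)
  })
  calls <- left_join(calls, samples[, c("sample_id", "status")],
                     by = "sample_id")

  candidates <- calls |>
    group_by(.data$locus_id) |>
    summarise(
      n_probes = .data$n_probes[1],
      case_loss = sum(.data$class == "loss" & .data$status == "case"),
      control_loss = sum(.data$class == "loss" & .data$status == "control"),
      .groups = "drop"
    ) |>
    left_join(loci, by = "locus_id") |>
    mutate(span_bp = .data$end - .data$start) |>
    select("locus_id", "start", "end", "span_bp", "n_probes",
           "case_loss", "control_loss") |>
    screen_candidates(min_probes = min_probes, min_span = min_span)

  structure(list(candidates = candidates, calls = calls),
            class = "cnv_screen")
}

#' @export
print.cnv_screen <- function(x, ...) {
  cat(sprintf("<cnv_screen> %d loci (%d passed screen)\n",
              nrow(x$candidates), sum(x$candidates$passed_screen)))
  print(x$candidates)
  invisible(x)
}

#' @rdname screen_cohort
#' @param x A `cnv_screen` object.
#' @param ... Unused.
#' @export
tidy.cnv_screen <- function(x, ...) x$candidates

#' @rdname screen_cohort
#' @export
glance.cnv_screen <- function(x, ...) {
  tibble(
    n_loci = nrow(x$candidates),
    n_passed = sum(x$candidates$passed_screen),
    n_samples = dplyr::n_distinct(x$calls$sample_id)
  )
}
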