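#' Region model for the 4p16.3 subtelomeric interval
#'
#' Describes the genomic territory the analysis operates on: a 1.3-Mb
#' subtelomeric interval on chromosome 4p16.3 containing a probe-free
#' reference-assembly gap ("gap-177") flanked by low-copy-repeat (LCR)
#' intervals where copy number cannot be inferred and calls are emitted
#' as `no_call`.
#'
#' All coordinates are internal 0-based half-open. The defaults encode the
#' published region `550,000..1,850,000` and the printed gap
#' `1,423,147..1,478,646` (1-based inclusive), converted on construction
#' to `[1423146, 1478646)` — 55,500 bp. The default LCR masks are two
#' synthetic intervals flanking the gap; real mask coordinates for this
#' subtelomere are not published, so these stand in for the repeat tracts
#' the reporting masks out.
#'
#' @param chrom Chromosome label.
#' @param region_start,region_end Half-open region bounds (bp).
#' @param gap_start,gap_end Half-open gap bounds (bp); no probe may be
#'   designed inside the gap.
#' @param lcr_masks A data frame with columns `start`, `end` (half-open) of
#'   pairwise non-overlapping mask intervals inside the region, or `NULL`
#'   for none.
#' @param build_label Assembly label carried through to outputs; no
#'   liftover is performed.
#' @return An object of class `region_model`.
#' @examples
#' reg <- region_model()
#' reg$region_end - reg$region_start # 1,300,000
#' reg$gap_end - reg$gap_start       # 55,500
#' @export
region_model <- function(chrom = "chr4",
                         region_start = 550000,
                         region_end = 1850000,
                         gap_start = printed_to_halfopen(1423147, 1478646)$start,
                         gap_end = printed_to_halfopen(1423147, 1478646)$end,
                         lcr_masks = default_lcr_masks(),
                         build_label = "synthetic-4p16.3") {
  if (!(region_start < region_end)) {
    abort("region_start must be < region_end")
  }
  check_interval(gap_start, gap_end, "gap")
  if (gap_start < region_start || gap_end > region_end) {
    abort(sprintf(
      "gap [%d, %d) not contained in region [%d, %d)",
      gap_start, gap_end, region_start, region_end
    ))
  }
  if (is.null(lcr_masks)) {
    lcr_masks <- tibble(start = double(), end = double())
  }
  lcr_masks <- as_tibble(lcr_masks)[, c("start", "end")]
  if (nrow(lcr_masks)) {
    check_interval(lcr_masks$start, lcr_masks$end, "lcr_mask")
    if (any(lcr_masks$start < region_start) || any(lcr_masks$end > region_end)) {
      bad <- which(lcr_masks$start < region_start | lcr_masks$end > region_end)[1]
      abort(sprintf(
        "lcr mask [%d, %d) not contained in region",
        lcr_masks$start[bad], lcr_masks$end[bad]
      ))
    }
    lcr_masks <- arrange(lcr_masks, .data$start)
    if (nrow(lcr_masks) > 1 &&
        any(lcr_masks$start[-1] < lcr_masks$end[-nrow(lcr_masks)])) {
      abort("lcr masks overlap each other")
    }
  }
  structure(
    list(
      chrom = chrom,
      region_start = region_start, region_end = region_end,
      gap_start = gap_start, gap_end = gap_end,
      lcr_masks = lcr_masks,
      build_label = build_label
    ),
    class = "region_model"
  )
}

#' Default low-copy-repeat masks flanking the gap
#'
#' Two synthetic no-call intervals abutting the gap on either side,
#' emulating the repeat tracts adjacent to a subtelomeric assembly gap.
#'
#' @return A tibble with columns `start`, `end`.
#' @export
default_lcr_masks <- function() {
  tibble(
    start = c(1400000, 1478646),
    end   = c(1423146, 1500000)
  )
}

#' @export
print.region_model <- function(x, ...) {
  cat(sprintf(
    "<region_model> %s:%d-%d (%s, %.2f Mb)\n", x$chrom,
    x$region_start, x$region_end, x$build_label,
    (x$region_end - x$region_start) / 1e6
  ))
  cat(sprintf(
    "  gap: [%d, %d) %d bp; lcr masks: %d (%d bp)\n",
    x$gap_start, x$gap_end, x$gap_end - x$gap_start,
    nrow(x$lcr_masks), sum(x$lcr_masks$end - x$lcr_masks$start)
  ))
  invisible(x)
}

# no-call territory (gap + masks) as one sorted tibble
nocall_intervals <- function(region) {
  arrange(
    bind_rows(
      tibble(start = region$gap_start, end = region$gap_end),
      region$lcr_masks
    ),
    .data$start
  )
}
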