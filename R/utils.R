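# Interval arithmetic is 0-based half-open throughout; printed array/report
# coordinates (1-based inclusive) are converted at the I/O boundary only.

#' Convert printed 1-based inclusive coordinates to 0-based half-open
#'
#' Array vendors and journals print intervals as 1-based inclusive
#' (`start..end`); internally every interval is 0-based half-open
#' (`[start, end)`), the BED convention, so that lengths are `end - start`
#' and adjacency is unambiguous.
#'
#' @param start,end Printed 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` in half-open convention.
#' @examples
#' printed_to_halfopen(1423147, 1478646) # the gap-177 interval
#' @export
printed_to_halfopen <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (any(end < start)) {
    abort("printed interval has end < start")
  }
  list(start = start - 1, end = end)
}

#' Overlap length of two half-open intervals
#'
#' Vectorised intersection length under 0-based half-open arithmetic.
#' Symmetric in its two intervals and never larger than either length.
#'
#' @param start1,end1 First interval(s).
#' @param start2,end2 Second interval(s).
#' @return Non-negative overlap length(s) in bp.
#' @examples
#' overlap_bp(0, 10, 5, 20)                       # 5
#' overlap_bp(1400000, 1500000, 1423146, 1478646) # 55500, the full gap
#' @export
overlap_bp <- function(start1, end1, start2, end2) {
  check_interval(start1, end1)
  check_interval(start2, end2)
  pmax(0, pmin(end1, end2) - pmax(start1, start2))
}

check_interval <- function(start, end, what = "interval") {
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(end < start)) {
    abort(sprintf("malformed %s: need finite start <= end", what))
  }
  invisible(TRUE)
}

# Jaccard index of two half-open intervals (used for recovery diagnostics).
interval_jaccard <- function(start1, end1, start2, end2) {
  inter <- overlap_bp(start1, end1, start2, end2)
  un <- (end1 - start1) + (end2 - start2) - inter
  ifelse(un > 0, inter / un, 1)
}

# Deterministic child seed derivation; keeps results < 2^31 and decoupled
# across the simulation stages that consume the same user seed.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}
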