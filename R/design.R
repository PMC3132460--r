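#' Build an array probe design over a region
#'
#' Tiles the region with fixed-length oligonucleotide probes at a constant
#' start-to-start spacing, dropping any probe that would overlap the
#' assembly gap (no sequence exists there to design against). Probes that
#' overlap LCR masks are retained — the callers later force them to
#' `no_call` — so the design itself stays platform-agnostic.
#'
#' Two platform presets mirror the two stages of the analysis:
#' `"screening"` is a sparse genome-screen style design (default spacing
#' 5,000 bp) and `"tiling"` a dense region-targeted 60-mer design
#' (default spacing 500 bp).
#'
#' Each probe carries a GC fraction from a smooth positional wave plus
#' seeded jitter, so that GC-bias correction has structure to learn.
#'
#' @param region A [region_model()].
#' @param platform `"screening"` or `"tiling"`.
#' @param spacing_bp Start-to-start probe spacing in bp; defaults to the
#'   platform preset.
#' @param probe_length Probe length in bp (default 60).
#' @param seed Integer seed for the GC jitter.
#' @return A tibble with columns `probe_id`, `chrom`, `start`, `end`,
#'   `gc`, `platform`, sorted by `start`, with no probe overlapping the gap.
#' @examples
#' reg <- region_model()
#' des <- build_array_design(reg, "tiling", spacing_bp = 5000)
#' any(des$end > reg$gap_start & des$start < reg$gap_end) # FALSE
#' @export
build_array_design <- function(region,
                               platform = c("tiling", "screening"),
                               spacing_bp = NULL,
                               probe_length = 60,
                               seed = 42L) {
  stopifnot(inherits(region, "region_model"))
  platform <- match.arg(platform)
  spacing_bp <- spacing_bp %||% switch(platform, tiling = 500, screening = 5000)
  if (spacing_bp <= 0) abort("spacing_bp must be > 0")
  if (spacing_bp >= region$region_end - region$region_start) {
    abort("spacing larger than region: empty design")
  }

  starts <- seq(region$region_start, region$region_end - probe_length,
                by = spacing_bp)
  if (!length(starts)) {
    abort("spacing larger than region: empty design")
  }
  ends <- starts + probe_length
  in_gap <- ends > region$gap_start & starts < region$gap_end
  starts <- starts[!in_gap]
  ends <- ends[!in_gap]

  mid <- (starts + ends) / 2
  gc <- withr::with_seed(seed, {
    0.45 +
      0.08 * sin(2 * pi * (mid - region$region_start) / 3e5) +
      rnorm(length(mid), 0, 0.01)
  })
  gc <- pmin(1, pmax(0, gc))

  tibble(
    probe_id = sprintf("%s_%07d", substr(platform, 1, 1), starts),
    chrom = region$chrom,
    start = starts,
    end = ends,
    gc = gc,
    platform = platform
  )
}

# TRUE for probes overlapping any LCR mask (these become no_call downstream)
probe_masked <- function(design, region) {
  masks <- region$lcr_masks
  if (!nrow(masks)) {
    return(rep(FALSE, nrow(design)))
  }
  vapply(
    seq_len(nrow(design)),
    function(i) {
      any(design$end[i] > masks$start & design$start[i] < masks$end)
    },
    logical(1)
  )
}
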