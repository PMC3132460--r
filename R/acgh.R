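#' Centered moving average with truncated edges
#'
#' Smooths a per-probe track with a centered window of `w` probes; at the
#' track ends the window is truncated to the available probes, so the
#' output has the same length as the input and `w = 1` is the identity.
#'
#' @param x Numeric per-probe values in design order.
#' @param w Odd window size in probes, `1 <= w <= length(x)`.
#' @return The smoothed numeric vector.
#' @examples
#' moving_average(c(0, 0, -1, -1, -1, 0, 0), 3)
#' @export
moving_average <- function(x, w = 5) {
  n <- length(x)
  if (w %% 2 == 0) abort("window w must be odd")
  if (w < 1 || w > n) abort("window w must lie in [1, length(x)]")
  if (w == 1) return(as.numeric(x))
  half <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Smooth every sample column of a log2-ratio matrix
#'
#' @param mat A wide log2-ratio tibble.
#' @param w Odd moving-average window in probes.
#' @return The tibble of smoothed tracks (attribute `window` records `w`).
#' @export
smooth_tracks <- function(mat, w = 5) {
  v <- ratio_matrix(mat)
  if (!ncol(v)) {
    out <- mat
    attributes(out)$window <- w
    return(out)
  }
  sm <- apply(v, 2, moving_average, w = w)
  out <- bind_cols_matrix(mat$probe_id, sm)
  attributes(out)$window <- w
  out
}

#' Reference envelope from a normal panel
#'
#' Per-probe median, mean, and sample SD (n - 1 denominator) of the
#' smoothed log2 ratios across a panel of normal individuals. The
#' `median - 1 SD` line is the loss-calling threshold; the `mean +/- 1 SD`
#' band defines the reported "unchanged" range.
#'
#' @param normal_mat A wide tibble of (smoothed) normal-panel tracks.
#' @param design Optional probe design for a consistency check.
#' @return A tibble `probe_id`, `median`, `mean`, `sd` with attributes
#'   `n_panel` and `window`.
#' @export
build_envelope <- function(normal_mat, design = NULL) {
  v <- ratio_matrix(normal_mat)
  if (ncol(v) < 2) abort("normal panel must have >= 2 samples")
  if (!is.null(design) &&
      (nrow(design) != nrow(v) || !all(design$probe_id == normal_mat$probe_id))) {
    abort("normal panel is not on the given design")
  }
  env <- tibble(
    probe_id = normal_mat$probe_id,
    median = unname(apply(v, 1, median)),
    mean = unname(rowMeans(v)),
    sd = unname(apply(v, 1, sd))
  )
  attributes(env)$n_panel <- ncol(v)
  attributes(env)$window <- attr(normal_mat, "window", exact = TRUE)
  env
}

#' Classify probes against the reference envelope
#'
#' A probe is `loss` iff its smoothed value falls strictly below
#' `median - 1 * SD` at that probe (the downward deviation must exceed
#' 1 SD from the median probe ratio); otherwise it is `unchanged`.
#' Boundary values — including every value when SD is 0 — are `unchanged`.
#'
#' @param values Numeric smoothed track aligned to the envelope.
#' @param envelope A [build_envelope()] tibble.
#' @return Character vector of `"loss"` / `"unchanged"` per probe.
#' @export
classify_probes <- function(values, envelope) {
  if (length(values) != nrow(envelope)) {
    abort("track and envelope are not on the same design")
  }
  ifelse(values < envelope$median - envelope$sd, "loss", "unchanged")
}

#' Delineate copy-number segments for one sample
#'
#' Turns per-probe classes into a partition of the region:
#' * probes overlapping LCR masks are excluded as evidence (their class
#'   is ignored and runs break there);
#' * maximal runs of at least `min_run` consecutive loss probes become
#'   `loss` segments; shorter loss runs are demoted to `unchanged`;
#' * the probe-free gap and every LCR mask are emitted as `no_call`
#'   segments at their exact coordinates;
#' * all remaining territory is `unchanged`.
#'
#' Probe classes are extended to the midpoints between adjacent probes,
#' so the returned segments tile `[region_start, region_end)` exactly.
#'
#' @param classes Per-probe classes from [classify_probes()].
#' @param design The probe design.
#' @param region The [region_model()].
#' @param min_run Minimum supporting probes for a loss segment
#'   (default 25; see the methods vignette for the run-length analysis
#'   behind this choice).
#' @param values Optional smoothed values used to report per-segment
#'   mean ratios.
#' @return A tibble `start`, `end`, `class`, `n_probes`, `mean_ratio`,
#'   sorted and non-overlapping, whose lengths sum to the region length.
#' @export
segment_calls <- function(classes, design, region, min_run = 25,
                          values = NULL) {
  if (length(classes) != nrow(design)) {
    abort("classes are not aligned to design probes")
  }
  cls <- classes
  cls[probe_masked(design, region)] <- "no_call"

  # demote sub-threshold loss runs (runs already broken by no_call/unchanged)
  r <- rle(cls)
  demote <- r$values == "loss" & r$lengths < min_run
  r$values[demote] <- "unchanged"
  cls <- inverse.rle(r)

  n <- nrow(design)
  mids <- if (n > 1) floor((design$end[-n] + design$start[-1]) / 2) else numeric(0)
  tile_bounds <- c(region$region_start, mids, region$region_end)

  nc <- nocall_intervals(region)
  cuts <- sort(unique(pmin(pmax(
    c(tile_bounds, nc$start, nc$end),
    region$region_start), region$region_end)))
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  keep <- hi > lo
  lo <- lo[keep]; hi <- hi[keep]
  mid <- (lo + hi) / 2

  in_nc <- vapply(mid, function(m) any(m >= nc$start & m < nc$end), logical(1))
  tile_idx <- findInterval(mid, tile_bounds, rightmost.closed = TRUE)
  tile_idx <- pmin(pmax(tile_idx, 1L), n)
  piece_class <- ifelse(in_nc, "no_call", cls[tile_idx])
  piece_class[!in_nc & piece_class == "no_call"] <- "unchanged"

  # merge adjacent equal-class pieces
  rr <- rle(piece_class)
  seg_end_i <- cumsum(rr$lengths)
  seg_start_i <- seg_end_i - rr$lengths + 1
  segs <- tibble(
    start = lo[seg_start_i],
    end = hi[seg_end_i],
    class = rr$values
  )

  pm <- (design$start + design$end) / 2
  segs$n_probes <- vapply(seq_len(nrow(segs)), function(i) {
    sum(pm >= segs$start[i] & pm < segs$end[i])
  }, integer(1))
  segs$mean_ratio <- NA_real_
  if (!is.null(values)) {
    segs$mean_ratio <- vapply(seq_len(nrow(segs)), function(i) {
      hit <- pm >= segs$start[i] & pm < segs$end[i]
      if (any(hit)) mean(values[hit]) else NA_real_
    }, numeric(1))
  }
  segs
}

#' Stage-2 tiling-aCGH validation of a cohort
#'
#' Composes the full envelope caller per test sample: moving-average
#' smoothing, normal-panel envelope, `median - 1 SD` probe
#' classification, and segment delineation with no-call masking. The
#' carrier verdict is `TRUE` when any loss segment overlaps the queried
#' locus by at least `min_overlap_bp`. Normal-panel members are also
#' called against the envelope (built including themselves) as a
#' self-consistency readout.
#'
#' @param mat Wide log2-ratio tibble of the test samples.
#' @param normal_mat Wide tibble of the normal reference panel (>= 2
#'   samples, same design).
#' @param design,region Probe design and [region_model()].
#' @param locus_start,locus_end Queried locus (default: the gap plus
#'   150 kb on each side, where deletions in this region cluster).
#' @param w Moving-average window (odd, default 5 probes).
#' @param min_run Minimum probes per loss segment (default 25).
#' @param min_overlap_bp Minimum locus overlap for a carrier verdict.
#' @param smooth Set `FALSE` to apply the 1-SD rule to raw ratios.
#' @param recenter Iteratively re-baseline each sample on its own
#'   probes classified `unchanged` in a first pass (default `TRUE`).
#'   Region-targeted arrays leave few guaranteed-diploid probes for the
#'   initial centering, so the first-pass baseline is noisy; one
#'   re-estimation pass over each sample's unchanged probes removes
#'   that per-sample offset (the classic iterative
#'   normalization-calling loop).
#' @return An object of class `cnv_validation`: `$verdicts` (per test
#'   sample: `carrier`, number of loss segments, bridged loss span),
#'   `$segments` (all samples), `$normal_verdicts`, `$envelope`, and the
#'   parameters used.
#' @export
validate_samples <- function(mat, normal_mat, design, region,
                             locus_start = region$gap_start - 150000,
                             locus_end = region$gap_end + 150000,
                             w = 5, min_run = 25, min_overlap_bp = 1,
                             smooth = TRUE, recenter = TRUE) {
  if (!identical(mat$probe_id, design$probe_id) ||
      !identical(normal_mat$probe_id, design$probe_id)) {
    abort("matrices and design must share the same probes")
  }
  sm_test <- if (smooth) smooth_tracks(mat, w) else mat
  sm_norm <- if (smooth) smooth_tracks(normal_mat, w) else normal_mat

  if (recenter) {
    env0 <- build_envelope(sm_norm, design)
    rebase <- function(sm) {
      v <- ratio_matrix(sm)
      off <- vapply(seq_len(ncol(v)), function(j) {
        unchanged <- classify_probes(v[, j], env0) == "unchanged"
        median(v[unchanged, j])
      }, numeric(1))
      out <- bind_cols_matrix(sm$probe_id, sweep(v, 2, off))
      attributes(out)$window <- attr(sm, "window", exact = TRUE)
      out
    }
    sm_norm <- rebase(sm_norm)
    sm_test <- rebase(sm_test)
  }
  envelope <- build_envelope(sm_norm, design)

  call_one <- function(values, sample_id, group) {
    cls <- classify_probes(values, envelope)
    segs <- segment_calls(cls, design, region, min_run = min_run,
                          values = values)
    segs$sample_id <- sample_id
    segs$group <- group
    loss <- segs[segs$class == "loss", , drop = FALSE]
    ov <- if (nrow(loss)) {
      overlap_bp(loss$start, loss$end, locus_start, locus_end)
    } else numeric(0)
    hit <- nrow(loss) > 0 && any(ov >= min_overlap_bp)
    span <- if (hit) {
      lh <- loss[ov >= min_overlap_bp, , drop = FALSE]
      c(min(lh$start), max(lh$end))
    } else c(NA_real_, NA_real_)
    list(
      verdict = tibble(
        sample_id = sample_id, group = group, carrier = hit,
        n_loss_segments = nrow(loss),
        loss_span_start = span[1], loss_span_end = span[2]
      ),
      segments = segs
    )
  }

  vt <- ratio_matrix(sm_test)
  vn <- ratio_matrix(sm_norm)
  res_test <- purrr::map(seq_len(ncol(vt)), function(j) {
    call_one(vt[, j], colnames(vt)[j], "test")
  })
  res_norm <- purrr::map(seq_len(ncol(vn)), function(j) {
    call_one(vn[, j], colnames(vn)[j], "normal_panel")
  })

  structure(
    list(
      verdicts = purrr::map_dfr(res_test, "verdict"),
      normal_verdicts = purrr::map_dfr(res_norm, "verdict"),
      segments = bind_rows(purrr::map_dfr(res_test, "segments"),
                           purrr::map_dfr(res_norm, "segments")),
      envelope = envelope,
      params = list(locus_start = locus_start, locus_end = locus_end,
                    w = w, min_run = min_run,
                    min_overlap_bp = min_overlap_bp, smooth = smooth,
                    recenter = recenter),
      region = region
    ),
    class = "cnv_validation"
  )
}

#' @export
print.cnv_validation <- function(x, ...) {
  cat(sprintf(
    "<cnv_validation> %d test samples (%d carriers), %d-sample normal panel (%d carriers)\n",
    nrow(x$verdicts), sum(x$verdicts$carrier),
    nrow(x$normal_verdicts), sum(x$normal_verdicts$carrier)
  ))
  invisible(x)
}

#' @rdname validate_samples
#' @param x A `cnv_validation` object.
#' @param ... Unused.
#' @export
tidy.cnv_validation <- function(x, ...) x$verdicts

#' @rdname validate_samples
#' @export
glance.cnv_validation <- function(x, ...) {
  tibble(
    n_test = nrow(x$verdicts),
    n_carrier = sum(x$verdicts$carrier),
    n_normal_panel = nrow(x$normal_verdicts),
    n_normal_carrier = sum(x$normal_verdicts$carrier),
    window = x$params$w, min_run = x$params$min_run
  )
}

#' Jaccard overlap between called loss spans and true deletions
#'
#' For each true carrier, compares the bridged loss span (minimum start
#' to maximum end of its loss segments at the locus — interior no-call
#' territory from the gap and the LCR masks is bridged, as a deletion
#' spanning the gap necessarily is) against the simulated truth interval.
#'
#' @param validation A [validate_samples()] result.
#' @param truths The [simulate_cohort()] truth tibble.
#' @return A tibble per true carrier: `sample_id`, `called`, `jaccard`.
#' @export
recovery_jaccard <- function(validation, truths) {
  tc <- truths[truths$carrier, , drop = FALSE]
  v <- left_join(tc, validation$verdicts, by = "sample_id")
  called <- !is.na(v$carrier.y) & v$carrier.y
  jac <- numeric(nrow(v))
  ok <- called & !is.na(v$loss_span_start)
  jac[ok] <- interval_jaccard(v$loss_span_start[ok], v$loss_span_end[ok],
                              v$del_start[ok], v$del_end[ok])
  tibble(sample_id = v$sample_id, called = called, jaccard = jac)
}
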