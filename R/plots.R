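#' Plot one sample's smoothed track against the reference envelope
#'
#' The classic tiling-aCGH view: the sample's moving-average log2 ratio
#' along the region, the normal-panel median (dotted) and the
#' mean +/- 1 SD band (light), with the gap and LCR masks shaded and
#' called loss segments highlighted.
#'
#' @param validation A [validate_samples()] result.
#' @param sample_id Which sample to draw.
#' @param mat The (unsmoothed) test matrix used in the validation; it is
#'   re-smoothed with the validation's window.
#' @param design The probe design.
#' @return A ggplot object.
#' @export
plot_track <- function(validation, sample_id, mat, design) {
  stopifnot(inherits(validation, "cnv_validation"))
  if (!sample_id %in% names(mat)) abort("sample not found in matrix")
  env <- validation$envelope
  region <- validation$region
  w <- validation$params$w
  sm <- if (validation$params$smooth) {
    moving_average(mat[[sample_id]], w)
  } else {
    mat[[sample_id]]
  }
  df <- tibble(
    pos = (design$start + design$end) / 2,
    value = sm, median = env$median,
    lo = env$mean - env$sd, hi = env$mean + env$sd
  )
  segs <- validation$segments
  loss <- segs[segs$sample_id == sample_id & segs$class == "loss", ]
  nc <- nocall_intervals(region)

  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos)) +
    ggplot2::geom_rect(
      data = nc,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "grey85", inherit.aes = FALSE
    ) +
    ggplot2::geom_rect(
      data = loss,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, fill = "grey70", alpha = 0.5,
      inherit.aes = FALSE
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lo), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hi), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "grey40",
                       linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value), colour = "black",
                       linewidth = 0.4) +
    ggplot2::labs(
      x = sprintf("position on %s (bp)", region$chrom),
      y = "moving-average log2 ratio",
      title = sample_id,
      subtitle = sprintf("window %d probes; band: normal-panel mean ± 1 SD", w)
    ) +
    ggplot2::theme_minimal()
}

#' Cohort segment bar view
#'
#' Horizontal per-sample bars across the region: loss segments dark,
#' no-call territory (gap, LCR masks) hatched grey — the whole-cohort
#' structural view of who lost what around the gap.
#'
#' @param validation A [validate_samples()] result.
#' @param which `"carriers"` (default) to show only carrier samples, or
#'   `"all"`.
#' @return A ggplot object.
#' @export
plot_cohort_segments <- function(validation, which = c("carriers", "all")) {
  stopifnot(inherits(validation, "cnv_validation"))
  which <- match.arg(which)
  segs <- validation$segments[validation$segments$group == "test", ]
  if (which == "carriers") {
    keep <- validation$verdicts$sample_id[validation$verdicts$carrier]
    segs <- segs[segs$sample_id %in% keep, ]
  }
  if (!nrow(segs)) abort("no segments to plot")
  segs <- mutate(segs, sample_id = factor(.data$sample_id))

  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = as.integer(.data$sample_id) - 0.4,
      ymax = as.integer(.data$sample_id) + 0.4,
      fill = .data$class
    )) +
    ggplot2::scale_fill_manual(values = c(
      loss = "grey10", unchanged = "grey92", no_call = "grey60"
    )) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(segs$sample_id)),
      labels = levels(segs$sample_id)
    ) +
    ggplot2::labs(x = "position (bp)", y = NULL, fill = "call") +
    ggplot2::theme_minimal()
}

#' @rdname plot_cohort_segments
#' @param object A `cnv_validation` object.
#' @param ... Passed to [plot_cohort_segments()].
#' @export
autoplot.cnv_validation <- function(object, ...) {
  plot_cohort_segments(object, ...)
}

#' Odds-ratio forest view of association results
#'
#' @param object A `cnv_assoc` tibble.
#' @param ... Unused.
#' @return A ggplot object (log-scaled odds ratios with Woolf CIs).
#' @export
autoplot.cnv_assoc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$or, y = .data$locus_id
  )) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.15
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% Woolf CI)", y = NULL) +
    ggplot2::theme_minimal()
}
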