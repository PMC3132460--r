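#' Median-center each sample column
#'
#' Subtracts the per-sample median log2 ratio so that every sample is
#' centered on the diploid baseline. First component of the intensity
#' normalization stage (the platform vendor's proprietary normalization
#' is not public; the pipeline uses documented standard steps).
#'
#' When a copy-number event can cover a large share of the probes — as a
#' deletion spanning much of a region-targeted array does — the sample's
#' own median is contaminated by the event; pass `design` and `exclude`
#' to compute the median over reference probes outside the candidate
#' territory while still shifting every probe.
#'
#' @param mat A wide log2-ratio tibble (`probe_id` + one column per sample).
#' @param design Probe design; required when `exclude` is given.
#' @param exclude Optional data frame of intervals (`start`, `end`)
#'   whose probes are withheld from the median estimate.
#' @return The tibble with every sample column shifted to median 0
#'   (median over the reference probes when `exclude` is used).
#' @examples
#' m <- tibble::tibble(probe_id = c("p1", "p2", "p3"), s1 = c(1, 2, 3))
#' median_center(m)$s1 # -1 0 1
#' @export
median_center <- function(mat, design = NULL, exclude = NULL) {
  if (!nrow(mat)) abort("matrix is empty")
  v <- ratio_matrix(mat)
  keep <- keep_probes(v, design, exclude)
  v <- sweep(v, 2, apply(v[keep, , drop = FALSE], 2, median))
  out <- bind_cols_matrix(mat$probe_id, v)
  attributes(out)$norm_report <- attr(mat, "norm_report", exact = TRUE)
  out
}

#' GC-content correction
#'
#' Per sample, fits the log2 ratio against probe GC fraction and
#' subtracts the GC-dependent part of the fit (the fit centered at the
#' mean GC), removing GC-dependent intensity bias while leaving the
#' sample baseline to [median_center()]. `method = "linear"` is a
#' closed-form least-squares line (exactly idempotent); `method =
#' "loess"` is a local regression with fixed span. A matrix with no GC
#' dependence passes through unchanged (up to fit noise).
#'
#' The fit can be estimated on reference probes only (outside `exclude`
#' intervals) and subtracted from all probes. By default all probes are
#' used: the fitted line is insensitive to a copy-number event because
#' a deletion spanning many GC-wave periods is nearly uncorrelated with
#' GC, and restricting to a narrow sub-region would under-sample the GC
#' range and extrapolate badly.
#'
#' @param mat A wide log2-ratio tibble.
#' @param design The matching probe design (supplies `gc`).
#' @param method `"linear"` (default) or `"loess"`.
#' @param span Loess span (default 0.3); ignored for linear.
#' @param exclude Optional intervals withheld from fit estimation.
#' @return The corrected tibble; the fit coefficients are recorded in the
#'   normalization report (see [norm_report()]).
#' @export
gc_correct <- function(mat, design, method = c("linear", "loess"),
                       span = 0.3, exclude = NULL) {
  method <- match.arg(method)
  v <- ratio_matrix(mat)
  if (nrow(v) != nrow(design) || !all(mat$probe_id == design$probe_id)) {
    abort("design does not match matrix probes")
  }
  gc <- design$gc
  if (any(!is.finite(gc))) abort("non-finite gc_fraction in design")

  if (isTRUE(all.equal(stats::var(gc), 0)) || length(unique(gc)) == 1L) {
    warn("constant GC across probes: GC correction skipped")
    rep_tbl <- tibble(
      sample_id = colnames(v), method = "skipped",
      intercept = NA_real_, slope = NA_real_
    )
    return(add_report(mat, gc_fit = rep_tbl))
  }

  keep <- keep_probes(v, design, exclude)
  gc_c <- gc - mean(gc[keep])
  if (method == "linear") {
    # closed-form least squares per sample column on reference probes;
    # only the GC-dependent term slope * (gc - mean gc) is subtracted
    vk <- sweep(v[keep, , drop = FALSE], 2, colMeans(v[keep, , drop = FALSE]))
    gk <- gc_c[keep] - mean(gc_c[keep])
    slope <- as.numeric(crossprod(gk, vk)) / sum(gk^2)
    res <- v - outer(gc_c, slope)
    rep_tbl <- tibble(
      sample_id = colnames(v), method = "linear",
      intercept = colMeans(v[keep, , drop = FALSE]), slope = slope
    )
  } else {
    res <- v
    slope <- rep(NA_real_, ncol(v))
    for (j in seq_len(ncol(v))) {
      fit <- loess(v[keep, j] ~ gc[keep], span = span, degree = 2,
                   family = "gaussian",
                   control = stats::loess.control(surface = "direct"))
      fitted <- predict(fit, gc)
      res[, j] <- v[, j] - (fitted - mean(fitted))
    }
    rep_tbl <- tibble(
      sample_id = colnames(v), method = "loess",
      intercept = NA_real_, slope = slope
    )
  }
  out <- bind_cols_matrix(mat$probe_id, res)
  attributes(out)$norm_report <- attr(mat, "norm_report", exact = TRUE)
  add_report(out, gc_fit = rep_tbl)
}

#' Remove batch effects by principal-component regression
#'
#' Estimates the top `k` sample-space principal components of the
#' probes-by-samples matrix by singular value decomposition — using only
#' probes outside `exclude` intervals, so that a real copy-number signal
#' at a candidate locus is not treated as a batch axis — and projects
#' those components out of every probe row. The input is expected to be
#' column-centered (run [median_center()] first); no further centering is
#' applied, so a pure low-rank artifact is removed exactly.
#'
#' @param mat A wide log2-ratio tibble, column-centered.
#' @param k Number of components to remove; `k <= 0` returns the input
#'   unchanged with a warning.
#' @param design Probe design (needed when `exclude` is given).
#' @param exclude Optional data frame of intervals (`start`, `end`) whose
#'   probes are withheld from component estimation (e.g. candidate CNV
#'   loci).
#' @return The corrected tibble; variance-explained fractions of the
#'   removed components are recorded in the normalization report.
#' @export
remove_batch_pca <- function(mat, k = 2, design = NULL, exclude = NULL) {
  v <- ratio_matrix(mat)
  if (k <= 0) {
    warn("k <= 0: batch removal is the identity transform")
    return(add_report(mat, pca = tibble(component = integer(),
                                        var_explained = double())))
  }
  if (k >= ncol(v)) abort("k must be smaller than the number of samples")

  keep <- keep_probes(v, design, exclude)

  sv <- svd(v[keep, , drop = FALSE], nu = 0, nv = k)
  tot <- sum(v[keep, , drop = FALSE]^2)
  varfrac <- (sv$d[seq_len(k)]^2) / tot
  res <- v - (v %*% sv$v) %*% t(sv$v)

  out <- bind_cols_matrix(mat$probe_id, res)
  attributes(out)$norm_report <- attr(mat, "norm_report", exact = TRUE)
  add_report(out, pca = tibble(component = seq_len(k),
                               var_explained = varfrac))
}

#' Normalize a log2-ratio matrix (median center + GC + batch PCA)
#'
#' Composes the three normalization steps in their standard order.
#'
#' @inheritParams gc_correct
#' @inheritParams remove_batch_pca
#' @return The normalized tibble with the accumulated report attached.
#' @export
#' @param gc_exclude Intervals withheld from the GC fit (default `NULL`:
#'   the GC line is fitted on all probes; see [gc_correct()]).
normalize_matrix <- function(mat, design, method = "linear", k = 2,
                             exclude = NULL, gc_exclude = NULL) {
  mat |>
    median_center(design = design, exclude = exclude) |>
    gc_correct(design, method = method, exclude = gc_exclude) |>
    remove_batch_pca(k = k, design = design, exclude = exclude)
}

#' Normalize a simulated study jointly
#'
#' Binds the cohort and the normal reference panel into one matrix,
#' normalizes once ([normalize_matrix()]) so both are corrected on the
#' same GC curve and batch axes, and splits them back. By default the
#' deletion territory implied by the simulation config is excluded from
#' every fit so the carrier contrast survives normalization.
#'
#' @param study A [simulate_study()] result.
#' @param method,k Passed to [normalize_matrix()].
#' @param exclude Intervals excluded from fit estimation; defaults to
#'   [deletion_territory()] of the study.
#' @return The study with `matrix` and `normal_matrix` normalized.
#' @export
normalize_study <- function(study, method = "linear", k = 2,
                            exclude = deletion_territory(study$region,
                                                         study$config)) {
  stopifnot(inherits(study, "cnv_study"))
  joint <- dplyr::bind_cols(
    study$matrix,
    study$normal_matrix[, setdiff(names(study$normal_matrix), "probe_id")]
  )
  norm <- normalize_matrix(joint, study$design, method = method, k = k,
                           exclude = exclude)
  study$matrix <- norm[, c("probe_id", study$truths$sample_id)]
  study$normal_matrix <- norm[, c("probe_id", study$normal_truths$sample_id)]
  study
}

# logical index of probes outside the exclude intervals
keep_probes <- function(v, design, exclude) {
  keep <- rep(TRUE, nrow(v))
  if (is.null(exclude) || !nrow(exclude)) {
    return(keep)
  }
  if (is.null(design)) abort("exclude requires the probe design")
  if (nrow(design) != nrow(v)) abort("design does not match matrix probes")
  for (i in seq_len(nrow(exclude))) {
    keep <- keep & !(design$end > exclude$start[i] &
                       design$start < exclude$end[i])
  }
  if (!any(keep)) abort("exclude intervals cover every probe")
  keep
}

#' Retrieve the normalization report
#'
#' @param mat A tibble returned by the normalization functions.
#' @return A list with elements `gc_fit` (per-sample fit coefficients)
#'   and/or `pca` (variance explained per removed component).
#' @export
norm_report <- function(mat) {
  attr(mat, "norm_report", exact = TRUE) %||% list()
}

add_report <- function(mat, ...) {
  rep <- attr(mat, "norm_report", exact = TRUE) %||% list()
  new <- list(...)
  rep[names(new)] <- new
  attributes(mat)$norm_report <- rep
  mat
}
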