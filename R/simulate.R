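#' Simulation configuration for a case-control array cohort
#'
#' Bundles every knob of the cohort generator. The defaults encode the
#' study conditions the pipeline is designed around: 100 cases and 100
#' controls, heterozygous-deletion carrier prevalence 0.13 among cases and
#' 0.01 among controls, one deletion per carrier anchored over the
#' assembly gap, a diploid log2 ratio of 0 and a heterozygous-deletion
#' ratio of -1 attenuated by a hybridisation response factor of 0.75,
#' per-probe Gaussian noise of SD 0.25, a GC-bias slope of 0.5 per unit GC
#' deviation, and two batches with rank-one batch structure.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param p_case,p_control Carrier prevalence by status, in `[0, 1]`.
#' @param del_min_bp,del_max_bp Deletion span range (bp); spans are drawn
#'   uniformly and positioned to contain the gap (deletions in this
#'   region cluster around the gap).
#' @param cn_loss Carrier copy number (default 1, heterozygous loss).
#' @param mu_per_cn Named vector mapping copy number to expected log2
#'   ratio before attenuation; must satisfy `mu_per_cn["2"] == 0` and
#'   `mu_per_cn["1"] == -1` (log2(1/2) for one lost copy of two).
#' @param response_factor Multiplicative attenuation in `(0, 1]` applied
#'   to `mu_per_cn`, emulating array ratio compression.
#' @param sigma_probe Per-probe Gaussian noise SD (>= 0; 0 gives the
#'   analytic noise-free limit).
#' @param gc_slope Log2-ratio change per unit GC deviation from the mean.
#' @param n_batches Number of processing batches.
#' @param batch_effect_sd SD of the per-batch loading in the rank-one
#'   batch term (loading x per-probe factor).
#' @param seed Integer seed; every generator output is a deterministic
#'   function of `(config, seed)`.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 100, n_controls = 100,
                       p_case = 0.13, p_control = 0.01,
                       del_min_bp = 200000, del_max_bp = 800000,
                       cn_loss = 1L,
                       mu_per_cn = c("0" = -3, "1" = -1, "2" = 0, "3" = 0.585),
                       response_factor = 0.75,
                       sigma_probe = 0.25,
                       gc_slope = 0.5,
                       n_batches = 2L,
                       batch_effect_sd = 0.1,
                       seed = 1L) {
  if (p_case < 0 || p_case > 1 || p_control < 0 || p_control > 1) {
    abort("prevalences must lie in [0, 1]")
  }
  if (sigma_probe < 0) abort("sigma_probe must be >= 0")
  if (response_factor <= 0 || response_factor > 1) {
    abort("response_factor must lie in (0, 1]")
  }
  if (is.null(names(mu_per_cn)) ||
      !all(c("1", "2") %in% names(mu_per_cn))) {
    abort("mu_per_cn must be named by copy number and include \"1\" and \"2\"")
  }
  if (mu_per_cn[["2"]] != 0) abort("mu_per_cn[\"2\"] must be 0 (diploid)")
  if (mu_per_cn[["1"]] != -1) {
    abort("mu_per_cn[\"1\"] must be -1 (log2(1/2), heterozygous loss)")
  }
  if (del_min_bp <= 0 || del_max_bp < del_min_bp) {
    abort("need 0 < del_min_bp <= del_max_bp")
  }
  if (n_batches < 1) abort("n_batches must be >= 1")
  structure(
    list(
      n_cases = n_cases, n_controls = n_controls,
      p_case = p_case, p_control = p_control,
      del_min_bp = del_min_bp, del_max_bp = del_max_bp,
      cn_loss = as.integer(cn_loss), mu_per_cn = mu_per_cn,
      response_factor = response_factor, sigma_probe = sigma_probe,
      gc_slope = gc_slope, n_batches = as.integer(n_batches),
      batch_effect_sd = batch_effect_sd, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate carrier truth profiles for a case-control cohort
#'
#' Draws carrier status independently per sample at the status-specific
#' prevalence and gives each carrier one deletion interval whose span is
#' uniform in `[del_min_bp, del_max_bp]` and which contains the gap
#' (placed with a uniformly drawn left overhang, clamped to the region).
#' Batches are assigned uniformly at random.
#'
#' @param config A [sim_config()].
#' @param region A [region_model()].
#' @param exact_carriers Optional named vector `c(case = k1, control = k2)`
#'   fixing the carrier counts instead of drawing them binomially —
#'   used to emulate a cohort with a known carrier table.
#' @param seed Seed override; defaults to `config$seed`.
#' @return A tibble with one row per sample: `sample_id`, `status`
#'   (`"case"`/`"control"`), `batch`, `carrier`, `del_start`, `del_end`
#'   (NA for non-carriers), `cn`.
#' @export
simulate_cohort <- function(config, region, exact_carriers = NULL,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(region, "region_model"))
  seed <- seed %||% config$seed
  n <- config$n_cases + config$n_controls
  status <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
  sample_id <- sprintf("%s_%03d", status,
                       c(seq_len(config$n_cases), seq_len(config$n_controls)))

  withr::with_seed(derive_seed(seed, 1L), {
    batch <- sample.int(config$n_batches, n, replace = TRUE)
    if (is.null(exact_carriers)) {
      carrier <- rbinom(n, 1, ifelse(status == "case",
                                     config$p_case, config$p_control)) == 1
    } else {
      carrier <- logical(n)
      for (st in c("case", "control")) {
        k <- unname(exact_carriers[[st]] %||% 0)
        idx <- which(status == st)
        if (k > length(idx)) abort("exact_carriers exceeds group size")
        carrier[sample(idx, k)] <- TRUE
      }
    }
    gap_len <- region$gap_end - region$gap_start
    if (config$del_min_bp < gap_len) {
      abort("del_min_bp smaller than the gap: deletions must contain the gap")
    }
    span <- runif(n, config$del_min_bp, config$del_max_bp)
    u <- runif(n)
    del_start <- round(region$gap_start - u * (span - gap_len))
    del_end <- del_start + round(span)
    shift_r <- pmax(0, region$region_start - del_start)
    del_start <- del_start + shift_r
    del_end <- del_end + shift_r
    shift_l <- pmax(0, del_end - region$region_end)
    del_start <- del_start - shift_l
    del_end <- del_end - shift_l
    del_start[!carrier] <- NA_real_
    del_end[!carrier] <- NA_real_

    tibble(
      sample_id = sample_id, status = status, batch = batch,
      carrier = carrier, del_start = del_start, del_end = del_end,
      cn = ifelse(carrier, config$cn_loss, 2L)
    )
  })
}

#' Simulate a probes-by-samples log2-ratio matrix
#'
#' Generates `value(probe, sample) = response_factor * mu_per_cn[cn] +
#' gc_slope * (gc - mean(gc)) + batch loading x probe factor + N(0,
#' sigma_probe)`, with the copy number at a probe determined by >= 1 bp
#' overlap with the sample's deletion interval. Bitwise reproducible from
#' `(design, truths, config, seed)`.
#'
#' @param design A probe design from [build_array_design()].
#' @param truths A truth tibble from [simulate_cohort()].
#' @param config A [sim_config()].
#' @param seed Seed override; defaults to `config$seed`.
#' @return A wide tibble: `probe_id` plus one numeric column per sample.
#' @export
simulate_log2_matrix <- function(design, truths, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!nrow(truths)) abort("truths is empty")
  if (!nrow(design)) abort("design is empty")
  seed <- seed %||% config$seed
  carriers <- truths[truths$carrier, , drop = FALSE]
  if (nrow(carriers)) {
    cover <- overlap_bp(carriers$del_start, carriers$del_end,
                        min(design$start), max(design$end))
    if (any(cover <= 0)) {
      abort("design/truth region mismatch: a deletion lies outside the design")
    }
  }

  np <- nrow(design)
  ns <- nrow(truths)
  gc_dev <- design$gc - mean(design$gc)
  mu2 <- config$response_factor * config$mu_per_cn[["2"]]

  # batch structure is a property of the protocol, not of the noise draw:
  # derive it from the config seed so every matrix simulated under one
  # config (cohort, reference panel) shares the same batch axes
  batch <- withr::with_seed(derive_seed(config$seed, 5L), {
    list(load = rnorm(config$n_batches, 0, config$batch_effect_sd),
         probe_factor = rnorm(np))
  })
  withr::with_seed(derive_seed(seed, 2L), {
    batch_load <- batch$load
    probe_factor <- batch$probe_factor
    vals <- matrix(rnorm(np * ns, 0, config$sigma_probe), np, ns)
    for (j in seq_len(ns)) {
      mu <- rep(mu2, np)
      if (truths$carrier[j]) {
        hit <- design$end > truths$del_start[j] &
          design$start < truths$del_end[j]
        mu[hit] <- config$response_factor *
          config$mu_per_cn[[as.character(truths$cn[j])]]
      }
      vals[, j] <- vals[, j] + mu + config$gc_slope * gc_dev +
        batch_load[truths$batch[j]] * probe_factor
    }
    colnames(vals) <- truths$sample_id
    bind_cols_matrix(design$probe_id, vals)
  })
}

# wide tibble <-> numeric matrix helpers -----------------------------------

bind_cols_matrix <- function(probe_id, vals) {
  if (is.null(dim(vals)) || ncol(vals) == 0) {
    return(tibble(probe_id = probe_id))
  }
  out <- as_tibble(as.data.frame(vals, check.names = FALSE))
  dplyr::bind_cols(tibble(probe_id = probe_id), out)
}

#' Extract the numeric value matrix from a wide log2-ratio tibble
#'
#' @param mat A wide tibble (`probe_id` + one column per sample).
#' @return A numeric matrix with probe ids as row names.
#' @export
ratio_matrix <- function(mat) {
  m <- as.matrix(mat[, setdiff(names(mat), "probe_id"), drop = FALSE])
  rownames(m) <- mat$probe_id
  m
}

#' Deletion territory implied by the anchoring rule
#'
#' Every simulated deletion contains the gap and spans at most
#' `del_max_bp`, so its extent is confined to the gap plus
#' `del_max_bp - gap length` on either side (clipped to the region).
#' This is the interval to exclude from batch-effect PC estimation so
#' that the carrier contrast is not regressed out (see
#' [remove_batch_pca()]).
#'
#' @param region A [region_model()].
#' @param config A [sim_config()].
#' @return A one-row tibble `start`, `end`.
#' @export
deletion_territory <- function(region, config) {
  reach <- config$del_max_bp - (region$gap_end - region$gap_start)
  tibble(
    start = max(region$region_start, region$gap_start - reach),
    end = min(region$region_end, region$gap_end + reach)
  )
}

#' Simulate a full two-stage study
#'
#' Convenience wrapper: builds the probe design, draws the case-control
#' cohort and its log2-ratio matrix, and additionally simulates a
#' diploid normal reference panel on the same design (used to build the
#' tiling-aCGH reference envelope).
#'
#' @param config A [sim_config()].
#' @param region A [region_model()].
#' @param platform,spacing_bp Passed to [build_array_design()].
#' @param n_normal_panel Size of the diploid reference panel (default 15).
#' @param exact_carriers Passed to [simulate_cohort()].
#' @return A list of class `cnv_study` with elements `region`, `design`,
#'   `truths`, `matrix`, `normal_truths`, `normal_matrix`, `config`.
#' @export
simulate_study <- function(config = sim_config(), region = region_model(),
                           platform = "tiling", spacing_bp = NULL,
                           n_normal_panel = 15, exact_carriers = NULL) {
  design <- build_array_design(region, platform, spacing_bp,
                               seed = derive_seed(config$seed, 3L))
  truths <- simulate_cohort(config, region, exact_carriers = exact_carriers)
  mat <- simulate_log2_matrix(design, truths, config)
  normal_truths <- tibble(
    sample_id = sprintf("normal_%03d", seq_len(n_normal_panel)),
    status = "normal",
    batch = rep_len(seq_len(config$n_batches), n_normal_panel),
    carrier = FALSE, del_start = NA_real_, del_end = NA_real_, cn = 2L
  )
  normal_mat <- simulate_log2_matrix(design, normal_truths, config,
                                     seed = derive_seed(config$seed, 4L))
  structure(
    list(
      region = region, design = design, truths = truths, matrix = mat,
      normal_truths = normal_truths, normal_matrix = normal_mat,
      config = config
    ),
    class = "cnv_study"
  )
}

#' @export
print.cnv_study <- function(x, ...) {
  cat(sprintf(
    "<cnv_study> %d probes (%s), %d cases + %d controls (+%d normal panel), %d carriers\n",
    nrow(x$design), x$design$platform[1],
    sum(x$truths$status == "case"), sum(x$truths$status == "control"),
    nrow(x$normal_truths), sum(x$truths$carrier)
  ))
  invisible(x)
}
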