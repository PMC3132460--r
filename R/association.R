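#' Cross-tabulate carrier status against case/control status
#'
#' Builds the 2x2 carrier table `(a, b, c, d)` = (case carriers, case
#' non-carriers, control carriers, control non-carriers).
#'
#' @param verdicts A tibble with `sample_id` and logical `carrier`.
#' @param samples Sample sheet with `sample_id` and `status` (`"case"` /
#'   `"control"`).
#' @return A one-row tibble `a`, `b`, `c`, `d`, `n_cases`, `n_controls`.
#' @examples
#' build_table(
#'   tibble::tibble(sample_id = c("s1", "s2"), carrier = c(TRUE, FALSE)),
#'   tibble::tibble(sample_id = c("s1", "s2"), status = c("case", "control"))
#' )
#' @export
build_table <- function(verdicts, samples) {
  if (!nrow(verdicts)) abort("no verdicts to tabulate")
  unknown <- setdiff(verdicts$sample_id, samples$sample_id)
  if (length(unknown)) {
    abort(sprintf("unknown sample id(s): %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  j <- left_join(verdicts, samples[, c("sample_id", "status")],
                 by = "sample_id")
  if (any(!j$status %in% c("case", "control"))) {
    abort("status must be case or control for every sample")
  }
  tibble(
    a = sum(j$status == "case" & j$carrier),
    b = sum(j$status == "case" & !j$carrier),
    c = sum(j$status == "control" & j$carrier),
    d = sum(j$status == "control" & !j$carrier)
  ) |>
    mutate(n_cases = .data$a + .data$b, n_controls = .data$c + .data$d)
}

#' Two-sided Fisher's exact test by hypergeometric enumeration
#'
#' Enumerates every 2x2 table compatible with the observed margins,
#' computes each point probability with log-factorial arithmetic, and
#' sums those not exceeding the observed table's probability (relative
#' tolerance `1e-7` for ties) — the standard two-sided convention.
#'
#' @param a,b,c,d Cell counts: case carriers, case non-carriers, control
#'   carriers, control non-carriers.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(13, 87, 1, 99)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("negative cell count")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    # a zero margin admits only the observed table
    return(1)
  }
  m1 <- a + b   # cases
  m2 <- c + d   # controls
  k <- a + c    # carriers
  n <- m1 + m2
  xs <- max(0, k - m2):min(m1, k)
  lp <- lgamma(m1 + 1) - lgamma(xs + 1) - lgamma(m1 - xs + 1) +
    lgamma(m2 + 1) - lgamma(k - xs + 1) - lgamma(m2 - k + xs + 1) -
    (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1))
  p <- exp(lp)
  p_obs <- p[xs == a]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

#' Odds ratio with Woolf (logit) confidence interval
#'
#' Point estimate `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied for both
#' the point estimate and the interval. The interval is the Woolf log
#' method: `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams fisher_exact_two_sided
#' @param alpha Two-sided significance level (default 0.05 for 95% CI).
#' @return A one-row tibble `or`, `ci_low`, `ci_high`, `ci_method`.
#' @examples
#' odds_ratio_ci(13, 87, 1, 99)
#' @export
odds_ratio_ci <- function(a, b, c, d, alpha = 0.05) {
  if (any(c(a, b, c, d) < 0)) abort("negative cell count")
  if ((a + b) == 0 || (c + d) == 0) abort("empty margin")
  method <- "woolf"
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    method <- "woolf+haldane"
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  tibble(
    or = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    ci_method = method
  )
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` for each p-value; `m` defaults to the number of
#' p-values supplied and may not be smaller (under-correction is
#' refused).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param m Number of tests (>= `length(p)`).
#' @return Adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 4)
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (m < 1) abort("m must be >= 1")
  if (m < length(p)) abort("m smaller than the number of p-values")
  pmin(1, m * p)
}

#' Case-control carrier association across loci
#'
#' Per locus: builds the carrier table, runs the exact two-sided Fisher
#' test, computes the odds ratio with its Woolf interval, and applies
#' Bonferroni correction with `m` = number of loci tested (overridable,
#' e.g. for a genome-wide test count). Results are sorted by p.
#'
#' @param verdicts A tibble with columns `locus_id`, `sample_id`,
#'   `carrier` (one row per locus x sample).
#' @param samples Sample sheet (`sample_id`, `status`).
#' @param m Bonferroni test count override; default = number of loci.
#' @param alpha CI level for the odds ratio.
#' @return A tibble of class `cnv_assoc`, one row per locus: the table
#'   cells, `p`, `p_bonferroni`, `m`, `or`, `ci_low`, `ci_high`,
#'   `ci_method`.
#' @export
associate_loci <- function(verdicts, samples, m = NULL, alpha = 0.05) {
  if (!"locus_id" %in% names(verdicts)) {
    verdicts <- mutate(verdicts, locus_id = "locus_01")
  }
  loci <- unique(verdicts$locus_id)
  if (!length(loci)) abort("need at least one locus")
  m <- m %||% length(loci)

  res <- purrr::map_dfr(loci, function(l) {
    tab <- build_table(verdicts[verdicts$locus_id == l, ], samples)
    p <- fisher_exact_two_sided(tab$a, tab$b, tab$c, tab$d)
    orci <- odds_ratio_ci(tab$a, tab$b, tab$c, tab$d, alpha = alpha)
    dplyr::bind_cols(tibble(locus_id = l), tab["a"], tab["b"], tab["c"],
                     tab["d"], tibble(p = p), orci)
  })
  p_adj <- bonferroni(res$p, m = m)
  res <- res |>
    mutate(m = !!m, p_bonferroni = !!p_adj) |>
    arrange(.data$p) |>
    select("locus_id", "a", "b", "c", "d", "p", "p_bonferroni", "m",
           "or", "ci_low", "ci_high", "ci_method")
  class(res) <- c("cnv_assoc", class(res))
  res
}

#' @rdname associate_loci
#' @param x A `cnv_assoc` tibble.
#' @param ... Unused.
#' @export
tidy.cnv_assoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "cnv_assoc")
  out
}

#' @rdname associate_loci
#' @export
glance.cnv_assoc <- function(x, ...) {
  tibble(
    n_loci = nrow(x), m = x$m[1],
    min_p = min(x$p), min_p_bonferroni = min(x$p_bonferroni),
    n_significant = sum(x$p_bonferroni < 0.05)
  )
}
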