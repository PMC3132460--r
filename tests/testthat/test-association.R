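# independent oracle: exhaustive table enumeration via stats::dhyper
fisher_oracle <- function(a, b, c, d) {
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) return(1)
  k <- a + c
  xs <- max(0, k - (c + d)):min(a + b, k)
  p <- dhyper(xs, a + b, c + d, k)
  min(1, sum(p[p <= p[xs == a] * (1 + 1e-7)]))
}

test_that("the carrier table cross-tabulates status by verdict", {
  verdicts <- tibble::tibble(
    sample_id = c(sprintf("ca%03d", 1:100), sprintf("co%03d", 1:100)),
    carrier = c(rep(TRUE, 13), rep(FALSE, 87), TRUE, rep(FALSE, 99))
  )
  sheet <- tibble::tibble(
    sample_id = verdicts$sample_id,
    status = rep(c("case", "control"), each = 100)
  )
  tab <- build_table(verdicts, sheet)
  expect_equal(unlist(tab[, c("a", "b", "c", "d")], use.names = FALSE),
               c(13, 87, 1, 99))

  all_car <- dplyr::mutate(verdicts, carrier = TRUE)
  tab2 <- build_table(all_car, sheet)
  expect_equal(tab2$b + tab2$d, 0)

  expect_error(build_table(tibble::tibble(sample_id = "zz", carrier = TRUE),
                           sheet), "unknown sample")
})

test_that("fisher enumeration handles degenerate and small tables exactly", {
  expect_equal(fisher_exact_two_sided(0, 10, 0, 10), 1)
  expect_equal(fisher_exact_two_sided(2, 0, 0, 2), 1 / 3)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "negative")
})

test_that("fisher enumeration equals the oracle on exhaustive small tables", {
  for (n in 2:16) {
    for (r in 1:(n - 1)) {
      for (k in 1:(n - 1)) {
        for (a in max(0, k - (n - r)):min(r, k)) {
          b <- r - a; c <- k - a; d <- n - r - c
          expect_equal(
            fisher_exact_two_sided(a, b, c, d),
            fisher_oracle(a, b, c, d),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("fisher agrees with stats::fisher.test on random tables", {
  withr::with_seed(22L, {
    for (i in 1:200) {
      tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(
        fisher_exact_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
        fisher.test(tab)$p.value,
        tolerance = 1e-9
      )
    }
  })
})

test_that("fisher p is invariant under joint row/column swap", {
  withr::with_seed(23L, {
    for (i in 1:50) {
      x <- rpois(4, 6) + 1
      expect_equal(
        fisher_exact_two_sided(x[1], x[2], x[3], x[4]),
        fisher_exact_two_sided(x[4], x[3], x[2], x[1]),
        tolerance = 1e-12
      )
    }
  })
})

test_that("odds ratio reproduces the published carrier table", {
  res <- odds_ratio_ci(13, 87, 1, 99)
  expect_equal(res$or, 1287 / 87, tolerance = 1e-12)
  # agrees with the printed value to two significant figures
  expect_equal(signif(res$or, 2), signif(14.7, 2))
  expect_equal(res$ci_method, "woolf")
  expect_true(res$ci_low < res$or && res$or < res$ci_high)
})

test_that("odds ratio CI matches the closed-form Woolf formula", {
  res <- odds_ratio_ci(1, 1, 1, 1)
  z <- qnorm(0.975)
  expect_equal(res$or, 1)
  expect_equal(res$ci_low, exp(-z * 2), tolerance = 1e-9)
  expect_equal(res$ci_high, exp(z * 2), tolerance = 1e-9)

  sym <- odds_ratio_ci(5, 5, 5, 5)
  expect_equal(sym$or, 1)
  expect_true(sym$ci_low < 1 && sym$ci_high > 1)
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  res <- odds_ratio_ci(5, 5, 0, 10)
  expect_equal(res$ci_method, "woolf+haldane")
  expect_equal(res$or, (5.5 * 10.5) / (5.5 * 0.5))
})

test_that("transposing case and control inverts the odds ratio exactly", {
  withr::with_seed(24L, {
    for (i in 1:20) {
      x <- rpois(4, 10) + 1
      expect_equal(
        odds_ratio_ci(x[1], x[2], x[3], x[4])$or,
        1 / odds_ratio_ci(x[3], x[4], x[1], x[2])$or,
        tolerance = 1e-12
      )
    }
  })
})

test_that("bonferroni multiplies, caps at one, and refuses under-correction", {
  expect_equal(bonferroni(0.01, m = 4), 0.04)
  expect_equal(bonferroni(0.5, m = 4), 1)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_true(all(bonferroni(runif(10), m = 10) >= 0))
  p <- withr::with_seed(25L, runif(5))
  expect_true(all(bonferroni(p, m = 5) >= p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "smaller")
  expect_error(bonferroni(1.5), "\\[0, 1\\]")
})

test_that("four sub-threshold screening p-values stay significant at m = 4", {
  p <- c(0.012, 0.0034, 0.0097, 0.0016)
  expect_true(all(bonferroni(p, m = 4) < 0.05))
})

test_that("associate_loci composes table, test, and odds ratio per locus", {
  sheet <- tibble::tibble(
    sample_id = c(sprintf("ca%03d", 1:100), sprintf("co%03d", 1:100)),
    status = rep(c("case", "control"), each = 100)
  )
  verdicts <- tibble::tibble(
    locus_id = "gap_locus",
    sample_id = sheet$sample_id,
    carrier = c(rep(TRUE, 13), rep(FALSE, 87), TRUE, rep(FALSE, 99))
  )
  res <- associate_loci(verdicts, sheet, m = 4)
  expect_s3_class(res, "cnv_assoc")
  expect_equal(unlist(res[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(13, 87, 1, 99))
  expect_equal(res$p, fisher_oracle(13, 87, 1, 99), tolerance = 1e-12)
  expect_equal(res$or, 1287 / 87, tolerance = 1e-12)
  expect_equal(res$p_bonferroni, pmin(1, 4 * res$p))

  # a locus with no carriers anywhere is null
  null_v <- dplyr::mutate(verdicts, carrier = FALSE)
  res0 <- associate_loci(null_v, sheet)
  expect_equal(res0$p, 1)
  expect_equal(res0$or, 1)

  gl <- glance(res)
  expect_equal(gl$n_loci, 1)
  expect_equal(gl$m, 4)
})
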