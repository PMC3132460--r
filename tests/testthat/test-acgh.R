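test_that("moving average matches direct arithmetic with truncated edges", {
  x <- c(0, 0, -1, -1, -1, 0, 0)
  sm <- moving_average(x, 3)
  expect_equal(sm[4], -1)
  expect_equal(sm[3], -2 / 3)
  expect_equal(sm[1], 0)
  expect_equal(moving_average(rep(2.5, 9), 5), rep(2.5, 9))
  expect_equal(moving_average(x, 1), x)
  expect_error(moving_average(x, 4), "odd")
  expect_error(moving_average(x, 9), "length")
})

test_that("moving average agrees with zoo::rollapply", {
  skip_if_not_installed("zoo")
  x <- withr::with_seed(14L, rnorm(200))
  for (w in c(3, 5, 11)) {
    expect_equal(
      moving_average(x, w),
      zoo::rollapply(x, w, mean, partial = TRUE, align = "center")
    )
  }
})

test_that("the envelope reports per-probe median, mean, and n-1 SD", {
  ids <- sprintf("p%02d", 1:3)
  panel <- dplyr::bind_cols(
    tibble::tibble(probe_id = ids),
    tibble::tibble(a = c(0.1, 0, 1), b = c(-0.1, 0, 1))
  )
  env <- build_envelope(panel)
  expect_equal(env$median, c(0, 0, 1))
  expect_equal(env$mean, c(0, 0, 1))
  expect_equal(env$sd, c(0.1 * sqrt(2), 0, 0))
  expect_error(build_envelope(panel[, 1:2]), ">= 2")

  ident <- dplyr::bind_cols(
    tibble::tibble(probe_id = ids),
    tibble::tibble(a = 1:3 / 10, b = 1:3 / 10, c = 1:3 / 10)
  )
  env2 <- build_envelope(ident)
  expect_equal(env2$sd, rep(0, 3))
  expect_equal(env2$median, 1:3 / 10)
})

test_that("panel SD estimates are nearly unbiased for the noise SD", {
  withr::with_seed(15L, {
    reps <- 1000
    sds <- vapply(seq_len(reps), function(i) sd(rnorm(15, 0, 0.25)),
                  numeric(1))
    expect_lt(abs(mean(sds) - 0.25) / 0.25, 0.05)
  })
})

test_that("loss requires strictly exceeding 1 SD below the median", {
  env <- tibble::tibble(probe_id = c("p1", "p2", "p3", "p4"),
                        median = 0, mean = 0, sd = c(0.1, 0.1, 0.1, 0))
  expect_equal(
    classify_probes(c(-0.25, -0.05, -0.1, 0), env),
    c("loss", "unchanged", "unchanged", "unchanged")
  )
  # SD = 0: threshold equals the median, strict inequality applies
  expect_equal(classify_probes(c(0, 0, 0, -0.001), env)[4], "loss")
})

test_that("segments partition the region with exact no-call territory", {
  reg <- fx_tiny_region()
  des <- fx_tiny_design()
  cls <- rep("unchanged", nrow(des))
  segs <- segment_calls(cls, des, reg, min_run = 2)
  expect_equal(sum(segs$end - segs$start),
               reg$region_end - reg$region_start)
  expect_true(all(segs$start[-1] >= segs$end[-nrow(segs)]))
  # no-call territory is exactly the gap plus the LCR mask (adjacent
  # intervals merge)
  nc <- segs[segs$class == "no_call", ]
  expect_equal(sum(nc$end - nc$start),
               (reg$gap_end - reg$gap_start) + 500)
  expect_true(all(nc$start >= 3500 & nc$end <= reg$gap_end))
  expect_false(any(segs$class == "loss"))
})

test_that("a loss run of exactly min_run probes becomes one segment", {
  reg <- fx_tiny_region()
  des <- fx_tiny_design()
  cls <- rep("unchanged", nrow(des))
  run <- 10:12                       # three consecutive unmasked probes
  cls[run] <- "loss"
  segs <- segment_calls(cls, des, reg, min_run = 3)
  loss <- segs[segs$class == "loss", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$n_probes, 3)
  # a shorter run is demoted
  segs2 <- segment_calls(cls, des, reg, min_run = 4)
  expect_equal(sum(segs2$class == "loss"), 0)
})

test_that("noise-free cohort emulation reproduces the carrier split exactly", {
  st <- fx_noisefree_study()
  val <- validate_samples(st$matrix, st$normal_matrix, st$design,
                          st$region, w = 5, min_run = 10)
  v <- dplyr::left_join(val$verdicts, st$truths, by = "sample_id")
  expect_equal(sum(v$carrier.x[v$status == "case"]), 13)
  expect_equal(sum(v$carrier.x[v$status == "control"]), 1)
  expect_equal(sum(val$normal_verdicts$carrier), 0)
  expect_equal(v$carrier.x, v$carrier.y)
})

test_that("carrier recovery under default noise is accurate", {
  st <- fx_noisy_study()
  val <- fx_noisy_validation()
  v <- dplyr::left_join(val$verdicts, st$truths, by = "sample_id")
  expect_gte(mean(v$carrier.x == v$carrier.y), 0.95)
  rj <- recovery_jaccard(val, st$truths)
  expect_gte(median(rj$jaccard), 0.8)
})

test_that("normal-panel members call almost no loss against their own envelope", {
  val <- fx_noisy_validation()
  segs <- val$segments[val$segments$group == "normal_panel", ]
  loss_frac <- segs |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(
      frac = sum(n_probes[class == "loss"]) / sum(n_probes),
      .groups = "drop"
    )
  expect_true(all(loss_frac$frac < 0.05))
})

test_that("deeper deletions never lose loss-classed probes", {
  withr::with_seed(16L, {
    reg <- fx_tiny_region()
    des <- fx_tiny_design()
    np <- nrow(des)
    noise <- rnorm(np, 0, 0.25)
    env <- tibble::tibble(probe_id = des$probe_id, median = 0, mean = 0,
                          sd = 0.11)
    inside <- des$start >= 6000 & des$end <= 8000
    prev <- -1
    for (depth in seq(0, 1, by = 0.1)) {
      x <- noise - depth * inside
      sm <- moving_average(x, 5)
      n_loss <- sum(classify_probes(sm, env)[inside] == "loss")
      expect_gte(n_loss, prev)
      prev <- n_loss
    }
  })
})

test_that("segmentation partitions the region for every noisy sample", {
  val <- fx_noisy_validation()
  reg <- region_model()
  tot <- val$segments |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(len = sum(end - start), .groups = "drop")
  expect_true(all(tot$len == reg$region_end - reg$region_start))
})

test_that("empty test set yields empty verdicts", {
  st <- fx_noisefree_study()
  empty <- st$matrix[, "probe_id", drop = FALSE]
  val <- validate_samples(empty, st$normal_matrix, st$design, st$region)
  expect_equal(nrow(val$verdicts), 0)
})
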