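mk_mat <- function(v, ids = sprintf("s%d", seq_len(ncol(v)))) {
  colnames(v) <- ids
  dplyr::bind_cols(
    tibble::tibble(probe_id = sprintf("p%04d", seq_len(nrow(v)))),
    tibble::as_tibble(as.data.frame(v, check.names = FALSE))
  )
}

test_that("median centering zeroes constant columns and is idempotent", {
  m <- mk_mat(cbind(rep(3.2, 5), c(-1, 0, 3, 0, 0), 1:5))
  out <- median_center(m)
  expect_equal(out$s1, rep(0, 5))
  expect_equal(out$s2, c(-1, 0, 3, 0, 0))     # already zero-median
  expect_equal(out$s3, (1:5) - 3)
  expect_equal(median_center(out)$s3, out$s3)  # idempotent
})

test_that("median centering can use reference probes only", {
  des <- tibble::tibble(
    probe_id = sprintf("p%04d", 1:6),
    start = seq(0, 500, by = 100), end = seq(50, 550, by = 100),
    gc = 0.5, chrom = "chr4", platform = "tiling"
  )
  v <- matrix(c(0, 0, 0, -1, -1, -1), ncol = 1)
  m <- mk_mat(v)
  # deletion covers half the probes; excluding it keeps the baseline at 0
  out <- median_center(m, des, tibble::tibble(start = 300, end = 600))
  expect_equal(out$s1, c(0, 0, 0, -1, -1, -1))
})

test_that("an exact linear GC signal is removed to numerical zero", {
  n <- 400
  gc <- runif(n, 0.3, 0.6)
  des <- tibble::tibble(
    probe_id = sprintf("p%04d", 1:n), chrom = "chr4",
    start = seq_len(n) * 100, end = seq_len(n) * 100 + 60,
    gc = gc, platform = "tiling"
  )
  v <- cbind(2 * (gc - mean(gc)), -0.7 * (gc - mean(gc)))
  out <- gc_correct(mk_mat(v), des, method = "linear")
  expect_lt(max(abs(ratio_matrix(out))), 1e-9)
  rep <- norm_report(out)$gc_fit
  expect_equal(rep$slope, c(2, -0.7), tolerance = 1e-9)
})

test_that("a GC-independent matrix passes through essentially unchanged", {
  withr::with_seed(4L, {
    n <- 2000
    gc <- runif(n, 0.3, 0.6)
    des <- tibble::tibble(
      probe_id = sprintf("p%04d", 1:n), chrom = "chr4",
      start = seq_len(n) * 100, end = seq_len(n) * 100 + 60,
      gc = gc, platform = "tiling"
    )
    v <- matrix(rnorm(2 * n, 0, 0.1), ncol = 2)
    out <- gc_correct(mk_mat(v), des, method = "linear")
    expect_lt(max(abs(ratio_matrix(out) - v)), 0.02)
    expect_lt(max(abs(norm_report(out)$gc_fit$slope)), 0.1)
  })
})

test_that("linear GC correction is idempotent to 1e-9", {
  st <- fx_noisy_study()   # already normalized once
  again <- gc_correct(st$matrix, st$design, method = "linear")
  expect_lt(max(abs(ratio_matrix(again) - ratio_matrix(st$matrix))), 1e-9)
})

test_that("GC correction decorrelates values from GC on the simulated cohort", {
  reg <- region_model()
  cfg <- sim_config(n_cases = 10, n_controls = 10, p_case = 0,
                    p_control = 0, n_batches = 1, batch_effect_sd = 0,
                    seed = 19L)
  des <- build_array_design(reg, "tiling")   # > 1000 probes
  mat <- simulate_log2_matrix(des, simulate_cohort(cfg, reg), cfg)
  out <- gc_correct(mat, des, method = "linear")
  cors <- apply(ratio_matrix(out), 2, function(x) cor(x, des$gc))
  expect_true(all(abs(cors) < 0.05))
})

test_that("constant GC skips correction with a warning", {
  des <- tibble::tibble(
    probe_id = sprintf("p%04d", 1:20), chrom = "chr4",
    start = 1:20 * 100, end = 1:20 * 100 + 60, gc = 0.5,
    platform = "tiling"
  )
  m <- mk_mat(matrix(rnorm(20), ncol = 1))
  expect_warning(out <- gc_correct(m, des), "skipped")
  expect_equal(ratio_matrix(out), ratio_matrix(m))
})

test_that("k = 0 batch removal is the identity with a warning", {
  m <- mk_mat(matrix(rnorm(40), ncol = 4))
  expect_warning(out <- remove_batch_pca(m, k = 0), "identity")
  expect_equal(ratio_matrix(out), ratio_matrix(m))
})

test_that("a rank-1 artifact is removed almost exactly with k = 1", {
  withr::with_seed(8L, {
    f <- rnorm(300)
    u <- rnorm(20)
    art <- outer(f, u)
    out <- remove_batch_pca(mk_mat(art), k = 1)
    expect_lt(
      norm(ratio_matrix(out), "F") / norm(art, "F"),
      1e-6
    )
    rep <- norm_report(out)$pca
    expect_equal(rep$var_explained[1], 1, tolerance = 1e-9)
  })
})

test_that("batch removal preserves dimensions, order, and declares variance", {
  withr::with_seed(12L, {
    m <- mk_mat(matrix(rnorm(600), ncol = 6))
    out <- remove_batch_pca(m, k = 2)
    expect_equal(dim(out), dim(m))
    expect_equal(out$probe_id, m$probe_id)
    vf <- norm_report(out)$pca$var_explained
    expect_true(all(vf >= 0 & vf <= 1))
    expect_true(all(diff(vf) <= 1e-12))   # non-increasing
    expect_error(remove_batch_pca(m, k = 6), "smaller")
  })
})

test_that("batch structure shrinks while a locus signal is preserved", {
  withr::with_seed(27L, {
    np <- 500; ns <- 150
    start <- seq_len(np) * 100
    des <- tibble::tibble(
      probe_id = sprintf("p%04d", seq_len(np)), chrom = "chr4",
      start = start, end = start + 60, gc = 0.5, platform = "tiling"
    )
    locus <- c(30000, 40000)              # probes 300..399
    in_locus <- start >= locus[1] & start < locus[2]
    batch <- rep(1:2, each = ns / 2)
    f <- rnorm(np)
    load <- c(0.25, -0.25)
    carriers <- c(1:5, 76:80)             # carriers balanced across batches
    v <- matrix(rnorm(np * ns, 0, 0.25), np, ns) +
      outer(f, load[batch])
    v[in_locus, carriers] <- v[in_locus, carriers] - 0.75
    m <- mk_mat(v)

    out <- remove_batch_pca(m, k = 2, design = des,
                            exclude = tibble::tibble(start = locus[1],
                                                     end = locus[2]))
    w <- ratio_matrix(out)

    batch_diff <- function(x) {
      rowMeans(x[, batch == 1]) - rowMeans(x[, batch == 2])
    }
    # compare against the known batch axis, net of sampling noise
    proj <- function(x) sum(batch_diff(x) * f) / sqrt(sum(f^2))
    expect_lt(abs(proj(w)), 0.1 * abs(proj(v)))

    shift <- function(x) {
      mean(x[in_locus, carriers]) - mean(x[in_locus, -carriers])
    }
    expect_lt(abs(shift(w) - shift(v)) / abs(shift(v)), 0.1)
  })
})

test_that("joint study normalization attenuates the deletion signal only mildly", {
  st_raw <- fx_cached("noisy_raw", {
    simulate_study(sim_config(seed = 1L), region_model())
  })
  st <- fx_noisy_study()
  tr <- st$truths
  carriers <- tr$sample_id[tr$carrier]
  des <- st$design
  shift_at_locus <- function(mat) {
    v <- ratio_matrix(mat)
    reg <- st$region
    sel <- des$start >= reg$gap_end & des$end <= reg$gap_end + 50000
    mean(v[sel, carriers]) - mean(v[sel, setdiff(tr$sample_id, carriers)])
  }
  s_raw <- shift_at_locus(st_raw$matrix)
  s_norm <- shift_at_locus(st$matrix)
  expect_lt(abs(s_norm - s_raw) / abs(s_raw), 0.1)
})
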