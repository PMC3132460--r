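# Shared fixtures, built once per test run and cached in the session.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, expr) {
  if (!exists(key, envir = .fx)) {
    assign(key, force(expr), envir = .fx)
  }
  get(key, envir = .fx)
}

# noise-free emulation cohort: 13 carrier cases / 87 / 1 carrier control / 99,
# plus a 15-sample diploid normal panel
fx_noisefree_study <- function() {
  fx_cached("noisefree", {
    cfg <- sim_config(
      sigma_probe = 0, gc_slope = 0, n_batches = 1, batch_effect_sd = 0,
      seed = 7L
    )
    simulate_study(cfg, region_model(),
                   exact_carriers = c(case = 13, control = 1))
  })
}

# default-noise study, normalized, on the dense tiling design
fx_noisy_study <- function() {
  fx_cached("noisy", {
    normalize_study(simulate_study(sim_config(seed = 1L), region_model()))
  })
}

fx_noisy_validation <- function() {
  fx_cached("noisy_val", {
    st <- fx_noisy_study()
    validate_samples(st$matrix, st$normal_matrix, st$design, st$region)
  })
}

# tiny design over a miniature region for fast unit tests
fx_tiny_region <- function() {
  region_model(
    region_start = 0, region_end = 10000,
    gap_start = 4000, gap_end = 5000,
    lcr_masks = tibble::tibble(start = 3500, end = 4000)
  )
}

fx_tiny_design <- function(spacing = 100) {
  build_array_design(fx_tiny_region(), "tiling", spacing_bp = spacing,
                     probe_length = 50, seed = 9L)
}
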