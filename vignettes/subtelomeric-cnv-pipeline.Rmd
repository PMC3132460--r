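---
title: "Calling subtelomeric copy-number losses around an assembly gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling subtelomeric copy-number losses around an assembly gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtelcnv)
library(dplyr)
```

## The analysis in one paragraph

`subtelcnv` analyses copy-number losses in a repeat-rich subtelomeric
interval — modelled on the 1.3-Mb region at 4p16.3 (550,000–1,850,000)
around the 55.5-kb assembly gap "gap-177" — in a case-control cohort
typed on two array platforms. A sparse *screening* design is analysed by
Gaussian-mixture clustering of per-locus summaries with a
consecutive-marker evidence rule and a reliability screen; a dense
*tiling* design validates candidates by comparing each sample's
moving-average log₂-ratio track with a reference envelope built from a
panel of normal individuals, calling **loss** where the smoothed ratio
drops strictly below `median − 1·SD` for a sufficient run of probes.
Carrier status is tested for association by exact two-sided Fisher
enumeration with Bonferroni correction, and effect size is reported as
the cross-product odds ratio with a Woolf logit confidence interval.
Because no raw data are deposited for the motivating study, a fully
specified simulator generates cohorts with the statistical structure the
analysis assumes, and every stage is tested against it.

## Coordinates

All internal coordinates are 0-based half-open (the BED convention), so
interval lengths are `end − start` and adjacency is unambiguous. Printed
1-based inclusive coordinates — the gap `1,423,147–1,478,646`, the gene
table — are converted on load by `printed_to_halfopen()`; the gap
becomes `[1423146, 1478646)`, 55,500 bp. The coordinate system is a
single synthetic frame labelled by `build_label`; no liftover is
performed because no reference genome is consumed.

## What the simulator emulates

`sim_config()` fixes the study conditions; `simulate_cohort()` and
`simulate_log2_matrix()` are deterministic functions of `(config, seed)`.

| parameter | default | meaning and rationale |
|---|---|---|
| `n_cases`, `n_controls` | 100, 100 | cohort sizes of the motivating study |
| `p_case`, `p_control` | 0.13, 0.01 | carrier prevalence by status (13/100 vs 1/100) |
| `del_min_bp`, `del_max_bp` | 200,000–800,000 | deletion span, uniform; spans must contain the gap (deletions in this region cluster around it), matching the wide range of published per-patient extents |
| `mu_per_cn["1"]` | −1 | log₂(1/2): one copy lost of two |
| `response_factor` | 0.75 | multiplicative ratio compression; arrays rarely achieve the theoretical −1 |
| `sigma_probe` | 0.25 | per-probe Gaussian noise SD, a realistic tiling-aCGH magnitude that makes calling non-trivial but recoverable |
| `gc_slope` | 0.5 | log₂-ratio change per unit GC deviation; GC varies along the region as a smooth wave plus jitter so the correction has structure to learn |
| `n_batches`, `batch_effect_sd` | 2, 0.1 | rank-one batch term: per-batch loading × per-probe factor. Both are drawn from the config seed, not the noise seed, because batch structure is a property of the protocol — every matrix simulated under one config (cohort and reference panel) shares the same batch axes |

The probe designs tile the region at 5,000 bp (screening) or 500 bp
(tiling, 60-mer probes), skipping any probe that would overlap the gap;
probes inside the two default LCR masks flanking the gap are retained
but downstream calling forces them to `no_call`. Heterozygous deletions
only are simulated (CN = 1); the analysis defines exactly two called
classes, unchanged and loss, plus no-call.

What the simulator does **not** emulate: raw two-channel (Cy5/Cy3)
intensities and dye effects, B-allele frequencies, cross-hybridisation
inside LCRs, genomic waves against a real reference, or population
structure. Passing tests therefore demonstrate the pipeline's behaviour
under its stated noise model, not performance on any real cohort.

## Normalization

Three documented standard steps stand in for the screening platform's
undisclosed vendor normalization:

1. **Median centering.** Each sample column is shifted to median 0. On a
   region-targeted array a deletion can cover more than half of all
   probes, contaminating the sample's own median; `median_center()`
   therefore accepts an `exclude` interval set and estimates the median
   on reference probes outside it (the *deletion territory*,
   `deletion_territory()`: the gap ± (`del_max_bp` − gap length),
   i.e. everywhere a gap-anchored deletion can reach).
2. **GC correction.** Per sample, a least-squares line (or loess,
   span 0.3) of log₂ ratio on GC fraction; only the GC-dependent,
   centered part of the fit is subtracted so a GC-independent matrix
   passes through unchanged and the baseline remains the median's job.
   The fit uses *all* probes by default: a deletion spanning several GC
   wave periods is nearly uncorrelated with GC, whereas restricting the
   fit to the narrow non-candidate flank under-samples the GC range and
   extrapolates sample-specific artefacts. The linear method is exactly
   idempotent.
3. **PCA batch removal.** The top *k* (default 2) sample-space singular
   vectors are estimated from probes outside the deletion territory and
   projected out of every probe row. Excluding the territory matters:
   carriers share the deletion direction, and PCs estimated on
   contaminated probes would regress the true signal out. The input is
   expected column-centered; no further centering is applied, so a pure
   low-rank artifact is removed exactly. Variance-explained fractions
   are recorded in the normalization report.

`normalize_study()` normalizes the cohort and the normal reference panel
jointly (one matrix), so both are corrected on the same GC curve and
batch axes, then splits them back.

## The tiling-aCGH caller

*Smoothing.* A centered moving average of `w = 5` probes (2.5 kb at the
default spacing), truncated at track ends. `w` trades breakpoint
resolution against noise (smoothed SD ≈ `sigma_probe/√w`); 5 keeps
sub-10-kb resolution while making the heterozygous shift (−0.75 after
attenuation) ≈ 6 smoothed-noise SDs deep. The 1-SD rule is applied to
smoothed values (the track view displays smoothed data); `smooth =
FALSE` applies it to raw ratios instead.

*Envelope.* Per-probe median, mean and sample SD (n − 1) of the smoothed
ratios across the normal panel (≥ 2, default study size 15). The loss
threshold is `median − 1·SD` (median is robust to a stray carrier in
the panel); the `mean ± 1·SD` band is reported as the "unchanged" range
in track plots.

*Classification and tie-break.* A probe is loss **iff** strictly below
the threshold; boundary values — including everything at probes with
SD = 0, where the threshold equals the median — are unchanged
("exceeds" is read strictly).

*Segmentation.* Probes overlapping LCR masks are excluded as evidence;
maximal loss runs of ≥ `min_run` probes become loss segments; probe
classes are extended to inter-probe midpoints so the segments partition
the region exactly, with the gap and the masks emitted as `no_call` at
their exact coordinates.

*Run-length threshold.* `min_run` defaults to **25 probes** (12.5 kb).
The moving average autocorrelates adjacent probes across the window, so
short runs below a 1-SD threshold (per-probe exceedance ≈ 16% under
Gaussian noise) are cheap: a run-length calculation at the default noise
level shows that ≥10-probe false runs appear in a large fraction of
normal samples within a few-hundred-probe locus, while ≥25-probe false
runs are vanishingly rare. Every gap-anchored deletion the simulator can
produce retains at least ≈100 consecutive unmasked probes on one side of
the gap, so 25 costs no sensitivity. The following snippet reproduces
the calculation:

```{r run-length, eval = FALSE}
set.seed(1)
w <- 5; sigma <- 0.25; npanel <- 15; nprobe <- 640
worst_run <- replicate(400, {
  panel <- sapply(seq_len(npanel), function(i)
    moving_average(rnorm(nprobe, 0, sigma), w))
  thr <- apply(panel, 1, median) - apply(panel, 1, sd)
  r <- rle(moving_average(rnorm(nprobe, 0, sigma), w) < thr)
  max(c(0, r$lengths[r$values]))
})
mean(worst_run >= 10); mean(worst_run >= 25)
```

*Re-baselining.* After a first classification pass, each sample's
baseline is re-estimated as the median of its own unchanged-classified
probes and the sample re-called (`recenter = TRUE`). The initial
centering uses only the few hundred guaranteed-diploid flank probes and
so carries per-sample offset noise; one iteration of this classic
normalize–call loop removes it using the ~2,000 unchanged probes each
sample actually has.

*Verdict.* A sample is a carrier when any loss segment overlaps the
queried locus (default: gap ± 150 kb) by ≥ 1 bp. For recovery
diagnostics, `recovery_jaccard()` compares the *bridged* loss span
(minimum start to maximum end of the loss segments at the locus) with
the simulated truth interval: the gap and masks are `no_call` by
construction and sit inside every true deletion, so a segment-union
Jaccard could never approach 1 even for a perfect caller.

## The screening caller

Per-locus summaries (mean log₂ ratio over probes with midpoint in the
locus) are clustered by a 1-D Gaussian-mixture EM, k ∈ {1, 2, 3}, chosen
by minimum BIC (−2ℓ + (3k−1)·log n). EM is deterministic: components
start at fixed data quantiles (median for k = 1; 10/90 percentiles for
k = 2; 10/50/90 for k = 3) with equal weights and pooled variance;
convergence at |Δℓ| < 10⁻⁶·(1+|ℓ|), at most 500 iterations; variances
floored at 10⁻⁶ against collapse. Non-convergence flags the model and
classes every sample unchanged. A component maps to *loss* (or *gain*)
only if its mean is more than `min_separation = 0.3` log₂ units below
(above) zero — half the attenuated heterozygous shift — otherwise
*unchanged*; gains are mapped but the validation stage deliberately
calls only unchanged/loss. The consecutive-marker rule (`min_run = 2`
at the screening stage: more than one abnormal marker in a row) converts
per-probe classes to candidate intervals, and the reliability screen
retains candidates with ≥ 50 probes *and* ≥ 50 kb — both thresholds read
inclusively, since "over 50" is ambiguous in the source description;
both are configurable.

## Association

The 2×2 carrier table (a = case carriers, b = case non-carriers, c, d
likewise for controls) is tested by exact enumeration of all tables with
the observed margins using log-factorial arithmetic; the two-sided p is
the sum of point probabilities ≤ the observed one (relative tolerance
10⁻⁷ for ties) — the common convention, chosen over doubling the
one-sided p. Bonferroni is `min(1, m·p)` with `m` = number of loci
tested by default (four candidates in the motivating study's screen);
under-correction (`m` smaller than the number of p-values) is refused.
The odds ratio is the cross product with the Woolf logit interval;
zero cells invoke Haldane–Anscombe (+0.5 everywhere), and every result
records its `ci_method` string, since differently-constructed intervals
are not comparable. The motivating study's printed interval is not
reproducible by this (or any standard closed-form) method, and its
printed point p differs from exact enumeration of its own printed
counts; both are therefore reported by this package as computed, with
the method stated, rather than targeted.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use the study-scale
conditions throughout: 2,489 tiling probes (500 bp spacing), 260
screening probes, 100 + 100 cohorts with a 15-sample normal panel,
exhaustive Fisher verification over every table with n ≤ 40, and 500
replicate null cohorts for the empirical size of the exact test. These
sizes keep a full run in the low minutes on one core while leaving the
statistical checks (binomial prevalence recovery, CLT bounds,
Monte-Carlo SD bias) adequately powered.

## Known limitations

* Breakpoints are resolved only to probe spacing ± half the smoothing
  window; no base-pair refinement is attempted.
* No gain calling in the validation stage, and no homozygous-deletion
  model (CN = 0) by default.
* The envelope is built including the panel member being evaluated when
  panel self-consistency is examined; with 15 samples the resulting
  shrinkage is small but real.
* Association is per-locus carrier-based; covariate adjustment
  (logistic regression) and genome-wide permutation significance are out
  of scope.
* The simulator's Gaussian, spatially independent noise is favourable
  to a 1-SD envelope rule; real tiling arrays show heavier tails and
  wave artefacts, so thresholds validated here should be re-examined on
  real data.
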