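# subtelcnv

Copy-number-loss calling and case-control association for a repeat-rich
subtelomeric region around a reference-assembly gap.

## The problem

Subtelomeres are rich in low-copy repeats (LCRs) and often border assembly
gaps where no array probe can be designed. Deletions there are invisible to
standard SNP panels and awkward for generic CNV callers: the gap splits
every event, the LCRs give ambiguous signal, and a deletion can span most
of a region-targeted array, which breaks the usual per-sample
normalization assumptions. `subtelcnv` implements a complete two-stage
analysis of such a region — modelled on the 1.3-Mb interval at 4p16.3
(positions 550,000–1,850,000) containing the 55.5-kb "gap-177" — for
case-control cohorts typed on two array platforms:

1. **Screening stage** (sparse genome-screen design): per-locus mean log₂
   ratios are clustered with a 1-D Gaussian mixture fitted by EM
   (k ∈ {1,2,3}, BIC selection); the lowest-mean component is the
   copy-number-loss class. Candidate CNVs must satisfy a reliability
   screen (≥ 50 consecutive probes, ≥ 50 kb) and a consecutive-marker
   evidence rule.
2. **Validation stage** (dense tiling design): each sample's track is
   smoothed by a centered moving average (window *w* = 5 probes) and
   compared with a reference envelope built from a panel of normal
   individuals — per-probe median, mean and SD of the smoothed ratios.
   A probe is called **loss** iff its smoothed ratio falls strictly below
   `median − 1·SD`; maximal loss runs of ≥ `min_run` probes become loss
   segments; the gap and LCR masks are emitted as `no_call`.

Carrier status (any loss segment overlapping the queried locus) is then
tested for case-control association with an exact two-sided Fisher test
(full hypergeometric enumeration; two-sided p = sum of point
probabilities ≤ the observed one), Bonferroni correction
`min(1, m·p)`, and the odds ratio

```
OR = (a·d)/(b·c),   95% CI = exp( ln OR ± z₀.₉₇₅ · √(1/a + 1/b + 1/c + 1/d) )
```

(Woolf logit interval; Haldane–Anscombe +0.5 on zero cells). For the
published carrier table (a, b, c, d) = (13, 87, 1, 99) this gives
OR = 1287/87 ≈ 14.79 with two-sided Fisher p ≈ 1.28 × 10⁻³, i.e.
p ≈ 5.1 × 10⁻³ after Bonferroni correction over four candidate loci.

Because no raw data are deposited for this study, the package ships a
fully specified cohort simulator (probe designs with GC structure,
heterozygous-deletion carriers at configurable prevalence, GC bias,
rank-one batch effects, per-probe Gaussian noise) so every stage is
testable end to end, plus the 34-gene annotation table of the region
(PDE6B … LETM1).

## Worked example

```r
library(subtelcnv)
library(dplyr)

reg <- region_model()
reg
#> <region_model> chr4:550000-1850000 (synthetic-4p16.3, 1.30 Mb)
#>   gap: [1423146, 1478646) 55500 bp; lcr masks: 2 (44500 bp)

cfg   <- sim_config(seed = 7)                      # 100 cases, 100 controls
study <- simulate_study(cfg, reg) |> normalize_study()
study
#> <cnv_study> 2489 probes (tiling), 100 cases + 100 controls (+15 normal panel), 11 carriers

val <- validate_samples(study$matrix, study$normal_matrix, study$design, reg)
glance(val)
#> # A tibble: 1 × 6
#>   n_test n_carrier n_normal_panel n_normal_carrier window min_run
#>    <int>     <int>          <int>            <int>  <dbl>   <dbl>
#> 1    200        11             15                0      5      25

res <- associate_loci(
  tibble(locus_id = "4p16.3_gap",
         sample_id = val$verdicts$sample_id,
         carrier   = val$verdicts$carrier),
  study$truths, m = 4)
tidy(res) |> select(locus_id, a, b, c, d, p, p_bonferroni, or, ci_low, ci_high)
#> # A tibble: 1 × 10
#>   locus_id       a     b     c     d        p p_bonferroni    or ci_low ci_high
#>   <chr>      <int> <int> <int> <int>    <dbl>        <dbl> <dbl>  <dbl>   <dbl>
#> 1 4p16.3_gap    11    89     0   100 0.000730      0.00292  25.8   1.50    445.
```

All 11 simulated carriers (and no non-carriers) are recovered; the
association at the gap locus is significant after Bonferroni correction
over four loci. `render_cohort_report()` adds gene and gap-overlap
annotation per segment:

```r
render_cohort_report(val, study$truths)$summary
#> # A tibble: 2 × 3
#>   status      n carriers
#>   <chr>   <int>    <int>
#> 1 case      100       11
#> 2 control   100        0
```

`plot_track()` draws one sample against the envelope (the classic
tiling-aCGH view) and `autoplot(val)` the per-sample segment bars across
the cohort.

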