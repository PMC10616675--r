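# decaychase

Tools for transcriptome-wide mRNA decay analysis of actinomycin-D (ActD)
chase RNA-seq experiments, built for the question: *which transcripts are
stabilized when the TTP family of AU-rich-element RNA-binding proteins
(ZFP36/ZFP36L1/ZFP36L2) is knocked out in macrophages?*

In an ActD chase, transcription is blocked at t = 0 (here, 1 h after LPS
stimulation) and RNA is sequenced along a timepoint grid. Remaining abundance
follows first-order decay, a(t) = a(0)·exp(−kt) with half-life t½ = ln2/k, so
each gene's per-mouse *percent remaining* P(t) = 100·x(t)/x(0) traces its
decay curve. The package implements:

- **Normalization and curves** — median-of-ratios size factors, per-kilobase
  normalized expression, FPKM, and per-subject percent-remaining curves
  anchored at each mouse's own t = 0 library.
- **Filter cascade** — non-mRNAs, knocked-out genes (and the artefactually
  elevated *Plekhg2*), genes below 0.1 FPKM in controls at t = 0, and genes
  whose control curve never falls below 85% remaining by 120 min are dropped
  with machine-readable reasons.
- **Two-stage stabilization screen** — stage 1: unpaired two-tailed t tests
  per post-anchor timepoint, requiring p < 0.008 at 3 consecutive timepoints
  with knockout above control; stage 2: mixed-design repeated-measures
  two-way ANOVA (genotype × time, subjects nested in genotype) with
  Greenhouse–Geisser-corrected degrees of freedom and Šídák-adjusted
  per-timepoint comparisons, gated at p < 0.05 on the interaction. Calls are
  ranked by the mean knockout-minus-control difference in percent remaining
  at 60 and 120 min; half-lives are interpolated at the 50% crossing and
  right-censored (">120") when never reached.
- **Binding-site scanner** — all overlapping occurrences of the AU-rich
  site classes UAUUUAU, UAUUUUAU, UUAUUUAUU, UUAUUUUAUU in 3′-UTR FASTA,
  1-based coordinates, U/T- and case-insensitive, with per-gene summaries and
  set-level site fractions.
- **DEG thresholds and cross-tabs** — |log2 FC| ≥ 0.3785 (1.3-fold),
  adjusted p ≤ 0.05, expression floor, exclusions; set overlaps and
  known-target flags for externally produced differential-expression tables.
- **Induction AUC** — trapezoid area under LPS-induction curves, AUC ratios,
  peak time and fold change.
- **Simulators with known truth** — negative-binomial chase counts
  (including the fixed-depth renormalization that makes slow transcripts
  *appear* to rise), planted-motif UTRs, and rise-and-fall induction curves,
  so the whole pipeline is testable without external data.

## Worked example

```r
library(decaychase)

cfg <- decay_sim_config(n_genes = 500, stabilized_fraction = 0.02,
                        stabilized_control_halflife = 20, seed = 42)
sim <- simulate_chase(cfg)            # 2 genotypes x 4 mice x 7 timepoints
res <- run_screen(sim$experiment, pair = c("control", "ko"))
print(res)
#> screen_result: 500 genes, 166 retained, 10 stage-1 passers, 10 stabilized

ranked <- rank_stabilized(res$table)
ranked[, c("gene_id", "rank_metric", "p_interaction_gg",
           "half_life_control", "half_life_ko")]
#>      gene_id rank_metric p_interaction_gg half_life_control half_life_ko
#> 1  gene00284        72.5         1.38e-04             24.15         >120
#> 2  gene00237        71.2         8.55e-07             15.83         >120
#> 3  gene00385        70.7         1.85e-05             24.57         >120
#> ...
```

Of 500 simulated genes, 166 survive the filter cascade (the rest are
long-lived, low-expressed, or non-mRNA); all 10 transcripts planted with a
20-min control half-life and a 6-fold stabilized knockout half-life are
recovered, each with a censored knockout half-life (">120" min) — the same
reporting convention as the published screen — and no false positives.
`rank_metric` is the mean percent-remaining difference (knockout − control)
at 60 and 120 min; `p_interaction_gg` is the Greenhouse–Geisser-corrected
genotype × time p-value that gates stage 2. `write_screen_tables()` writes
the full per-gene table (per-timepoint means, SDs and t-test p-values for
both genotypes, ANOVA terms, ε, ranking, half-lives, stabilized flag), the
filter report, and the long-format curves.

The numbered scripts under `analysis/` run the full workflow end to end —
simulate a 2,000-gene chase with planted truth and UTRs (`01`), screen and
score recovery (`02`), scan binding sites (`03`), apply DEG thresholds and
cross-tabs (`04`), and compute induction AUC statistics (`05`) — writing
their tables under `results/`.

## Vignette

`vignettes/decay-screen-methods.Rmd` documents the model, the two-stage
screen and its corrections, all tunable parameters with defaults and
rationale, what the simulators do and do not emulate, and numerical edge
cases.
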