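# mirsecretome

Analysis pipeline for the **sEV miRNA secretome**: which microRNAs a
tumour cell exports into small extracellular vesicles (sEVs), which
sequence motifs and RNA-binding proteins (RBPs) mark them for export,
which cell types the exported miRNAs plausibly target, and whether the
secretory signature tracks nodal stage, occult metastasis and survival
in a clinical cohort.

It is written for computational biologists working with paired
cell/sEV small-RNA-seq count matrices (plus mature-sequence FASTA,
interaction edge lists, marker tables and a clinical TSV). Every stage
is also runnable end-to-end on synthetic data with planted ground
truth, so the statistical behaviour of the whole chain is testable
offline.

## What it computes

1. **Differential abundance** (sEV vs cell): median-of-ratios
   normalization, per-miRNA method-of-moments NB dispersion, Wald-type
   statistic log2FC/se referred to *t*(n−2), BH adjustment, and a
   two-pass composition refinement that re-anchors size factors on the
   non-differential bulk. Classification: *secretory* (p_adj < 0.05,
   log2FC > 0), *retained* (log2FC < 0), with a `strict` profile
   requiring |log2FC| > 1.
2. **Sorting/retention motifs**: all 4^k motifs for k = 4..7 (21,760),
   membership by substring over mature sequences (sets < 6 members
   dropped), pre-ranked enrichment on the log2FC ranking — running-sum
   ES, size-matched gene-permutation null, NES = ES / mean same-sign
   |null ES|, permutation p with BH FDR per k and jointly. Positive NES
   = sEV-sorting motif, negative = cell-retention.
3. **RBP screen**: per-RBP 2×2 tables (enriched vs background miRNAs ×
   bound/unbound), Pearson chi-squared (exact-test fallback for small
   expected counts), ranking by observed/expected ratio, top-10 report.
4. **Target cell types**: pooled target mRNAs of secretory miRNAs
   tested against marker sets by the exact hypergeometric upper tail
   P[X ≥ k] over the interaction-reachable gene universe; per-type
   bipartite subnetwork export. The same operation accepts any GMT, so
   pathway annotation is the identical computation.
5. **Clinical signature**: per-patient score = mean of per-miRNA
   z-scores of log2(x+1); Welch t / ANOVA+Tukey stage contrasts; the
   occult-metastasis contrast (pN+ within cN0); Kaplan–Meier with the
   lowest-p cutpoint (arm floor max(10, 10 % n)), always reporting the
   full cutpoint scan and an optional permutation-adjusted p as a
   selection-bias guardrail.

The methods, parameter meanings and design decisions are documented in
`vignettes/secretome-methods.Rmd`.

## Worked example

One call runs the whole chain on a generated study (2 cell lines ×
{cell, sEV} × 3 replicates, 500 miRNAs with a planted GCGC sorting
motif in 20 % of them, biased RBPs, a true target cell type, and a
300-patient cohort whose hazard follows the signature):

```r
library(mirsecretome)
man <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
vapply(man$stages, `[[`, "", "status")
#> simulate     diff   motifs      rbp celltypes clinical
#>     "ok"     "ok"     "ok"     "ok"      "ok"     "ok"
man$stages$diff[c("n_detected", "n_secretory", "n_retained")]
#> $n_detected  [1] 500
#> $n_secretory [1] 102
#> $n_retained  [1] 21
```

Top 4-mers of the motif screen (`run1/motif_results.tsv`) — the
planted GCGC motif is rank 1 with ES = 1 (every carrier precedes every
non-carrier in the ranking) and its overlapping variants follow:

```
 motif size        es      nes      p_perm  fdr_per_k   direction
  GCGC  100 1.0000000 2.473440 0.001000000 0.02920374 sev_sorting
  CGCG   66 0.8411022 2.061647 0.001003009 0.02920374 sev_sorting
  AGCG   49 0.7999297 1.923963 0.001005025 0.02920374 sev_sorting
```

All five planted RBPs head the secretory top-10
(`run1/rbp_secretory_top.tsv`), the planted cell type wins the
hypergeometric screen (30/50 markers in the 759-gene target pool,
p_adj = 9.5e-06, decoys at p = 1), and the clinical stage reports the
occult-metastasis contrast (p = 1.1e-07) and the lowest-p survival
cutpoint (log-rank p = 6.9e-23, high-score arm worse):

```
          comparison status      p_value
      cN0_vs_cNpos       ok 6.643090e-09
 occult_within_cN0       ok 1.149954e-07
      pN0_vs_pNpos       ok 5.389236e-15
```

A `manifest.json` in the run directory records stage statuses,
parameters and output checksums; the run is byte-reproducible given
the seed. To analyse your own data instead, disable the `simulate`
stage and point `inputs` at your files (`?pipeline_config`,
`?run_pipeline`).

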