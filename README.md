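# ricproteo

Downstream analysis of UV-crosslink RNA-capture proteomics in animal organs.

RNA interactome capture isolates proteins covalently crosslinked to RNA by
UV light and quantifies them by isobaric-label (TMT) mass spectrometry.
Applied to organs, each comparison is small — two +UV capture samples
against one pooled −UV control per organ, for both a poly(A) capture (eRIC)
and a non-poly(A) capture of the poly(A)-depleted supernatant — and the
question is which proteins are *active* RNA binders in each organ, whether
they bind poly(A) RNA, non-poly(A) RNA or both, and how binding activity
differs between organs independently of protein abundance.

`ricproteo` implements the complete path from a protein-level
quantification table to an organ RBP atlas, for analysts working with
capture-proteomics data (or evaluating the statistics of such pipelines):

* **Normalization** — per-protein batch-effect removal and an affine-arsinh
  (glog2) variance-stabilizing transform, `h_s(x) = arsinh(a_s + b_s x)/ln 2`,
  calibrated per sample stratum by alternating trimmed least squares, with
  the stratification strategies the organ analyses require (per
  tissue × condition; one stratum for all +UV samples; +UV-only fitting
  that preserves the abundance difference from the −UV control).
* **Moderated enrichment testing** — per-protein least squares of the
  +UV − −UV contrast (condition + replicate design), empirical-Bayes
  variance moderation `s̃²_g = (d0 s0² + d_g s²_g)/(d0 + d_g)` with the
  prior `(d0, s0²)` estimated by a closed-form moment method on log
  variances, two-sided moderated t-tests, Benjamini–Hochberg correction,
  and hit/candidate calling (hit: FDR < 0.05 and fold-change > 2;
  candidate: FDR < 0.2 and fold-change > 1.5; ≥ 2 unique peptides).
* **Integration** — dual / exclusive / unresolved binder classes from the
  poly(A) and non-poly(A) class pairs, cross-organ Venn counts, novel-RBP
  calls against a published-atlas flag, and the staged cascade of cell-line
  RBPs missing from the organ atlases.
* **Organ activity** — RNA-content-adjusted signal, per-organ mean
  signal-sum ratios, relative-abundance heatmap matrices with
  average-linkage clustering on 1 − Pearson, replicate correlation, and
  binding-vs-abundance decoupling under equal-mean renormalization.
* **Crosslink QC** — gel-fraction iBAQ proportion profiles, weighted
  molecular-weight densities, and migration calls (monomeric /
  boundary-proximal / bimodal / shifted) that flag potential
  protein–protein crosslink "piggy-back" artifacts via the 10 kDa boundary
  rule.
* **Annotation enrichment** — exact Fisher tests (one-tailed hypergeometric
  or two-sided point-probability) for domains, cofactors, catalytic classes
  and pathway RBP fractions.
* **Synthetic data** — a generator that emulates the study design with
  known ground truth (planted enrichment, batch effects, sample scaling,
  abundance-dependent missingness, planted migration classes and annotation
  structure), so every stage is testable without instrument data.

The methods vignette (`vignettes/organ-rbp-workflow.Rmd`) documents the
models, parameter defaults and design choices.

## Worked example

```r
library(ricproteo)

cfg <- sim_config(seed = 7)                    # the simulated study design
sim <- simulate_eric_experiment(cfg)
sim$quant
#> quant_matrix: 2000 proteins x 24 samples
#>   tissues: brain, kidney, liver
#>   assays:  eric, nonpolya_ric, input
#>   missing cells: 4.1%

tab <- differential_enrichment(sim$quant, rp_thresholds(),
                               tissue = "kidney", assay = "eric")
table(tab$enrich_class)
#>    candidate          hit       no_hit not_detected
#>           69          273         1654            4
attr(tab, "moderation")[c("d0", "s0_sq")]
#> $d0
#> [1] 1.61776
#> $s0_sq
#> [1] 0.009368363
```

273 kidney proteins are called active poly(A) binders (enriched in +UV over
−UV at FDR < 0.05 and fold-change > 2 on the glog2 scale); the
empirical-Bayes prior adds ~1.6 degrees of freedom to each protein's single
residual degree of freedom, which is what makes the 2-vs-1 design testable.
Against the generator's ground truth, these 273 hits are 68% of the planted
kidney-active poly(A)/dual binders with zero false positives in this run
(the union over all three organs recovers ~75%).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow — `01_simulate.R` through `06_enrichment.R` — writing their tables
under `results/`; each script prints what it found (hit counts per organ
and assay, biotype class counts, cascade stage sizes, migration-call
accuracy, enriched cofactor categories).

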