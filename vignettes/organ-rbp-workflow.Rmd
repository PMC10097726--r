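---
title: "From capture proteomics to organ RBP atlases: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From capture proteomics to organ RBP atlases: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricproteo)
```

# The problem

RNA interactome capture experiments isolate proteins covalently crosslinked
to RNA by UV irradiation and quantify them by isobaric-label (TMT) mass
spectrometry. In the organ setting each (organ, assay) comparison is tiny:
two +UV capture samples against a single pooled -UV control, for both a
poly(A) capture (eRIC) and a non-poly(A) capture of the poly(A)-depleted
supernatant, plus total-proteome inputs. `ricproteo` implements the full
downstream path from a protein-level quantification table to an organ RBP
atlas: normalization, moderated enrichment testing, hit calling, poly(A) /
non-poly(A) integration, cross-organ activity comparison, gel-fraction
crosslink QC, and annotation enrichment. A synthetic-data generator with
known ground truth stands in for deposited instrument data, so every stage
is testable end to end.

# The statistical model

## Normalization

Raw reporter-ion signal sums are first cleaned for additive batch effects on
the `log2(x + 1)` scale (`remove_batch_effects()`): per protein, ordinary
least squares of log intensity on `[preserved design | batch indicators]`
over the observed cells, subtracting only the fitted batch component. The
first batch level is the reference; a batch confounded with a preserved term
raises an error naming the offending columns. The scale of batch removal is
a package choice (documented here) — the operation is linear either way and
back-transformation restores the intensity scale.

Variance stabilization uses the affine-arsinh transform
`h_s(x) = arsinh(a_s + b_s x) / ln 2` (glog2: `~log2(2 b_s x)` at high
intensity, linear near zero). Calibration coefficients `(a_s, b_s)` are
estimated within user-defined sample strata by alternating trimmed least
squares: (i) per-protein row means over the stratum in transformed space,
keeping the least-variable 90% of proteins by residual sum of squares;
(ii) per-sample minimization of the trimmed squared deviation from the row
means, with a Jacobian penalty `-Σ log h'_s(x)` scaled by the current
residual variance. The penalty matters: the bare least-squares objective has
degenerate minima where the transform collapses all columns (`b → 0` or
`|a| → ∞`), and the alternating fit drifts toward them instead of
converging; penalizing the log-derivative — the same device used by
maximum-likelihood glog calibration — removes both. The fit is anchored at
`b_s = 1/median(x_s)`, `a_s = 0`, the trimmed protein set is frozen once the
parameters settle (guarding against selection cycling), and after
convergence the within-stratum product of `b_s` is restored to its initial
value. That final rescale keeps different strata location-comparable on the
glog2 scale — essential when +UV and -UV samples are calibrated in separate
strata and their difference is the tested contrast. Iteration stops at a
relative parameter change below 1e-8 or 50 alternations; non-convergence is
recorded in the returned parameters (with a warning) and the best iterate is
used. In practice the remaining motion at 50 iterations is below 0.1% of the
coefficients and does not affect ratio recovery, which is the accuracy that
matters and is what the tests assert (planted sample-scale ratios recovered
within 5%).

Three stratum layouts mirror the analysis variants (`vst_strata()`):
`per-tissue-condition` (coefficients per tissue x assay x condition),
`single-plusUV` (one stratum pooling all +UV capture samples across
tissues), and `plusUV-only` (one stratum per tissue x assay but fitted on
the +UV samples only; -UV samples are transformed with the mean
coefficients of their stratum, preserving the abundance difference from the
control). A single-sample stratum keeps its anchored initial coefficients
(scale-only). `equal_mean_renormalization()` additionally forces equal
per-sample means over the shared proteins — used when overall
capture-efficiency differences between organs should be deliberately
discarded to compare individual proteins.

## Moderated enrichment testing

Per protein, ordinary least squares on the observed cells with a design of
UV condition plus a replicate blocking factor; the tested contrast is
+UV minus -UV on the glog2 scale. The replicate factor is kept only when it
leaves at least one residual degree of freedom — in the minimal
2 +UV vs 1 -UV design the model reduces to the two-sample comparison, and
the empirical-Bayes prior supplies the degrees of freedom that make testing
well-posed there. Proteins observed in fewer samples than the design rank
are flagged untestable, never errors.

The variance prior `(d0, s0^2)` is estimated by the closed-form moment
method on log residual variances: with `z_g = ln s^2_g` and
`e_g = z_g - ψ(d_g/2) + ln(d_g/2)`, solve
`ψ'(d0/2) = mean((e_g - ē)^2 · G/(G-1) - ψ'(d_g/2))` via a monotone Newton
inversion of the trigamma function, and set
`s0^2 = exp(ē + ψ(d0/2) - ln(d0/2))`; a non-positive right-hand side yields
the point-mass prior `d0 = ∞`, `s0^2 = exp(ē)`. The moderated statistic uses
the shrunken variance `s̃^2_g = (d0 s0^2 + d_g s^2_g)/(d0 + d_g)` with
`d0 + d_g` degrees of freedom (normal reference at `d0 = ∞`; the ordinary t
at `d0 = 0`). P-values are two-sided; multiple testing is controlled by
Benjamini–Hochberg (`benjamini_hochberg()`, `stats::p.adjust` behind the
module surface, with missing p-values excluded from the test count).

A protein is a **hit** at FDR < 0.05 with fold-change above 2 (log2
enrichment >= 1, +UV direction only — depletion is never a hit) and a
**candidate** at FDR < 0.2 with fold-change above 1.5; only proteins
quantified with at least two unique peptides are tested. The boundary is
resolved as `>=` on the log2 threshold, a measure-zero choice.

## Integration and organ comparison

`classify_biotype()` combines a protein's poly(A) and non-poly(A) enrichment
classes: *dual* when both qualify, *exclusive* when the qualifying side is
matched by complete non-detection on the other, *unresolved* when the other
side is detected but unenriched (its binding status cannot be ruled either
way), *none* otherwise. Two qualification modes exist as presets: hit-only
(`fig4f`) and hit-or-candidate (`liver_deep`). "Detected" means present in
the assay's quantified protein list regardless of the peptide filter;
an optional exclusion list marks proteins detected in a deeper non-poly(A)
run, which demotes would-be exclusive poly(A) binders to unresolved.

Cross-organ summaries are exact set algebra (`cross_organ_overlap()`,
`identify_novel_rbps()`, `missing_in_organ_cascade()`,
`cell_line_presence_profile()`). The cascade stages are nested by
construction: commonly reported cell-line RBPs (members of at least half the
published atlas studies) absent from every organ poly(A) hit set; minus
those detected in any non-poly(A) hit set; the remainder split by
total-proteome input detection, with the focus set being proteins expressed
in all organs' inputs yet never captured on RNA.

`mean_signal_summary()` averages linear-scale signal over all
(protein, sample) cells per organ for the proteins that are hits in at least
one organ (the "at least one" convention is deliberate and matches the
headline organ-ratio computation); `rna_adjust_signal()` divides capture
signal by the tissue's RNA content for the matching biotype.
`relative_abundance_matrix()` uses the arithmetic row mean on the linear
scale within each sample family — the convention is pinned by a hand-computed
fixture (`[1, 2, 4]` against mean `7/3` gives `-1.222, -0.222, 0.778`).
Clustering is agglomerative with average linkage on `1 - Pearson` across
columns; rows are pre-sorted by accession so the result is
permutation-invariant, and metric/linkage are package choices since nothing
in the data dictates them. `binding_vs_abundance()` classifies organ-pair
contrasts computed under equal-mean renormalization into
concordant / binding_only / abundance_only / neither, with `log2(1.5)` as
the default "essentially unchanged" tolerance.

## Gel-fraction crosslink QC

Proteins crosslinked to other proteins ("piggy-back riders") migrate above
their predicted monomeric mass in SDS gels. Fractions follow the gel cuts at
20, 25, 37, 50, 75, 100, 150 kDa plus the unbounded top region. Detections
require at least 2 unique peptides in at least 2 of 3 replicates per
(protein, fraction); each valid iBAQ value is divided by the protein's total
valid iBAQ, so per-protein proportions sum to one. Migration calls compare
the modal fraction with the fraction containing the predicted mass:
*monomeric* (equal), *boundary_proximal* (one fraction up with the predicted
mass within 10 kDa below its boundary — gel resolution, not crosslinking),
*bimodal* (two local maxima each holding at least `bimodal_tau = 0.25` of
the mass, separated by at least one fraction, one at the predicted or
boundary fraction), *shifted* otherwise above, *unclassified* below.
"Peak" means a local maximum over the ordered fractions with plateaus
collapsed to their lowest-mass index; "preferentially localizes to higher
fractions" means more than half the proportion mass above the predicted
fraction — both operationalizations are package conventions, stated here
because the informal descriptions they formalize do not fix them. The
piggy-back summary reports, among preferentially-shifted proteins, the
percentage that are capture hits with a boundary-proximal predicted mass.

## Annotation enrichment

`fisher_enrichment()` computes per-term 2x2 tables (foreground vs
background-minus-foreground, or an explicitly disjoint contrast), one-tailed
p-values as exact hypergeometric upper tails, two-sided p-values by the
point-probability rule (the standard exact-test convention), sample odds
ratios with Haldane 0.5 correction when a cell is zero, and BH correction
across terms. The enzyme-RBP analysis contrasts metabolite-interconversion
enzymes that are capture hits against enzymes present in inputs but not in
eluates; catalytic-type profiles deliberately report uncorrected one-tailed
p-values, flagged as such in the output. Domain-to-nucleotide-class maps and
all other annotations are consumed as input tables; no web services are
queried. Independent hypothesis weighting is not implemented — BH is used
throughout and outputs are labelled accordingly.

# The synthetic-data generator

`simulate_eric_experiment()` draws linear-scale intensities as
`2^(a_g + t_gT + b_B + u_s + δ_g·[+UV] + ε) + background`: lognormal
baseline abundance (`a_g ~ N(20, 2)` on log2, i.e. median ~1e6 instrument
units), per-(protein, tissue) effects, additive log-scale batch effects
(sd 0.3), per-sample scaling (sd 0.5), residual noise (sd 0.25), and planted
crosslink enrichment `δ_g` in true RBPs only. Defaults emulate the study
design: three organs; per organ and capture assay two +UV samples and one
pooled -UV control; duplicate inputs; 25% true RBPs split 50/20/30 into
poly(A)-only, non-poly(A)-only and dual binders; `δ_g ~ N(2, 0.5)` on log2
(fold-changes centred at 4, comfortably above the hit threshold of 2, as in
the published volcano plots) scaled by organ activity multipliers
(brain 1.0 < liver 1.1 < kidney 1.5, the ordering the capture signal shows).
Cells go missing with abundance-dependent logistic probability (midpoint
log2 = 15, slope 0.8, ~4% of cells) — independent per cell, a documented
simplification of protein-level MS missingness, which is why "detected in
eluates" is operationalized as "enriched over the control" when the demo
pipeline builds its enzyme contrast set. Unique-peptide counts are
`1 + Poisson` with rate proportional to linear abundance, capped at 60; the
rate constant (30) makes the median protein carry ~12 unique peptides so the
two-peptide filter removes a small but non-trivial ~5% of proteins, as in
deep TMT tissue data. All draws descend from one seed via fixed offsets, so
every output is a pure function of (config, seed).

`simulate_fraction_profiles()` plants monomeric (80%), shifted (10%) and
bimodal (10%) migration classes as Dirichlet-perturbed proportion profiles;
bimodal proteins keep their predicted mass below ~90 kDa and carry the
larger peak (58%) two or more fractions above the predicted one — a
dominant predicted-mass peak would be indistinguishable from monomeric, and
an adjacent second peak indistinguishable from shifted, under the stated
call rules. `simulate_annotations()` plants a configurable novel-RBP
fraction and a configurable odds ratio for nucleotide-cofactor possession
among RBP-enzymes.

What the generator does *not* emulate: reporter-ion ratio compression,
isotope impurity, peptide-level variance structure, protein-level (MNAR)
missingness, and correlated annotation structure. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
the stated generative model, not that the biological conclusions of any
particular dataset would reproduce.

# Numerical choices and degenerate inputs

* VST: trim fraction 0.9, tolerance 1e-8, 50 iterations, BFGS with analytic
  gradients; all-missing samples are errors; single-sample strata are
  scale-only.
* Moderation: variances of exactly zero are excluded from prior estimation;
  all-zero variances return a minimal-variance prior with a warning; the
  trigamma inverse uses the standard monotone Newton iteration with
  asymptotic endpoints.
* Linear models: proteins are grouped by missingness pattern and solved by
  QR once per pattern; contrasts inestimable on the observed cells mark the
  protein untestable.
* Ties: the modal gel fraction takes the lowest index; plateau local maxima
  collapse to their lowest-mass fraction; cluster leaf order is the
  deterministic `hclust` order after sorting rows by accession.
* Missing values are explicit `NA`s everywhere; TSV files encode them as
  empty cells, and observed zeros are kept as zeros (a reporter-ion zero is
  informative). Accessions are compared case-sensitively, isoform suffixes
  kept verbatim.

# Problem sizes

The test suite and the acceptance script run the pipeline at 2000 simulated
proteins per experiment, 200 null replicates for type-I calibration, 100
replicates for prior recovery, and 400 proteins for gel-fraction recovery —
sizes at which every Monte-Carlo interval in the tests is meaningfully
tight while a full run stays in the minutes range on one core.

# Known limitations

* The VST is this package's own alternating trimmed fit of the affine-arsinh
  model; it recovers calibration ratios accurately but is not bit-compatible
  with any external implementation.
* Fold-change thresholds act on the glog2 contrast, which compresses
  low-intensity fold-changes by design; at typical capture intensities the
  effect is negligible.
* The peptide filter consumes a single per-protein unique-peptide count; no
  peptide-level evidence is modelled.
* The pathway-fraction denominator defaults to all annotated members, with
  input-detected members as an option — the choice changes the fractions and
  is surfaced as a parameter rather than hidden.
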