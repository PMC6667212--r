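---
title: "Methods: jury-based consensus DE and trajectory categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jury-based consensus DE and trajectory categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(juryde)
```

This vignette is the package's own account of the statistics it implements:
the three simplified DE callers, the jury aggregation, the trajectory
alphabet, the enrichment and mirror comparisons, the synthetic generator that
stands in for the study data, and the numerical choices made where the
design was genuinely open.

## The design and its contrasts

A staged drying experiment samples one tissue at an ordered series of
estimated-water-content (EWC) stages, by default 35% (fully watered), 15%,
5% and 1%, with four biological replicates per stage. Two contrast schemes
are derived from the same ordering (`build_contrasts()`):

* **AR (against reference)** — every later stage against the first:
  (15 vs 35), (5 vs 35), (1 vs 35), labelled Early/Middle/Late;
* **TC (time course)** — each stage against its predecessor:
  (15 vs 35), (5 vs 15), (1 vs 5).

Stage values are treated as ordered design labels, never as numbers: the
ordering is declared, not inferred, because EWC percentages are sampling
checkpoints rather than a covariate.

## The three callers

All callers share the significance rule: a gene is `up` in a contrast iff
log2FC ≥ 1 and BH-adjusted p ≤ 0.05, `down` symmetrically, else `ns`
(`call_deg()`; both thresholds configurable via `pipeline_config()`). The
fold change thresholded is the raw per-caller estimate — no shrinkage —
because the 2-fold criterion is stated on the fold change itself. BH
adjustment is applied within each contrast.

**Exact conditional NB test** (`exact_nb_test`). Counts are scaled by TMM
size factors and rounded, equalizing effective library sizes; per gene the
test conditions on the total count `t` across both groups. Under equal group
means the test-group total `S` follows the normalized product of two NB
convolutions, `dnbinom(s, n1/α, μ = n1·m) · dnbinom(t − s, n2/α, μ = n2·m)`
with `m = t/(n1+n2)`; the two-sided p sums all outcomes whose probability
does not exceed the observed one. The common dispersion α comes from a
pooled method-of-moments ratio estimator on normalized counts
(`Σ df·(v−m) / Σ df·m²`, floored at 1e-6); `dispersion_mode = "tagwise"`
shrinks genewise moment estimates toward the common value with 10 prior
degrees of freedom. The full support is enumerated up to `t = 20000`;
beyond that a central window is used and extended outward until its boundary
probabilities fall below the observed one — valid because the conditional
law is log-concave, so the selection set `{s : f(s) > f(obs)}` is a single
interval.

**NB GLM Wald test** (`nb_wald_test`). A log-link NB regression with an
intercept, a group indicator and log RLE (median-of-ratios) size factors as
offsets, fit by Fisher-scoring IRLS (cap 50 iterations, deviance tolerance
1e-8, coefficients clamped to |β| ≤ 20 so all-zero groups cannot diverge).
Genewise method-of-moments dispersions are shrunk in log space toward a
fitted mean-dispersion trend α(μ) = a₀ + a₁/μ (least squares over genes with
positive moment estimates, coefficients floored at zero / 1e-6) with 10
prior degrees of freedom. The Wald z uses the standard error from the
expected (Fisher) information at convergence — for the two-group design this
is the closed form `Var(β₁) = 1/Σ_test w + 1/Σ_ref w` with `w = μ/(1+αμ)`,
which is also the oracle the test suite checks against. Non-converged genes
are flagged and reported at p = 1.

**Precision-weighted moderated t** (`voom_lm_test`). log2-CPM with a 0.5
count offset on TMM-effective library sizes; an unweighted genewise
two-group fit gives residual standard deviations whose square roots are
smoothed against mean log2-count by `lowess` (span 0.5, the conventional
default); weights 1/trend⁴ evaluated at each observation's fitted log2-count
feed a weighted refit; residual variances are moderated by moment-matching a
scaled-F model on the log scale (inverse-trigamma estimate of the prior
degrees of freedom), and the group effect is tested with a moderated t on
residual-plus-prior degrees of freedom. Setting `prior_df = 0` and
`use_weights = FALSE` reduces the caller exactly to an ordinary equal-variance
t-test on log2-CPM, which the suite exploits as a degenerate oracle.

### Normalization conventions

`tmm_factors()` returns *size factors*: library size times the
trimmed-mean-of-M-values adjustment, rescaled to geometric mean 1 — so a
sample whose column is a doubled copy of another receives twice its factor.
The TMM adjustment itself uses the canonical recipe: reference sample by
upper-quartile closest to the mean upper quartile, M/A values over genes
positive in both samples, 30%/5% trims from each tail, inverse-asymptotic-
variance weights. `rle_size_factors()` is the plain median of ratios to
per-gene geometric means over genes expressed everywhere.

### Unreplicated contrasts

The emulated design loses replicates at the final stage (the unreplicated
1%-EWC root case). The policy: `exact-nb` and `nb-wald` estimate dispersion
from whichever side still has replication; if neither side does, they fall
back to the configured `fixed_dispersion` (default 0.1, a typical bulk
RNA-seq biological CV² of ~0.32). Either way results carry an
`"unreplicated"` flag. `voom-lm` runs whenever at least one residual degree
of freedom remains (1-vs-4 works, 1-vs-1 is refused). The replicated
Early+Middle analysis is also available as a first-class two-contrast mode
with a 9-way category alphabet.

## Jury aggregation and trajectories

`J1` is the union rule (significant by any caller), `J3` the intersection
(same direction by all callers). The source description never says how J1
should behave when two callers disagree on *direction* for the same gene —
possibly no such gene occurred. Our declared rule: the J1 call becomes `ns`
and the conflict is flagged, because the downstream category partition needs
a single direction per gene and a conservative, auditable resolution beats a
precedence order. `combination_table()` partitions the J1 set into the seven
caller combinations; displayed percentages round half away from zero, so a
direction-consistent table's all-caller cell equals the J3/J1 percentage.

`classify_trajectory()` joins the per-contrast calls Early→Late into the
category string; `mirror_category()` swaps `up`↔`down` at every position and
is an involution whose unique fixed point is the all-`ns` category.

## Enrichment and mirror comparisons

`fisher_two_sided()` enumerates the hypergeometric support and sums the
probabilities of all tables no more probable than the observed one (with the
usual 1+1e-7 tie tolerance). This probability-mass convention reproduces the
published mirror-table p-values the package ships (and `fisher.test`).

`enrich_category()` tests every annotated term: k of n category genes versus
K−k of N−n reference genes, the reference being the annotated universe
*minus* the category (the two-set contrast is ambiguous in typical enrichment
GUIs; the overlapping variant is available via `reference = "whole"`). BH
runs across the terms within each category — matching the per-category
reporting structure — and only over-represented terms (k/n > K/N) count as
enriched; depletion sits behind `direction = "both"`. Annotation
propagation up the ontology (is_a and part_of only, the standard enrichment
practice) is on by default when a DAG is supplied and is idempotent;
`most_specific_terms()` then reports enriched terms with no enriched
descendant. The universe defaults to the full annotated gene set rather
than only expressed genes, matching a genome-wide reference-set convention.

`mirror_kegg_tests()` screens each mirror pair and enzyme code at raw
p < 0.05 with no multiplicity correction, as the published comparison table
reports raw values.

## The synthetic generator

`simulate_counts()` emulates the study conditions: 4 stages × 4 replicates
of one tissue; NB counts with variance μ + αμ² (α = 0.05 by default, a
clean-replicate bulk setting); per-gene baselines log-normal(log 100, 1);
per-sample library factors log-normal with CV 0.3 (echoing the few-fold
read-depth spread across real libraries without copying any particular
values); designed |log2FC| of 2 applied per AR contrast according to a
category drawn from the 27-way alphabet (65% flat, the rest uniform, so a
run contains a realistic DEG fraction). TC truth is derived by differencing
cumulative AR truth, keeping the two schemes mutually consistent. Designed
categories are re-derived from the realized fold-change matrix at the
declared threshold, so a zero effect size yields an all-flat truth table by
construction. `drop_replicates()` reproduces replicate loss;
`simulate_annotations()` plants terms at a requested odds ratio inside a
target category (infinite odds places the term only inside it, at
probability 0.5 so planted counts stay binomially variable).

What the generator does *not* emulate: gene-gene correlation, gene-specific
mean-dispersion trends, outlier replicates with partial degradation,
mapping/assembly artefacts, or annotation bias toward highly expressed
genes. Passing tests therefore demonstrate the pipeline's correctness and
calibration under a faithful NB world, not robustness to every pathology of
real libraries.

Problem sizes used by the suite and the acceptance script — 2000-gene
simulations for calibration and recovery, 20 replicates for planted-term
recovery, 300-400 random tables for the Fisher oracle — were chosen as the
smallest sizes at which the binomial/Monte-Carlo error bands are tight
enough to be informative.

## Numerical choices, in one place

* BH is the FDR procedure throughout (the callers' shared default).
* Dispersion floors at 1e-6; MoM estimates clipped below at the floor.
* IRLS: 50 iterations, deviance tolerance 1e-8, |β| ≤ 20, η ≤ 50.
* lowess span 0.5; precision weights floored via trend ≥ 1e-4.
* Pseudo-count 0.5 for fold changes of zero-count groups; log2-CPM offset
  0.5 on effective library size + 1.
* Integer percentages round half away from zero.
* PCA signs follow a deterministic convention (largest-magnitude loading
  positive) so scores are reproducible across platforms.
* Replicate outlier flagging compares each sample's median within-stage
  distance to the group median of those distances (default multiple 2) — a
  mechanized, advisory stand-in for what is usually a manual exclusion; the
  published root exclusions were made by inspection, so exclusion here
  requires an explicit configuration choice rather than an automatic drop.

## Known limitations

* The callers are deliberately simplified: no Cook's-distance outlier
  handling, no quasi-likelihood or shrunken-LFC variants, single-factor
  designs only. Numerical agreement with the full reference tools is
  approximate by design; only the TMM factors and the variance-moderation
  machinery are cross-checked against them exactly.
* The exact NB test rounds TMM-scaled counts to integers; for very small
  counts this quantization can shift p-values slightly.
* Two printed p-values in the shipped mirror-comparison reference table are
  inconsistent with their own printed contingency counts (independently
  confirmed against `fisher.test`); the package reports the recomputed
  values.
* GO propagation treats is_a and part_of uniformly and ignores other
  relationship types (regulates, occurs_in).
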