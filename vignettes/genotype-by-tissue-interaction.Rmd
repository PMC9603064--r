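---
title: "Partitioning tissue-specific gene expression: split-split-plot ANOVA, AMMI and GGE biplots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning tissue-specific gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueGxE)
```

## The question and the modelling idea

A gene family measured by qPCR across many tissues rarely shows one
expression profile: the same gene ranks differently from tissue to tissue,
and the ranking itself can change with an environmental driver such as
water temperature. `tissueGxE` treats this as a classical
genotype-by-environment (G×E) problem, with the *gene* in the genotype role
and the *tissue* in the environment role. The motivating design is a heat
stress experiment on turbot: four PPAR genes (PPARα1, PPARα2, PPARβ, PPARγ
— regulators of lipid metabolism), ten tissues, five temperatures
(14–28 °C) and three replicate blocks of relative expression from the
2^−ΔΔCt method.

Three complementary analyses are implemented, each authored here from its
closed form:

1. **Split-split-plot (SSP) ANOVA.** The experiment assigns temperature to
   main plots, tissue to subplots and gene to sub-subplots inside complete
   replicate blocks:
   \[
   y_{ihjk} = \mu + b_k + d_{ihj} + f_{ik} + g_{ihk} + e_{ihjk},
   \]
   with a random main-plot error \(f_{ik}\) (block × temperature), a
   subplot error \(g_{ihk}\) (block × temperature × tissue) and a residual
   sub-subplot error \(e_{ihjk}\). The balanced closed-form decomposition
   yields eleven rows; F ratios use the stratum-correct denominators
   (temperature vs main-plot error; tissue terms vs split-plot error;
   gene-bearing terms vs split-split-plot error). Blocks are reported
   without an F test, and block × treatment interactions beyond the defined
   strata are pooled into those strata, the standard SSP convention that
   produces exactly three error rows.

2. **AMMI.** Per temperature, the gene × tissue cell-mean table is split
   into additive main effects plus a multiplicative interaction:
   \[
   y_{ge} = \mu + \alpha_g + \beta_e + \sum_n \lambda_n \gamma_{gn}
   \delta_{en} + \theta_{ge},
   \]
   where the \(\lambda_n, \gamma_{\cdot n}, \delta_{\cdot n}\) come from
   the SVD of the doubly-centered residual matrix. Sums of squares are kept
   on the replicate-observation scale (means-based SS × r) so the pooled
   within-cell Error row, with df \(ge(r-1)\), balances the Total. Axis
   F tests use Gollob degrees of freedom \(g + e - 1 - 2n\) against the
   pooled Error mean square. The per-temperature percentages of total SS
   for gene, tissue and interaction form the effect-contribution profile
   across temperatures.

3. **GGE biplots.** Centering each tissue column of the cell-mean table by
   its mean removes \(\mu + \beta_e\) and leaves genotype main effect plus
   interaction (G + GE), which is what biplot-based gene evaluation should
   see jointly:
   \[
   y_{ge} - \mu - \beta_e = \sum_n \lambda_n \gamma_{gn}\delta_{en} + \theta_{ge}.
   \]
   Three axes are retained for distances (with four genes the centered
   matrix has rank ≤ 3, so they are complete); all biplot geometry —
   tissue-relationship angles, which-won-where sectors, the
   average-environment axis and the ideal point — is planar on PC1–PC2, as
   the standard figures are.

## Tunable parameters

* `nAxes` (AMMI, default 2): retained IPCA axes; the remainder pools into
  a Residual row. Two axes mirror the standard reporting layout and carry
  most of the interaction in practice.
* `partition` (GGE, default `"symmetric"`): the singular-value partition
  exponent f allocates each \(\lambda_n\) between gene scores
  (\(\lambda^f\gamma\)) and tissue scores (\(\lambda^{1-f}\delta\));
  `"genotype"` (f = 1) and `"environment"` (f = 0) are available. Inner
  products of gene and tissue scores — and therefore every rank-based
  output — are partition-invariant; only the visual scaling of a biplot
  changes.
* Generator parameters (below), all in relative-expression units.

## What the synthetic-data generator emulates

`twoWaySimSpec()`/`sspSimSpec()` plus `simulateExpression()` produce
replicate tables with known ground truth, so every downstream stage can be
tested against planted parameters.

* The **defaults are the study layout**: 4 genes × 10 tissues (× 5
  temperatures × 3 blocks for the SSP generator), grand mean ~1.5 relative
  units, sum-to-zero main effects of moderate amplitude, and a rank-2
  planted interaction on deterministic orthonormal contrast vectors.
* **Stratified noise** is placed exactly as the SSP model demands: one
  main-plot draw shared within block × temperature, one subplot draw shared
  within block × temperature × tissue, one residual draw per observation.
  Default s.d. values (σ_f = 0.12, σ_g = 0.1, σ_e = 0.5) are of the
  magnitude seen in replicated qPCR relative-expression tables, where the
  residual mean square sits around 0.2–0.3 and main-plot mean squares are a
  few-fold larger.
* **Gaussian noise is the default** because every analysis here is
  least-squares/SVD based; a lognormal option exists since expression is
  non-negative, with the caveat that the ANOVA expectations then hold on
  the log scale. Negative simulated values are allowed (the analyses do not
  require positivity) and the generator warns when any are produced.
* Planted singular vectors are orthonormalized internally (Gram–Schmidt
  against the constant vector), so a spec is valid even if its input
  vectors are merely linearly independent.

What the generator does **not** emulate: Ct-level amplification noise,
efficiency differences between primer pairs, tissue-dependent variance
heterogeneity, and correlation between genes sharing a reference gene.
Passing recovery tests on synthetic data therefore demonstrates that the
algebra and the error-strata bookkeeping are right, not that real qPCR data
meet the model's assumptions.

## Numerical and design choices

* **Balance is enforced, not repaired.** The closed-form strata df only
  hold for complete balanced designs, so unbalanced input is an error;
  nothing is imputed.
* **Sign convention.** Every SVD axis is oriented so the
  largest-magnitude tissue score is positive. Signs of singular vectors are
  arbitrary; rank outputs are invariant to flips (tested).
* **Ties.** Equal sector-winner projections are broken by gene label
  order — arbitrary and documented.
* **Degenerate inputs.** An all-equal (after centering) matrix yields all
  zero singular values and zero scores, not an error; collinear gene scores
  collapse which-won-where to two half-plane sectors; zero-length tissue
  vectors are flagged in the relationship grid rather than thrown.
* **p-values** are exact upper-tail F probabilities at full precision; the
  display formatter floors them at 1 × 10⁻⁷, mirroring the conventional
  table rendering. Significance stars are ** at p < 0.01 and * at p < 0.05.
* **Gollob liberality.** The Gollob axis test is known to reject more
  often than its nominal level because the leading singular value of a
  noise matrix is stochastically larger than its F reference assumes. It is
  implemented as the field's conventional default; the calibration test in
  the suite is therefore *self-calibrated* (threshold from one half of the
  null draws, rejection rate on the other half) and the nominal-level
  behaviour should be read as approximate.
* **External scores.** `ggeFromScores()` builds the geometry object from
  an already-partitioned score table (e.g. published values). Because the
  partition behind such scores may be unknown, only partition-invariant
  outputs (distances, inner products, rankings, sectors) should be compared
  across sources.

## Problem sizes used in the test-bed

The suite runs entirely on generated data plus the published summary
tables shipped in `inst/extdata`: oracle comparisons use 100 random
3 × 4 × 2 two-way designs and 20 random 2 × 3 × 2 × 2 SSP designs;
moment checks of the error strata use 150–200 small-layout simulations;
the null calibration of the IPCA1 test uses 500 simulations of the
4 × 10 × 3 layout; a law-of-large-numbers check uses one 2 × 2 cell at
r = 10⁴. These sizes keep every statistical tolerance comfortably inside
binomial/Monte-Carlo error while the whole suite runs in well under a
minute.

## Known limitations

* Unbalanced or missing-cell designs are out of scope (a mixed-model/REML
  route would be needed).
* No amplification-efficiency correction (Pfaffl-type) in the ddCt step;
  efficiencies are assumed equal to 2.
* Expression units are treated as opaque positive reals; any rescaling
  applied upstream of the input table is invisible to the analyses.
* The comprehensive ranking implements the ideal-point (concentric-circles)
  distance; published tables built with a weighted index could order
  near-tied genes differently.

## A worked run

```{r pipeline}
x <- suppressWarnings(simulateExpression(sspSimSpec(seed = 11)))
x
fitSspAnova(x)
ammiDecompose(x, "23")
g <- ggeDecompose(cellMeans(x, "23"))
ggeRankings(g)
sectorWinners(whichWonWhere(g))
```

The same pipeline, starting from a CSV and ending in TSV reports plus a
full-precision JSON sidecar, is available as `runReport()` and as the thin
command-line wrapper in `inst/scripts/tissueGxE-report.R`.
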