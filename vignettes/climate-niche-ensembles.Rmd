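---
title: "Comparing climate occupancy with gated ensemble distribution models"
author: "climNiche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing climate occupancy with gated ensemble distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climNiche)
```

## The question the pipeline answers

When a species splits into genetically differentiated population clusters —
for instance a northern cluster (NC) and a southwestern cluster (SC) of a
widespread tree — do the clusters occupy the same climate, or different
ones? climNiche answers this by fitting one ensemble species distribution
model (SDM) per cluster, plus one for the entire population (EP), from
presence/absence records and gridded climate variables, and then comparing
the predicted occupancy surfaces with niche-overlap statistics, permutation
variable importance, and per-variable rank-sum contrasts of the climates at
the presence points.

## The model

**Members and committees.** Each ensemble is a committee of base
classifiers fitted on repeated stratified 80/20 train/test splits. Within a
run all methods see the same split, so methods are comparable; across runs
the splits differ, so the committee integrates over sampling noise. The
native methods are a quadratic logistic regression (GLM), a generalized
additive model (GAM), a classification tree (CTA), a random forest (RF), a
small single-hidden-layer neural network (ANN), and a BIOCLIM-style surface
range envelope (SRE) that classifies a point as suitable iff every climate
variable lies inside the [q, 1−q] quantile envelope of the training
presences (q = 0.025 by default). Further acronyms (GBM, FDA, MARS, MAXENT)
are open registry slots: `registerSDMMethod()` accepts any fit/predict pair
and the rest of the pipeline treats it identically.

**Gating.** Every member is scored on its held-out test fraction with the
true skill statistic,
TSS = sensitivity + specificity − 1,
after binarizing its probabilities at the threshold (searched over the
observed prediction values) that maximizes TSS; ties resolve to the lowest
threshold. Only members with TSS strictly above the gate (default 0.6)
participate in prediction. The committee prediction is the unweighted mean
of the included members' probabilities by default; a TSS-weighted mean is
available, and whichever rule is chosen also weights the importance
aggregation, so reported importances reflect the actual model contributions.

**Overlap.** Two ensemble surfaces are compared after normalizing each to
sum to one over the cells valid in both (so cell values become occurrence
probabilities $p_i$):

$$D = 1 - \tfrac12 \sum_i |p_{x,i} - p_{y,i}|, \qquad
I_{\mathrm{hellinger}} = 1 - \tfrac12 \sum_i
  \left(\sqrt{p_{x,i}} - \sqrt{p_{y,i}}\right)^2.$$

Both run from 0 (disjoint occupancy) to 1 (identical occupancy), and
$D \le I_{\mathrm{hellinger}}$ always. A second variant,
$I_{\mathrm{printed}} = 1 - \tfrac12 \sum_i (p_{x,i} - p_{y,i})^2$, omits
the square roots; this form appears typeset in parts of the applied
literature, and since reports rarely say which was computed, both are
implemented. The Hellinger form is the default because it is the standard
"modified Hellinger" overlap statistic; the two differ numerically
(the printed form is compressed toward 1), so results always record the
variant used. Normalizing before comparing is assumed — without it the
[0, 1] bounds of both statistics do not hold.

**Importance.** For one model and one variable: predict, permute that
variable's column, predict again, and take one minus the Pearson
correlation between the two prediction vectors; the default averages 5
seeded permutations to damp permutation noise (a single randomization is
the `nReps = 1` special case). Values are reported as computed, without
clipping or per-model rescaling. A variable the model ignores scores
exactly 0. If the original predictions are constant the correlation is
undefined and the importance is defined as 0 with a warning (a constant
model is insensitive to everything); if only the permuted predictions are
constant the correlation is taken as 0, i.e. maximal importance, since the
permutation destroyed all structure.

**Climate contrasts.** Five-number summaries (boxplot ingredients) of each
climate variable at each group's presence points, and two-sided
Wilcoxon–Mann–Whitney tests per variable and group pair: exact enumeration
for small untied samples (both n ≤ 20), normal approximation with tie and
continuity correction otherwise. Raw per-variable p-values are the primary
output, matching conventional reporting; a Holm-adjusted column is emitted
alongside as a clearly labelled extension. An absence-climate contrast is
available behind `presenceOnly = FALSE`.

## Partition design

`assemblePartitions()` encodes the regional-ensemble design: each cluster's
partition pairs that cluster's presences with *all* shared absences, while
the whole-population partition pairs all presences with an equal-sized
seeded absence subsample (the balanced whole-range design). This mirrors
range-wide studies in which absences are common to every regional model.

## The synthetic landscape and what it does (not) emulate

The generator stands in for real climate rasters and occurrence databases
so that every claim the package makes can be checked against known ground
truth.

* **Climate fields.** Each variable is Gaussian-filtered white noise on a
  torus (filter SD = correlation length, in cells), standardized, mixed
  across variables through the eigendecomposition of a target correlation
  matrix, then scaled to the requested marginal mean/SD. Realized marginals
  are exact by construction; realized cross-correlations are approximate
  because the filtered fields are only empirically orthogonal. This is far
  cheaper than exact Gaussian-process sampling and adequate for fixtures.
* **Niches.** Ground truth is a weighted Gaussian product (a smooth,
  unimodal climate envelope):
  $s(x) = m \exp(-\tfrac12 \sum_v w_v ((x_v - o_v)/\tau_v)^2)$.
* **Occurrences.** Presences are rejection-sampled with acceptance
  probability $s$, absences with $1 - s$, at cell-centre coordinates.
  Acceptance is stochastic, so labels are noisy and no model can be
  trivially perfect — fitted member TSS is bounded by the Bayes-optimal
  value the sampling scheme implies.

What it does **not** emulate: real map projections, derivation of
evapotranspiration-type layers from raw temperature and precipitation,
anisotropic or nonstationary spatial structure, observation bias, and the
strong density asymmetry real occurrence databases show between regions
(per-cluster counts are exposed so users can mimic it, but no default
asymmetry is asserted). Tests passing on this generator therefore validate
the pipeline's statistical machinery, not any claim about a particular real
landscape.

## Reference study conditions (defaults and why)

`makeTwoClusterScenario()` fixes the package's reference conditions:

| Parameter | Default | Rationale |
|---|---|---|
| grid | 128 × 128 cells | large enough for ~16k-cell surface comparisons, small enough for test-suite runtimes |
| variables | 4, names `v1..v4` | two drive the niche, two are pure-noise companions for importance checks |
| correlation length | 12 cells | visible spatial patchiness without reducing the field to a single blob |
| cross-correlation | 0.3 (all pairs) | climate layers are mutually correlated in practice; 0.3 keeps the design well-conditioned |
| niche tolerance τ | 0.4 SD | with weight 1 on two active variables this puts the Bayes-optimal member TSS near 0.72 (closed-form calculation under the rejection-sampling label model), comparable to published ensemble member scores, so the conventional 0.6 TSS gate retains competent members without being vacuous |
| max suitability m | 0.95 | suitable habitat is never occupied with certainty |
| presences | 1000 per cluster | desk-scale analogue of large occurrence databases |
| absences | 2000, shared | absences ≈ total presences, the balance real range-wide designs use |
| divergence | user-set, in τ units | 0 = one shared niche; 6 = optima 2.4 SD apart, essentially disjoint occupancy |

Absences are drawn from the complement of the *combined* suitability of the
two clusters, since a landscape cell is an absence for the species, not for
one cluster.

## Numerical choices

* **Cell convention.** Half-open cells with the floor convention:
  a point on a shared edge belongs to the upper/right cell; the grid's
  upper/right outer boundary is outside. Records off-grid or on no-data
  cells are dropped and counted, never imputed.
* **Thresholding.** The maximize-TSS search uses the observed prediction
  values as candidate thresholds with `>=` classification, so every
  achievable confusion matrix except "all negative" is reachable; ties go
  to the lowest threshold for determinism.
* **Determinism.** Every operation is a pure function of its inputs and a
  seed. Learners with internal randomness (RF, ANN) are fitted after
  putting training rows into a canonical sort order, so input row order
  cannot leak into results. A master seed fans out to stage seeds by
  hashing stage names (`seedForStage()`), which lets any stage be re-run in
  isolation and makes whole studies reproducible byte-for-byte from their
  manifest.
* **Degenerate inputs.** All-zero surfaces cannot be normalized (error);
  identical-valued rank-sum samples return p = 1 with a degenerate flag;
  single-class training data is rejected naming the method and counts;
  an ensemble in which no member clears the gate fails loudly, listing
  every member's TSS.
* **Float policy.** Probabilities stay in [0, 1] as doubles throughout
  (no integer rescaling); text grids round-trip losslessly via `%.17g`;
  TIFF export is 32-bit float with per-band min/max scaling recorded in a
  JSON sidecar, because multi-band float TIFF stores [0, 1].

## Design notes and caveats

* The committee default is the plain mean of member probabilities; the
  TSS-weighted mean is provided as an option since both conventions exist
  in ensemble-SDM software. Whether to weight rarely changes the overlap
  statistics materially, but it does change importance aggregation.
* One fresh split per run — not per member — so per-run method comparisons
  are apples-to-apples.
* Per-run holdout evaluation is assumed (rather than a single pooled
  holdout); every member's evaluation is retained in the report either way.
* Gate semantics deserve care when building adversarial checks: fitting a
  *low-capacity* learner to label-shuffled data does not reliably produce
  a no-skill member, because with few informative variables a randomly
  oriented quadratic can align with the true niche by chance. A tree fit
  to shuffled labels collapses to near-constant predictions and is the
  better "crippled member" construction.
* Known limitations, deliberately out of scope: spatial block
  cross-validation and any correction for spatial autocorrelation (member
  TSS on spatially dependent splits is optimistic); niche
  identity/background randomization tests; reprojection and resampling;
  faithful replication of any particular SDM framework's internal learner
  defaults.

## Problem sizes used by the shipped checks

The test suite exercises the reference scenario at full size (128 × 128,
10 seeds × 5 divergence levels for overlap recovery; 100 seeded runs for
importance recovery; 200 seeds for the null uniformity of rank-sum
p-values), chosen so the whole suite completes in a couple of minutes on a
single core. `scripts/acceptance.R` recomputes the headline quantities at
3 scenario replicates per divergence and 30 importance replicates — enough
to stabilize medians and rates while staying fast.

## A compact end-to-end example

```{r example, eval = FALSE}
sc <- makeTwoClusterScenario(divergence = 6, seed = 3)
surfaces <- lapply(list(NC = sc$occNC, SC = sc$occSC), function(occ) {
  adm <- extractFeatures(sc$grid, occ)
  ens <- buildEnsemble(adm, c("GLM", "CTA", "SRE"), nRuns = 5, seed = 11)
  predictSurface(ens, sc$grid)
})
pairwiseOverlap(surfaces)      # low D and I: the clusters' climates differ
```
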