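# climNiche

Gated ensemble species distribution models (SDMs) and climate-niche
overlap, for asking a concrete biogeographic question: **do genetically
differentiated population clusters of one species occupy the same climate,
or different climates?** The motivating case is a widespread tree whose
range splits into a northern cluster (NC) and a southwestern cluster (SC);
the package fits one ensemble SDM per cluster and one for the entire
population (EP) from presence/absence records and gridded climate layers,
then quantifies how much the predicted climate occupancies overlap.

It is aimed at ecologists and biogeographers who want the full comparative
pipeline — partition design, committee fitting, accuracy gating, overlap
statistics, variable importance, climate contrasts — as tested, scriptable
building blocks, plus a synthetic-landscape generator with known ground
truth so every step can be validated end to end.

## The statistics at the core

* **Member evaluation — true skill statistic.** Each committee member is
  fitted on a stratified 80/20 split and scored on the held-out fraction:
  TSS = sensitivity + specificity − 1, with the binarization threshold
  chosen to maximize TSS. Only members with TSS > 0.6 (the conventional
  gate) contribute to the ensemble, which averages the surviving members'
  probabilities (optionally TSS-weighted).
* **Niche overlap.** Two ensemble surfaces, each normalized to sum to one
  over their shared cells so cell values are occurrence probabilities
  p_i, are compared with Schoener's D and the Hellinger-based I:

      D = 1 − ½ Σ_i | p_x.i − p_y.i |
      I = 1 − ½ Σ_i ( √p_x.i − √p_y.i )²

  Both run from 0 (no overlap) to 1 (identical occupancy). A "printed"
  I variant without the square roots, 1 − ½ Σ (p_x.i − p_y.i)², is also
  implemented because that form circulates in the applied literature.
* **Permutation importance.** One minus the Pearson correlation between a
  model's predictions before and after randomizing one input variable,
  averaged over seeded permutations and aggregated across ensemble members
  with the committee's own weights.
* **Climate contrasts.** Boxplot five-number summaries of each climate
  variable at each cluster's presence points, and two-sided Wilcoxon
  rank-sum tests per variable and cluster pair (exact for small untied
  samples).

Base models available natively: GLM (quadratic logistic), GAM, CTA
(classification tree), RF (random forest), ANN (small neural network), and
SRE (BIOCLIM-style surface range envelope). Other acronyms (GBM, FDA,
MARS, MAXENT) are open registry slots — `registerSDMMethod()` plugs any
fit/predict pair into the same pipeline.

## Worked example

Simulate a two-cluster landscape whose niche optima are 6 tolerance units
apart (strongly diverged clusters), fit one gated ensemble per cluster,
and measure the overlap of the predicted occupancies:

```r
library(climNiche)

sc <- makeTwoClusterScenario(divergence = 6, seed = 3)
sc$occ
#> OccurrenceSet: 4000 records (2000 presences, 2000 absences)
#>   clusters: NC (1000), none (2000), SC (1000)

surfaces <- lapply(list(NC = sc$occNC, SC = sc$occSC), function(occ) {
  adm <- extractFeatures(sc$grid, occ)
  ens <- buildEnsemble(adm, c("GLM", "CTA", "SRE"), nRuns = 5, seed = 11)
  print(ens)
  predictSurface(ens, sc$grid)
})
#> EnsembleModel: 15 members, 15 pass TSS gate > 0.60 (unweighted mean aggregation)
#>   median member TSS by method: CTA 0.700, GLM 0.777, SRE 0.663
#> EnsembleModel: 15 members, 15 pass TSS gate > 0.60 (unweighted mean aggregation)
#>   median member TSS by method: CTA 0.802, GLM 0.862, SRE 0.748

pairwiseOverlap(surfaces)
#>   surfaceX surfaceY         d         i  iVariant nCells
#> 1       NC       SC 0.1239475 0.3952067 hellinger  16384
```

All 30 members clear the 0.6 TSS gate (member TSS 0.66–0.86 — the label
noise built into the generator caps what any model can score), yet the two
committees' predicted occupancies barely overlap: D ≈ 0.12 on the shared
16,384-cell landscape. Rank-sum contrasts of the climate at the presence
points tell the same story for the diverged variable:

```r
tab <- climateContrast(sc$occ, sc$grid, groups = list(NC = "NC", SC = "SC"))
subset(tab, variable == "v1")
#>   groupA groupB variable   nA   nB statistic p pHolm degenerate
#> 1     NC     SC       v1 1000 1000        12 0     0      FALSE
```

At divergence 0 the same pipeline returns D above 0.9: the statistics
recover the ground truth at both extremes.

The whole comparison — EP, NC and SC ensembles, member reports, surfaces,
overlap table, importances, contrasts and a reproducibility manifest — runs
from a single config with `runStudy(studyConfig(...))`, or from the shell
via `inst/cli/climniche run-study`. A study re-run from its
`manifest.json` reproduces every table byte-for-byte.

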