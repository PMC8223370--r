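---
title: "Dynamic network analysis of mediator time courses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network analysis of mediator time courses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynanet)
```

## The design this package analyses

A cohort of animals receives an inflammatory challenge; at each of several
time points (0, 1, 4, 6, 12, 24, 48 h by default) a group of animals is
sacrificed and a mediator panel (20 cytokines/chemokines/growth factors by
default) is measured in plasma and several organs. Two features shape every
method in the package:

* **Terminal sampling.** Each animal contributes one time point, so there
  are no within-animal trajectories. All correlation is cross-sectional.
* **Compartment units.** Plasma concentrations are pg/ml, tissue
  concentrations pg/mg total protein; quantities in different compartments
  are therefore compared only as within-compartment ratios between groups,
  never summed across compartments.

## The interval-network model

For one strain and compartment, a network is built per analysis interval.
The default intervals (1–4, 4–6, 6–12, 12–24, 24–48 h) are consecutive and
share endpoints. The interval's sample is the pooled cross-section of all
animals sacrificed at either endpoint. Pooling two endpoint groups is the
minimal assembly consistent with five two-endpoint intervals on this grid;
an interval can be widened to include interior time points by passing a
custom interval matrix.

**Baseline-change filter.** A mediator may carry edges only if its pooled
interval values differ from the 0 h control group. We use a two-sided
Mann–Whitney U test (exact when tie-free, normal approximation with
continuity correction otherwise) at α = 0.05. A rank test is preferred to a
t-test because group sizes of 4–8 make normality unverifiable and Luminex
data are right-skewed. Both endpoints of an edge must pass the filter:
an unchanged mediator is noise around baseline, and correlations among
unchanged mediators are exactly the false edges the filter exists to
exclude. No multiple-testing correction is applied by default — the filter
is a gate, not an inference, and correcting it would change the method's
operating characteristics; a Benjamini–Hochberg option (`p_adjust = "BH"`)
is available.

**Edge rule.** For every unordered pair of changed mediators the Pearson
correlation of the pooled sample is computed on pairwise-complete animals.
An edge requires |r| ≥ 0.7, *inclusive*. Edges are signed: positive when
the mediators move in parallel, negative when they oppose. Pairs with
undefined correlation (fewer than 3 complete pairs, or a constant vector)
are skipped and logged rather than propagated as `NaN` — silent skipping
would bias connectivity counts, so skip logs are first-class outputs of the
pipeline report.

**Complexity and totals.** Per-interval complexity is
`sum(degree) / (n - 1)` with `n` the number of mediators *analysed* (the
panel size, 20), not the number that passed the filter; this keeps the
statistic comparable across intervals and groups with different responder
counts, and equals `2|E|/(n-1)`. Total connections per group sum edge
counts over intervals; the connection ratio between strains divides the
totals. Degenerate ratios are kept in-band: `Inf` when only the denominator
is zero, `NaN` when both are — a zero denominator is a scientifically
meaningful outcome (a compartment whose knockout networks are empty), not
an error.

## AUC summaries

Each mediator's mean trajectory (per-time-point group means) is integrated
over 0–48 h by the trapezoid rule on the actual sampling grid. Per-animal
AUCs are impossible under terminal sampling; integrating the mean
trajectory is the estimable analogue. Missing time points are linearly
interpolated across (i.e., simply absent from the grid) and logged.
Compartment sums add the panel's AUCs within one compartment; the strain
ratio of sums shares the `connection_ratio` degenerate-value contract.
No baseline subtraction or incremental-AUC variant is applied.

## Windowed Spearman correlations

For selected mediator pairs, rank correlations are computed in two broad
windows, 0–12 h and 12–48 h, pooling all animals at time points inside the
window. The 12 h boundary belongs to **both** windows, matching how such
windows are conventionally printed; `boundary = "right-open"` makes
membership exclusive instead. Spearman's rho uses midranks for ties. The
95% confidence interval is a percentile bootstrap (B = 1000 by default):
index pairs are resampled with replacement, rho recomputed, and the 2.5/97.5
percentiles taken. The percentile method is the simplest defensible reading
of a "bootstrapped confidence interval"; bias-corrected variants could be
added behind the same interface. Resamples with undefined rho are redrawn
and counted. Significance is defined as the CI excluding zero — no p-value
machinery. The percentile CI can, rarely, fail to contain the point
estimate; the result object records a flag (`rho_outside_ci`) rather than
silently widening the interval.

## The synthetic-cohort generator

`dyna_design()` describes a cohort with known ground truth; `simulate()` /
`simulate_cohort()` draws it. Concentrations are exponentials of a
multivariate normal — log-normal, because immunoassay concentrations are
positive and right-skewed. The paper-like sampling design (two strains at
8 and 4 animals per time point, seven compartments, the canonical grid and
20-mediator panel) is the generator's default frame of reference.

* **Noise.** `noise_cv = 0.3` (log-scale SD ≈ 0.294). Mid-range for
  multiplex immunoassay biological+technical variation; stated as an
  assumption — the measurement model is not identifiable from published
  figures.
* **Responders** get mean shifts in units of the baseline log-scale SD
  (so power statements are scale-free), multiplied by a per-strain
  `response_scaling` (1.0 wild type, 0.4 null in the canned scenario).
* **Planted correlations** are declared per (strain, compartment,
  interval, pair) and installed in the correlation matrix of every time
  point inside the interval. Because consecutive intervals share
  endpoints, blocks of adjacent intervals combine at the shared time
  point; the combined matrix must be positive semi-definite, which
  restricts planted structure at any one time point to disjoint pairs or
  complete cliques (the constructor validates this and names the offending
  group/time). Correlation is planted — and therefore measured in tests —
  on the log scale.
* **Baseline animals** (0 h) form the single control group used by every
  interval's filter, mirroring one control group per strain.

`scenario_paperlike()` encodes the qualitative structure the method is
meant to resolve: a dense, steep, wild-type-only heart network (a
5-mediator 0.9-equicorrelated clique over 1–12 h), sparser wild-type
networks elsewhere, null-strain-only blocks in lung (negative, via one
latent factor with opposite loadings) and spleen (positive) at 12–24 h, and
a late IL-17A/GM-CSF/TNF association in wild-type plasma and spleen only.
The late trio stays at baseline through 12 h and rises only at 24–48 h:
since 12 h belongs to both analysis windows, any planted 12 h response
would leak the association into the early window and destroy the
localization the scenario exists to test.

What the generator does *not* emulate: assay floor/ceiling censoring,
between-animal random effects shared across compartments, non-log-normal
tails, and drifting baselines. Passing recovery tests therefore shows the
pipeline is correct and well-powered under a realistic positive, skewed,
correlated measurement model — not that any particular real dataset meets
those assumptions.

## Numerical and interface choices

* Exact Mann–Whitney p-values whenever the pooled data are tie-free;
  with ties, the normal approximation with continuity correction.
* The edge threshold comparison is inclusive (`>=`), so an |r| exactly at
  the threshold yields an edge.
* Text serializations (edge lists, GraphML) print numbers as the shortest
  decimal that parses back to the identical double, so `read(write(x))`
  reproduces a network exactly; the edge sign travels as an explicit
  `+`/`-` character so it survives any downstream rounding of `r`.
* All simulation and bootstrap code paths take explicit seeds; the
  pipeline derives per-stage substreams from one master seed by hashing
  stage names, so adding or reordering stages cannot silently change
  another stage's draws.
* Degenerate inputs (constant mediators, n < 3 pairs, empty baseline
  groups, zero-edge networks) are defined outcomes, not errors, except
  where the analysis is meaningless (no baseline group at all; fewer than
  two time points for an AUC).

## Validation strategy and problem sizes

The test suite validates each stage against an independent route: a
covariance-formula Pearson oracle, a midrank-construction Spearman oracle,
a full-enumeration Mann–Whitney oracle (the separated 8-vs-8 comparison
has exact p = 2/C(16,8)), a fine-grid quadrature oracle for the AUC, and
brute-force double-loop network construction. Simulation-based checks use
fixed seeds and pre-computed Monte-Carlo envelopes: planted-edge recovery
at ρ = 0.95 with pooled n = 16 over 500 cohorts (sensitivity ≥ 0.9;
false-edge rate under the |r| ≥ 0.7, n = 16 null envelope of 0.006),
percentile-bootstrap coverage at n = 20 and B = 1000 over 500 replicates
(band 0.91–0.99 around the nominal 95%), window localization over 200
cohorts, and 100 end-to-end runs of the full scenario for the
compartment-ranking claims. These sizes keep the full suite in the
tens-of-minutes range on one CPU while leaving the Monte-Carlo bounds
comfortably away from their thresholds.

## Known limitations

* Pooling interval endpoints mixes two sacrifice groups; a mediator with a
  strong monotone trend can show inflated pooled correlation with another
  trending mediator. This is intrinsic to cross-sectional DyNA ("moving in
  parallel" is the signal), but users should read dense networks in
  steeply-trending intervals with that in mind.
* With 4 animals per time point in the null strain, the interval filter
  (8 pooled vs 4 baseline) has limited power; empty null networks are
  common and the connection ratio is then infinite. The ratio contract
  keeps this explicit.
* The baseline filter and edge rule are applied without multiplicity
  control by design; the network is a descriptive screen, not a family of
  confirmatory tests.
* Bootstrap CIs at n ≈ 12 (one strain's late window) are approximate; the
  coverage validation is at n = 20.
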