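# dynanet

Dynamic network analysis of inflammatory-mediator time courses across
tissue compartments.

## The problem

Multiplexed immunoassays measure panels of cytokines, chemokines and growth
factors ("mediators") in plasma and organs of animals challenged with an
inflammatory stimulus. Because the animals are terminally sampled — each
contributes exactly one time point — classical longitudinal methods do not
apply, yet the scientific question is dynamic: *which mediators co-vary,
where, and when, and how does that coordination differ between experimental
groups* (for example a wild-type strain versus a receptor-knockout)?

`dynanet` implements Dynamic Network Analysis (DyNA) for this design,
together with the companion trajectory and correlation summaries, and a
synthetic-cohort generator with planted ground truth so that every stage of
the method can be validated by parameter recovery.

## The method

For each experimental group (strain × compartment), networks are inferred
over consecutive time intervals (by default 1–4, 4–6, 6–12, 12–24 and
24–48 h, sharing endpoints):

1. **Baseline-change filter.** A mediator may carry edges in an interval
   only if its pooled interval values differ from the 0 h control group
   (two-sided Mann–Whitney U, α = 0.05 by default).
2. **Edge rule.** For every unordered pair of changed mediators, the
   Pearson correlation *r* of the pooled cross-section (all animals at the
   interval's two endpoint time points) is computed; an edge is drawn when
   |r| ≥ 0.7 (inclusive), signed by the sign of *r*.
3. **Network complexity** per interval is the degree sum over the panel
   divided by (n − 1), with n the number of mediators analysed:
   complexity = Σᵢ Nᵢ / (n − 1) = 2·|E| / (n − 1).
4. **Total connections** per group is the edge count summed over intervals,
   and the **connection ratio** between two strains compares those totals
   per compartment.
5. **AUC summaries.** Each mediator's mean trajectory is integrated over
   0–48 h by the trapezoid rule; compartment sums and strain ratios mirror
   the connection-ratio comparison.
6. **Windowed Spearman correlations.** For selected mediator pairs (e.g.
   IL-17A/GM-CSF, IL-17A/TNF) the rank correlation is computed in the
   0–12 h and 12–48 h windows with a percentile-bootstrap 95% confidence
   interval (B = 1000); an association is called significant when the
   interval excludes zero.

The synthetic-data module draws cohorts as exponentials of multivariate
normals: responder mediators get planted log-scale mean shifts (in
baseline-SD units), and planted mediator pairs get a target log-scale
correlation per interval, so sensitivity, specificity and localization of
every stage can be measured against known truth.

## Worked example

```r
library(dynanet)

design <- scenario_paperlike(seed = 3)   # two-strain, seven-compartment design
sim    <- simulate_cohort(design)

fit <- dyna(sim$cohort, "C57BL/6", "heart")
fit
#> DyNA fit: C57BL/6 | heart (|r| >= 0.7, baseline alpha = 0.05)
#>   interval    edges  complexity
#>   1-4 h         18      1.8947
#>   4-6 h         10      1.0526
#>   6-12 h        10      1.0526
#>   12-24 h        3      0.3158
#>   24-48 h        2      0.2105
#>   total connections: 43

dyna(sim$cohort, "TLR4-null", "heart")$total_connections
#> [1] 2

compartment_auc_summary(sim$cohort, "heart")
#> AUC summary: heart (0-48 h trapezoid of mean trajectories)
#>   sum of mediator AUCs  C57BL/6: 1.409e+05 | TLR4-null: 1.009e+05
#>   ratio (C57BL/6 : TLR4-null): 1.397

window_correlation(sim$cohort, "C57BL/6", "spleen",
                   c("IL-17A", "GM-CSF"), c(12, 48), seed = 5)
#> Spearman correlation: IL-17A vs GM-CSF | C57BL/6 | spleen | 12-48 h
#>   rho = 0.843, 95% bootstrap CI [0.556, 0.944], n = 24, B = 1000
#>   significant (CI excludes 0): TRUE
```

The wild-type heart carries a dense, shifting network (43 total
connections against 2 in the knockout — a connection ratio of 21.5) and the
largest AUC ratio, while the late-window IL-17A/GM-CSF association is
significant only in the 12–48 h window of the wild type — the qualitative
pattern the planted design encodes.

The full pipeline (simulate → networks → AUC → correlations → report) runs
from one call or from the command line:

```r
run_pipeline(run_config(design = scenario_paperlike(seed = 3), seed = 3,
                        out_dir = "dyna-run"))
```

```sh
Rscript inst/scripts/dyna-pipeline.R --simulate --seed 3 --out dyna-run
```

which writes per-interval edge lists and GraphML files, JSON summaries of
complexity, AUC and windowed correlations, and a consolidated Markdown/JSON
report ranking compartments by connection ratio and AUC ratio, all stamped
with the seed and a configuration hash.

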