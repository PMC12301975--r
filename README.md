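# progsyn

Quantitative analysis of **genetic-interaction synergy in progeroid
double-knockout mouse cohorts**, plus the downstream transcriptome
statistics used to characterise the aged expression state. The package
is aimed at researchers analysing time-resolved phenotype incidence in
multi-genotype knockout colonies (WT, two single knockouts, the double
knockout) and the matching bulk RNA-seq readouts.

## The statistics at its core

**Bliss-independence synergy.** At a horizon *t*, with single-knockout
incidences *p*<sub>A</sub>, *p*<sub>B</sub> and double-knockout
incidence *p*<sub>AB</sub>, independence predicts

&nbsp;&nbsp;&nbsp;&nbsp;*E* = *p*<sub>A</sub> + *p*<sub>B</sub> − *p*<sub>A</sub>·*p*<sub>B</sub>,

and the synergy score is *S* = *p*<sub>AB</sub> − *E*. `progsyn`
estimates the incidences from right-censored cohort tables (crude
proportion or Kaplan–Meier complement), attaches a percentile-bootstrap
95 % CI (within-genotype resampling) and a one-sided resampling p-value
whose null simulates the double-knockout arm at the Bliss-expected rate,
and traces *S*(*t*) over a grid of horizons.

**Survival.** Product-limit curves, median survival, two-group log-rank,
fixed-horizon incidence, and the percent-reduction arithmetic used for
lifespan statements.

**Transcriptome signatures.** Expression/DEG filters (counts > 10 in ≥ 3
samples; |log<sub>2</sub>FC| > 1 and BH-adjusted p < 0.05), the signed
ranking metric −log<sub>10</sub>(p<sub>adj</sub>)·sign(FC), pre-ranked
GSEA (weighted Kolmogorov–Smirnov running sum, gene-label permutation
null, NES, BH FDR), transcript-length imbalance of up- vs
down-regulated genes, cross-tissue core signatures, paired fold-change
comparison, marker-based immune scores, and exact small-sample Wilcoxon
kernels.

**Synthetic data.** A deterministic generator
(`simConfig()` / `simulateCohort()` / `simulateDegTable()` /
`simulateCounts()`) produces four-genotype cohorts with exponential
lesion hazards and a tunable interaction multiplier θ (θ = 1 is *exact*
Bliss independence at every horizon), and DE tables / count matrices
with planted enrichment and a planted short-transcript bias — so the
whole pipeline is testable without animal data.

## Worked example

```r
library(progsyn)

# Published 400-day incidences: DKO 85.4 %, Sirt2-KO 35.0 %, Sod1-KO 4.5 %
100 * blissExpected(0.350, 0.045)
#> [1] 37.925
synergyScore(0.854, 0.350, 0.045)
#> [1] 0.47475
percentReduction(83, 65)   # median lifespan 65 vs 83 weeks
#> [1] 21.7

# The same analysis end-to-end on a simulated cohort (default
# conditions: hazards back-solved from the published incidences,
# interaction multiplier 4.04, 40 animals per genotype)
cohort <- simulateCohort(simConfig(seed = 1))
tc <- synergyTimecourse(cohort, c(100, 200, 300, 400),
                        nBoot = 1000, nPerm = 1000, seed = 1)
round(as.data.frame(tc), 3)
#>   horizon   pAB    pA    pB expected score ciLow ciHigh pPerm
#> 1     100 0.462 0.051 0.025    0.075 0.387 0.210  0.564 0.001
#> 2     200 0.692 0.132 0.026    0.154 0.538 0.363  0.716 0.001
#> 3     300 0.868 0.243 0.051    0.282 0.586 0.404  0.743 0.001
#> 4     400 0.919 0.297 0.053    0.334 0.585 0.397  0.743 0.001
```

Each row reports the observed double-knockout incidence (`pAB`), the
single-knockout incidences, the Bliss expectation, the synergy score
with its 95 % bootstrap CI, and the resampling p-value (`0.001` is the
add-one floor at 1000 resamples): the simulated interaction is detected
at every horizon, with scores far above zero.

A full pipeline run (cohort → synergy time-course → DEG calling →
length imbalance → GSEA → core signature) is driven by a YAML config:

```r
runPipeline(system.file("extdata", "demo_config.yaml", package = "progsyn"),
            outputDir = "demo_out")
```

## Documentation

The methods vignette
(`vignettes/progeroid-synergy-methods.Rmd`) documents the models, the
resampling-null construction, the generator's study conditions, the
numerical conventions, and known limitations.
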