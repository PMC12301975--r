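---
title: "Methods: Bliss synergy inference and aging-signature statistics"
author: "progsyn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bliss synergy inference and aging-signature statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsyn)
```

# The scientific problem

Double-knockout (DKO) mouse cohorts are the standard instrument for asking
whether two genes interact: if losing gene A and losing gene B each raise
the incidence of some phenotype (here, skin lesions in a progeroid model
combining an oxidative-stress knockout with a sirtuin knockout), does
losing both raise it *more than independence predicts*? `progsyn`
implements the quantitative backbone of that question — time-to-event
estimation, Bliss-independence synergy inference with resampling
uncertainty, and the downstream transcriptome statistics used to
characterise the aged expression state — together with a synthetic-data
generator so that every stage can be exercised and validated without
animal data.

# Bliss independence on time-resolved incidence

At a fixed horizon $t$ (days), let $p_A$, $p_B$ and $p_{AB}$ be the
lesion incidences of the two single knockouts and the double knockout.
Bliss independence states that independent causes combine as

$$E = p_A + p_B - p_A p_B,$$

the probability that at least one of two independent events occurs. The
synergy score is the excess of the observed double-knockout incidence
over this expectation,

$$S(t) = p_{AB}(t) - E(t) \in [-1, 1],$$

positive under synergy, negative under antagonism (`blissExpected()`,
`synergyScore()`). A time-course of $S$ over horizons
(`synergyTimecourse()`) shows when an interaction emerges.

## Incidence with right censoring

Not every animal is observed through every horizon. `incidenceAt()`
offers two estimators:

* **crude** (default): the proportion of lesioned animals among those
  whose status at $t$ is known — an event by $t$, or lesion-free
  follow-up through $t$. This matches reporting of incidences as simple
  proportions of small integer counts, and is the default because the
  published percentages at fixed horizons are consistent with exactly
  such proportions.
* **km**: one minus the Kaplan–Meier lesion-free survival at $t$, which
  also uses animals censored before $t$.

The two coincide whenever no censoring occurs before $t$ (a unit test
asserts this). Whether death before lesion should censor the lesion-free
analysis is a preprocessing decision: the cohort table's
`lesion_time`/`lesion_event` columns are taken as already encoding the
chosen convention, and the package does not guess one.

## Uncertainty: bootstrap CI

`synergyCI()` resamples subjects with replacement *within each of the
three knockout genotypes*, recomputes $S$ per resample, and reports the
2.5/97.5 percentiles (type-7 quantiles) of the resampled scores. The
percentile bootstrap is the simplest defensible interval for a bounded
score built from three independent proportions; `nBoot` defaults to
1000, matching the scale of the resampling used for the p-value.
Coverage at nominal 95 % is verified by simulation in the test suite
(true synergy 0.3, 45 animals per genotype, 300 replicates).

## Significance: the resampling null

Bliss independence specifies the null hypothesis exactly: the DKO
incidence *equals* the expected $E(p_A, p_B)$. `synergyPermutationP()`
therefore builds a parametric-resampling null rather than a label
permutation (the labels are not exchangeable between genotypes):

1. resample each single-KO arm with replacement and recompute
   $p_A^*, p_B^*$, capturing estimation noise in the expectation;
2. form $E^* = p_A^* + p_B^* - p_A^* p_B^*$ and simulate the DKO arm as
   independent Bernoulli draws at rate $E^*$ (same number of
   status-known animals as observed);
3. score the replicate against the observed expectation,
   $S^* = \hat p_{AB}^* - \hat E_{obs}$.

The p-value is the add-one estimator
$p = (1 + \#\{S^* \ge S_{obs}\})/(n_{perm} + 1)$, one-sided toward
synergy, which is super-uniform at finite $n_{perm}$ and never returns
0. The scheme is a design choice the data model dictates; it is
documented here precisely so it can be swapped if a different null is
preferred. Its type-I calibration under exact independence is verified
by simulation (500 cohorts of 40 animals per genotype, 1000 resamples
each; the rejection rate at $\alpha = 0.05$ must fall in the exact
binomial 95 % band).

Association between genotype and lesion status at a horizon is tested
separately with the two-tailed Fisher's exact test (`fisherExact2x2()`),
using the probability-mass two-tailed rule (sum of all tables with the
observed margins whose point probability does not exceed the observed
one). The doubling rule is a known alternative; the probability-mass
rule is the dominant convention and the one implemented.

# Survival statistics

`kmEstimate()` wraps the product-limit estimator (via the `survival`
package) in a validated S4 curve; events precede censoring at tied
times, the classical convention. `medianSurvival()` returns the first
time at which $S(t) \le 0.5$ (undefined, `NA`, when the curve never
crosses), and `percentReduction()` performs the lifespan-reduction
arithmetic ($100 (r - x)/r$, one decimal). `logrankTest()` is the
standard two-group log-rank: observed-minus-expected over pooled event
times with hypergeometric variance, $\chi^2_1$ reference. Times are days
internally; week/day conversion belongs at the interface, since lifespan
is conventionally reported in weeks and lesion horizons in days.

# Transcriptome statistics

The expression stack mirrors a conventional bulk RNA-seq downstream
analysis:

* `filterExpressed()`: keep genes with counts strictly above 10 in at
  least 3 samples.
* `callDegs()`: differential genes at $|\log_2 FC| > 1$ and BH-adjusted
  $p < 0.05$, strict inequalities at both cutoffs.
* `rankMetric()` / `rankGenes()`: the signed score
  $-\log_{10}(p_{adj}) \cdot \mathrm{sign}(\log_2 FC)$. `padj = 0` is
  clamped to `1e-300` (finite scores, order preserved, with a warning);
  `log2fc = 0` has no sign and scores 0 with a warning. Ties are broken
  lexicographically by gene id so rankings are identical across
  platforms.
* `gseaPreranked()`: classical weighted Kolmogorov–Smirnov running sum.
  Hits increment by $|s_i|^{w}$ (normalised by the in-set total), misses
  decrement uniformly; the enrichment score (ES) is the extreme
  deviation, with near-ties (floating-point noise on symmetric sums)
  resolved to the earliest list position. Defaults: weight 1, 1000
  gene-label permutations, size gates 15–500 after intersection with the
  ranked list (lower `minSize` for toy examples). NES divides the ES by
  the mean magnitude of same-sign permutation scores; the p-value is the
  one-sided add-one estimate among same-sign nulls; FDR is BH across the
  supplied sets. These are the classical published choices; adaptive or
  multilevel p-value refinement is deliberately out of scope, so
  normalized scores from tools using those variants are comparable only
  qualitatively.
* `lengthImbalance()`: two-sided rank-sum test on transcript lengths of
  up- vs down-regulated DEGs — the short-transcript bias of aged
  transcriptomes. One length per gene is taken as given in the input
  table; how isoforms were collapsed to a gene-level length is upstream
  of this package.
* `coreSignature()`: cross-tissue intersection of per-tissue DEG sets
  plus pairwise overlaps; order-independent and idempotent.
* `foldchangeComparison()`: paired signed-rank comparison of common
  genes' fold changes between the double and a single knockout.
* `immuneScore()`: a deliberately simple marker-mean analogue of murine
  immune deconvolution — per-population mean of marker-gene log
  expression, z-scored across samples. Scores are relative between
  samples of one dataset, never absolute proportions, and the user
  supplies the marker catalog.

## Exact small-sample kernels

`wilcoxonRankSum()` and `wilcoxonSignedRank()` switch between exact
enumeration and the normal approximation (with continuity correction) at
a combined sample size of 12. Enumeration is instantaneous below that
boundary and, unlike off-the-shelf exact routines, handles ties through
average ranks; the boundary itself is covered by a test comparing the
two branches (they agree within 0.02 there). Two-sided exact p-values
use $\min(1, 2\min(P_{\le}, P_{\ge}))$.

# The synthetic-data generator

`simConfig()` fixes the study conditions; the generators split
deterministic named RNG streams from one master seed, so cohorts, DEG
tables and count matrices are reproducible independently and do not
perturb each other or the caller's RNG state.

**Cohorts** (`simulateCohort()`): lesion onset is exponential per
genotype. The defaults back-solve the hazards from the published 400-day
incidences — $\lambda = -\log(1 - p_{400})/400$ gives
$1.08 \times 10^{-3}$/day for the sirtuin knockout (35.0 %),
$1.15 \times 10^{-4}$/day for the SOD knockout (4.5 %), and a near-zero
WT hazard — with 40 animals per genotype (published range 30–48),
400 days of administrative follow-up and mild independent exponential
censoring ($3 \times 10^{-4}$/day, about 11 % lost by day 400; the
censoring pattern of the real colony is unpublished, so this is a free
parameter with a deliberately modest default). The key structural
choice: the DKO hazard is $\theta(\lambda_A + \lambda_B)$. Because
exponential survivals multiply, $\theta = 1$ reproduces
$1 - e^{-(\lambda_A+\lambda_B)t} = E(t)$ — *exact* Bliss independence at
every horizon simultaneously — which is precisely the property that
makes "no synergy" expressible in closed form and the calibration of the
test verifiable. `thetaForSynergy()` inverts the relation to plant a
chosen true score at a chosen horizon (the default multiplier 4.04
reproduces the published 85.4 % DKO incidence at 400 days).

**DEG tables** (`simulateDegTable()`): each gene is planted up, down or
null (5 %/5 %/90 % by default); the observed log2 fold change is the
planted effect ($\pm 2$ by default) plus Gaussian estimation noise
(sd 0.5), and the p-value is the matching Gaussian tail, so null genes
have exactly uniform p-values and BH behaves as in a real DE result.
Transcript lengths are log-normal (median ≈ 2.5 kb, log-sd 1, the
scale of mammalian transcripts); planted up genes have their log-length
reduced by `lengthShift` (default 0.6, a ~45 % median shortening — a
marked but realistic imbalance). Hidden truth labels are returned
separately for recovery tests.

**Counts** (`simulateCounts()`): negative-binomial counts (dispersion
0.05) around log-normal baseline means with planted fold changes,
returned as a `SummarizedExperiment`; `simpleDeTest()` (library-size
scaling, pseudo-count 0.5, per-gene Welch test on the log scale, BH) is
a deliberately plain two-group test that closes the loop on synthetic
data — it is *not* a shrinkage-based negative-binomial model and should
not be used on real counts when such a model is available.

What the generator does **not** emulate: correlated genes, batch
effects, mean–variance coupling beyond the NB marginal,
isoform-resolution lengths, non-exponential (e.g. late-accelerating)
lesion hazards, or informative censoring. Passing tests therefore
demonstrate correctness of the estimators under a clean data-generating
model, not robustness to every pathology of real data.

# Numerical conventions and degenerate inputs

* Percentile CIs use type-7 quantiles; degenerate (constant-outcome)
  cohorts legitimately give zero-width intervals.
* Crude incidence is undefined (NA, with a warning) when every subject
  is censored before the horizon; the KM complement remains usable.
* A log-rank test with no events in either group returns $p = 1$ with a
  warning rather than NaN.
* `simulateCohort` rounds times to 0.001 day and floors them at 1 (ages
  are positive days).
* All resampling outputs are bit-reproducible under a fixed seed; tests
  assert `identical()` on serialised outputs.

# Problem sizes in the test suite

The validation suites run at sizes chosen to make Monte-Carlo bands
tight enough to be meaningful while keeping the full suite around a
minute: 500 simulated cohorts for type-I calibration, 300 for CI
coverage, 100 replicates for length-imbalance recovery, 5000 subjects
for the closed-form incidence check, and exhaustive enumeration for the
exact-test and enrichment-score oracles (all 2×2 tables with total ≤ 30;
all subsets of size 2–4 of ranked lists up to length 8).

# Known limitations

* Only 2×2 exact tests and two-group log-rank; no Cox models,
  competing-risks estimators or multi-group trend tests.
* GSEA p-values are permutation-based; very small p-values saturate at
  $1/(n_{perm}+1)$.
* The immune scoring is a relative marker-mean analogue, not a
  calibrated deconvolution.
* The Bliss machinery assumes the three genotype arms are independent
  samples; shared-litter or cage effects are not modelled.
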