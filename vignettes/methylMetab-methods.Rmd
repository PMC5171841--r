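---
title: "Modelling metabolic determinants of DNA methylation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling metabolic determinants of DNA methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylMetab)
```

# The scientific problem

DNA methylation varies substantially between tumours of the same type, and
part of that variation tracks the activity of the methionine cycle — the
metabolic pathway that regenerates S-adenosylmethionine (SAM), the methyl
donor consumed by DNA methyltransferases. methylMetab asks, for a cohort with
matched methylation, expression, mutation, copy-number and clinical data:

1. How much of the inter-patient variation in methylation (globally, in
   variable 10 kb regions, and at cancer-gene promoters/bodies) is explained
   by methionine-cycle enzyme expression relative to seven other functional
   variable classes?
2. Where in the genome does methylation correlate with methionine-cycle
   expression in sharp, localised peaks, and are those peaks specific to the
   pathway rather than to expression in general?
3. Do patients whose cancer-gene methylation is *predictable* from
   methionine-cycle expression fare differently from patients in whom that
   coupling is broken?

Because the real cohorts behind these questions are controlled-access, the
package ships a seeded generative model (`simulateCohort()`) that plants all
three phenomena with known ground truth, so every stage of the pipeline is
exercised end to end by the test suite.

# The dual modelling core

Each methylation response $y$ (a 10 kb region mean or a gene promoter/body
mean beta value) is modelled twice under threefold cross-validation from the
same encoded design matrix (`encodeDesign()`):

* **Elastic Net** (`fitEnFold()`, via glmnet), minimising
  $\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2
  + \lambda\left[\frac{(1-\alpha)}{2}\lVert\beta\rVert_2^2
  + \alpha\lVert\beta\rVert_1\right]$ with $\alpha = 0.5$ to spread credit
  across correlated predictors. $\lambda$ is selected per training fold by
  inner fivefold cross-validation over a grid of 100 values log-spaced from
  $\lambda_{\max}$ (the smallest value zeroing every coefficient) down by a
  factor $10^{-4}$. Numeric columns are standardized internally and
  coefficients reported on the original scale; 0/1 indicator columns are
  left unscaled, since scaling is not meaningful for categorical factors.
  The per-variable summary is **usage**: the fraction of all
  cross-validation folds in which the variable received a nonzero
  coefficient (a categorical variable counts as selected when *any* of its
  indicator columns is nonzero — the most permissive reading, matching the
  intent of a selection rate).
* **Random Forest** (`fitRfFold()`): a 500-tree regression forest with
  `mtry = floor(p/3)` and minimum node size 5 (the classical regression
  defaults), fit with the ranger engine for speed on a single thread.
  Importance is permutation importance on out-of-bag samples, expressed as
  percent increase in OOB MSE. A categorical variable's importance is the
  sum over its indicator columns; summing is used rather than jointly
  permuting the columns because the engine permutes columns independently,
  and for full indicator sets the sum is the natural additive decomposition.
  Missing predictor values are imputed by the column median (the roughfix
  convention).

Test error is always the mean squared difference between predicted and
observed methylation on the held-out fold. Two identities anchor the
implementation and are asserted in the tests: an Elastic Net forced to
$\lambda_{\max}$ is exactly the training-mean predictor, so its test MSE
equals the test-response variance about the training mean; and a forest
given pure-noise predictors approaches the same quantity.

Variable scores are pooled over responses and folds (`aggregateScores()`),
and class contributions (`classContributions()`) average usage (Elastic Net)
and importance (Random Forest) over the variables of each of eight classes:
methionine-cycle enzymes, other serine/glycine/one-carbon (SGOC) enzymes,
chromatin remodelling factors, transcription factors, SAM-metabolizing
enzymes, clinical factors, copy-number variations, and mutations. Classes
are ranked 1–8 per learner; ties break by class-name order so ranks are
deterministic.

# Preprocessing rules

* Probes with **more than** 80% missing values are dropped (exactly 80% is
  retained — the threshold is read strictly). Sex-chromosome probes are
  dropped at load.
* Global methylation is the per-sample mean beta over retained probes.
* Local methylation tiles the genome into fixed 10 kb intervals anchored at
  coordinate 1 (`[1,10000]`, `[10001,20000]`, ...). The anchor is a
  convention choice; a fixed origin keeps region identities stable across
  runs. Regions with cross-sample standard deviation below 0.2 (sample s.d.,
  $n-1$ denominator) are removed as uninformative.
* Promoter methylation averages probes in TSS1500/TSS200/5'UTR; gene-body
  methylation averages 1st exon/Body/3'UTR.
* Low-expression genes are those with fewer than 70% of samples at a count
  **strictly** above 3; survivors are analysed as $\log_2(\text{count}+1)$,
  the convention for normalized RNA-seq counts.

# The peak scanner

`correlationTrack()` computes, per probe, the Spearman correlation between
the chosen methionine-cycle gene's expression (`selectMetGene()` picks the
candidate with the highest mean |rho| against global and local methylation)
and the probe's beta values, with the two-sided p-value from the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ and average ranks for
ties. Probes with fewer than 8 pairwise-complete samples are skipped.

`scanPeaks()` seeds on the top decile of |rho| genome-wide (direction-
agnostic; the same-direction criterion below encodes sign), opens a ±3 kb
window around each seed, and keeps windows with (a) at least 3 probes
(including the seed) correlated in the seed's direction and (b) at least 80%
of all window probes significant at $p < 10^{-5}$. Overlapping qualifying
windows merge into maximal peaks that keep the largest-|rho| seed; a merged
span must itself still meet both criteria, so every emitted peak satisfies
them by construction.

## Turning-point shape filter

Peaks are ranked by whether their rho series actually forms a peak shape
rather than a plateau. After collapsing runs of exactly equal adjacent
values, a turning point is a strict local extremum. For a turning point with
monotone runs of lengths $l_1$ and $l_2$ on its two sides, the probability
of that event under a random ordering is

$$P = \frac{2\binom{l_1+l_2}{l_1}}{(l_1+l_2+1)!},$$

and its information quantity is $-\log_2 P$ (for the minimal case
$l_1=l_2=1$, $P = 2/3$, the classical probability that the middle of three
distinct values is an extremum). The formula is validated in the test suite
against exhaustive enumeration of all orderings for series up to length 8.
A peak's `turnpoint_p` is the smallest turning-point probability in its
series (1 if the collapsed series is monotone or shorter than 3), and the
lowest 20% are retained. The series-level statistic — the turning-point
count with mean $2(m-2)/3$ and variance $(16m-29)/90$ and its two-sided
normal-approximation p-value — is exposed as `turnpointAnalysis()$p_count`
and checked against Monte-Carlo moments; the per-turning-point exact
probability is used for ranking because it is what distinguishes one sharp
extremum from the many shallow ones an irregular series accumulates.

## Specificity and bias checks

`specificityTest()` compares the fraction of peak probes significantly
(Spearman $p < 0.05$) correlated with the metabolic gene against the same
fraction for 500 random genome genes (excluding all catalog genes), with the
permutation-corrected $q = (1 + \#\{f_i \ge f_\text{met}\})/501$, so $q$ is
never zero and has resolution 1/501. A caveat the simulations make visible:
$f$ is a *fraction of significant correlations* and discards magnitude, so
for a perfectly coherent peak (every probe tracking one latent factor)
$f_\text{met}$ saturates at 1 and a random gene ties it exactly when its
chance correlation with the latent factor clears the 0.05 significance
cutoff — hence $q \approx 0.05$ is the floor for such peaks, not evidence
against specificity. `methylationBiasCheck()` guards against the scanner
favouring highly methylated regions by correlating per-probe mean beta with
per-probe rho over 2,000 sampled probes.

`nearestTss()` annotates peaks with the single nearest TSS within 1 Mb,
distance signed by gene orientation, ties resolved to the lexicographically
smaller symbol.

# Validation suite

* **Random-gene control**: 100 random genome genes, each variance-matched
  within ±25% to the s.d. of a randomly chosen original expression variable,
  join the design; original and random gene-expression variables are then
  compared by one-sided Mann–Whitney on usage (Elastic Net) and importance
  (Random Forest).
* **Permuted/random responses**: methionine-cycle-only models are refit on
  permuted (never-identity) responses, or on iid Uniform(0,1) responses, and
  the per-response usage distributions are compared with a Kolmogorov–
  Smirnov statistic.
* **Random-predictor benchmark and MSE-Imp**: forests fit on fresh
  standard-normal predictor matrices give the null MSE distribution;
  `mseImprovement()` reports MSE-rand/MSE-orig, and `linearBenchmark()`
  reproduces the fully linear simulated comparison
  ($X \sim N(0,1)$, $\beta \sim U(0,1)$, noise s.d. 0.05).

Two statistical choices make the negative controls *exactly* calibrated,
which the acceptance tests verify at nominal 5% over 100 signal-free
simulations:

1. Usage values are heavily tied and, within one response, dependent across
   variables. The KS comparison therefore treats the *response* as the
   exchangeable unit — permutations flip random subsets of true/null
   response pairs between arms — and resolves permutation ties with a
   seeded randomized tie-break. Without both devices the test is
   conservative (ties) or anticonservative (ignored dependence).
2. The Mann–Whitney comparison breaks score ties with a seeded hairline
   jitter, the randomized-test construction that restores exact size under
   exchangeability.

The random-response control asks whether cancer-gene methylation behaves
like unstructured noise on $[0,1]$; its calibration world draws the "true"
responses from exactly that null, since a signal-free cohort's promoter
means still differ from U(0,1) in marginal shape for reasons unrelated to
metabolic signal.

# Survival stratification

Per patient, the mean squared held-out error across all methionine-cycle-
only models of cancer-gene methylation (`metCycleOnlyModels()`) is split at
the cohort median: strictly below-median errors are `predictable`, ties at
the median go to `not_predictable` (the knife-edge is undefined in the
below/above-median convention; the stricter rule is fixed here and makes the
all-tied case degenerate rather than arbitrary). Groups are compared by
Kaplan–Meier curves with the log-rank test, and by per-covariate Cox
proportional-hazards models (Efron ties), one model per covariate with
predictability as the fixed effect. Patients without survival data are
excluded from survival analyses only; non-convergence of a Cox model is
flagged per model, never fatal.

# The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis assumes,
on two synthetic chromosomes:

* **Expression**: log2-scale values, Normal per gene with gene-specific
  mean (U(4,9) for catalog genes, U(1,9) for the 600-gene genome pool) and
  s.d. (U(0.5,1.5), pool U(0.3,2.0)), clamped non-negative. The pool's wider
  s.d. range guarantees variance-matched controls exist.
* **Latent metabolic factor**: $s_j = \sum_g w_g\,\mathrm{expr}_{jg} +
  N(0, 0.2)$ over the four methionine-cycle enzymes (MAT2B, MTR, BHMT2,
  AHCY), with $w$ drawn once per simulation and scaled so the weighted sum
  has unit variance — effect sizes are then in interpretable logit-per-s.d.
  units.
* **Planted regions**: 10 regions of 8 probes spanning 6 kb, each inside
  its own 10 kb tile and serving as the promoter of a synthetic cancer
  gene. Probe beta values are
  $\mathrm{clip}_{[0,1]}(\mathrm{logistic}(b_0 + \beta_\text{met} d\, s_j +
  \beta_\text{tf}\,\mathrm{TF}_j + \beta_\text{mut} M_j +
  \beta_\text{age}(\text{age}_j - 57.5)) + N(0, \sigma_\beta))$ with
  per-probe baseline $b_0 \sim U(-0.8, 0.8)$ and region direction
  $d = \pm 1$ alternating. Defaults:
  $\beta_\text{met} = 1.5$, $\beta_\text{tf} = \beta_\text{mut} = 0.4$,
  $\beta_\text{age} = 0.01$/year, $\sigma_\beta = 0.05$. For a **disrupted**
  patient (default fraction 0.3) the met term uses an independent
  $N(0, \mathrm{sd}(s))$ draw — the metabolic link is broken while the
  marginal variance is preserved. Note the ground truth is deliberately
  fuzzy at the edges: a disrupted patient whose replacement draw lands near
  their true factor *is* predictable, which caps the achievable
  assignment-recovery rate below 1.
* **Background probes**: Beta$(a_p, b_p)$ with bimodal means (mixture of
  Beta(8,2) and Beta(2,8)) and target s.d. drawn U(0.02, 0.35), truncated to
  feasibility — cross-sample variability deliberately brackets the 0.2
  region filter. A handful of extreme-mean probes end up nearly constant,
  as real arrays have.
* **Mutations/CNA/clinical**: Bernoulli mutations with frequency
  U(0.05, 0.35), GISTIC calls with nonzero frequency U(0.15, 0.5) (the 5%
  and 15% inclusion floors of the predictor sets), age U(30, 85), gender,
  and a four-level stage.
* **Survival**: exponential times with hazard
  $h_0 \cdot \mathrm{HR}^{[\text{disrupted}]}$
  ($h_0 = 5\times10^{-4}$/day, HR = 3, administrative censoring at 3000
  days — a median around 3.8 years and ~85% event rate, typical of the
  cohort sizes simulated).

All draws come from named substreams of one master seed, so identical
configurations are bit-identical and adding one stage never perturbs
another's draws. What the generator does **not** emulate: probe chemistry
and SNP artefacts, cell-type composition, co-expression structure in the
genome pool (its genes are independent — the hardest null for the
specificity test), batch effects, and non-exponential hazards. Passing the
recovery tests therefore demonstrates the machinery is sound, not that real
cohorts will show effects of the planted size.

# Problem sizes and numerical choices

The test suite runs the full recovery studies at n = 300 samples with 10
planted regions (scanner and class-contribution checks, 10 seeds), 80
seeds at n = 300 for the null class-rank study, 100 signal-free cohorts of
n = 50 for negative-control calibration, and a 424 x 200 linear benchmark
with 30 train/test simulations of 500-tree forests — sizes chosen so the
whole study re-runs comfortably on a laptop while keeping every Monte-Carlo
bound meaningful. Spearman p-values are floored at the smallest positive
double so $-\log_{10} p$ stays finite at $|\rho| = 1$; the BED score caps at
1000; the specificity q is never zero by the +1 permutation correction;
`makeFolds()` always yields fold sizes differing by at most one.

# Known limitations

* The class-rank *uniformity* one might expect for an effect-free class is
  structurally unattainable: the eight classes differ in size and value
  type, and permutation importance of continuous noise variables sits
  slightly below that of rarely-split discrete variables, so ranks are
  exchangeable neither across classes nor learners. The package reports
  ranks as descriptive summaries; their null distribution must be
  calibrated by simulation for the exact catalog at hand.
* The specificity q saturates near the significance level for perfectly
  coherent peaks (see above).
* Elastic Net captures the logistic link only linearly; strongly saturated
  probes (baselines near 0 or 1) dilute both learners' apparent skill.
* The scanner assumes a dense, ordered probe track; sparse annotations make
  the 80%-significant criterion trivially unstable for windows with very
  few probes (the 3-probe floor is the guard).
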