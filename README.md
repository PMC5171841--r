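# methylMetab

Integrative modelling of metabolic determinants of DNA methylation in tumour
cohorts.

Inter-tumour variation in DNA methylation partly tracks the activity of the
methionine cycle, the pathway that regenerates S-adenosylmethionine (SAM) —
the methyl donor for DNA methyltransferases. Given matched per-patient
matrices (450K-style beta values, log2 expression, binary somatic mutations,
GISTIC copy-number calls in {−2..2}, clinical attributes, survival),
methylMetab quantifies that link three ways:

1. **Dual modelling with class contributions.** Every methylation response
   (variable 10 kb region means, cancer-gene promoter/body means) is fit
   under threefold cross-validation by an Elastic Net
   (α = 0.5, λ by inner fivefold CV; objective
   `(1/2n)‖y − β₀ − Xβ‖² + λ[(1−α)‖β‖²/2 + α‖β‖₁]`) and a 500-tree
   regression Random Forest (permutation importance, %IncMSE on out-of-bag
   samples). Per-variable *usage* (fraction of CV folds with a nonzero
   coefficient) and mean importance are averaged over eight functional
   classes — methionine-cycle enzymes, other SGOC enzymes, chromatin
   remodellers, transcription factors, SAM-metabolizing enzymes, clinical
   factors, copy-number variations, mutations — and the classes ranked 1–8
   per learner.
2. **A genome-wide peak scanner.** Spearman correlation of one
   methionine-cycle enzyme's expression against every probe, seeds in the
   top decile of |rho|, ±3 kb windows kept when ≥3 probes share the seed's
   direction and ≥80% of window probes have p < 1e−5; merged peaks are
   shape-ranked by a Kendall turning-point score
   (`P = 2·C(l1+l2, l1)/(l1+l2+1)!` per turning point), tested for pathway
   specificity against 500 random genes (randomization q-value), checked
   for methylation-level bias, and annotated with the nearest TSS (≤1 Mb,
   signed by gene orientation).
3. **Predictability-based survival stratification.** Patients split at the
   median of their mean held-out error from methionine-cycle-only models of
   cancer-gene methylation; groups compared by Kaplan–Meier/log-rank and by
   per-covariate Cox models with predictability as the fixed effect.

A seeded synthetic-cohort generator (`simulateCohort()`) plants all three
phenomena — a latent metabolic factor driving designated regions, patients
whose methylation is decoupled from it, and survival tied to that
disruption — with full ground truth, plus negative controls
(variance-matched random genes, permuted/random responses, random-predictor
benchmarks and the MSE-Imp fold-change) to validate the machinery.

## Worked example

```r
library(methylMetab)

cfg <- simulationConfig(n_samples = 120, n_probes = 2000, seed = 3)
sim <- simulateCohort(cfg)          # cohort + annotations + ground truth

meth <- filterProbes(methylation(sim$cohort))
regions <- bin10kb(meth, sim$probes)          # 10 kb tiles, s.d. >= 0.2
gene <- selectMetGene(exprMatrix(sim$cohort), globalMethylation(meth),
                      regions, sim$truth$met_genes)
track <- correlationTrack(meth, exprMatrix(sim$cohort)[, gene], sim$probes)
peaks <- scanPeaks(track)
length(peaks)                                  # 10
sum(GenomicRanges::countOverlaps(sim$truth$planted_regions, peaks) > 0)  # 10

des   <- encodeDesign(sim$cohort, sim$catalog)
resp  <- geneMethylationMatrix(meth, sim$probes,
                               sim$truth$cancer_genes[1:4], "promoter")
folds <- makeFolds(120, 3, seed = 11)
fits  <- lapply(1:4, function(j)
  evaluateResponse(des, resp[, j], folds, responseId = colnames(resp)[j],
                   nTrees = 200, seed = j))
classContributions(aggregateScores(fits), sim$catalog)[1, ]
#>                      class en_score en_rank rf_score rf_rank
#> 1 methionine_cycle_enzymes        1       1  8.1296       1

mc  <- metCycleOnlyModels(exprMatrix(sim$cohort)[, sim$truth$met_genes],
                          resp, folds, seed = 2)
asg <- assignPredictability(mc$per_sample_errors)
kmLogrank(asg, survivalTable(sim$cohort))$logrank_p
#> [1] 0.02312772
```

With the default planted effect (1.5 logit units per s.d. of the latent
metabolic factor) the scanner recovers all ten planted regions with no
off-plant peaks, the methionine-cycle class ranks first of eight under both
learners (usage 1.0; mean %IncMSE 8.1), and patients whose methylation was
decoupled from the metabolic factor — who are enriched in the
`not_predictable` group — show significantly worse survival (log-rank
p = 0.023; Cox HR for predictability 0.61 adjusted for age).

A thin command-line front end wraps the same functions
(`inst/cli/methylmetab.R`, subcommands `simulate`, `preprocess`, `model`,
`scan`, `survival`, `validate`, each driven by one YAML config).

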