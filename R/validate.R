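# Negative-control and simulation-based checks of the modelling machinery:
# variance-matched random-gene controls, permuted/random response tests,
# random-predictor benchmarks and the MSE improvement metric.

#' Two-sample Kolmogorov-Smirnov test with permutation p-value
#'
#' Uses the KS sup-distance statistic with a label-permutation null. Usage
#' fractions carry heavy ties, which make both the asymptotic KS p and the
#' conventional `>=` permutation p conservative; the permutation p here uses
#' a seeded randomized tie-break over permutations tied with the observed
#' statistic, which gives the test exact size under exchangeability.
#'
#' @param a,b Numeric samples.
#' @param B Number of permutations (default 199).
#' @param seed Integer seed.
#' @return List: `ks_stat`, `ks_p`.
#' @export
ksPermutationTest <- function(a, b, B = 199L, seed = 1L) {
  stopifnot(length(a) > 0, length(b) > 0)
  stat <- function(x, y) suppressWarnings(
    as.numeric(stats::ks.test(x, y)$statistic))
  obs <- stat(a, b)
  pooled <- c(a, b)
  na <- length(a)
  withSubstream(seed, "ks_perm", {
    perm <- vapply(seq_len(B), function(i) {
      idx <- sample.int(length(pooled), na)
      stat(pooled[idx], pooled[-idx])
    }, numeric(1))
    c_gt <- sum(perm > obs)
    c_eq <- sum(perm == obs)
    u <- sample.int(c_eq + 1L, 1L) - 1L
    list(ks_stat = obs, ks_p = (1 + c_gt + u) / (B + 1))
  })
}

.usageDistribution <- function(fits) {
  # variables x responses matrix of per-response selection rates over folds
  vapply(fits, function(ft) {
    sel <- do.call(cbind, lapply(ft$folds, function(r) r$en_selected))
    rowMeans(sel)
  }, numeric(length(fits[[1]]$variables)))
}

# Exact paired permutation KS for arm comparisons: usage values within one
# response are dependent, so the unit of exchangeability is the response
# column. Under the null the true and null fits of a response are
# exchangeable; each permutation flips a random subset of response pairs
# between arms. A seeded randomized tie-break gives exact size.
.pairedFlipKS <- function(A, B, nPerm = 199L, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B), nrow(A) == nrow(B))
  r <- ncol(A)
  stat <- function(x, y) suppressWarnings(
    as.numeric(stats::ks.test(x, y)$statistic))
  obs <- stat(as.vector(A), as.vector(B))
  withSubstream(seed, "paired_flip_ks", {
    perm <- vapply(seq_len(nPerm), function(i) {
      fl <- stats::runif(r) < 0.5
      Ai <- A; Bi <- B
      Ai[, fl] <- B[, fl]; Bi[, fl] <- A[, fl]
      stat(as.vector(Ai), as.vector(Bi))
    }, numeric(1))
    c_gt <- sum(perm > obs)
    c_eq <- sum(perm == obs)
    u <- sample.int(c_eq + 1L, 1L) - 1L
    list(ks_stat = obs, ks_p = (1 + c_gt + u) / (nPerm + 1))
  })
}

#' Variance-matched random-gene control
#'
#' Adds `nRandom` random genome genes, each matched to the cross-sample s.d.
#' of a randomly chosen original expression variable within +-25%, refits
#' both learners with the combined predictor set, ranks all gene-expression
#' variables by Elastic Net usage and Random Forest importance, and compares
#' original versus random variables with a one-sided Mann-Whitney test
#' (alternative: originals score higher).
#'
#' @param cohort [OmicsCohort-class] whose expression matrix contains both
#'   the catalog variables and a larger genome pool.
#' @param cat_df [variableCatalog()] data.frame.
#' @param responses samples x responses matrix of methylation responses.
#' @param folds Fold labels from [makeFolds()].
#' @param nRandom Number of random control genes (default 100).
#' @param nTrees Forest size (default 500).
#' @param seed Integer seed.
#' @return List: `rank_table` (variable, group, usage, importance),
#'   `p_en`, `p_rf` (one-sided Mann-Whitney p per learner).
#' @export
randomGeneControl <- function(cohort, cat_df, responses, folds,
                              nRandom = 100L, nTrees = 500L, seed = 1L) {
  expr <- exprMatrix(cohort)
  exprClasses <- c("methionine_cycle_enzymes", "other_SGOC_enzymes",
                   "chromatin_remodelling_factors", "transcription_factors",
                   "SAM_metabolizing_enzymes")
  orig <- cat_df$variable[cat_df$var_class %in% exprClasses]
  pool <- setdiff(colnames(expr), cat_df$variable)
  if (length(pool) <= nRandom)
    stop("genome gene pool too small for the requested random set")
  sds_pool <- apply(expr[, pool, drop = FALSE], 2L, stats::sd)
  sds_orig <- apply(expr[, orig, drop = FALSE], 2L, stats::sd)
  picked <- withSubstream(seed, "random_gene_control", {
    avail <- pool
    out <- character(nRandom)
    for (i in seq_len(nRandom)) {
      target <- sample(orig, 1L)
      s <- sds_orig[[target]]
      cand <- avail[abs(sds_pool[avail] - s) <= 0.25 * s]
      if (!length(cand))
        stop(sprintf("no variance-matched candidate for '%s' (s.d. %.3f)",
                     target, s))
      out[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
      avail <- setdiff(avail, out[i])
    }
    out
  })
  aug <- variableCatalog(
    variable = c(cat_df$variable, picked),
    var_class = c(cat_df$var_class,
                  rep("transcription_factors", nRandom)),  # placeholder class
    value_type = c(cat_df$value_type, rep("numeric", nRandom)))
  # encode against an expression matrix view containing the random genes
  design <- encodeDesign(cohort, aug)
  fits <- lapply(seq_len(ncol(responses)), function(j) {
    evaluateResponse(design, responses[, j], folds,
                     responseId = colnames(responses)[j], nTrees = nTrees,
                     seed = seed + j)
  })
  scores <- aggregateScores(fits)
  grp <- ifelse(scores$variable %in% picked, "random",
                ifelse(scores$variable %in% orig, "original", NA))
  tab <- data.frame(variable = scores$variable, group = grp,
                    usage = scores$usage,
                    importance = scores$mean_importance)
  tab <- tab[!is.na(tab$group), , drop = FALSE]
  # a seeded hairline jitter breaks score ties (random rank tie-break), so
  # the one-sided test keeps exact size when usage values are heavily tied
  wt <- function(score) {
    eps <- 1e-9 * (diff(range(score)) + 1)
    jit <- score + stats::runif(length(score), 0, eps)
    suppressWarnings(stats::wilcox.test(
      jit[tab$group == "original"], jit[tab$group == "random"],
      alternative = "greater"))$p.value
  }
  withSubstream(seed, "rank_test",
                list(rank_table = tab, p_en = wt(tab$usage),
                     p_rf = wt(tab$importance)))
}

.nonIdentityPermutation <- function(n) {
  if (n < 2L) stop("cannot permute fewer than 2 values non-trivially")
  repeat {
    p <- sample.int(n)
    if (!all(p == seq_len(n))) return(p)
  }
}

#' Permuted-response negative control
#'
#' Refits methionine-cycle-only models on a seeded (non-identity)
#' permutation of each response and compares the per-response met-cycle
#' usage distributions, true versus permuted, with the permutation KS test.
#'
#' @param exprMet samples x met-genes expression matrix.
#' @param yTrue samples x responses matrix of true methylation responses.
#' @param folds Fold labels.
#' @param seed Integer seed.
#' @param B KS permutations (default 199).
#' @return List (NullComparison): `true_dist`, `null_dist`, `ks_stat`,
#'   `ks_p`.
#' @export
permutedResponseTest <- function(exprMet, yTrue, folds, seed = 1L, B = 199L) {
  yTrue <- as.matrix(yTrue)
  yPerm <- withSubstream(seed, "permute_response", {
    apply(yTrue, 2L, function(v) v[.nonIdentityPermutation(length(v))])
  })
  dimnames(yPerm) <- dimnames(yTrue)
  fit_t <- metCycleOnlyModels(exprMet, yTrue, folds, seed = seed)
  fit_p <- metCycleOnlyModels(exprMet, yPerm, folds, seed = seed + 7919L)
  a <- .usageDistribution(fit_t$fits)
  b <- .usageDistribution(fit_p$fits)
  ks <- .pairedFlipKS(a, b, nPerm = B, seed = seed)
  list(true_dist = as.vector(a), null_dist = as.vector(b),
       ks_stat = ks$ks_stat, ks_p = ks$ks_p)
}

#' Random-response negative control
#'
#' Same comparison as [permutedResponseTest()], but the null responses are
#' iid Uniform(0,1) beta values of the same shape as the true response
#' matrix.
#'
#' @inheritParams permutedResponseTest
#' @return List (NullComparison): `true_dist`, `null_dist`, `ks_stat`,
#'   `ks_p`.
#' @export
randomResponseTest <- function(exprMet, yTrue, folds, seed = 1L, B = 199L) {
  yTrue <- as.matrix(yTrue)
  yRand <- withSubstream(seed, "random_response", {
    matrix(stats::runif(length(yTrue)), nrow(yTrue), ncol(yTrue),
           dimnames = dimnames(yTrue))
  })
  fit_t <- metCycleOnlyModels(exprMet, yTrue, folds, seed = seed)
  fit_r <- metCycleOnlyModels(exprMet, yRand, folds, seed = seed + 7919L)
  a <- .usageDistribution(fit_t$fits)
  b <- .usageDistribution(fit_r$fits)
  ks <- .pairedFlipKS(a, b, nPerm = B, seed = seed)
  list(true_dist = as.vector(a), null_dist = as.vector(b),
       ks_stat = ks$ks_stat, ks_p = ks$ks_p)
}

#' Random-predictor Random Forest benchmark
#'
#' For a fixed response, repeatedly draws a fresh standard-normal predictor
#' matrix and a fresh 2/3-1/3 train/test split, fits a regression forest and
#' records the test MSE. With predictors unrelated to the response the mean
#' of this distribution approaches the response variance.
#'
#' @param y Response vector.
#' @param p Number of random predictors.
#' @param nSims Number of simulations (default 100).
#' @param nTrees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return Numeric vector of test MSEs (length `nSims`).
#' @export
randomPredictorBenchmark <- function(y, p, nSims = 100L, nTrees = 500L,
                                     seed = 1L) {
  stopifnot(p >= 1, nSims >= 1)
  n <- length(y)
  base <- (as.integer(seed) %% 100000L) * 1000L
  vapply(seq_len(nSims), function(i) {
    X <- simulateRandomPredictors(n, p, seed = base + i)
    sp <- withSubstream(base + i, "split",
                        sample.int(n, floor(2 * n / 3)))
    te <- setdiff(seq_len(n), sp)
    rf <- fitRfFold(X[sp, , drop = FALSE], y[sp], nTrees = nTrees,
                    seed = base + i)
    mean((predictRfFold(rf, X[te, , drop = FALSE]) - y[te])^2)
  }, numeric(1))
}

#' MSE improvement metric
#'
#' `MSE-Imp = mean(MSE-rand) / mean(MSE-orig)`: the fold-reduction in test
#' MSE from using the informative predictors instead of random ones; values
#' above 1 indicate usable signal.
#'
#' @param mse_orig_dist,mse_rand_dist Non-empty MSE samples with strictly
#'   positive means.
#' @return List: `mse_orig`, `mse_rand`, `mse_imp`.
#' @export
mseImprovement <- function(mse_orig_dist, mse_rand_dist) {
  stopifnot(length(mse_orig_dist) > 0, length(mse_rand_dist) > 0)
  mo <- mean(mse_orig_dist); mr <- mean(mse_rand_dist)
  if (mo <= 0 || mr <= 0) stop("MSE distributions must have positive means")
  list(mse_orig = mo, mse_rand = mr, mse_imp = mr / mo)
}

#' Linear-simulation benchmark of the Random Forest
#'
#' Builds one linearly related dataset (`X` standard normal, coefficients
#' Uniform(0,1), Gaussian noise) and, over repeated train/test splits,
#' compares forest test MSE on the true predictors against forests fit on
#' fresh standard-normal predictor matrices with the same response.
#'
#' @param n,p Dataset dimensions.
#' @param noiseSd Noise s.d. (default 0.05).
#' @param nSims Number of train/test simulations (default 100).
#' @param nTrees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return [mseImprovement()] result, with the per-simulation MSE vectors
#'   attached as `mse_orig_dist` and `mse_rand_dist`.
#' @export
linearBenchmark <- function(n, p, noiseSd = 0.05, nSims = 100L,
                            nTrees = 500L, seed = 1L) {
  stopifnot(n >= 1, p >= 1)
  ds <- simulateLinearDataset(n, p, noise_sd = noiseSd, seed = seed)
  mo <- mr <- numeric(nSims)
  base <- (as.integer(seed) %% 100000L) * 1000L
  for (i in seq_len(nSims)) {
    si <- base + i
    sp <- withSubstream(si, "split", sample.int(n, floor(2 * n / 3)))
    te <- setdiff(seq_len(n), sp)
    rf1 <- fitRfFold(ds$X[sp, , drop = FALSE], ds$y[sp], nTrees = nTrees,
                     seed = si)
    mo[i] <- mean((predictRfFold(rf1, ds$X[te, , drop = FALSE]) - ds$y[te])^2)
    Xr <- simulateRandomPredictors(n, p, seed = si + 500000L)
    rf2 <- fitRfFold(Xr[sp, , drop = FALSE], ds$y[sp], nTrees = nTrees,
                     seed = si)
    mr[i] <- mean((predictRfFold(rf2, Xr[te, , drop = FALSE]) - ds$y[te])^2)
  }
  out <- mseImprovement(mo, mr)
  out$mse_orig_dist <- mo
  out$mse_rand_dist <- mr
  out
}
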