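# Design encoding, folds and the two learners.

test_that("design encoding expands categoricals and drops constants", {
  sim <- smallSim()
  des <- encodeDesign(sim$cohort, sim$catalog)
  map <- columnMap(des)
  # gender and stage expand to full indicator sets
  expect_identical(sum(map$variable == "gender"), 2L)
  expect_identical(sum(map$variable == "stage"), 4L)
  # hand-derived column count: numerics one column each + factor levels
  n_num <- sum(sim$catalog$value_type == "numeric")
  expect_identical(ncol(designMatrix(des)), n_num + 2L + 4L)
  expect_true(all(map$variable %in% sim$catalog$variable))

  clin <- clinicalTable(sim$cohort)
  clin$gender <- "male"                      # single level -> dropped
  co2 <- OmicsCohort(methylation(sim$cohort), exprMatrix(sim$cohort),
                     mutationCalls(sim$cohort), cnaCalls(sim$cohort),
                     clin, survivalTable(sim$cohort))
  expect_warning(des2 <- encodeDesign(co2, sim$catalog), "gender")
  expect_false("gender" %in% columnMap(des2)$variable)
})

test_that("fold assignment is balanced and seed-reproducible", {
  expect_identical(as.integer(table(makeFolds(9, 3, seed = 1))), rep(3L, 3))
  expect_setequal(as.integer(table(makeFolds(10, 3, seed = 1))), c(4L, 3L, 3L))
  expect_identical(makeFolds(50, 3, seed = 5), makeFolds(50, 3, seed = 5))
  expect_false(identical(makeFolds(50, 3, seed = 5), makeFolds(50, 3, seed = 6)))
  expect_error(makeFolds(2, 3), "at least")
})

test_that("elastic net shrinks fully at huge lambda and reaches OLS at tiny lambda", {
  set.seed(21)
  n <- 200
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, 0, 0.01)
  X <- cbind(x1 = x, x2 = rnorm(n))
  big <- fitEnFold(X, y, lambdaGrid = c(1e9, 9e8), seed = 1)
  expect_true(all(big$coef == 0))
  expect_equal(big$intercept, mean(y), tolerance = 1e-8)
  tiny <- fitEnFold(X, y, lambdaGrid = c(1e-7, 9e-8), seed = 1)
  expect_equal(unname(tiny$coef["x1"]), 2, tolerance = 0.01)

  cst <- fitEnFold(X, rep(0.3, n), seed = 1)
  expect_true(all(cst$coef == 0))
  expect_equal(cst$intercept, 0.3)
})

test_that("the returned elastic-net solution is a local optimum of its objective", {
  set.seed(33)
  n <- 50; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- drop(X %*% c(1, -0.5, 0, 0, 0.3)) + rnorm(n, 0, 0.2)
  fit <- fitEnFold(X, y, seed = 2)
  sds <- apply(X, 2, sd)
  Xs <- sweep(X, 2, sds, "/")
  b_std <- fit$coef * sds
  obj <- function(b0, b) {
    r <- y - b0 - drop(Xs %*% b)
    sum(r^2) / (2 * n) +
      fit$lambda * (0.25 * sum(b^2) + 0.5 * sum(abs(b)))
  }
  f0 <- obj(fit$intercept, b_std)
  set.seed(99)
  worse <- vapply(1:1000, function(i) {
    obj(fit$intercept, b_std + rnorm(p, 0, 0.02)) >= f0 - 1e-8
  }, logical(1))
  expect_true(all(worse))
})

test_that("forest importance singles out the true predictor", {
  # pure noise: importance distribution centred on zero
  set.seed(3)
  Xn <- matrix(rnorm(100 * 8), 100, 8, dimnames = list(NULL, paste0("n", 1:8)))
  yn <- rnorm(100)
  rf0 <- fitRfFold(Xn, yn, nTrees = 300, seed = 4)
  expect_lt(abs(mean(rf0$importance)), 15)

  top <- vapply(1:15, function(sd_) {
    set.seed(sd_)
    X <- matrix(rnorm(120 * 11), 120, 11,
                dimnames = list(NULL, c("x1", paste0("n", 1:10))))
    y <- X[, "x1"]
    rf <- fitRfFold(X, y, nTrees = 300, seed = sd_)
    names(which.max(rf$importance)) == "x1"
  }, logical(1))
  expect_gte(sum(top), 14)

  # a duplicated predictor splits credit but the pair still dominates noise
  dup <- vapply(1:10, function(sd_) {
    set.seed(sd_)
    X <- matrix(rnorm(120 * 10), 120, 10,
                dimnames = list(NULL, c("x1", "x1b", paste0("n", 1:8))))
    X[, "x1b"] <- X[, "x1"]
    y <- X[, "x1"]
    rf <- fitRfFold(X, y, nTrees = 300, seed = sd_)
    (rf$importance["x1"] + rf$importance["x1b"]) >
      max(rf$importance[paste0("n", 1:8)])
  }, logical(1))
  expect_gte(sum(dup), 9)

  expect_error(fitRfFold(Xn, yn, nTrees = 0), "nTrees")
})

test_that("ranger importance agrees with the randomForest reference", {
  skip_if_not_installed("randomForest")
  set.seed(10)
  X <- matrix(rnorm(150 * 6), 150, 6,
              dimnames = list(NULL, c("a", "b", paste0("n", 1:4))))
  y <- 2 * X[, "a"] + X[, "b"] + rnorm(150, 0, 0.3)
  mine <- fitRfFold(X, y, nTrees = 500, seed = 1)
  ref <- randomForest::randomForest(X, y, ntree = 500, importance = TRUE)
  ref_imp <- randomForest::importance(ref, type = 1, scale = FALSE)[, 1]
  # both engines rank the informative pair above every noise column
  expect_identical(order(-mine$importance)[1:2], c(1L, 2L))
  expect_identical(order(-ref_imp)[1:2], c(1L, 2L))
  expect_gt(min(mine$importance[1:2]), max(mine$importance[3:6]))
  expect_gt(min(ref_imp[1:2]), max(ref_imp[3:6]))
})

test_that("cross-validated evaluation obeys null-model identities", {
  sim <- smallSim()
  des <- encodeDesign(sim$cohort, sim$catalog)
  n <- length(sampleIDs(sim$cohort))
  folds <- makeFolds(n, 3, seed = 2)

  # constant response: both learners reach zero test error
  ycst <- rep(0.5, n)
  ft <- evaluateResponse(des, ycst, folds, nTrees = 100, seed = 1)
  expect_true(all(vapply(ft$folds, `[[`, numeric(1), "test_mse_en") == 0))
  expect_true(all(vapply(ft$folds, `[[`, numeric(1), "test_mse_rf") < 1e-10))

  # forcing lambda to the grid maximum reproduces the training-mean predictor
  set.seed(6)
  y <- rnorm(n)
  X <- designMatrix(des)
  for (f in 1:3) {
    tr <- folds != f; te <- folds == f
    en <- fitEnFold(X[tr, ], y[tr], lambdaGrid = c(1e9, 9e8), seed = f)
    mse <- mean((en$intercept - y[te])^2)
    expect_equal(mse, mean((mean(y[tr]) - y[te])^2), tolerance = 1e-10)
  }

  # planted linear response: skill beats the null variance
  yl <- drop(X[, "MAT2B"]) * 0.1 + rnorm(n, 0, 0.05)
  ftl <- evaluateResponse(des, yl, folds, nTrees = 200, seed = 3)
  expect_lt(mean(vapply(ftl$folds, `[[`, numeric(1), "test_mse_en")), var(yl))

  expect_error(evaluateResponse(des, y, rep(c(1, 2), c(1, n - 1))),
               "fewer than 2")
})

test_that("score aggregation and class contributions match hand computation", {
  mkfit <- function(sel, imp) {
    structure(list(response_id = "r", variables = names(sel[[1]]),
                   folds = lapply(seq_along(sel), function(i)
                     list(fold = i, test_mse_en = 0.1, test_mse_rf = 0.1,
                          en_selected = sel[[i]], en_coef = NULL,
                          en_lambda = 0.1, rf_importance = imp[[i]]))),
              class = "RegionModelFit")
  }
  v <- c(a = TRUE, b = FALSE)
  fits <- list(
    mkfit(list(c(a = TRUE, b = FALSE), c(a = TRUE, b = TRUE),
               c(a = FALSE, b = FALSE)),
          list(c(a = 3, b = 1), c(a = 2, b = 2), c(a = 4, b = 0))),
    mkfit(list(c(a = TRUE, b = FALSE), c(a = FALSE, b = FALSE),
               c(a = FALSE, b = FALSE)),
          list(c(a = 1, b = 1), c(a = 1, b = 3), c(a = 1, b = 1))))
  sc <- aggregateScores(fits)
  expect_equal(sc$usage[sc$variable == "a"], 3 / 6)   # selected 3 of 6 folds
  expect_equal(sc$usage[sc$variable == "b"], 1 / 6)
  expect_equal(sc$mean_importance[sc$variable == "a"], 2)
  # percent of variables ranked strictly lower: last of 2 -> 0
  expect_equal(sc$rank_percentile_en[sc$variable == "b"], 0)
  expect_equal(sc$rank_percentile_en[sc$variable == "a"], 50)

  cat2 <- variableCatalog(c("a", "b", "unscored"),
                          c("methionine_cycle_enzymes", "mutations",
                            "clinical_factors"),
                          c("numeric", "numeric", "numeric"))
  expect_warning(cc <- classContributions(sc, cat2), "excluded")
  expect_identical(cc$en_rank[cc$class == "methionine_cycle_enzymes"], 1L)
  expect_identical(cc$rf_rank[cc$class == "mutations"], 2L)

  # equal scores: ties broken by class-name order
  sc2 <- sc; sc2$usage <- c(0.5, 0.5); sc2$mean_importance <- c(1, 1)
  cc2 <- suppressWarnings(classContributions(sc2, cat2))
  expect_identical(cc2$en_rank[cc2$class == "methionine_cycle_enzymes"], 1L)
})

test_that("met-cycle-only models cover each sample exactly once per response", {
  sim <- smallSim()
  meth <- methylation(sim$cohort)
  resp <- geneMethylationMatrix(meth, sim$probes,
                                sim$truth$cancer_genes[1:3], "promoter")
  n <- nrow(resp)
  folds <- makeFolds(n, 3, seed = 9)
  emet <- exprMatrix(sim$cohort)[, sim$truth$met_genes]
  mc <- metCycleOnlyModels(emet, resp, folds, seed = 3)
  expect_identical(sum(!is.na(mc$per_sample_errors)), n * 3L)

  # a response unrelated to met expression: mean error near its variance
  set.seed(77)
  ynull <- matrix(runif(n), dimnames = list(rownames(resp), "null"))
  mc0 <- metCycleOnlyModels(emet, ynull, folds, seed = 4)
  expect_equal(mean(mc0$per_sample_errors), var(ynull[, 1]), tolerance = 0.25)

  ycst <- matrix(0.2, n, 1, dimnames = list(rownames(resp), "cst"))
  expect_error(expect_warning(metCycleOnlyModels(emet, ycst, folds),
                              "zero variance"),
               "no non-degenerate")
})
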