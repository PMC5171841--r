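# Dual Elastic Net / Random Forest modelling of methylation responses under
# threefold cross-validation, with variable-usage, permutation-importance and
# functional-class contribution summaries.
#
# Elastic Net is fit with glmnet (alpha = 0.5; its objective is
# (1/2n)||y - b0 - Xb||^2 + lambda[(1-alpha)||b||^2/2 + alpha||b||_1]),
# with numeric columns standardized internally and coefficients reported on
# the original scale; lambda is chosen by inner fivefold CV over a grid of
# 100 values log-spaced from lambda_max down by a factor 1e-4. The forest is
# a 500-tree regression forest (ranger engine, mtry = floor(p/3),
# min.node.size = 5) with permutation importance on out-of-bag samples
# expressed as percent increase in OOB MSE.

#' Encode an OmicsCohort into a numeric design matrix
#'
#' Numeric catalog variables (expression, copy-number calls as ordered
#' integers, mutations as 0/1, numeric clinical attributes) pass through;
#' categorical clinical attributes expand to a full indicator set (one column
#' per level). Variables constant across samples (including single-level
#' factors) are dropped with a warning.
#'
#' @param cohort [OmicsCohort-class].
#' @param catalog [variableCatalog()] data.frame; every variable must exist
#'   in one cohort component.
#' @return A [DesignMatrix-class].
#' @export
encodeDesign <- function(cohort, catalog) {
  expr <- exprMatrix(cohort); mut <- mutationCalls(cohort)
  cna <- cnaCalls(cohort); clin <- clinicalTable(cohort)
  n <- length(sampleIDs(cohort))
  cols <- list(); map <- list()
  for (i in seq_len(nrow(catalog))) {
    v <- catalog$variable[i]
    vt <- catalog$value_type[i]
    raw <- if (v %in% colnames(expr)) expr[, v]
      else if (v %in% colnames(mut)) mut[, v]
      else if (v %in% colnames(cna)) cna[, v]
      else if (v %in% colnames(clin)) clin[[v]]
      else stop(sprintf("catalog variable '%s' not found in cohort", v))
    if (vt == "categorical") {
      f <- factor(raw)
      if (nlevels(f) < 2L) {
        warning(sprintf("variable '%s' has a single level; dropped", v))
        next
      }
      ind <- stats::model.matrix(~ 0 + f)
      for (j in seq_len(ncol(ind))) {
        cn <- paste0(v, ".", levels(f)[j])
        cols[[cn]] <- ind[, j]
        map[[cn]] <- data.frame(column = cn, variable = v,
                                level = levels(f)[j])
      }
    } else {
      x <- as.numeric(raw)
      if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
        warning(sprintf("variable '%s' is constant; dropped", v))
        next
      }
      cols[[v]] <- x
      map[[v]] <- data.frame(column = v, variable = v, level = NA_character_)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- sampleIDs(cohort)
  new("DesignMatrix", X = X,
      columnMap = do.call(rbind, c(map, list(make.row.names = FALSE))),
      catalog = catalog)
}

#' Seeded cross-validation fold labels
#'
#' @param n Number of samples.
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return Integer vector of labels in `1..k` with sizes differing by at
#'   most one.
#' @export
makeFolds <- function(n, k = 3L, seed = 1L) {
  if (n < k) stop("need at least as many samples as folds")
  withSubstream(seed, "folds", {
    f <- integer(n)
    f[sample.int(n)] <- rep(seq_len(k), length.out = n)
    f
  })
}

.binaryCols <- function(X) {
  apply(X, 2L, function(v) all(v %in% c(0, 1, NA)))
}

.medianImpute <- function(X) {
  nas <- which(colSums(is.na(X)) > 0)
  for (j in nas) {
    X[is.na(X[, j]), j] <- stats::median(X[, j], na.rm = TRUE)
  }
  X
}

#' Fit one Elastic Net fold
#'
#' @param X_train,y_train Training design matrix and response.
#' @param alpha Elastic Net mixing parameter (default 0.5).
#' @param lambdaGrid Optional lambda grid; by default 100 values log-spaced
#'   from lambda_max down by factor 1e-4.
#' @param innerK Inner CV folds for lambda selection (default 5).
#' @param seed Integer seed (inner fold assignment).
#' @return List: `coef` (named, original scale), `intercept`, `lambda`
#'   (inner-CV MSE minimizer), `selected` (named logical per column).
#' @export
fitEnFold <- function(X_train, y_train, alpha = 0.5, lambdaGrid = NULL,
                      innerK = 5L, seed = 1L) {
  stopifnot(nrow(X_train) == length(y_train), all(is.finite(y_train)))
  X_train <- .medianImpute(X_train)
  p <- ncol(X_train)
  if (stats::var(y_train) == 0) {
    cf <- stats::setNames(rep(0, p), colnames(X_train))
    return(list(coef = cf, intercept = y_train[1], lambda = Inf,
                selected = cf != 0))
  }
  # standardize numeric (non-indicator) columns only; indicators are 0/1
  scl <- rep(1, p)
  std <- !.binaryCols(X_train)
  sds <- apply(X_train[, std, drop = FALSE], 2L, stats::sd)
  sds[sds == 0] <- 1
  scl[std] <- sds
  Xs <- sweep(X_train, 2L, scl, "/")
  if (is.null(lambdaGrid)) {
    fit0 <- glmnet::glmnet(Xs, y_train, alpha = alpha, nlambda = 100,
                           lambda.min.ratio = 1e-4, standardize = FALSE)
    lambdaGrid <- fit0$lambda
  }
  foldid <- makeFolds(length(y_train), innerK, seed)
  cvf <- glmnet::cv.glmnet(Xs, y_train, alpha = alpha, lambda = lambdaGrid,
                           foldid = foldid, standardize = FALSE)
  b <- as.numeric(stats::coef(cvf, s = "lambda.min"))
  cf <- stats::setNames(b[-1] / scl, colnames(X_train))
  list(coef = cf, intercept = b[1], lambda = cvf$lambda.min,
       selected = cf != 0)
}

predictEnFold <- function(fit, X) {
  X <- .medianImpute(X)
  drop(fit$intercept + X[, names(fit$coef), drop = FALSE] %*% fit$coef)
}

# Elastic Net objective the fit minimizes (used by optimality tests)
enObjective <- function(X, y, intercept, coef, lambda, alpha = 0.5,
                        scale = NULL) {
  if (!is.null(scale)) coef <- coef * scale  # to standardized scale
  r <- y - intercept - drop(X %*% (if (is.null(scale)) coef else coef / scale))
  sum(r^2) / (2 * length(y)) +
    lambda * ((1 - alpha) * sum(coef^2) / 2 + alpha * sum(abs(coef)))
}

#' Fit one Random Forest fold
#'
#' Missing predictor values are imputed by the column median before fitting.
#' Importance is permutation importance on out-of-bag samples, reported as
#' percent increase in OOB MSE.
#'
#' @param X_train,y_train Training design matrix and response.
#' @param nTrees Number of trees (default 500).
#' @param seed Integer seed.
#' @return List: `model` (ranger fit), `importance` (named numeric, %IncMSE
#'   per column), `oob_mse`.
#' @export
fitRfFold <- function(X_train, y_train, nTrees = 500L, seed = 1L) {
  if (nTrees < 1) stop("nTrees must be >= 1")
  stopifnot(all(is.finite(y_train)))
  X_train <- .medianImpute(X_train)
  fit <- ranger::ranger(
    x = X_train, y = y_train, num.trees = nTrees,
    mtry = max(floor(ncol(X_train) / 3), 1L), min.node.size = 5L,
    importance = "permutation", seed = substreamSeed(seed, "rf"),
    num.threads = 1L)
  imp <- 100 * fit$variable.importance / max(fit$prediction.error, 1e-12)
  list(model = fit, importance = imp, oob_mse = fit$prediction.error)
}

predictRfFold <- function(fit, X) {
  stats::predict(fit$model, data = .medianImpute(X),
                 num.threads = 1L)$predictions
}

.varImportance <- function(impCols, map) {
  # sum a variable's importance over its indicator columns
  vars <- unique(map$variable)
  out <- vapply(vars, function(v) {
    sum(impCols[map$column[map$variable == v]])
  }, numeric(1))
  stats::setNames(out, vars)
}

.varSelected <- function(selCols, map) {
  vars <- unique(map$variable)
  out <- vapply(vars, function(v) {
    any(selCols[map$column[map$variable == v]])
  }, logical(1))
  stats::setNames(out, vars)
}

#' Evaluate one methylation response under cross-validation
#'
#' For each fold, trains both learners on the remaining folds and records
#' held-out test MSE, Elastic Net selection flags and lambda, and Random
#' Forest permutation importance, all aggregated to the variable level
#' (a categorical variable is selected when any of its indicator columns has
#' a nonzero coefficient; its importance is the sum over its columns).
#'
#' @param design [DesignMatrix-class] (or plain matrix, in which case each
#'   column is its own variable).
#' @param y Response vector (finite).
#' @param folds Fold labels from [makeFolds()].
#' @param responseId Identifier stored in the result.
#' @param nTrees,alpha,innerK,seed Learner settings.
#' @param fitRf Set `FALSE` to skip the forest (Elastic-Net-only models).
#' @return An object of class `RegionModelFit`: `response_id`, `variables`,
#'   and per-fold records (`test_mse_en`, `test_mse_rf`, `en_selected`,
#'   `en_coef`, `en_lambda`, `rf_importance`, per-sample squared errors).
#' @export
evaluateResponse <- function(design, y, folds, responseId = "response",
                             nTrees = 500L, alpha = 0.5, innerK = 5L,
                             seed = 1L, fitRf = TRUE) {
  if (is(design, "DesignMatrix")) {
    X <- designMatrix(design); map <- columnMap(design)
  } else {
    X <- as.matrix(design)
    map <- data.frame(column = colnames(X), variable = colnames(X),
                      level = NA_character_)
  }
  stopifnot(nrow(X) == length(y), length(folds) == length(y))
  ks <- sort(unique(folds))
  recs <- vector("list", length(ks))
  persample_en <- rep(NA_real_, length(y))
  names(persample_en) <- rownames(X)
  for (fi in seq_along(ks)) {
    f <- ks[fi]
    te <- folds == f; tr <- !te
    if (sum(te) < 2) stop("fold with fewer than 2 test samples")
    en <- fitEnFold(X[tr, , drop = FALSE], y[tr], alpha = alpha,
                    innerK = innerK, seed = seed + f)
    pred_en <- predictEnFold(en, X[te, , drop = FALSE])
    err_en <- (pred_en - y[te])^2
    persample_en[te] <- err_en
    rec <- list(fold = f,
                test_mse_en = mean(err_en),
                en_selected = .varSelected(en$selected, map),
                en_coef = en$coef,
                en_lambda = en$lambda)
    if (fitRf) {
      rf <- fitRfFold(X[tr, , drop = FALSE], y[tr], nTrees = nTrees,
                      seed = seed + f)
      pred_rf <- predictRfFold(rf, X[te, , drop = FALSE])
      rec$test_mse_rf <- mean((pred_rf - y[te])^2)
      rec$rf_importance <- .varImportance(rf$importance, map)
    }
    recs[[fi]] <- rec
  }
  structure(list(response_id = responseId,
                 variables = unique(map$variable),
                 per_sample_sqerr_en = persample_en,
                 folds = recs),
            class = "RegionModelFit")
}

#' Aggregate variable scores over fits and folds
#'
#' Usage is the fraction of all cross-validation folds (pooled over
#' responses) in which a variable was selected by the Elastic Net; mean
#' importance is the average Random Forest %IncMSE over the same pool. Rank
#' percentiles give, per learner, the percent of variables scoring strictly
#' lower.
#'
#' @param fits List of `RegionModelFit` objects (or a single one).
#' @return data.frame: `variable`, `usage`, `mean_importance`,
#'   `rank_percentile_en`, `rank_percentile_rf`.
#' @export
aggregateScores <- function(fits) {
  if (inherits(fits, "RegionModelFit")) fits <- list(fits)
  stopifnot(length(fits) >= 1)
  vars <- fits[[1]]$variables
  sel <- list(); imp <- list()
  for (ft in fits) for (rec in ft$folds) {
    sel[[length(sel) + 1L]] <- rec$en_selected[vars]
    if (!is.null(rec$rf_importance))
      imp[[length(imp) + 1L]] <- rec$rf_importance[vars]
  }
  usage <- rowMeans(do.call(cbind, sel))
  mimp <- if (length(imp)) rowMeans(do.call(cbind, imp)) else
    stats::setNames(rep(NA_real_, length(vars)), vars)
  pct <- function(s) 100 * vapply(s, function(x) sum(s < x), numeric(1)) /
    length(s)
  data.frame(variable = vars, usage = as.numeric(usage),
             mean_importance = as.numeric(mimp),
             rank_percentile_en = pct(usage),
             rank_percentile_rf = if (all(is.na(mimp))) NA_real_ else pct(mimp),
             row.names = NULL)
}

#' Functional-class contributions
#'
#' Averages Elastic Net usage and Random Forest importance over the variables
#' of each of the eight functional classes and ranks classes per learner
#' (rank 1 = largest contribution; ties broken by class-name order).
#' Classes with no scored variables are excluded with a warning.
#'
#' @param scores Output of [aggregateScores()].
#' @param catalog [variableCatalog()] data.frame.
#' @return data.frame: `class`, `en_score`, `en_rank`, `rf_score`, `rf_rank`.
#' @export
classContributions <- function(scores, catalog) {
  stopifnot(all(scores$variable %in% catalog$variable))
  cls <- catalog$var_class[match(scores$variable, catalog$variable)]
  present <- intersect(VAR_CLASSES, unique(cls))
  absent <- setdiff(unique(catalog$var_class), present)
  if (length(absent))
    warning("class(es) with no scored variables excluded: ",
            paste(absent, collapse = ", "))
  en <- vapply(present, function(k) mean(scores$usage[cls == k]), numeric(1))
  rf <- vapply(present, function(k) mean(scores$mean_importance[cls == k]),
               numeric(1))
  rnk <- function(s) {
    o <- order(-s, present)   # stable: score desc, class name asc
    r <- integer(length(s)); r[o] <- seq_along(s); r
  }
  data.frame(class = present, en_score = as.numeric(en), en_rank = rnk(en),
             rf_score = as.numeric(rf),
             rf_rank = if (all(is.na(rf))) NA_integer_ else rnk(rf),
             row.names = NULL)
}

#' Mean class ranks across datasets
#'
#' @param contribs List of [classContributions()] tables from several
#'   datasets or cohorts.
#' @return data.frame of mean ranks per class and learner.
#' @export
aggregateClassRanks <- function(contribs) {
  cls <- sort(unique(unlist(lapply(contribs, function(x) x$class))))
  en <- vapply(cls, function(k) {
    mean(vapply(contribs, function(x) x$en_rank[match(k, x$class)], numeric(1)),
         na.rm = TRUE)
  }, numeric(1))
  rf <- vapply(cls, function(k) {
    mean(vapply(contribs, function(x) x$rf_rank[match(k, x$class)], numeric(1)),
         na.rm = TRUE)
  }, numeric(1))
  data.frame(class = cls, mean_en_rank = en, mean_rf_rank = rf,
             row.names = NULL)
}

#' Methionine-cycle-only Elastic Net models
#'
#' Fits Elastic Net models of each response using only methionine-cycle gene
#' expression as predictors, and records every sample's squared prediction
#' error from the fold in which it was held out.
#'
#' @param exprMet samples x met-genes expression matrix (e.g.
#'   `exprMatrix(cohort)[, metGenes]`).
#' @param responses samples x responses matrix (e.g. from
#'   [geneMethylationMatrix()]).
#' @param folds Fold labels from [makeFolds()].
#' @param alpha,innerK,seed Learner settings.
#' @return List: `per_sample_errors` (samples x responses matrix of held-out
#'   squared errors), `fits` (list of `RegionModelFit`, Elastic Net only).
#' @export
metCycleOnlyModels <- function(exprMet, responses, folds, alpha = 0.5,
                               innerK = 5L, seed = 1L) {
  responses <- as.matrix(responses)
  stopifnot(nrow(exprMet) == nrow(responses))
  fits <- list()
  errs <- matrix(NA_real_, nrow(responses), ncol(responses),
                 dimnames = dimnames(responses))
  for (j in seq_len(ncol(responses))) {
    y <- responses[, j]
    if (stats::var(y, na.rm = TRUE) == 0) {
      warning(sprintf("response '%s' has zero variance; skipped",
                      colnames(responses)[j]))
      next
    }
    ft <- evaluateResponse(exprMet, y, folds,
                           responseId = colnames(responses)[j],
                           alpha = alpha, innerK = innerK,
                           seed = seed + j, fitRf = FALSE)
    errs[, j] <- ft$per_sample_sqerr_en
    fits[[colnames(responses)[j]]] <- ft
  }
  if (!length(fits)) stop("no non-degenerate responses")
  list(per_sample_errors = errs, fits = fits)
}
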