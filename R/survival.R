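# Predictability-based survival stratification: patients are split at the
# median of their mean held-out prediction error from methionine-cycle-only
# models, compared by Kaplan-Meier / log-rank, and tested in per-covariate
# Cox models.

#' Assign patients to predictability groups
#'
#' Per-patient mean squared held-out prediction error across all
#' methionine-cycle-only models (missing-aware), split at the median:
#' strictly below-median errors are `predictable`, ties at the median go to
#' `not_predictable`. Patients with no observed error are excluded with a
#' warning.
#'
#' @param per_sample_errors samples x responses matrix of held-out squared
#'   errors ([metCycleOnlyModels()]).
#' @return data.frame: `sample`, `mean_error`, `group` (factor with levels
#'   `not_predictable`, `predictable`).
#' @export
assignPredictability <- function(per_sample_errors) {
  m <- as.matrix(per_sample_errors)
  me <- rowMeans(m, na.rm = TRUE)
  drop_idx <- rowSums(!is.na(m)) == 0
  if (any(drop_idx)) {
    warning(sum(drop_idx), " patient(s) with no observed errors excluded")
    me <- me[!drop_idx]
  }
  med <- stats::median(me)
  grp <- factor(ifelse(me < med, "predictable", "not_predictable"),
                levels = c("not_predictable", "predictable"))
  data.frame(sample = names(me), mean_error = as.numeric(me), group = grp,
             row.names = NULL)
}

.survivalFrame <- function(assignment, survival) {
  sv <- survival[assignment$sample, , drop = FALSE]
  df <- data.frame(sample = assignment$sample,
                   time = sv$time_days, event = sv$event,
                   group = assignment$group)
  miss <- is.na(df$time) | is.na(df$event)
  if (any(miss)) {
    message(sum(miss), " patient(s) without survival data excluded")
    df <- df[!miss, , drop = FALSE]
  }
  df
}

#' Kaplan-Meier curves and log-rank test by predictability group
#'
#' @param assignment Output of [assignPredictability()].
#' @param survival data.frame with columns `time_days`, `event`, rownames =
#'   sample ids (as in [survivalTable()]).
#' @return List: `km` (survfit object), `curves` (tidy per-group step
#'   function: time, n_risk, n_event, surv, group), `logrank_p`,
#'   `logrank_chisq`.
#' @export
kmLogrank <- function(assignment, survival) {
  df <- .survivalFrame(assignment, survival)
  if (any(table(df$group) == 0)) stop("a predictability group is empty")
  if (sum(df$event) < 2) stop("need at least 2 events overall")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1, lower.tail = FALSE)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(group = sub("^group=", "", strata),
                       time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, surv = fit$surv,
                       censored = fit$n.censor > 0)
  list(km = fit, curves = curves, logrank_p = as.numeric(p),
       logrank_chisq = as.numeric(sd_$chisq))
}

#' Per-covariate Cox models with predictability as the fixed effect
#'
#' Fits one proportional-hazards model (Efron tie handling) per covariate,
#' each containing the predictability group plus that covariate, and reports
#' the hazard ratio and p-value of the `predictable` term in each model.
#' Non-convergence is flagged per model, not fatal.
#'
#' @param assignment Output of [assignPredictability()].
#' @param survival data.frame with `time_days`, `event`, rownames = sample
#'   ids.
#' @param covariates data.frame of clinical/mutation covariates, rownames =
#'   sample ids; constant covariates are rejected.
#' @return data.frame: `covariate`, `hr_predictable`, `p_predictable`,
#'   `converged`.
#' @export
coxWithCovariates <- function(assignment, survival, covariates) {
  df <- .survivalFrame(assignment, survival)
  if (nlevels(droplevels(df$group)) < 2)
    stop("predictability group is constant")
  out <- lapply(colnames(covariates), function(cv) {
    x <- covariates[df$sample, cv]
    if (length(unique(x[!is.na(x)])) < 2)
      stop(sprintf("covariate '%s' is constant", cv))
    d2 <- cbind(df, .cov = if (is.character(x)) factor(x) else x)
    res <- tryCatch({
      fit <- survival::coxph(survival::Surv(time, event) ~ group + .cov,
                             data = d2, ties = "efron")
      sm <- summary(fit)
      i <- grep("^grouppredictable$", rownames(sm$coefficients))
      warn <- !is.null(fit$info) || any(!is.finite(sm$coefficients[i, ]))
      data.frame(covariate = cv,
                 hr_predictable = sm$coefficients[i, "exp(coef)"],
                 p_predictable = sm$coefficients[i, "Pr(>|z|)"],
                 converged = !warn)
    }, warning = function(w) {
      fit <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ group + .cov,
                        data = d2, ties = "efron"))
      sm <- summary(fit)
      i <- grep("^grouppredictable$", rownames(sm$coefficients))
      data.frame(covariate = cv,
                 hr_predictable = sm$coefficients[i, "exp(coef)"],
                 p_predictable = sm$coefficients[i, "Pr(>|z|)"],
                 converged = FALSE)
    }, error = function(e) {
      data.frame(covariate = cv, hr_predictable = NA_real_,
                 p_predictable = NA_real_, converged = FALSE)
    })
    res
  })
  do.call(rbind, out)
}
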