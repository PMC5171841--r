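# Synthetic multi-omics cohort generator with known ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# beta-distributed background methylation with cross-sample s.d. spanning the
# 0.2 region filter, planted genomic regions whose methylation follows a
# latent metabolic factor driven by methionine-cycle expression (plus
# transcription-factor, mutation and age effects), and survival times whose
# hazard depends on whether a patient's methylation is decoupled from that
# metabolic link.

#' Simulation configuration
#'
#' Defaults define the reference simulated study: 200 samples, 4,000 probes
#' on two synthetic chromosomes, 10 planted 6 kb regions of 8 probes each,
#' and a catalog of 69 expression variables over five functional classes plus
#' clinical, mutation and copy-number predictors, with 600 background genes
#' forming the genome pool for randomization tests.
#'
#' @param n_samples Number of patients.
#' @param n_probes Total probe count (planted + background).
#' @param n_genes_per_class Named counts of expression variables for the five
#'   expression classes.
#' @param n_background_genes Genome pool genes outside the catalog.
#' @param n_mutation_genes,n_cna_genes Binary mutation / GISTIC copy-number
#'   predictors.
#' @param n_planted_regions Number of planted metabolically driven regions.
#' @param probes_per_region Probes per planted region (within 6 kb).
#' @param effect_sizes Named vector: `met_effect` (logit units per s.d. of the
#'   latent metabolic factor), `tf_effect`, `mut_effect` (logit units),
#'   `age_effect` (logit units per year from the age midpoint).
#' @param noise_sd_beta Additive Gaussian noise s.d. on the beta scale.
#' @param frac_disrupted_patients Fraction of patients whose planted-region
#'   methylation is decoupled from the metabolic factor.
#' @param survival_params List: `baseline_hazard` (events/day),
#'   `disruption_hr` (hazard ratio for disrupted patients), `censor_time`
#'   (administrative censoring, days).
#' @param seed Integer master seed; all draws derive from named substreams of
#'   it so one stage's draws do not perturb another's.
#' @return A classed list of validated settings.
#' @export
simulationConfig <- function(n_samples = 200L,
                             n_probes = 4000L,
                             n_genes_per_class = c(
                               methionine_cycle_enzymes = 4L,
                               other_SGOC_enzymes = 20L,
                               chromatin_remodelling_factors = 20L,
                               transcription_factors = 15L,
                               SAM_metabolizing_enzymes = 10L),
                             n_background_genes = 600L,
                             n_mutation_genes = 8L,
                             n_cna_genes = 8L,
                             n_planted_regions = 10L,
                             probes_per_region = 8L,
                             effect_sizes = c(met_effect = 1.5,
                                              tf_effect = 0.4,
                                              mut_effect = 0.4,
                                              age_effect = 0.01),
                             noise_sd_beta = 0.05,
                             frac_disrupted_patients = 0.3,
                             survival_params = list(baseline_hazard = 5e-4,
                                                    disruption_hr = 3,
                                                    censor_time = 3000),
                             seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              n_genes_per_class = n_genes_per_class,
              n_background_genes = as.integer(n_background_genes),
              n_mutation_genes = as.integer(n_mutation_genes),
              n_cna_genes = as.integer(n_cna_genes),
              n_planted_regions = as.integer(n_planted_regions),
              probes_per_region = as.integer(probes_per_region),
              effect_sizes = effect_sizes,
              noise_sd_beta = noise_sd_beta,
              frac_disrupted_patients = frac_disrupted_patients,
              survival_params = survival_params,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples > 0, cfg$n_probes > 0,
            all(cfg$n_genes_per_class > 0),
            cfg$noise_sd_beta > 0,
            cfg$frac_disrupted_patients >= 0,
            cfg$frac_disrupted_patients <= 1,
            cfg$survival_params$baseline_hazard > 0,
            cfg$survival_params$disruption_hr > 0)
  if (cfg$n_planted_regions * cfg$probes_per_region > cfg$n_probes)
    stop("planted probes (n_planted_regions * probes_per_region) exceed n_probes")
  stopifnot(all(c("met_effect", "tf_effect", "mut_effect", "age_effect") %in%
                  names(cfg$effect_sizes)))
  class(cfg) <- "SimulationConfig"
  cfg
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a multi-omics cohort with known ground truth
#'
#' See [simulationConfig()] for the generative model's knobs. Planted regions
#' sit in their own 10 kb tiles, each hosting a synthetic "cancer gene" whose
#' promoter probes carry the planted signal; 60% of background probes lie
#' within 2 kb of a TSS (mirroring array design bias), the rest in gene
#' bodies or intergenic space. Identical config (including seed) gives
#' bit-identical output.
#'
#' @param config A [simulationConfig()].
#' @return List with `cohort` ([OmicsCohort-class]), `probes`, `genes`
#'   (annotation `GRanges`), `catalog` (see [variableCatalog()]) and `truth`:
#'   planted regions (`GRanges` with `direction`, `gene`), disrupted patient
#'   ids, the latent metabolic factor, driver variable names and effect sizes.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  n <- cfg$n_samples
  seed <- cfg$seed
  samples <- sprintf("S%04d", seq_len(n))
  K <- cfg$n_planted_regions
  ppr <- cfg$probes_per_region

  ## gene layout -------------------------------------------------------------
  ngc <- cfg$n_genes_per_class
  met_genes <- c("MAT2B", "MTR", "BHMT2", "AHCY")[seq_len(min(4, ngc[["methionine_cycle_enzymes"]]))]
  if (ngc[["methionine_cycle_enzymes"]] > 4)
    met_genes <- c(met_genes, sprintf("METC%02d", seq_len(ngc[["methionine_cycle_enzymes"]] - 4)))
  sgoc_genes <- sprintf("SGOC%02d", seq_len(ngc[["other_SGOC_enzymes"]]))
  crf_genes <- sprintf("CRF%02d", seq_len(ngc[["chromatin_remodelling_factors"]]))
  tf_genes <- sprintf("TF%02d", seq_len(ngc[["transcription_factors"]]))
  sam_genes <- sprintf("SAM%02d", seq_len(ngc[["SAM_metabolizing_enzymes"]]))
  cg_genes <- sprintf("CG%02d", seq_len(K))
  bg_genes <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  expr_genes <- c(met_genes, sgoc_genes, crf_genes, tf_genes, sam_genes,
                  cg_genes, bg_genes)

  # planted tiles: one per region, well separated, alternating chromosomes
  tile_idx <- 50L * seq_len(K)
  pl_chrom <- paste0("chr", (seq_len(K) - 1L) %% 2L + 1L)
  tile_start <- (tile_idx - 1L) * 10000L + 1L
  region_start <- tile_start + 2000L
  region_end <- region_start + 6000L
  cg_tss <- tile_start + 5000L

  # remaining genes beyond the planted zone, alternating chromosomes
  other_genes <- setdiff(expr_genes, cg_genes)
  og_chrom <- paste0("chr", (seq_along(other_genes) - 1L) %% 2L + 1L)
  og_tss <- 10000000L + 37000L * seq_along(other_genes)
  gdf <- data.frame(
    gene = c(cg_genes, other_genes),
    chrom = c(pl_chrom, og_chrom),
    tss = c(cg_tss, og_tss),
    strand = rep_len(c("+", "-"), K + length(other_genes)))
  genes <- geneAnnotation(gdf)

  ## probe layout ------------------------------------------------------------
  planted <- data.frame(
    probe_id = sprintf("pl_%02d_%02d", rep(seq_len(K), each = ppr),
                       rep(seq_len(ppr), K)),
    chrom = rep(pl_chrom, each = ppr),
    pos = as.integer(rep(region_start, each = ppr) +
                       round(seq(0, 6000, length.out = ppr))),
    gene = rep(cg_genes, each = ppr),
    region_category = rep_len(PROMOTER_CATEGORIES, K * ppr))

  n_bg <- cfg$n_probes - K * ppr
  bg <- withSubstream(seed, "layout", {
    n_tssprox <- round(0.6 * n_bg)
    n_body <- round(0.25 * n_bg)
    n_inter <- n_bg - n_tssprox - n_body
    gi <- sample(seq_len(nrow(gdf))[-seq_len(K)], n_tssprox, replace = TRUE)
    prox <- data.frame(chrom = gdf$chrom[gi],
                       pos = gdf$tss[gi] + sample(-2000:2000, n_tssprox, TRUE),
                       gene = gdf$gene[gi],
                       region_category = sample(PROMOTER_CATEGORIES, n_tssprox, TRUE))
    gi2 <- sample(seq_len(nrow(gdf))[-seq_len(K)], n_body, replace = TRUE)
    body <- data.frame(chrom = gdf$chrom[gi2],
                       pos = gdf$tss[gi2] + sample(500:20000, n_body, TRUE),
                       gene = gdf$gene[gi2],
                       region_category = sample(BODY_CATEGORIES, n_body, TRUE))
    chrom_len <- max(og_tss) + 50000L
    inter <- data.frame(chrom = paste0("chr", sample(1:2, n_inter, TRUE)),
                        pos = sample(chrom_len, n_inter, TRUE),
                        gene = "",
                        region_category = "Intergenic")
    out <- rbind(prox, body, inter)
    # keep background probes out of planted tiles so planted windows are clean
    tile0 <- tile_start; names(tile0) <- pl_chrom
    inplanted <- rep(FALSE, nrow(out))
    for (k in seq_len(K)) {
      inplanted <- inplanted | (out$chrom == pl_chrom[k] &
                                  out$pos >= tile_start[k] &
                                  out$pos <= tile_start[k] + 9999L)
    }
    out$pos[inplanted] <- out$pos[inplanted] + 600000L
    out$pos <- pmax(out$pos, 1L)
    out
  })
  bg$probe_id <- sprintf("bg_%05d", seq_len(nrow(bg)))
  pdf <- rbind(planted, bg[, colnames(planted)])
  # unique positions within chromosome (jitter duplicates deterministically)
  dup <- duplicated(paste(pdf$chrom, pdf$pos))
  while (any(dup)) {
    pdf$pos[dup] <- pdf$pos[dup] + 1L
    dup <- duplicated(paste(pdf$chrom, pdf$pos))
  }
  ord <- order(pdf$chrom, pdf$pos)
  pdf <- pdf[ord, ]
  probes <- probeAnnotation(pdf)

  ## expression --------------------------------------------------------------
  G <- length(expr_genes)
  catalog_expr <- c(met_genes, sgoc_genes, crf_genes, tf_genes, sam_genes)
  expr <- withSubstream(seed, "expression", {
    mu <- numeric(G); sdv <- numeric(G)
    is_cat <- expr_genes %in% catalog_expr
    mu[is_cat] <- stats::runif(sum(is_cat), 4, 9)
    sdv[is_cat] <- stats::runif(sum(is_cat), 0.5, 1.5)
    mu[!is_cat] <- stats::runif(sum(!is_cat), 1, 9)
    sdv[!is_cat] <- stats::runif(sum(!is_cat), 0.3, 2.0)
    e <- matrix(stats::rnorm(n * G, mean = rep(mu, each = n),
                             sd = rep(sdv, each = n)), n, G)
    pmax(e, 0)
  })
  dimnames(expr) <- list(samples, expr_genes)

  ## latent metabolic factor -------------------------------------------------
  lat <- withSubstream(seed, "latent", {
    w_raw <- stats::runif(length(met_genes), 0.5, 1.5)
    v <- drop(expr[, met_genes, drop = FALSE] %*% w_raw)
    sv <- stats::sd(v); if (sv == 0) sv <- 1
    w <- w_raw / sv
    s <- (v - mean(v)) / sv + stats::rnorm(n, 0, 0.2)
    list(w = stats::setNames(w, met_genes), s = s)
  })
  s <- lat$s

  ## clinical ----------------------------------------------------------------
  clin <- withSubstream(seed, "clinical", {
    data.frame(age = stats::runif(n, 30, 85),
               gender = sample(c("male", "female"), n, TRUE),
               stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                              prob = c(0.3, 0.3, 0.25, 0.15)),
               row.names = samples, stringsAsFactors = FALSE)
  })

  ## mutations ---------------------------------------------------------------
  mut_genes <- sprintf("MUT%02d", seq_len(cfg$n_mutation_genes))
  mut <- withSubstream(seed, "mutations", {
    freq <- stats::runif(cfg$n_mutation_genes, 0.05, 0.35)
    m <- vapply(freq, function(f) stats::rbinom(n, 1L, f), integer(n))
    # the driver mutation must vary
    if (sum(m[, 1]) == 0) m[sample(n, 1L), 1] <- 1L
    if (sum(m[, 1]) == n) m[sample(n, 1L), 1] <- 0L
    m
  })
  dimnames(mut) <- list(samples, mut_genes)

  ## copy number -------------------------------------------------------------
  cna_genes <- sprintf("CNA%02d", seq_len(cfg$n_cna_genes))
  cna <- withSubstream(seed, "cna", {
    pnz <- stats::runif(cfg$n_cna_genes, 0.15, 0.5)
    vapply(pnz, function(f) {
      sample(c(-2L, -1L, 0L, 1L, 2L), n, TRUE,
             prob = c(0.10 * f, 0.35 * f, 1 - f, 0.35 * f, 0.20 * f))
    }, integer(n))
  })
  dimnames(cna) <- list(samples, cna_genes)

  ## disruption --------------------------------------------------------------
  disrupted <- withSubstream(seed, "disruption", {
    nd <- round(cfg$frac_disrupted_patients * n)
    d <- sort(sample(samples, nd))
    z <- stats::rnorm(n, 0, stats::sd(s))
    list(ids = d, z = z)
  })
  is_dis <- samples %in% disrupted$ids
  s_eff <- ifelse(is_dis, disrupted$z, s)

  ## methylation -------------------------------------------------------------
  eff <- cfg$effect_sizes
  tfv <- drop(scale(expr[, tf_genes[1]]))
  mv <- mut[, 1]
  agec <- clin$age - 57.5
  dir_k <- ifelse(seq_len(K) %% 2L == 1L, 1, -1)
  meth <- withSubstream(seed, "methylation", {
    m <- matrix(NA_real_, n, cfg$n_probes,
                dimnames = list(samples, names(probes)))
    # planted probes
    for (k in seq_len(K)) {
      ids <- planted$probe_id[planted$gene == cg_genes[k]]
      for (pid in ids) {
        b0 <- stats::runif(1, -0.8, 0.8)
        mu <- stats::plogis(b0 + eff[["met_effect"]] * dir_k[k] * s_eff +
                              eff[["tf_effect"]] * tfv +
                              eff[["mut_effect"]] * mv +
                              eff[["age_effect"]] * agec)
        m[, pid] <- .clip01(mu + stats::rnorm(n, 0, cfg$noise_sd_beta))
      }
    }
    # background probes: Beta(a_p, b_p) with s.d. spanning [0.02, 0.35]
    bg_ids <- setdiff(colnames(m), planted$probe_id)
    nb <- length(bg_ids)
    mix <- stats::rbinom(nb, 1L, 0.5)
    mp <- ifelse(mix == 1L, stats::rbeta(nb, 8, 2), stats::rbeta(nb, 2, 8))
    mp <- pmin(pmax(mp, 0.03), 0.97)
    sp <- stats::runif(nb, 0.02, 0.35)
    sp <- pmin(sp, 0.95 * sqrt(mp * (1 - mp)))
    nu <- mp * (1 - mp) / sp^2 - 1
    a <- mp * nu; b <- (1 - mp) * nu
    m[, bg_ids] <- matrix(stats::rbeta(n * nb, rep(a, each = n),
                                       rep(b, each = n)), n, nb)
    m
  })

  ## survival ----------------------------------------------------------------
  surv <- withSubstream(seed, "survival", {
    h <- cfg$survival_params$baseline_hazard *
      cfg$survival_params$disruption_hr^as.numeric(is_dis)
    tt <- stats::rexp(n, rate = h)
    ct <- cfg$survival_params$censor_time
    data.frame(time_days = pmin(tt, ct),
               event = as.integer(tt <= ct),
               row.names = samples)
  })

  ## catalog -----------------------------------------------------------------
  cat_df <- variableCatalog(
    variable = c(catalog_expr, "age", "gender", "stage", cna_genes, mut_genes),
    var_class = c(rep("methionine_cycle_enzymes", length(met_genes)),
                  rep("other_SGOC_enzymes", length(sgoc_genes)),
                  rep("chromatin_remodelling_factors", length(crf_genes)),
                  rep("transcription_factors", length(tf_genes)),
                  rep("SAM_metabolizing_enzymes", length(sam_genes)),
                  rep("clinical_factors", 3L),
                  rep("copy_number_variations", length(cna_genes)),
                  rep("mutations", length(mut_genes))),
    value_type = c(rep("numeric", length(catalog_expr)), "numeric",
                   "categorical", "categorical",
                   rep("numeric", length(cna_genes)),
                   rep("numeric", length(mut_genes))))

  cohort <- OmicsCohort(meth, expr, mut, cna, clin, surv)
  planted_gr <- GenomicRanges::GRanges(
    seqnames = pl_chrom,
    ranges = IRanges::IRanges(start = region_start, end = region_end),
    direction = dir_k, gene = cg_genes)
  names(planted_gr) <- cg_genes
  truth <- list(planted_regions = planted_gr,
                true_effects = eff,
                disrupted_patients = disrupted$ids,
                latent_factor = stats::setNames(s, samples),
                met_weights = lat$w,
                driver_tf = tf_genes[1], driver_mutation = mut_genes[1],
                met_genes = met_genes,
                cancer_genes = cg_genes,
                background_genes = bg_genes,
                linear_beta = NULL)
  list(cohort = cohort, probes = probes, genes = genes, catalog = cat_df,
       truth = truth)
}

#' Simulate a linearly related predictor/response dataset
#'
#' Entries of `X` are iid standard normal, coefficients iid Uniform(0,1)
#' fixed for the dataset, and `y = X beta + eps` with Gaussian noise.
#'
#' @param n,p Dimensions.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List `X` (n x p, columns `V1..Vp`), `y`, `beta`.
#' @export
simulateLinearDataset <- function(n, p, noise_sd = 0.05, seed = 1L) {
  stopifnot(n >= 1, p >= 1)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  withSubstream(seed, "linear_dataset", {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("V", seq_len(p))))
    beta <- stats::runif(p)
    y <- drop(X %*% beta) + stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y, beta = beta)
  })
}

#' Simulate a pure-noise predictor matrix
#'
#' iid standard-normal entries, independent of any response by construction.
#'
#' @param n,p Dimensions.
#' @param seed Integer seed.
#' @return n x p matrix with columns `V1..Vp`.
#' @export
simulateRandomPredictors <- function(n, p, seed = 1L) {
  stopifnot(n >= 1, p >= 1)
  withSubstream(seed, "random_predictors", {
    matrix(stats::rnorm(n * p), n, p,
           dimnames = list(NULL, paste0("V", seq_len(p))))
  })
}
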