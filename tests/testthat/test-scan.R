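# Correlation track, peak scanning, turning-point filter, specificity,
# bias check and nearest-TSS annotation.

test_that("Spearman correlation matches the brute-force rank oracle", {
  # the classic length-6 example, exact to 4 decimals
  r <- spearmanRho(1:6, c(2, 1, 4, 3, 6, 5))
  expect_equal(round(r$rho, 4), 0.8286)

  set.seed(101)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 2 == 0) {            # introduce ties half the time
      x <- round(x, 1); y <- round(y, 1)
    }
    if (i %% 5 == 0) x[sample(n, 2)] <- NA
    mine <- spearmanRho(x, y)
    ref <- bruteSpearman(x, y)
    expect_equal(mine$rho, ref$rho, tolerance = 1e-12)
    expect_equal(mine$p, ref$p, tolerance = 1e-12)
  }
})

test_that("correlation track handles perfect association and ordering", {
  probes <- probeAnnotation(data.frame(
    probe_id = c("p2", "p1"), chrom = "chr1", pos = c(500L, 100L),
    gene = "", region_category = "Intergenic"))
  set.seed(5)
  b <- runif(30)
  m <- cbind(p1 = b, p2 = rev(b))
  rownames(m) <- sprintf("s%02d", 1:30)
  e <- qlogis(b)                          # monotone transform of p1
  tr <- correlationTrack(m, e, probes)
  expect_identical(tr$probe, c("p1", "p2"))    # genomic order restored
  expect_equal(tr$rho[1], 1)
  expect_lt(tr$p[1], 1e-20)
  tr2 <- correlationTrack(m, -e, probes)
  expect_equal(tr2$rho[1], -1)
})

test_that("the met gene with the strongest methylation correlation is selected", {
  sim <- smallSim()
  meth <- filterProbes(methylation(sim$cohort))
  gm <- globalMethylation(meth)
  rm_ <- bin10kb(meth, sim$probes)
  expr <- exprMatrix(sim$cohort)
  expect_identical(selectMetGene(expr, gm, rm_, "MTR"), "MTR")
  # two candidates with identical expression: first in list wins
  expr2 <- cbind(expr, MTRcopy = expr[, "MTR"])
  expect_identical(selectMetGene(expr2, gm, rm_, c("MTRcopy", "MTR")),
                   "MTRcopy")
  expect_error(selectMetGene(expr, gm, rm_, character(0)), "candidate")
  # the selected gene should carry weight in the planted latent factor
  g <- selectMetGene(expr, gm, rm_, sim$truth$met_genes)
  expect_true(g %in% sim$truth$met_genes)
})

test_that("window criteria reject sparse or weakly significant windows", {
  mktrack <- function(rho, p, pos, chrom = "chr1") {
    data.frame(probe = sprintf("p%02d", seq_along(rho)), chrom = chrom,
               pos = pos, rho = rho, p = p, neglog10p = -log10(p))
  }
  # 2 same-direction probes only -> rejected
  t1 <- mktrack(c(0.9, 0.8, -0.5, -0.4, -0.3),
                c(1e-9, 1e-8, 0.5, 0.5, 0.5),
                c(1000, 1500, 2000, 2500, 3000))
  expect_length(scanPeaks(t1, topFrac = 0.2, minProbes = 3, minFrac = 0.2), 0)

  # 10 probes in one window, 7 significant (0.7 < 0.8) -> rejected
  t2 <- mktrack(rep(0.9, 10), c(rep(1e-9, 7), rep(0.5, 3)),
                seq(1000, 3250, by = 250))
  expect_length(scanPeaks(t2, topFrac = 1, minFrac = 0.8), 0)
  # same but 8 significant -> accepted
  t3 <- mktrack(rep(0.9, 10), c(rep(1e-9, 8), rep(0.5, 2)),
                seq(1000, 3250, by = 250))
  pk <- scanPeaks(t3, topFrac = 1, minFrac = 0.8)
  expect_gte(length(pk), 1)
  expect_true(all(S4Vectors::mcols(pk)$n_probes >= 3))
  expect_true(all(S4Vectors::mcols(pk)$frac_significant >= 0.8))

  expect_error(scanPeaks(t3, halfWindow = 0), "positive")
})

test_that("a planted block yields exactly one merged peak covering it", {
  set.seed(17)
  npos <- c(seq(1000, 96000, by = 5000))          # sparse null probes
  null_rho <- runif(length(npos), -0.2, 0.2)
  block_pos <- seq(50000, 52500, by = 500)        # 6 tight block probes
  pos <- c(npos, block_pos)
  rho <- c(null_rho, rep(0.9, 6))
  p <- c(runif(length(npos), 0.2, 1), rep(1e-9, 6))
  o <- order(pos)
  track <- data.frame(probe = sprintf("p%02d", seq_along(pos))[o],
                      chrom = "chr1", pos = pos[o], rho = rho[o], p = p[o],
                      neglog10p = -log10(p[o]))
  pk <- scanPeaks(track, topFrac = 0.25)
  expect_length(pk, 1)
  expect_lte(GenomicRanges::start(pk), 50000)
  expect_gte(GenomicRanges::end(pk), 52500)
  expect_identical(S4Vectors::mcols(pk)$direction, 1)
})

test_that("turning-point probabilities match exhaustive enumeration", {
  # strictly monotone: no turning point, p = 1
  expect_equal(turnpointAnalysis(1:10)$p_min, 1)
  expect_equal(turnpointAnalysis(10:1)$n_turnpoints, 0L)

  # (0,1,0): single turning point with P = 2/3 (all 6 orderings)
  ta <- turnpointAnalysis(c(0, 1, 0))
  expect_identical(ta$n_collapsed, 3L)          # tie collapse keeps 3 here
  expect_equal(ta$proba, 2 / 3)
  expect_equal(ta$info, -log2(2 / 3))
  expect_equal(enumTurnProb(3, 2, 1, 1), 2 / 3)

  # run-length probability formula vs enumeration for all windows, m <= 6
  for (m in 4:6) {
    for (i in 2:(m - 1)) {
      for (l1 in 1:(i - 1)) for (l2 in 1:(m - i)) {
        expect_equal(2 * choose(l1 + l2, l1) / factorial(l1 + l2 + 1),
                     enumTurnProb(m, i, l1, l2),
                     tolerance = 1e-12,
                     label = sprintf("m=%d i=%d l1=%d l2=%d", m, i, l1, l2))
      }
    }
  }

  # exact ties collapse before analysis
  tc <- turnpointAnalysis(c(1, 2, 2, 2, 1))
  expect_identical(tc$n_collapsed, 3L)
  expect_identical(tc$n_turnpoints, 1L)

  # degenerate collapsed series
  expect_equal(turnpointAnalysis(c(3, 3, 3))$p_min, 1)
})

test_that("turning-point counts match Kendall's moments on iid series", {
  set.seed(2024)
  counts <- vapply(1:400, function(i)
    turnpointAnalysis(rnorm(100))$n_turnpoints, integer(1))
  mu <- 2 * (100 - 2) / 3
  v <- (16 * 100 - 29) / 90
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(v / 400))
  expect_lt(abs(var(counts) - v), 3 * v * sqrt(2 / 399))
})

test_that("the shape filter keeps the sharpest fraction of peaks", {
  sim <- smallSim()
  meth <- filterProbes(methylation(sim$cohort))
  g <- sim$truth$met_genes[1]
  tr <- correlationTrack(meth, exprMatrix(sim$cohort)[, g], sim$probes)
  pk <- scanPeaks(tr)
  if (length(pk) >= 2) {
    kept <- turnpointFilter(pk, tr, keepFrac = 0.5)
    expect_lte(length(kept), ceiling(0.5 * length(pk)))
    expect_true(all(S4Vectors::mcols(kept)$turnpoint_p <= 1))
    all_p <- S4Vectors::mcols(attr(kept, "all_peaks"))$turnpoint_p
    expect_lte(max(S4Vectors::mcols(kept)$turnpoint_p),
               min(all_p[!attr(kept, "all_peaks") %in% kept]))
  } else succeed("single peak: filter trivially keeps it")
})

test_that("specificity q is extreme when only the met gene correlates", {
  sim <- smallSim()
  meth <- methylation(sim$cohort)
  pr <- sim$truth$planted_regions[1]
  g <- selectMetGene(exprMatrix(sim$cohort),
                     globalMethylation(meth),
                     bin10kb(filterProbes(meth), sim$probes),
                     sim$truth$met_genes)
  st <- specificityTest(pr, meth, sim$probes, exprMatrix(sim$cohort), g,
                        excludeGenes = sim$catalog$variable,
                        nRandom = 100, seed = 8)
  expect_gte(st$q, 1 / 101)
  expect_lte(st$q, 1)
  expect_lt(st$q, 0.05)
  expect_equal(st$f_met, 1)

  expect_error(specificityTest(pr, meth, sim$probes, exprMatrix(sim$cohort),
                               g, nRandom = 10000, seed = 1),
               "eligible")
})

test_that("bias check is null on background and exact under construction", {
  sim <- smallSim()
  meth <- methylation(sim$cohort)
  bg <- grep("^bg_", colnames(meth), value = TRUE)
  bc <- methylationBiasCheck(meth[, bg], exprMatrix(sim$cohort)[, "MTR"],
                             nProbes = 400, seed = 3)
  expect_gt(bc$p, 0.001)
  expect_error(methylationBiasCheck(meth, exprMatrix(sim$cohort)[, "MTR"],
                                    nProbes = 1e6), "exceeds")
})

test_that("nearest TSS distances match exhaustive search with signed offsets", {
  genes <- geneAnnotation(data.frame(
    gene = c("B", "A", "C"), chrom = c("chr1", "chr1", "chr2"),
    tss = c(1000L, 3000L, 500L), strand = c("+", "-", "+")))
  iv <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr2"),
    IRanges::IRanges(start = c(990, 1990, 5000, 2000000),
                     end = c(1010, 2010, 5200, 2000100)))
  nt <- nearestTss(iv, genes)
  expect_identical(nt$nearest_gene[1], "B")
  expect_equal(nt$tss_distance[1], 0)            # midpoint exactly at TSS
  # equidistant between B (1000) and A (3000): lexicographically smaller = A
  expect_identical(nt$nearest_gene[2], "A")
  expect_equal(nt$tss_distance[2], 1000)         # upstream of '-' gene => downstream in gene orientation
  expect_identical(nt$nearest_gene[3], "A")
  expect_equal(nt$tss_distance[3], -2100)        # downstream of '-' gene
  expect_true(is.na(nt$nearest_gene[4]))         # beyond 1 Mb cap

  # random layout vs brute force
  set.seed(55)
  gdf <- data.frame(gene = sprintf("G%03d", 1:40),
                    chrom = sample(c("chr1", "chr2"), 40, TRUE),
                    tss = sample.int(5e6, 40),
                    strand = sample(c("+", "-"), 40, TRUE))
  gg <- geneAnnotation(gdf)
  ivr <- GenomicRanges::GRanges(sample(c("chr1", "chr2"), 25, TRUE),
                                IRanges::IRanges(start = sample.int(5e6, 25),
                                                 width = 100))
  nt2 <- nearestTss(ivr, gg)
  for (i in 1:25) {
    mid <- floor((GenomicRanges::start(ivr)[i] + GenomicRanges::end(ivr)[i]) / 2)
    same <- gdf[gdf$chrom == as.character(GenomicRanges::seqnames(ivr))[i], ]
    d <- abs(same$tss - mid)
    expect_identical(abs(nt2$tss_distance[i]), min(d))
  }
})
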