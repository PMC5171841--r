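# Probe/expression filters and aggregation rules.

test_that("probe missingness filter drops strictly above 80%", {
  m <- matrix(runif(100 * 3), 100, 3,
              dimnames = list(sprintf("s%03d", 1:100), c("keep", "edge", "drop")))
  m[1:50, "keep"] <- NA          # 50% missing
  m[1:80, "edge"] <- NA          # exactly 80%
  m[1:81, "drop"] <- NA          # 81%
  out <- filterProbes(m)
  expect_identical(colnames(out), c("keep", "edge"))

  # counting oracle on a random missingness pattern, and idempotence
  set.seed(4)
  mm <- matrix(runif(60 * 40), 60, 40,
               dimnames = list(sprintf("s%02d", 1:60), sprintf("p%02d", 1:40)))
  mm[sample(length(mm), 1200)] <- NA
  out2 <- filterProbes(mm)
  brute <- sum(vapply(seq_len(40), function(j)
    sum(is.na(mm[, j])) / 60 <= 0.8, logical(1)))
  expect_identical(ncol(out2), brute)
  expect_identical(filterProbes(out2), out2)
})

test_that("global methylation is a missing-aware mean and equivariant", {
  m <- matrix(0.5, 4, 10, dimnames = list(paste0("s", 1:4), paste0("p", 1:10)))
  expect_equal(unname(globalMethylation(m)), rep(0.5, 4))
  m2 <- rbind(s1 = rep(c(0, 1), 5), s2 = runif(10))
  colnames(m2) <- paste0("p", 1:10)
  expect_equal(globalMethylation(m2)[["s1"]], 0.5)

  set.seed(2)
  mm <- matrix(runif(20 * 50), 20, 50,
               dimnames = list(sprintf("s%02d", 1:20), sprintf("p%02d", 1:50)))
  mm[sample(length(mm), 100)] <- NA
  gm <- globalMethylation(mm)
  oracle <- vapply(seq_len(20), function(i) mean(mm[i, ], na.rm = TRUE),
                   numeric(1))
  expect_equal(unname(gm), oracle)
  pi_ <- sample(20)
  expect_equal(globalMethylation(mm[pi_, ]), gm[pi_])

  mall <- mm; mall[3, ] <- NA
  expect_warning(g2 <- globalMethylation(mall), "all probes missing")
  expect_true(is.na(g2[3]))
})

test_that("10 kb binning uses a fixed origin and the s.d. filter", {
  ids <- sprintf("s%02d", 1:30)
  probes <- probeAnnotation(data.frame(
    probe_id = c("a", "b", "c", "d"),
    chrom = "chr1", pos = c(9999L, 10001L, 10500L, 60000L),
    gene = "", region_category = "Intergenic"))
  set.seed(8)
  m <- cbind(a = runif(30), b = runif(30), c = runif(30),
             d = rep(0.4, 30))                      # constant -> s.d. 0
  rownames(m) <- ids
  rm_ <- bin10kb(m, probes, sd_min = 0.05)
  regs <- names(regionRanges(rm_))
  # boundary probes 9,999 and 10,001 fall in different tiles
  expect_true("chr1:1-10000" %in% regs)
  expect_true("chr1:10001-20000" %in% regs)
  expect_false("chr1:50001-60000" %in% regs)        # constant region filtered
  expect_equal(regionValues(rm_)[, "chr1:10001-20000"],
               rowMeans(m[, c("b", "c")]))

  # brute-force recomputation of the surviving-region set on simulated data
  sim <- smallSim()
  meth <- filterProbes(methylation(sim$cohort))
  rm2 <- bin10kb(meth, sim$probes, sd_min = 0.2)
  ann <- sim$probes[colnames(meth)]
  tile <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(ann)),
                  (GenomicRanges::start(ann) - 1L) %/% 10000L)
  brute <- vapply(unique(tile), function(tt) {
    v <- rowMeans(meth[, tile == tt, drop = FALSE], na.rm = TRUE)
    sd(v) >= 0.2
  }, logical(1))
  expect_identical(ncol(regionValues(rm2)), sum(brute))
  expect_true(all(regionSD(rm2) >= 0.2))

  expect_error(bin10kb(rm2, sim$probes), "already")
  badprobe <- meth
  colnames(badprobe)[1] <- "unknown_probe"
  expect_error(bin10kb(badprobe, sim$probes), "unknown_probe")
})

test_that("promoter and body methylation partition the probe categories", {
  probes <- probeAnnotation(data.frame(
    probe_id = c("p1", "p2", "p3"),
    chrom = "chr1", pos = c(100L, 200L, 300L),
    gene = "G1", region_category = c("TSS200", "Body", "TSS1500")))
  m <- matrix(c(0.1, 0.2, 0.9, 0.8, 0.3, 0.4), 2, 3,
              dimnames = list(c("s1", "s2"), c("p1", "p2", "p3")))
  pr <- geneMethylation(m, probes, "G1", "promoter")
  expect_equal(as.numeric(pr), unname(rowMeans(m[, c("p1", "p3")])))
  bd <- geneMethylation(m, probes, "G1", "body")
  expect_equal(as.numeric(bd), unname(m[, "p2"]))
  expect_error(geneMethylation(m, probes, "G2", "promoter"), "G2")

  sim <- smallSim()
  meth <- methylation(sim$cohort)
  g <- sim$truth$cancer_genes[1]
  mc <- S4Vectors::mcols(sim$probes)
  ids <- names(sim$probes)[mc$gene == g &
                             mc$region_category %in% c("TSS1500", "TSS200", "5UTR")]
  expect_equal(as.numeric(geneMethylation(meth, sim$probes, g, "promoter")),
               unname(rowMeans(meth[, ids])))
})

test_that("low-expression filter uses a strict count threshold", {
  cnt <- cbind(all3 = rep(3, 10),                 # 3 is not > 3 -> dropped
               edge = c(rep(4, 7), rep(0, 3)),    # exactly 70% -> retained
               low = c(rep(4, 6), rep(0, 4)))     # 60% -> dropped
  rownames(cnt) <- paste0("s", 1:10)
  out <- filterExpression(cnt)
  expect_identical(colnames(out), "edge")
  expect_equal(out[1, "edge"], log2(5))

  set.seed(13)
  cnt2 <- matrix(rpois(50 * 30, lambda = rep(runif(30, 2, 12), each = 50)), 50, 30,
                 dimnames = list(sprintf("s%02d", 1:50), sprintf("g%02d", 1:30)))
  out2 <- filterExpression(cnt2)
  brute <- colnames(cnt2)[vapply(seq_len(30), function(j)
    mean(cnt2[, j] > 3) >= 0.7, logical(1))]
  expect_identical(colnames(out2), brute)
})
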