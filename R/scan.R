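# Genome-wide scanner for peaks of correlation between methionine-cycle
# expression and probe-level methylation: Spearman correlation track,
# top-decile seeded 6 kb window scan, Kendall turning-point shape filter,
# randomization specificity test, methylation-bias check and nearest-TSS
# annotation.

#' Select the metabolic enzyme most correlated with methylation
#'
#' Returns the candidate gene with the largest mean absolute Spearman
#' correlation between its expression and the set {global methylation} union
#' {all retained 10 kb region values}. Ties go to the earlier candidate.
#'
#' @param expr samples x genes expression matrix.
#' @param globalMeth Per-sample global methylation ([globalMethylation()]).
#' @param regions [RegionMatrix-class] of retained 10 kb regions.
#' @param candidates Character vector of candidate gene symbols (must be
#'   columns of `expr`).
#' @return The selected gene symbol.
#' @export
selectMetGene <- function(expr, globalMeth, regions, candidates) {
  if (!length(candidates)) stop("no candidate genes supplied")
  stopifnot(all(candidates %in% colnames(expr)))
  targets <- cbind(global = as.numeric(globalMeth), regionValues(regions))
  score <- vapply(candidates, function(g) {
    rho <- vapply(seq_len(ncol(targets)), function(j)
      spearmanRho(expr[, g], targets[, j])$rho, numeric(1))
    mean(abs(rho), na.rm = TRUE)
  }, numeric(1))
  candidates[which.max(score)]   # which.max keeps the first tie
}

#' Probe-level Spearman correlation track
#'
#' Correlates one gene's expression with every probe's beta values across
#' samples (pairwise-complete, average ranks for ties; two-sided p from the
#' t approximation), ordered by genomic coordinate. Probes with fewer than
#' `minPairs` complete pairs are skipped with a warning.
#'
#' @param meth samples x probes beta matrix (filtered).
#' @param exprGene Per-sample expression of the chosen gene.
#' @param probes Probe annotation `GRanges`.
#' @param minPairs Minimum pairwise-complete sample count (default 8).
#' @return data.frame sorted by (chrom, pos): `probe`, `chrom`, `pos`,
#'   `rho`, `p`, `neglog10p`.
#' @export
correlationTrack <- function(meth, exprGene, probes, minPairs = 8L) {
  stopifnot(nrow(meth) == length(exprGene))
  ids <- intersect(colnames(meth), names(probes))
  if (!length(ids)) stop("no annotated probes in the methylation matrix")
  m <- meth[, ids, drop = FALSE]
  if (!anyNA(m) && !anyNA(exprGene)) {
    sm <- spearmanMatrix(m, matrix(exprGene, ncol = 1))
    rho <- sm$rho[, 1]; p <- sm$p[, 1]
    nn <- rep(nrow(m), length(ids))
  } else {
    res <- lapply(seq_along(ids), function(j) spearmanRho(m[, j], exprGene))
    rho <- vapply(res, `[[`, numeric(1), "rho")
    p <- vapply(res, `[[`, numeric(1), "p")
    nn <- vapply(res, `[[`, numeric(1), "n")
  }
  low <- nn < minPairs
  if (any(low)) {
    warning(sum(low), " probe(s) with fewer than ", minPairs,
            " complete pairs skipped")
  }
  keep <- !low & !is.na(rho)
  if (!any(keep)) stop("no usable probes for the correlation track")
  ann <- probes[ids[keep]]
  out <- data.frame(probe = ids[keep],
                    chrom = as.character(GenomicRanges::seqnames(ann)),
                    pos = GenomicRanges::start(ann),
                    rho = rho[keep], p = p[keep])
  out$neglog10p <- -log10(out$p)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Scan a correlation track for peaks
#'
#' Seeds are probes whose |rho| lies in the top `topFrac` genome-wide. Each
#' seed opens a +-`halfWindow` window on its chromosome; the window qualifies
#' when (a) at least `minProbes` probes (seed included) have rho of the
#' seed's sign and (b) at least `minFrac` of all window probes have
#' `p < pThresh`. Overlapping qualifying windows on a chromosome are merged
#' into maximal peaks retaining the largest-|rho| seed; merged spans must
#' themselves still satisfy both criteria.
#'
#' @param track data.frame from [correlationTrack()].
#' @param topFrac Seed fraction (default 0.10).
#' @param halfWindow Half window in bases (default 3000).
#' @param minProbes Minimum same-direction probes (default 3).
#' @param minFrac Minimum fraction of significant probes (default 0.8).
#' @param pThresh Probe significance threshold (default 1e-5).
#' @return `GRanges` of peaks (1-based inclusive) with metadata
#'   `seed_probe`, `seed_rho`, `direction` (+1/-1), `n_probes`
#'   (same-direction count) and `frac_significant`.
#' @export
scanPeaks <- function(track, topFrac = 0.10, halfWindow = 3000L,
                      minProbes = 3L, minFrac = 0.8, pThresh = 1e-5) {
  if (halfWindow <= 0) stop("halfWindow must be positive")
  if (!nrow(track)) stop("empty track")
  cut <- stats::quantile(abs(track$rho), 1 - topFrac, names = FALSE)
  seeds <- which(abs(track$rho) >= cut & track$rho != 0)
  qual <- list()
  for (i in seeds) {
    ch <- track$chrom[i]; ps <- track$pos[i]
    w <- which(track$chrom == ch & track$pos >= ps - halfWindow &
                 track$pos <= ps + halfWindow)
    same <- sum(sign(track$rho[w]) == sign(track$rho[i]))
    fsig <- mean(track$p[w] < pThresh)
    if (same >= minProbes && fsig >= minFrac) {
      qual[[length(qual) + 1L]] <- data.frame(
        chrom = ch, start = max(ps - halfWindow, 1L), end = ps + halfWindow,
        seed = track$probe[i], rho = track$rho[i])
    }
  }
  if (!length(qual)) {
    return(GenomicRanges::GRanges(seed_probe = character(0),
                                  seed_rho = numeric(0),
                                  direction = numeric(0),
                                  n_probes = integer(0),
                                  frac_significant = numeric(0)))
  }
  qd <- do.call(rbind, qual)
  gr <- GenomicRanges::GRanges(qd$chrom,
                               IRanges::IRanges(qd$start, qd$end))
  merged <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(gr, merged)
  out <- list()
  for (k in seq_along(merged)) {
    members <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == k]
    best <- members[which.max(abs(qd$rho[members]))]
    ch <- as.character(GenomicRanges::seqnames(merged))[k]
    st <- GenomicRanges::start(merged)[k]; en <- GenomicRanges::end(merged)[k]
    w <- which(track$chrom == ch & track$pos >= st & track$pos <= en)
    dir <- sign(qd$rho[best])
    same <- sum(sign(track$rho[w]) == dir)
    fsig <- mean(track$p[w] < pThresh)
    if (same < minProbes || fsig < minFrac) next  # consolidation diluted it
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, start = st, end = en, seed_probe = qd$seed[best],
      seed_rho = qd$rho[best], direction = dir, n_probes = same,
      frac_significant = fsig)
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(seed_probe = character(0),
                                  seed_rho = numeric(0),
                                  direction = numeric(0),
                                  n_probes = integer(0),
                                  frac_significant = numeric(0)))
  }
  od <- do.call(rbind, out)
  res <- GenomicRanges::GRanges(od$chrom, IRanges::IRanges(od$start, od$end),
                                seed_probe = od$seed_probe,
                                seed_rho = od$seed_rho,
                                direction = od$direction,
                                n_probes = od$n_probes,
                                frac_significant = od$frac_significant)
  sort(res)
}

#' Kendall turning-point analysis of a series
#'
#' Runs of exactly equal adjacent values are collapsed to one point; a
#' turning point is a strict local extremum of the collapsed series. Each
#' turning point's probability is the chance, under exchangeable random
#' orderings, of an extremum at that position with monotone runs of the
#' observed left/right lengths `l1`, `l2`:
#' `P = 2 * choose(l1 + l2, l1) / (l1 + l2 + 1)!`; its information quantity
#' is `-log2(P)`. The turning-point count `T` of an iid series of collapsed
#' length `m` has mean `2(m-2)/3` and variance `(16m-29)/90`, giving a
#' series-level two-sided normal-approximation p-value.
#'
#' @param x Numeric series (genomic order).
#' @return List: `n`, `n_collapsed`, `n_turnpoints`, `positions` (in the
#'   collapsed series), `l1`, `l2`, `proba`, `info`, `expected_count`,
#'   `count_var`, `p_count` (series-level normal test; 1 when the collapsed
#'   series is shorter than 3), `p_min` (min turning-point probability; 1
#'   when there is none).
#' @export
turnpointAnalysis <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  z <- x[c(TRUE, diff(x) != 0)]          # collapse exact ties
  m <- length(z)
  empty <- list(n = n, n_collapsed = m, n_turnpoints = 0L,
                positions = integer(0), l1 = integer(0), l2 = integer(0),
                proba = numeric(0), info = numeric(0),
                expected_count = if (m >= 3) 2 * (m - 2) / 3 else 0,
                count_var = if (m >= 3) (16 * m - 29) / 90 else 0,
                p_count = 1, p_min = 1)
  if (m < 3) return(empty)
  mid <- z[2:(m - 1)]
  tp <- (mid > z[1:(m - 2)] & mid > z[3:m]) |
        (mid < z[1:(m - 2)] & mid < z[3:m])
  pos <- which(tp) + 1L
  Tn <- length(pos)
  mu <- 2 * (m - 2) / 3
  v <- (16 * m - 29) / 90
  p_count <- if (Tn == 0) 1 else
    min(1, 2 * stats::pnorm(-abs((Tn - mu) / sqrt(v))))
  if (Tn == 0) { empty$p_count <- 1; return(empty) }
  bounds <- c(1L, pos, m)
  l1 <- pos - bounds[seq_along(pos)]
  l2 <- bounds[seq_along(pos) + 2L] - pos
  proba <- 2 * choose(l1 + l2, l1) / factorial(l1 + l2 + 1)
  list(n = n, n_collapsed = m, n_turnpoints = Tn, positions = pos,
       l1 = l1, l2 = l2, proba = proba, info = -log2(proba),
       expected_count = mu, count_var = v, p_count = p_count,
       p_min = min(proba))
}

#' Shape-filter peaks by turning-point probability
#'
#' For each peak the rho values of its probes (genomic order) are analysed
#' with [turnpointAnalysis()]; the peak's `turnpoint_p` is the smallest
#' turning-point probability (1 when the collapsed series has no turning
#' point or fewer than 3 points). Peaks are ranked by `turnpoint_p` and the
#' lowest `keepFrac` retained.
#'
#' @param peaks `GRanges` from [scanPeaks()].
#' @param track data.frame from [correlationTrack()].
#' @param keepFrac Fraction of peaks to keep (default 0.2).
#' @return The retained peaks with a `turnpoint_p` metadata column (the
#'   full annotated set is in `attr(,"all_peaks")`).
#' @export
turnpointFilter <- function(peaks, track, keepFrac = 0.2) {
  if (!length(peaks)) return(peaks)
  tp <- vapply(seq_along(peaks), function(k) {
    ch <- as.character(GenomicRanges::seqnames(peaks))[k]
    w <- which(track$chrom == ch &
                 track$pos >= GenomicRanges::start(peaks)[k] &
                 track$pos <= GenomicRanges::end(peaks)[k])
    turnpointAnalysis(track$rho[w])$p_min
  }, numeric(1))
  S4Vectors::mcols(peaks)$turnpoint_p <- tp
  keep_n <- max(1L, ceiling(keepFrac * length(peaks)))
  o <- order(tp)
  kept <- sort(peaks[o[seq_len(keep_n)]])
  attr(kept, "all_peaks") <- peaks
  kept
}

#' Randomization specificity test for one peak
#'
#' Compares the fraction of peak probes significantly correlated with the
#' metabolic gene's expression against the same fraction for `nRandom`
#' randomly drawn genome genes: `q = (1 + #{f_i >= f_met}) / (nRandom + 1)`.
#'
#' @param peak Single-element `GRanges`.
#' @param meth samples x probes beta matrix.
#' @param probes Probe annotation `GRanges`.
#' @param expr samples x genes expression matrix (the genome pool).
#' @param metGene The metabolic gene symbol.
#' @param excludeGenes Genes never drawn as controls (e.g. all
#'   methionine-cycle and SGOC catalog genes), in addition to `metGene`.
#' @param nRandom Number of random genes (default 500).
#' @param sigLevel Spearman p threshold defining "significant" (default
#'   0.05).
#' @param seed Integer seed.
#' @return List: `q`, `f_met`, `f_random` (length `nRandom`),
#'   `random_genes`.
#' @export
specificityTest <- function(peak, meth, probes, expr, metGene,
                            excludeGenes = character(0), nRandom = 500L,
                            sigLevel = 0.05, seed = 1L) {
  stopifnot(length(peak) == 1L, metGene %in% colnames(expr))
  ids <- names(probes)[IRanges::overlapsAny(probes, peak)]
  ids <- intersect(ids, colnames(meth))
  if (!length(ids)) stop("no methylation probes inside the peak")
  pool <- setdiff(colnames(expr), c(metGene, excludeGenes))
  if (length(pool) < nRandom)
    stop(sprintf("only %d eligible genes for %d randomizations",
                 length(pool), nRandom))
  rg <- withSubstream(seed, "specificity", sample(pool, nRandom))
  M <- meth[, ids, drop = FALSE]
  fsig <- function(g) {
    p <- if (!anyNA(M) && !anyNA(expr[, g]))
      spearmanMatrix(M, matrix(expr[, g], ncol = 1))$p[, 1]
    else vapply(seq_len(ncol(M)), function(j)
      spearmanRho(M[, j], expr[, g])$p, numeric(1))
    mean(p < sigLevel, na.rm = TRUE)
  }
  f_met <- fsig(metGene)
  f_rand <- vapply(rg, fsig, numeric(1))
  q <- (1 + sum(f_rand >= f_met)) / (nRandom + 1)
  list(q = q, f_met = f_met, f_random = f_rand, random_genes = rg)
}

#' Check for bias of correlation towards methylation level
#'
#' Samples probes without replacement and correlates (Spearman) each probe's
#' mean beta with its correlation rho against the metabolic gene's
#' expression. A significant association would indicate the scanner favours
#' highly (or lowly) methylated regions.
#'
#' @param meth samples x probes beta matrix.
#' @param exprGene Per-sample expression of the metabolic gene.
#' @param nProbes Number of probes to sample (default 2000).
#' @param seed Integer seed.
#' @return List: `rho`, `p`, `n_probes`.
#' @export
methylationBiasCheck <- function(meth, exprGene, nProbes = 2000L, seed = 1L) {
  if (nProbes > ncol(meth))
    stop("nProbes exceeds the number of available probes")
  sel <- withSubstream(seed, "bias_check",
                       sample(colnames(meth), nProbes))
  mb <- colMeans(meth[, sel, drop = FALSE], na.rm = TRUE)
  rr <- vapply(sel, function(pid) spearmanRho(meth[, pid], exprGene)$rho,
               numeric(1))
  res <- spearmanRho(mb, rr)
  list(rho = res$rho, p = res$p, n_probes = nProbes)
}

#' Nearest-TSS annotation of intervals
#'
#' Distance from each interval's midpoint to the nearest TSS on the same
#' chromosome, signed positive when the midpoint lies downstream of the TSS
#' in the gene's orientation. Equidistant TSSs resolve to the
#' lexicographically smaller gene symbol; intervals farther than
#' `maxExtension` from every TSS get `NA`.
#'
#' @param intervals `GRanges`.
#' @param genes Gene annotation `GRanges` (width-1 TSS, stranded, named).
#' @param maxExtension Maximum distance in bases (default 1e6).
#' @return data.frame: `nearest_gene`, `tss_distance` per interval.
#' @export
nearestTss <- function(intervals, genes, maxExtension = 1000000L) {
  if (!length(genes)) stop("empty gene annotation")
  mid <- floor((GenomicRanges::start(intervals) +
                  GenomicRanges::end(intervals)) / 2)
  ichr <- as.character(GenomicRanges::seqnames(intervals))
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gtss <- GenomicRanges::start(genes)
  gstr <- as.character(GenomicRanges::strand(genes))
  gname <- names(genes)
  out <- data.frame(nearest_gene = rep(NA_character_, length(intervals)),
                    tss_distance = rep(NA_real_, length(intervals)))
  for (i in seq_along(intervals)) {
    j <- which(gchr == ichr[i])
    if (!length(j)) next
    d <- abs(gtss[j] - mid[i])
    dmin <- min(d)
    if (dmin > maxExtension) next
    cand <- j[d == dmin]
    best <- cand[order(gname[cand])][1]
    signed <- if (gstr[best] == "-") gtss[best] - mid[i] else
      mid[i] - gtss[best]
    out$nearest_gene[i] <- gname[best]
    out$tss_distance[i] <- signed
  }
  out
}
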