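# Filtering and aggregation rules that turn raw matrices into modelling
# responses: probe missingness filter, global methylation, 10 kb binning with
# an s.d. >= 0.2 variability filter, promoter/body gene-level methylation,
# and the low-expression gene filter.

#' Filter probes by missingness
#'
#' Drops probes with more than `max_missing` missing values across samples
#' (strictly greater; a probe missing in exactly 80% of samples is retained).
#'
#' @param meth samples x probes beta matrix.
#' @param max_missing Maximum tolerated missing fraction (default 0.8).
#' @return The matrix restricted to retained probes.
#' @export
filterProbes <- function(meth, max_missing = 0.8) {
  frac <- colMeans(is.na(meth))
  meth[, frac <= max_missing, drop = FALSE]
}

#' Global methylation per sample
#'
#' Mean beta across all (filtered) probes, ignoring missing entries. A sample
#' with no observed probe yields `NA` with a warning.
#'
#' @param meth samples x probes beta matrix (already probe-filtered).
#' @return Named numeric vector, one value in `[0,1]` per sample.
#' @export
globalMethylation <- function(meth) {
  out <- rowMeans(meth, na.rm = TRUE)
  allna <- rowSums(!is.na(meth)) == 0
  if (any(allna)) {
    out[allna] <- NA_real_
    warning(sum(allna), " sample(s) with all probes missing: NA returned")
  }
  out
}

.tileID <- function(chrom, pos, width = 10000L) {
  i <- (pos - 1L) %/% width
  sprintf("%s:%d-%d", chrom, i * width + 1L, (i + 1L) * width)
}

#' Bin methylation into 10 kb regions and filter by variability
#'
#' The genome is tiled into fixed 10 kb intervals anchored at coordinate 1
#' (`[1,10000]`, `[10001,20000]`, ...). A region's value per sample is the
#' missing-aware mean beta over its probes; regions whose cross-sample
#' standard deviation (n-1 denominator) falls below `sd_min` are removed.
#' Empty tiles are never materialized.
#'
#' @param meth samples x probes beta matrix (probe-filtered).
#' @param probes Probe annotation `GRanges` covering every column of `meth`.
#' @param sd_min Minimum cross-sample s.d. for a region to survive
#'   (default 0.2).
#' @return A [RegionMatrix-class].
#' @export
bin10kb <- function(meth, probes, sd_min = 0.2) {
  if (is(meth, "RegionMatrix"))
    stop("input is already a RegionMatrix; refusing to re-bin")
  missing_ann <- setdiff(colnames(meth), names(probes))
  if (length(missing_ann))
    stop("probes without annotation: ",
         paste(utils::head(missing_ann, 10), collapse = ", "))
  ann <- probes[colnames(meth)]
  tid <- .tileID(as.character(GenomicRanges::seqnames(ann)),
                 GenomicRanges::start(ann))
  tiles <- unique(tid)
  vals <- vapply(tiles, function(tt) {
    rowMeans(meth[, tid == tt, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(meth)))
  vals[is.nan(vals)] <- NA_real_
  sds <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  keep <- !is.na(sds) & sds >= sd_min
  vals <- vals[, keep, drop = FALSE]
  sds <- sds[keep]
  reg <- do.call(rbind, strsplit(colnames(vals), "[:-]"))
  gr <- GenomicRanges::GRanges(
    seqnames = reg[, 1],
    ranges = IRanges::IRanges(start = as.integer(reg[, 2]),
                              end = as.integer(reg[, 3])))
  names(gr) <- colnames(vals)
  new("RegionMatrix", values = vals, sd = sds, regions = gr)
}

#' Promoter or gene-body methylation of one gene
#'
#' Promoter uses probes in categories TSS1500/TSS200/5'UTR; body uses
#' 1st exon/Body/3'UTR. The value per sample is the missing-aware mean over
#' matching probes.
#'
#' @param meth samples x probes beta matrix.
#' @param probes Probe annotation `GRanges`.
#' @param gene Gene symbol.
#' @param part `"promoter"` or `"body"`.
#' @return Named numeric vector of per-sample means, with attributes `gene`
#'   and `part`.
#' @export
geneMethylation <- function(meth, probes, gene, part = c("promoter", "body")) {
  part <- match.arg(part)
  cats <- if (part == "promoter") PROMOTER_CATEGORIES else BODY_CATEGORIES
  mc <- S4Vectors::mcols(probes)
  ids <- names(probes)[mc$gene == gene & mc$region_category %in% cats]
  ids <- intersect(ids, colnames(meth))
  if (!length(ids))
    stop(sprintf("no %s probes for gene '%s'", part, gene))
  v <- rowMeans(meth[, ids, drop = FALSE], na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  attr(v, "gene") <- gene
  attr(v, "part") <- part
  attr(v, "n_probes") <- length(ids)
  v
}

#' Gene-level methylation response matrix
#'
#' Convenience wrapper building a samples x responses matrix of promoter
#' and/or body methylation for a gene list; genes lacking probes for a part
#' are skipped with a warning.
#'
#' @param meth samples x probes beta matrix.
#' @param probes Probe annotation `GRanges`.
#' @param genes Character vector of gene symbols.
#' @param parts Parts to include (default both).
#' @return Matrix with columns named `gene.part`.
#' @export
geneMethylationMatrix <- function(meth, probes, genes,
                                  parts = c("promoter", "body")) {
  cols <- list()
  for (g in genes) for (pt in parts) {
    v <- tryCatch(geneMethylation(meth, probes, g, pt), error = function(e) NULL)
    if (is.null(v)) {
      warning(sprintf("skipping %s/%s: no matching probes", g, pt))
    } else cols[[paste(g, pt, sep = ".")]] <- as.numeric(v)
  }
  if (!length(cols)) stop("no gene/part responses could be built")
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(meth)
  out
}

#' Filter low-expression genes and log-transform
#'
#' A gene is retained when at least `min_frac` of samples have a count
#' strictly greater than `min_count`; survivors are returned as
#' `log2(count + 1)`.
#'
#' @param expr_counts samples x genes matrix of non-negative normalized
#'   counts.
#' @param min_frac Minimum fraction of samples above the count threshold
#'   (default 0.7).
#' @param min_count Count threshold, exceeded strictly (default 3).
#' @return Log2-transformed matrix of retained genes.
#' @export
filterExpression <- function(expr_counts, min_frac = 0.7, min_count = 3) {
  stopifnot(all(expr_counts >= 0, na.rm = TRUE))
  frac <- colMeans(expr_counts > min_count, na.rm = TRUE)
  log2(expr_counts[, frac >= min_frac, drop = FALSE] + 1)
}
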