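# TSV readers/writers for cohort bundles, and BED output for peaks.
#
# Matrix files are TSV with the sample id in the first column and feature
# names in the header; missing values are the literal "NA" (TCGA-style).
# Probe/gene coordinates are 1-based inclusive internally (Illumina manifest
# convention); BED output is 0-based half-open.

.readMatrixTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

.readTableTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  rownames(dt) <- as.character(dt[[1]])
  dt[, -1, drop = FALSE]
}

# full-precision numeric formatting so written cohorts reload bit-for-bit
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

.writeMatrixTSV <- function(m, path, idcol = "sample_id") {
  body <- apply(m, 2L, .fmtNum)
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  lines <- c(paste(c(idcol, colnames(m)), collapse = "\t"),
             apply(cbind(rownames(m), body), 1L, paste, collapse = "\t"))
  writeLines(lines, path)
}

.writeTableTSV <- function(df, path, idcol = "sample_id") {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) .fmtNum(col) else {
      out <- as.character(col); out[is.na(out)] <- "NA"; out
    }
  })
  body <- do.call(cbind, cols)
  lines <- c(paste(c(idcol, colnames(df)), collapse = "\t"),
             apply(cbind(rownames(df), body), 1L, paste, collapse = "\t"))
  writeLines(lines, path)
}

#' Read a probe annotation TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, `gene`, `region_category`.
#' @param path TSV file path.
#' @return `GRanges`, see [probeAnnotation()].
#' @export
readProbeAnnotation <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          data.table = FALSE)
  df$gene[is.na(df$gene)] <- ""
  probeAnnotation(df)
}

#' Read a gene annotation TSV
#'
#' Columns: `gene`, `chrom`, `tss`, `strand`.
#' @param path TSV file path.
#' @return `GRanges`, see [geneAnnotation()].
#' @export
readGeneAnnotation <- function(path) {
  geneAnnotation(data.table::fread(path, sep = "\t", header = TRUE,
                                   data.table = FALSE))
}

.defaultManifest <- list(
  methylation = "methylation.tsv", expression = "expression.tsv",
  mutations = "mutations.tsv", cna = "cna.tsv", clinical = "clinical.tsv",
  survival = "survival.tsv", probe_annotation = "probe_annotation.tsv",
  gene_annotation = "gene_annotation.tsv")

#' Load a cohort bundle from a directory of TSV files
#'
#' Reads the matrices named in the manifest, restricts them to the
#' intersection of their sample ids (sorted lexicographically) and validates
#' value ranges. Samples absent from any file are dropped with a message.
#' Probes on sex chromosomes (chrX/chrY) are removed by default, together
#' with their methylation columns.
#'
#' @param directory Directory holding the TSV files.
#' @param manifest Named list mapping component names
#'   (`methylation`, `expression`, `mutations`, `cna`, `clinical`,
#'   `survival`, `probe_annotation`, `gene_annotation`) to file names, or a
#'   path to a YAML file with those entries. `NULL` uses the default names
#'   written by [writeCohort()].
#' @param dropSexChromosomes Drop chrX/chrY probes (default `TRUE`).
#' @return List with elements `cohort` ([OmicsCohort-class]), `probes`,
#'   `genes` (both `GRanges`).
#' @export
loadCohort <- function(directory, manifest = NULL, dropSexChromosomes = TRUE) {
  if (is.null(manifest)) {
    ypath <- file.path(directory, "manifest.yaml")
    manifest <- if (file.exists(ypath)) yaml::read_yaml(ypath) else .defaultManifest
  } else if (is.character(manifest) && length(manifest) == 1L) {
    manifest <- yaml::read_yaml(manifest)
  }
  pathOf <- function(nm) file.path(directory, manifest[[nm]])
  meth <- .readMatrixTSV(pathOf("methylation"))

  # beta range check with file/row/column coordinates
  bad <- which(meth < 0 | meth > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "beta value outside [0,1] in '%s': sample '%s', probe '%s' (value %g)",
      manifest$methylation, rownames(meth)[bad[1, 1]],
      colnames(meth)[bad[1, 2]], meth[bad[1, , drop = FALSE]]))
  }

  expr <- .readMatrixTSV(pathOf("expression"))
  mut  <- .readMatrixTSV(pathOf("mutations"))
  cna  <- .readMatrixTSV(pathOf("cna"))
  clin <- .readTableTSV(pathOf("clinical"))
  surv <- .readTableTSV(pathOf("survival"))

  idsets <- list(methylation = rownames(meth), expression = rownames(expr),
                 mutations = rownames(mut), cna = rownames(cna),
                 clinical = rownames(clin), survival = rownames(surv))
  common <- Reduce(intersect, idsets)
  if (!length(common)) {
    # name the two most disjoint files for the error message
    ov <- outer(seq_along(idsets), seq_along(idsets), Vectorize(function(i, j)
      length(intersect(idsets[[i]], idsets[[j]]))))
    diag(ov) <- Inf
    ij <- which(ov == min(ov), arr.ind = TRUE)[1, ]
    stop(sprintf("no samples shared across all files; most disjoint: '%s' vs '%s'",
                 manifest[[names(idsets)[ij[1]]]], manifest[[names(idsets)[ij[2]]]]))
  }
  dropped <- setdiff(unique(unlist(idsets)), common)
  if (length(dropped))
    message(length(dropped), " sample(s) dropped (absent from some file): ",
            paste(utils::head(sort(dropped), 10), collapse = ", "))

  probes <- readProbeAnnotation(pathOf("probe_annotation"))
  genes <- readGeneAnnotation(pathOf("gene_annotation"))

  if (dropSexChromosomes) {
    sex <- as.character(GenomicRanges::seqnames(probes)) %in% c("chrX", "chrY")
    if (any(sex)) {
      message(sum(sex), " sex-chromosome probe(s) dropped")
      drop_ids <- names(probes)[sex]
      probes <- probes[!sex]
      meth <- meth[, setdiff(colnames(meth), drop_ids), drop = FALSE]
    }
  }

  cohort <- OmicsCohort(meth, expr, mut, cna, clin, surv)
  list(cohort = cohort, probes = probes, genes = genes)
}

#' Write a cohort bundle to TSV files
#'
#' Inverse of [loadCohort()]: writes each component plus annotations and a
#' `manifest.yaml`, at full numeric precision so a written cohort reloads
#' bit-for-bit.
#'
#' @param cohort [OmicsCohort-class].
#' @param probes,genes Annotation `GRanges`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
writeCohort <- function(cohort, probes, genes, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  man <- .defaultManifest
  .writeMatrixTSV(methylation(cohort), file.path(directory, man$methylation))
  .writeMatrixTSV(exprMatrix(cohort), file.path(directory, man$expression))
  .writeMatrixTSV(mutationCalls(cohort), file.path(directory, man$mutations))
  .writeMatrixTSV(cnaCalls(cohort), file.path(directory, man$cna))
  .writeTableTSV(clinicalTable(cohort), file.path(directory, man$clinical))
  .writeTableTSV(survivalTable(cohort), file.path(directory, man$survival))
  pdf <- data.frame(probe_id = names(probes),
                    chrom = as.character(GenomicRanges::seqnames(probes)),
                    pos = GenomicRanges::start(probes),
                    gene = S4Vectors::mcols(probes)$gene,
                    region_category = S4Vectors::mcols(probes)$region_category)
  data.table::fwrite(pdf, file.path(directory, man$probe_annotation),
                     sep = "\t", na = "NA", quote = FALSE)
  gdf <- data.frame(gene = names(genes),
                    chrom = as.character(GenomicRanges::seqnames(genes)),
                    tss = GenomicRanges::start(genes),
                    strand = as.character(GenomicRanges::strand(genes)))
  data.table::fwrite(gdf, file.path(directory, man$gene_annotation),
                     sep = "\t", na = "NA", quote = FALSE)
  yaml::write_yaml(man, file.path(directory, "manifest.yaml"))
  invisible(man)
}

#' Write peaks as a 6-column BED file
#'
#' Converts 1-based inclusive peak coordinates to BED's 0-based half-open
#' convention. Name is the seed probe, score is
#' `round(-10 * log10(turnpoint_p))` capped at 1000, strand is `+` for
#' positive-direction peaks and `-` otherwise. Lines are sorted by
#' chromosome then start.
#'
#' @param peaks `GRanges` with metadata columns `seed_probe`, `direction`
#'   (`+`/`-` or +-1) and `turnpoint_p`.
#' @param out Output file path.
#' @return Invisibly, the data.frame written.
#' @export
writePeaksBed <- function(peaks, out) {
  if (!length(peaks)) {
    writeLines(character(0), out)
    return(invisible(data.frame()))
  }
  mc <- S4Vectors::mcols(peaks)
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  if (any(start0 >= end0))
    stop("peak with start >= end after BED conversion")
  p <- pmax(mc$turnpoint_p, 1e-100)
  dirch <- if (is.character(mc$direction)) mc$direction else
    ifelse(mc$direction > 0, "+", "-")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                   start = start0, end = end0,
                   name = mc$seed_probe,
                   score = pmin(round(-10 * log10(p)), 1000),
                   strand = dirch)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  data.table::fwrite(df, out, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(df)
}
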