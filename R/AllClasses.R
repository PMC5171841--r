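#' OmicsCohort: aligned multi-omic matrices for one cohort
#'
#' Container for the per-sample matrices the pipeline consumes: methylation
#' beta values, log2 expression, binary somatic mutations, GISTIC copy-number
#' calls, clinical attributes and survival. All components share one ordered
#' sample set (matrix/table rows), enforced by the validity method.
#'
#' @slot methylation samples x probes matrix of beta values in `[0,1]`,
#'   `NA` allowed.
#' @slot expression samples x genes matrix of `log2(normalized count + 1)`.
#' @slot mutations samples x genes 0/1 matrix.
#' @slot cna samples x genes integer matrix of GISTIC calls in `{-2..2}`
#'   (-2 homozygous deletion ... 2 high-level amplification).
#' @slot clinical samples x attributes data.frame; attributes numeric or
#'   factor/character.
#' @slot survival data.frame with columns `time_days` (non-negative) and
#'   `event` (0/1); row order matches the samples.
#'
#' @export
setClass("OmicsCohort",
  representation(
    methylation = "matrix",
    expression  = "matrix",
    mutations   = "matrix",
    cna         = "matrix",
    clinical    = "data.frame",
    survival    = "data.frame"
  )
)

setValidity("OmicsCohort", function(object) {
  msgs <- character()
  ids <- rownames(object@methylation)
  if (is.null(ids)) return("methylation matrix must have sample rownames")
  comp <- list(expression = rownames(object@expression),
               mutations = rownames(object@mutations),
               cna = rownames(object@cna),
               clinical = rownames(object@clinical),
               survival = rownames(object@survival))
  for (nm in names(comp)) {
    if (!identical(comp[[nm]], ids))
      msgs <- c(msgs, sprintf("sample ids of '%s' differ from methylation", nm))
  }
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicated sample ids")
  b <- object@methylation
  if (any(b < 0 | b > 1, na.rm = TRUE))
    msgs <- c(msgs, "methylation beta values outside [0,1]")
  if (length(object@cna) && !all(object@cna %in% c(-2:2, NA)))
    msgs <- c(msgs, "cna values outside {-2,...,2}")
  if (length(object@mutations) && !all(object@mutations %in% c(0, 1, NA)))
    msgs <- c(msgs, "mutation values outside {0,1}")
  sv <- object@survival
  if (!all(c("time_days", "event") %in% colnames(sv)))
    msgs <- c(msgs, "survival must have columns time_days and event")
  else {
    if (any(sv$time_days < 0, na.rm = TRUE))
      msgs <- c(msgs, "negative survival times")
    if (!all(sv$event %in% c(0, 1, NA)))
      msgs <- c(msgs, "survival event must be 0/1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an OmicsCohort
#'
#' Components are restricted to the intersection of their sample ids and
#' reordered lexicographically, so fold assignment downstream is reproducible.
#'
#' @param methylation,expression,mutations,cna Matrices with sample rownames.
#' @param clinical,survival data.frames with sample rownames; `survival`
#'   needs columns `time_days` and `event`.
#' @return An [OmicsCohort-class] object.
#' @export
OmicsCohort <- function(methylation, expression, mutations, cna, clinical,
                        survival) {
  parts <- list(methylation, expression, mutations, cna, clinical, survival)
  ids <- Reduce(intersect, lapply(parts, rownames))
  ids <- sort(ids)
  if (!length(ids)) stop("no common samples across cohort components")
  new("OmicsCohort",
      methylation = as.matrix(methylation)[ids, , drop = FALSE],
      expression  = as.matrix(expression)[ids, , drop = FALSE],
      mutations   = as.matrix(mutations)[ids, , drop = FALSE],
      cna         = as.matrix(cna)[ids, , drop = FALSE],
      clinical    = clinical[ids, , drop = FALSE],
      survival    = survival[ids, , drop = FALSE])
}

#' RegionMatrix: 10 kb-binned methylation
#'
#' Mean beta per sample for fixed 10 kb genomic tiles, with the cross-sample
#' standard deviation recorded per region (computed before any s.d. filter).
#'
#' @slot values samples x regions matrix of mean beta values.
#' @slot sd named numeric, cross-sample standard deviation per region.
#' @slot regions `GRanges` of the retained tiles (1-based inclusive).
#' @export
setClass("RegionMatrix",
  representation(values = "matrix", sd = "numeric", regions = "GRanges"))

setValidity("RegionMatrix", function(object) {
  if (ncol(object@values) != length(object@regions))
    return("values columns and regions length differ")
  if (length(object@sd) != length(object@regions))
    return("sd length and regions length differ")
  TRUE
})

#' DesignMatrix: encoded predictors plus provenance
#'
#' Numeric design matrix used by both learners, with a map from every column
#' back to the catalog variable that produced it (categorical variables expand
#' to a full indicator set, one column per level).
#'
#' @slot X samples x columns numeric matrix.
#' @slot columnMap data.frame with columns `column`, `variable`, `level`.
#' @slot catalog the variable catalog (`variable`, `var_class`, `value_type`).
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", columnMap = "data.frame", catalog = "data.frame"))

setValidity("DesignMatrix", function(object) {
  if (!identical(colnames(object@X), object@columnMap$column))
    return("columnMap rows must match X columns in order")
  if (!all(object@columnMap$variable %in% object@catalog$variable))
    return("columnMap refers to variables absent from the catalog")
  TRUE
})

VAR_CLASSES <- c("methionine_cycle_enzymes", "other_SGOC_enzymes",
                 "chromatin_remodelling_factors", "transcription_factors",
                 "SAM_metabolizing_enzymes", "clinical_factors",
                 "copy_number_variations", "mutations")

REGION_CATEGORIES <- c("TSS1500", "TSS200", "5UTR", "FirstExon", "Body",
                       "3UTR", "Intergenic")

PROMOTER_CATEGORIES <- c("TSS1500", "TSS200", "5UTR")
BODY_CATEGORIES <- c("FirstExon", "Body", "3UTR")

#' Variable catalog constructor
#'
#' Maps each model predictor to one of the eight functional classes
#' (methionine-cycle enzymes, other SGOC enzymes, chromatin remodelling
#' factors, transcription factors, SAM-metabolizing enzymes, clinical factors,
#' copy-number variations, mutations) and a value type.
#'
#' @param variable Character, predictor names (unique).
#' @param var_class Character, one of the eight class labels per variable.
#' @param value_type `"numeric"` or `"categorical"` per variable.
#' @return A validated data.frame with the three columns.
#' @export
variableCatalog <- function(variable, var_class, value_type) {
  stopifnot(length(variable) == length(var_class),
            length(variable) == length(value_type))
  if (anyDuplicated(variable)) stop("duplicated catalog variables")
  bad <- setdiff(unique(var_class), VAR_CLASSES)
  if (length(bad))
    stop("unknown variable class(es): ", paste(bad, collapse = ", "))
  if (!all(value_type %in% c("numeric", "categorical")))
    stop("value_type must be 'numeric' or 'categorical'")
  data.frame(variable = variable, var_class = var_class,
             value_type = value_type, stringsAsFactors = FALSE)
}

#' Probe annotation as GRanges
#'
#' @param df data.frame with columns `probe_id`, `chrom`, `pos` (1-based),
#'   `gene` (symbol or ""), `region_category` (one of the Illumina-style
#'   positional categories).
#' @return A `GRanges`, one width-1 range per probe, named by probe id, with
#'   metadata columns `gene` and `region_category`.
#' @export
probeAnnotation <- function(df) {
  req <- c("probe_id", "chrom", "pos", "gene", "region_category")
  stopifnot(all(req %in% colnames(df)))
  if (anyDuplicated(df$probe_id)) stop("duplicated probe ids")
  if (any(df$pos < 1)) stop("probe positions must be >= 1")
  bad <- setdiff(unique(df$region_category), REGION_CATEGORIES)
  if (length(bad))
    stop("unknown region category: ", paste(bad, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$pos, width = 1L),
    gene = as.character(df$gene),
    region_category = df$region_category)
  names(gr) <- df$probe_id
  gr
}

#' Gene annotation as GRanges
#'
#' @param df data.frame with columns `gene`, `chrom`, `tss` (1-based),
#'   `strand` (`+`/`-`). One row per gene symbol.
#' @return A `GRanges` of width-1 TSS positions named by gene symbol.
#' @export
geneAnnotation <- function(df) {
  req <- c("gene", "chrom", "tss", "strand")
  stopifnot(all(req %in% colnames(df)))
  if (anyDuplicated(df$gene)) stop("duplicated gene symbols")
  if (any(df$tss < 1)) stop("TSS positions must be >= 1")
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$tss, width = 1L),
    strand = df$strand)
  names(gr) <- df$gene
  gr
}
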