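# Accessor generics and show methods.

#' @rdname OmicsCohort-class
#' @param x An object.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname OmicsCohort-class
#' @export
setGeneric("methylation", function(x) standardGeneric("methylation"))
#' @rdname OmicsCohort-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))
#' @rdname OmicsCohort-class
#' @export
setGeneric("mutationCalls", function(x) standardGeneric("mutationCalls"))
#' @rdname OmicsCohort-class
#' @export
setGeneric("cnaCalls", function(x) standardGeneric("cnaCalls"))
#' @rdname OmicsCohort-class
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname OmicsCohort-class
#' @export
setGeneric("survivalTable", function(x) standardGeneric("survivalTable"))

#' @rdname OmicsCohort-class
setMethod("sampleIDs", "OmicsCohort", function(x) rownames(x@methylation))
#' @rdname OmicsCohort-class
setMethod("methylation", "OmicsCohort", function(x) x@methylation)
#' @rdname OmicsCohort-class
setMethod("exprMatrix", "OmicsCohort", function(x) x@expression)
#' @rdname OmicsCohort-class
setMethod("mutationCalls", "OmicsCohort", function(x) x@mutations)
#' @rdname OmicsCohort-class
setMethod("cnaCalls", "OmicsCohort", function(x) x@cna)
#' @rdname OmicsCohort-class
setMethod("clinicalTable", "OmicsCohort", function(x) x@clinical)
#' @rdname OmicsCohort-class
setMethod("survivalTable", "OmicsCohort", function(x) x@survival)

setMethod("show", "OmicsCohort", function(object) {
  cat("OmicsCohort with", nrow(object@methylation), "samples\n")
  cat("  methylation:", ncol(object@methylation), "probes",
      sprintf("(%.1f%% missing)\n", 100 * mean(is.na(object@methylation))))
  cat("  expression: ", ncol(object@expression), "genes\n")
  cat("  mutations:  ", ncol(object@mutations), "genes\n")
  cat("  cna:        ", ncol(object@cna), "genes\n")
  cat("  clinical:   ", ncol(object@clinical), "attributes\n")
  ev <- object@survival$event
  cat("  survival:   ", sum(ev == 1, na.rm = TRUE), "events /",
      length(ev), "subjects\n")
})

#' @rdname RegionMatrix-class
#' @param x An object.
#' @export
setGeneric("regionValues", function(x) standardGeneric("regionValues"))
#' @rdname RegionMatrix-class
#' @export
setGeneric("regionSD", function(x) standardGeneric("regionSD"))
#' @rdname RegionMatrix-class
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @rdname RegionMatrix-class
setMethod("regionValues", "RegionMatrix", function(x) x@values)
#' @rdname RegionMatrix-class
setMethod("regionSD", "RegionMatrix", function(x) x@sd)
#' @rdname RegionMatrix-class
setMethod("regionRanges", "RegionMatrix", function(x) x@regions)

setMethod("show", "RegionMatrix", function(object) {
  cat("RegionMatrix:", ncol(object@values), "10 kb regions x",
      nrow(object@values), "samples\n")
  if (length(object@sd))
    cat("  cross-sample s.d. range:",
        sprintf("%.3f-%.3f\n", min(object@sd), max(object@sd)))
})

#' @rdname DesignMatrix-class
#' @param x An object.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname DesignMatrix-class
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))
#' @rdname DesignMatrix-class
#' @export
setGeneric("catalog", function(x) standardGeneric("catalog"))

#' @rdname DesignMatrix-class
setMethod("designMatrix", "DesignMatrix", function(x) x@X)
#' @rdname DesignMatrix-class
setMethod("columnMap", "DesignMatrix", function(x) x@columnMap)
#' @rdname DesignMatrix-class
setMethod("catalog", "DesignMatrix", function(x) x@catalog)

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "samples x", ncol(object@X),
      "columns from", length(unique(object@columnMap$variable)),
      "variables\n")
  tab <- table(object@catalog$var_class[
    match(unique(object@columnMap$variable), object@catalog$variable)])
  for (nm in names(tab)) cat("  ", nm, ":", tab[[nm]], "\n")
})
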