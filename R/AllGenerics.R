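#' @name metabopredict-accessors
#' @title Accessors for metabopredict S4 classes
#'
#' @description Slot accessors: prefer these over direct `@` access.
#' `abundances()` returns the primary assay matrix; `featureIDs()` and
#' `sampleIDs()` its dimnames; `sampleGroups()` / `sampleStudies()` the
#' case-control labels and study IDs from `colData`; `chemicalDictionary()`
#' the compound universe of a [ReferenceMap-class]; `modelSizes()` the
#' per-metabolite count of nonzero coefficients of a [ModelSet-class].
#'
#' @param x a metabopredict object.
#' @return See individual generic descriptions.
#' @aliases abundances featureIDs sampleIDs sampleGroups sampleStudies
#'   chemicalDictionary modelSizes orphanReactions
NULL

#' @rdname metabopredict-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("sampleStudies", function(x) standardGeneric("sampleStudies"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("chemicalDictionary", function(x) standardGeneric("chemicalDictionary"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("orphanReactions", function(x) standardGeneric("orphanReactions"))

#' @rdname metabopredict-accessors
#' @export
setGeneric("modelSizes", function(x) standardGeneric("modelSizes"))

#' @describeIn metabopredict-accessors assay matrix of an AbundanceTable.
setMethod("abundances", "SummarizedExperiment", function(x)
  SummarizedExperiment::assay(x, 1))

#' @describeIn metabopredict-accessors feature (row) IDs.
setMethod("featureIDs", "SummarizedExperiment", function(x) rownames(x))

#' @describeIn metabopredict-accessors sample (column) IDs.
setMethod("sampleIDs", "SummarizedExperiment", function(x) colnames(x))

#' @describeIn metabopredict-accessors per-sample group labels (or NULL).
setMethod("sampleGroups", "SummarizedExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("group" %in% names(cd)) setNames(as.character(cd$group), rownames(cd)) else NULL
})

#' @describeIn metabopredict-accessors per-sample study IDs (or NULL).
setMethod("sampleStudies", "SummarizedExperiment", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("study" %in% names(cd)) setNames(as.character(cd$study), rownames(cd)) else NULL
})

#' @describeIn metabopredict-accessors compound universe of a ReferenceMap.
setMethod("chemicalDictionary", "ReferenceMap", function(x) x@dictionary)

#' @describeIn metabopredict-accessors reactions referenced without compounds.
setMethod("orphanReactions", "ReferenceMap", function(x) x@orphanRxns)

#' @describeIn metabopredict-accessors named integer vector of model sizes.
setMethod("modelSizes", "ModelSet", function(x)
  vapply(x@models, function(m) as.integer(m$size), integer(1)))

setMethod("show", "ReferenceMap", function(object) {
  cat("ReferenceMap\n")
  cat(sprintf("  functions with direct reactions : %d\n", length(object@koToRxn)))
  cat(sprintf("  functions with EC annotations   : %d\n", length(object@koToEc)))
  cat(sprintf("  EC numbers mapped to reactions  : %d\n", length(object@ecToRxn)))
  cat(sprintf("  reactions with compounds        : %d\n", length(object@rxnToCpd)))
  cat(sprintf("  transporter functions           : %d\n", length(object@transporterToCpd)))
  cat(sprintf("  chemical dictionary             : %d compounds\n", length(object@dictionary)))
  if (length(object@orphanRxns))
    cat(sprintf("  orphan reactions                : %d\n", length(object@orphanRxns)))
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d features x %d samples\n",
              nrow(object), ncol(object)))
  g <- sampleGroups(object)
  if (!is.null(g)) cat("  groups:", paste(names(table(g)), table(g), sep = "=", collapse = ", "), "\n")
  s <- sampleStudies(object)
  if (!is.null(s)) cat("  studies:", length(unique(s)), "\n")
})

setMethod("show", "CMPMatrix", function(object) {
  v <- abundances(object)
  cat(sprintf("CMPMatrix: %d compounds x %d samples (signed scores, range %.3g .. %.3g)\n",
              nrow(object), ncol(object),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "ModelSet", function(object) {
  cat(sprintf("ModelSet: %d metabolite models over %d candidate functions\n",
              length(object@models), length(object@features)))
  if (length(object@models)) {
    sz <- modelSizes(object)
    cat(sprintf("  model sizes: min %d / median %g / max %d\n",
                min(sz), median(sz), max(sz)))
  }
})
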