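#' ReferenceMap: the function-to-compound relationship graph
#'
#' An S4 container for the relationship table linking microbial functions
#' (KEGG orthologs, reactions) to chemical compounds. Four linkage routes are
#' stored: direct KO to reaction edges, KO to enzyme-number (EC) annotations
#' with EC to reaction edges (the fallback route used when a KO has no direct
#' reaction), reaction to compound edges carrying optional signed
#' stoichiometric coefficients, and manual transporter-to-compound links.
#' The chemical dictionary is the compound universe from which random
#' coverage-null draws are taken; it may contain compounds never linked to
#' any function.
#'
#' Reaction directionality is deliberately not encoded in the compound sets
#' (substrates and products are treated alike for occurrence prediction);
#' the signed coefficients are retained separately because the
#' community-metabolic-potential score does consume them.
#'
#' @slot koToRxn named list; per function, character vector of reaction IDs.
#' @slot koToEc named list; per function, character vector of EC numbers.
#' @slot ecToRxn named list; per EC number, character vector of reaction IDs.
#' @slot rxnToCpd named list; per reaction, a named numeric vector mapping
#'   compound IDs to signed stoichiometric coefficients (`NA` when the source
#'   records carried none).
#' @slot transporterToCpd named list; per transporter function, character
#'   vector of compound IDs.
#' @slot dictionary character vector of compound IDs (the compound universe).
#' @slot orphanRxns character vector of reaction IDs referenced by a linkage
#'   route but lacking any compound entry.
#'
#' @seealso [buildRelationshipTable()], [compoundsForFunction()],
#'   [writeReferenceMap()]
#' @export
setClass("ReferenceMap",
  representation(
    koToRxn = "list",
    koToEc = "list",
    ecToRxn = "list",
    rxnToCpd = "list",
    transporterToCpd = "list",
    dictionary = "character",
    orphanRxns = "character"
  ),
  prototype(
    koToRxn = structure(list(), names = character(0)),
    koToEc = structure(list(), names = character(0)),
    ecToRxn = structure(list(), names = character(0)),
    rxnToCpd = structure(list(), names = character(0)),
    transporterToCpd = structure(list(), names = character(0)),
    dictionary = character(0),
    orphanRxns = character(0)
  )
)

setValidity("ReferenceMap", function(object) {
  msg <- character(0)
  for (sl in c("koToRxn", "koToEc", "ecToRxn", "rxnToCpd", "transporterToCpd")) {
    m <- slot(object, sl)
    if (length(m) && (is.null(names(m)) || anyDuplicated(names(m))))
      msg <- c(msg, sprintf("slot '%s' must be uniquely named", sl))
  }
  linked <- c(
    unlist(lapply(object@rxnToCpd, names), use.names = FALSE),
    unlist(object@transporterToCpd, use.names = FALSE)
  )
  if (!all(linked %in% object@dictionary))
    msg <- c(msg, "every linked compound must be a member of the dictionary")
  coefs <- unlist(object@rxnToCpd, use.names = FALSE)
  if (any(!is.na(coefs) & coefs == 0))
    msg <- c(msg, "stoichiometric coefficients, when present, must be nonzero")
  referenced <- unique(c(
    unlist(object@koToRxn, use.names = FALSE),
    unlist(object@ecToRxn, use.names = FALSE)
  ))
  dangling <- setdiff(referenced, c(names(object@rxnToCpd), object@orphanRxns))
  if (length(dangling))
    msg <- c(msg, sprintf("reaction(s) referenced but neither resolved nor recorded as orphan: %s",
                          paste(head(dangling, 3), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' AbundanceTable: features-by-samples abundance matrix with cohort metadata
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass for microbial
#' function counts or metabolite intensities. Rows are namespaced feature IDs
#' (functions or compounds), columns are samples. Per-sample case/control
#' group labels and study IDs live in `colData` under `group` and `study`.
#' Values must be finite and non-negative (signed community-metabolic-
#' potential scores use [CMPMatrix-class] instead).
#'
#' @seealso [AbundanceTable()], [CMPMatrix-class]
#' @export
#' @import SummarizedExperiment
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- .validate_table_core(object)
  v <- SummarizedExperiment::assay(object, 1)
  if (length(v) && any(v < 0))
    msg <- c(msg, "abundance values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CMPMatrix: signed community-metabolic-potential scores
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding compounds
#' by samples community-metabolic-potential (CMP) scores. Unlike
#' [AbundanceTable-class], values may be negative: the sign carries net
#' production (+) versus net consumption (-) semantics.
#'
#' @seealso [computeCMP()]
#' @export
setClass("CMPMatrix", contains = "SummarizedExperiment")

setValidity("CMPMatrix", function(object) {
  msg <- .validate_table_core(object)
  if (length(msg)) msg else TRUE
})

.validate_table_core <- function(object) {
  msg <- character(0)
  v <- SummarizedExperiment::assay(object, 1)
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate feature IDs")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample IDs")
  if (length(v) && !all(is.finite(v))) msg <- c(msg, "values must be finite")
  msg
}

#' ModelSet: fitted per-metabolite regression models
#'
#' Holds one elastic-net model per metabolite (selected functions with
#' coefficients plus intercept, on the arcsine-square-root transformed
#' relative-abundance scale), the training feature universe, and provenance
#' (training study IDs and the seed). Model size is the number of functions
#' with nonzero coefficients; size-1 models are pruned by [pruneModels()]
#' because a metabolite predicted by a single function is prone to spurious
#' association.
#'
#' @slot models named list, one entry per compound with elements
#'   `coefficients` (named numeric, nonzero only), `intercept` (numeric),
#'   `size` (integer), `alpha` and `lambda` (selected hyperparameters).
#' @slot features character; the function IDs the models were trained on.
#' @slot provenance list with at least `studies` and `seed`.
#' @export
setClass("ModelSet",
  representation(models = "list", features = "character", provenance = "list"),
  prototype(models = structure(list(), names = character(0)),
            features = character(0), provenance = list())
)

setValidity("ModelSet", function(object) {
  msg <- character(0)
  if (length(object@models) && is.null(names(object@models)))
    msg <- c(msg, "models must be named by compound ID")
  ok <- vapply(object@models, function(m) {
    all(c("coefficients", "intercept", "size") %in% names(m)) &&
      all(is.finite(m$coefficients)) && is.finite(m$intercept) &&
      m$size == sum(m$coefficients != 0)
  }, logical(1))
  if (!all(ok)) msg <- c(msg, "each model needs finite coefficients/intercept and size == #nonzero")
  if (length(msg)) msg else TRUE
})
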