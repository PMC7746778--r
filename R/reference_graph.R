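#' Build the function-to-compound relationship table
#'
#' Assembles a [ReferenceMap-class] from annotation records of five mapping
#' kinds: `ko_to_rxn`, `ko_to_ec`, `ec_to_rxn`, `rxn_to_cpd` (optionally with
#' a signed stoichiometric coefficient) and `transporter_to_cpd`. Duplicate
#' records collapse to one edge; reaction directionality is not encoded in
#' the compound sets (many reactions are reversible in vivo), but signed
#' coefficients, when supplied, are retained for community-metabolic-
#' potential scoring. Reactions referenced by a KO or EC route but lacking
#' any compound record are kept as orphans (logged, not fatal). Compounds
#' linked by a record but absent from a supplied dictionary are auto-added
#' with a warning.
#'
#' @param records data.frame with columns `kind`, `from`, `to` and optional
#'   `coef` (numeric, used only for `rxn_to_cpd` rows; `NA` elsewhere). All
#'   identifiers must carry a namespace prefix (`ko:`, `rxn:`, `cpd:`,
#'   `ec:`, `biocyc:` ...).
#' @param dictionary optional character vector of compound IDs forming the
#'   chemical dictionary (compound universe). Defaults to the compounds seen
#'   in the records.
#' @return A validated [ReferenceMap-class].
#' @examples
#' rec <- data.frame(
#'   kind = c("ko_to_rxn", "rxn_to_cpd", "rxn_to_cpd"),
#'   from = c("ko:K00001", "rxn:R00001", "rxn:R00001"),
#'   to   = c("rxn:R00001", "cpd:C00001", "cpd:C00002"),
#'   coef = c(NA, -1, 1))
#' buildRelationshipTable(rec)
#' @export
buildRelationshipTable <- function(records, dictionary = NULL) {
  kinds <- c("ko_to_rxn", "ko_to_ec", "ec_to_rxn", "rxn_to_cpd",
             "transporter_to_cpd")
  if (is.null(records) || nrow(records) == 0) {
    return(new("ReferenceMap",
               dictionary = sort(unique(as.character(dictionary)))))
  }
  stopifnot(all(c("kind", "from", "to") %in% names(records)))
  records$kind <- as.character(records$kind)
  records$from <- as.character(records$from)
  records$to <- as.character(records$to)
  if (is.null(records$coef)) records$coef <- NA_real_
  bad_kind <- which(!records$kind %in% kinds)
  if (length(bad_kind))
    stop(sprintf("unknown mapping kind '%s' (record %d)",
                 records$kind[bad_kind[1]], bad_kind[1]))
  for (col in c("from", "to")) {
    bad <- which(!.is_namespaced(records[[col]]))
    if (length(bad))
      stop(sprintf(
        "malformed identifier (missing namespace): '%s' (record %d, column '%s')",
        records[[col]][bad[1]], bad[1], col))
  }
  bad_coef <- which(records$kind == "rxn_to_cpd" & !is.na(records$coef) &
                      records$coef == 0)
  if (length(bad_coef))
    stop(sprintf("zero stoichiometric coefficient (record %d)", bad_coef[1]))

  pick <- function(kind) records[records$kind == kind, , drop = FALSE]
  edge_list <- function(df) {
    if (!nrow(df)) return(structure(list(), names = character(0)))
    lapply(split(df$to, df$from), function(x) sort(unique(x)))
  }
  koToRxn <- edge_list(pick("ko_to_rxn"))
  koToEc <- edge_list(pick("ko_to_ec"))
  ecToRxn <- edge_list(pick("ec_to_rxn"))
  transporterToCpd <- edge_list(pick("transporter_to_cpd"))

  rc <- pick("rxn_to_cpd")
  rxnToCpd <- structure(list(), names = character(0))
  if (nrow(rc)) {
    rxnToCpd <- lapply(split(rc[, c("to", "coef")], rc$from), function(df) {
      ## duplicate (rxn, cpd) records must agree on the coefficient;
      ## an NA duplicate defers to a stated one
      agg <- tapply(df$coef, df$to, function(v) {
        v <- unique(v[!is.na(v)])
        if (length(v) > 1)
          stop("conflicting stoichiometric coefficients for one (reaction, compound) pair")
        if (length(v)) v else NA_real_
      })
      out <- as.numeric(agg)
      names(out) <- names(agg)
      out[order(names(out))]
    })
  }

  linked_cpds <- sort(unique(as.character(c(
    unlist(lapply(rxnToCpd, names), use.names = FALSE),
    unlist(transporterToCpd, use.names = FALSE)))))
  if (is.null(dictionary)) {
    dictionary <- linked_cpds
  } else {
    dictionary <- sort(unique(as.character(dictionary)))
    missing <- setdiff(linked_cpds, dictionary)
    if (length(missing)) {
      warning(sprintf(
        "%d linked compound(s) absent from the supplied dictionary were auto-added (e.g. %s)",
        length(missing), paste(head(missing, 3), collapse = ", ")))
      dictionary <- sort(c(dictionary, missing))
    }
  }

  referenced <- unique(c(unlist(koToRxn, use.names = FALSE),
                         unlist(ecToRxn, use.names = FALSE)))
  orphans <- sort(setdiff(referenced, names(rxnToCpd)))
  if (length(orphans))
    message(sprintf("%d orphan reaction(s) without compound records (e.g. %s)",
                    length(orphans), paste(head(orphans, 3), collapse = ", ")))

  new("ReferenceMap", koToRxn = koToRxn, koToEc = koToEc, ecToRxn = ecToRxn,
      rxnToCpd = rxnToCpd, transporterToCpd = transporterToCpd,
      dictionary = dictionary, orphanRxns = orphans)
}

#' Compounds linked to a microbial function
#'
#' Resolves one function ID through the relationship graph. A function in
#' the reaction namespace resolves through its own compound record. A KO
#' resolves through the union of (i) the compounds of its direct reactions,
#' (ii) -- only when it has no direct reaction -- the compounds of reactions
#' reached via its EC numbers (the fallback route), and (iii) its
#' transporter compounds. An unknown function yields the empty set.
#'
#' @param ref a [ReferenceMap-class].
#' @param f a single function ID (e.g. `"ko:K24443"`, `"rxn:R02428"`).
#' @param ecFallback `"fallback"` (EC route used only when a KO has zero
#'   direct reactions; the default) or `"always"` (EC-route compounds always
#'   unioned in).
#' @return Sorted character vector of compound IDs.
#' @export
compoundsForFunction <- function(ref, f, ecFallback = c("fallback", "always")) {
  stopifnot(is(ref, "ReferenceMap"), is.character(f), length(f) == 1L)
  ecFallback <- match.arg(ecFallback)
  .check_namespaced(f, "function ID")
  rxn_cpds <- function(rxns) {
    hit <- ref@rxnToCpd[intersect(rxns, names(ref@rxnToCpd))]
    unlist(lapply(hit, names), use.names = FALSE)
  }
  out <- character(0)
  if (f %in% names(ref@rxnToCpd)) {
    ## reaction-namespace features resolve directly
    out <- c(out, names(ref@rxnToCpd[[f]]))
  } else {
    direct <- ref@koToRxn[[f]]
    if (!is.null(direct) && length(direct)) {
      out <- c(out, rxn_cpds(direct))
      if (ecFallback == "always")
        out <- c(out, rxn_cpds(.ec_reactions(ref, f)))
    } else {
      out <- c(out, rxn_cpds(.ec_reactions(ref, f)))
    }
  }
  tr <- ref@transporterToCpd[[f]]
  if (!is.null(tr)) out <- c(out, tr)
  sort(unique(out))
}

.ec_reactions <- function(ref, f) {
  ecs <- ref@koToEc[[f]]
  if (is.null(ecs)) return(character(0))
  unlist(ref@ecToRxn[intersect(ecs, names(ref@ecToRxn))], use.names = FALSE)
}

#' Compounds linked to a set of functions
#'
#' Bulk union of [compoundsForFunction()] over a vector of function IDs.
#'
#' @inheritParams compoundsForFunction
#' @param fs character vector of function IDs (may be empty).
#' @return Sorted character vector: the union of per-function compound sets.
#' @export
compoundsForFunctions <- function(ref, fs, ecFallback = c("fallback", "always")) {
  ecFallback <- match.arg(ecFallback)
  if (!length(fs)) return(character(0))
  .dedup_union(lapply(unique(fs), compoundsForFunction, ref = ref,
                      ecFallback = ecFallback))
}

#' Serialize / restore a ReferenceMap as JSON
#'
#' JSON with sorted keys is the canonical serialized form, so identical maps
#' round-trip byte-identically. Stoichiometric coefficients absent in the
#' source are stored as `null` and restored as `NA`.
#'
#' @param ref a [ReferenceMap-class].
#' @param path file path.
#' @return `writeReferenceMap()` the path, invisibly; `readReferenceMap()`
#'   a [ReferenceMap-class].
#' @export
writeReferenceMap <- function(ref, path) {
  stopifnot(is(ref, "ReferenceMap"))
  sort_named <- function(l) if (length(l)) l[order(names(l))] else structure(list(), names = character(0))
  doc <- list(
    ko_to_rxn = sort_named(lapply(ref@koToRxn, sort)),
    ko_to_ec = sort_named(lapply(ref@koToEc, sort)),
    ec_to_rxn = sort_named(lapply(ref@ecToRxn, sort)),
    rxn_to_cpd = sort_named(lapply(ref@rxnToCpd, function(v)
      list(cpd = names(v), coef = unname(v)))),
    transporter_to_cpd = sort_named(lapply(ref@transporterToCpd, sort)),
    dictionary = sort(ref@dictionary),
    orphan_rxns = sort(ref@orphanRxns)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = FALSE, na = "null", digits = NA,
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeReferenceMap
#' @export
readReferenceMap <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  as_chr_list <- function(l) {
    if (!length(l)) return(structure(list(), names = character(0)))
    lapply(l, function(x) as.character(unlist(x)))
  }
  rxnToCpd <- structure(list(), names = character(0))
  if (length(doc$rxn_to_cpd)) {
    rxnToCpd <- lapply(doc$rxn_to_cpd, function(e) {
      coef <- vapply(e$coef, function(x) if (is.null(x)) NA_real_ else as.numeric(x),
                     numeric(1))
      names(coef) <- as.character(unlist(e$cpd))
      coef
    })
  }
  new("ReferenceMap",
      koToRxn = as_chr_list(doc$ko_to_rxn),
      koToEc = as_chr_list(doc$ko_to_ec),
      ecToRxn = as_chr_list(doc$ec_to_rxn),
      rxnToCpd = rxnToCpd,
      transporterToCpd = as_chr_list(doc$transporter_to_cpd),
      dictionary = as.character(unlist(doc$dictionary)),
      orphanRxns = as.character(unlist(doc$orphan_rxns)))
}

#' Read annotation records from per-kind TSV files
#'
#' Alternative reference input: one TSV per mapping kind, two columns
#' (`from`, `to`) or three (`from`, `to`, `coef`) for `rxn_to_cpd`.
#'
#' @param paths named character vector; names are mapping kinds
#'   (`ko_to_rxn`, `ko_to_ec`, `ec_to_rxn`, `rxn_to_cpd`,
#'   `transporter_to_cpd`), values are file paths.
#' @return A records data.frame suitable for [buildRelationshipTable()].
#' @export
readAnnotationRecords <- function(paths) {
  stopifnot(!is.null(names(paths)), all(nzchar(names(paths))))
  out <- lapply(names(paths), function(kind) {
    df <- read.delim(paths[[kind]], header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, quote = "")
    if (ncol(df) < 2) stop("mapping TSV needs >= 2 columns: ", paths[[kind]])
    data.frame(kind = kind, from = as.character(df[[1]]),
               to = as.character(df[[2]]),
               coef = if (ncol(df) >= 3) as.numeric(df[[3]]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
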