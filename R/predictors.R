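#' Relationship-table occurrence prediction
#'
#' Reports every compound linked through the relationship table to any
#' function observed in the community (nonzero abundance in at least one
#' sample). When a function links to multiple metabolites, all are reported;
#' the prediction is a pure presence set, invariant to abundance scaling and
#' sample order.
#'
#' @param table an [AbundanceTable-class] of function abundances.
#' @param ref a [ReferenceMap-class] sharing the table's namespace.
#' @param ecFallback see [compoundsForFunction()].
#' @return Sorted character vector of predicted compound IDs.
#' @export
mangosteenOccurrence <- function(table, ref, ecFallback = c("fallback", "always")) {
  stopifnot(is(table, "AbundanceTable"), is(ref, "ReferenceMap"))
  ecFallback <- match.arg(ecFallback)
  m <- abundances(table)
  present <- rownames(m)[rowSums(m > 0) > 0]
  if (!length(present)) {
    warning("no function with nonzero abundance; empty prediction")
    return(character(0))
  }
  compoundsForFunctions(ref, present, ecFallback = ecFallback)
}

#' Relationship-table differential-metabolite prediction
#'
#' Maps a set of differential microbial functions (typically the output of
#' [nbWaldDiffFunctions()] or [importDifferential()]) to the union of their
#' linked compounds. All linked compounds are reported as differential; no
#' abundance or direction is attached.
#'
#' @param diffFunctions character vector of function IDs.
#' @inheritParams mangosteenOccurrence
#' @return Sorted character vector of predicted differential compound IDs.
#' @export
mangosteenDifferential <- function(diffFunctions, ref,
                                   ecFallback = c("fallback", "always")) {
  stopifnot(is(ref, "ReferenceMap"))
  ecFallback <- match.arg(ecFallback)
  compoundsForFunctions(ref, diffFunctions, ecFallback = ecFallback)
}

#' Normalize function abundances by single-copy marker medians
#'
#' Inter-sample normalization against universal single-copy marker genes:
#' each sample's column is divided by the median abundance of the marker
#' functions in that sample, so the per-sample marker median becomes 1 and
#' abundances read as copies per genome. Tables normalized externally by
#' other tools can be passed straight to [computeCMP()] instead.
#'
#' @param table an [AbundanceTable-class] of function abundances.
#' @param markers character vector of marker function IDs; each sample must
#'   have a nonzero marker median.
#' @return A normalized [AbundanceTable-class].
#' @export
singleCopyNormalize <- function(table, markers) {
  stopifnot(is(table, "AbundanceTable"), length(markers) >= 1)
  m <- abundances(table)
  found <- intersect(markers, rownames(m))
  if (!length(found)) stop("none of the marker functions are in the table")
  med <- apply(m[found, , drop = FALSE], 2, median)
  zero <- med <= 0
  if (any(zero))
    stop("zero marker median in sample(s): ",
         paste(head(colnames(m)[zero], 5), collapse = ", "))
  .retable("AbundanceTable", sweep(m, 2, med, "/"), table)
}

#' Community metabolic potential scores
#'
#' Computes the signed community-metabolic-potential (CMP) matrix used as a
#' predicted metabolome: for compound c and sample s,
#' \deqn{CMP[c,s] = \sum_{r \ni c} coef(c,r) \sum_{f \to r} abundance(f,s),}
#' the stoichiometry-weighted sum of (normalized) abundances of all
#' functions linked to each reaction involving c. Positive scores read as
#' net predicted production, negative as net consumption. Functions route to
#' reactions as in [compoundsForFunction()] (direct edges, EC fallback for
#' KOs without direct reactions, reaction-namespace features as themselves);
#' transporter links carry no stoichiometry and do not enter CMP. Compounds
#' with no linked function are omitted.
#'
#' @param table an [AbundanceTable-class] of (normalized) function
#'   abundances, e.g. from [singleCopyNormalize()].
#' @param ref a [ReferenceMap-class]; its stoichiometric coefficients are
#'   consumed here.
#' @param defaultCoef policy for reaction-compound edges lacking a
#'   coefficient: `"plus_one"` substitutes +1 with a warning, `"error"`
#'   aborts.
#' @return A [CMPMatrix-class] (compounds by samples) carrying the table's
#'   sample metadata.
#' @export
computeCMP <- function(table, ref, defaultCoef = c("plus_one", "error")) {
  stopifnot(is(table, "AbundanceTable"), is(ref, "ReferenceMap"))
  defaultCoef <- match.arg(defaultCoef)
  m <- abundances(table)
  n_missing <- 0L

  ## per-function reaction routing (direct, else EC; rxn features are themselves)
  fun_rxns <- lapply(rownames(m), function(f) {
    if (f %in% names(ref@rxnToCpd)) return(f)
    direct <- ref@koToRxn[[f]]
    if (!is.null(direct) && length(direct)) {
      intersect(direct, names(ref@rxnToCpd))
    } else {
      intersect(.ec_reactions(ref, f), names(ref@rxnToCpd))
    }
  })
  names(fun_rxns) <- rownames(m)

  ## reaction -> summed abundance of its linked functions, per sample
  pairs <- data.frame(
    fun = rep(names(fun_rxns), lengths(fun_rxns)),
    rxn = unlist(fun_rxns, use.names = FALSE), stringsAsFactors = FALSE)
  if (!nrow(pairs)) {
    return(CMPMatrix(matrix(numeric(0), 0, ncol(m),
                            dimnames = list(character(0), colnames(m)))))
  }
  rxns <- sort(unique(pairs$rxn))
  rxn_abund <- matrix(0, length(rxns), ncol(m),
                      dimnames = list(rxns, colnames(m)))
  agg <- rowsum(m[pairs$fun, , drop = FALSE], group = pairs$rxn)
  rxn_abund[rownames(agg), ] <- agg

  ## stoichiometry matrix S (compounds x reactions): CMP = S %*% rxn_abund
  cpds <- sort(unique(unlist(lapply(ref@rxnToCpd[rxns], names),
                             use.names = FALSE)))
  S <- matrix(0, length(cpds), length(rxns), dimnames = list(cpds, rxns))
  for (r in rxns) {
    v <- ref@rxnToCpd[[r]]
    if (anyNA(v)) {
      if (defaultCoef == "error")
        stop("missing stoichiometric coefficient in reaction ", r,
             " and defaultCoef = 'error'")
      n_missing <- n_missing + sum(is.na(v))
      v[is.na(v)] <- 1
    }
    S[names(v), r] <- v
  }
  if (n_missing > 0)
    warning(sprintf("%d reaction-compound edge(s) lacked a coefficient; +1 assumed",
                    n_missing))
  .retable("CMPMatrix", S %*% rxn_abund, table)
}
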