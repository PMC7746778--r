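#' Occurrence set of an abundance or CMP matrix
#'
#' The compounds a predicted (or measured) metabolome "contains": features
#' surviving the prevalence filter at `minFrac` (default 5%). For signed
#' CMP scores, presence means `|value| > 1e-12`.
#'
#' @param table an [AbundanceTable-class] or [CMPMatrix-class] of compounds.
#' @param minFrac prevalence threshold.
#' @return Sorted character vector of compound IDs.
#' @export
occurrenceFromAbundance <- function(table, minFrac = 0.05) {
  sort(featureIDs(prevalenceFilter(table, minFrac)))
}

#' Precision / recall / F1 of a predicted compound set
#'
#' Presence/absence scoring of a predicted against a measured compound set:
#' tp is the intersection, fp the predicted-only, fn the measured-only
#' compounds; precision tp/(tp+fp), recall tp/(tp+fn), F1 their harmonic
#' mean (all defined as 0 when the denominator is 0).
#'
#' @param predicted,measured character vectors of compound IDs in one
#'   namespace.
#' @return An `EvalMetrics` list: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`.
#' @export
setMetrics <- function(predicted, measured) {
  predicted <- unique(as.character(predicted))
  measured <- unique(as.character(measured))
  if (!length(predicted) && !length(measured))
    warning("both sets are empty; all metrics defined as 0")
  tp <- length(intersect(predicted, measured))
  fp <- length(setdiff(predicted, measured))
  fn <- length(setdiff(measured, predicted))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1), class = "EvalMetrics")
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf("EvalMetrics: P=%.3f R=%.3f F1=%.3f (tp=%d fp=%d fn=%d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Procrustes comparison of predicted and measured metabolomes
#'
#' How similar are two abundance matrices as sample configurations?
#' Each matrix (samples restricted to the shared set) is turned into
#' Euclidean distances between samples, ordinated by classical
#' multidimensional scaling (principal coordinates; axes with positive
#' eigenvalues retained), and the two configurations are superimposed by
#' symmetric least-squares Procrustes rotation (translation, rotation /
#' reflection, uniform scaling). The squared residual m12-squared is 0 for
#' identical configurations and near 1 for unrelated ones;
#' `correlation = sqrt(1 - m12sq)`. Significance is assessed by permuting
#' sample labels of one configuration and applying the add-one empirical-p
#' rule to the correlation statistic.
#'
#' @param pred a predicted metabolome ([AbundanceTable-class] or
#'   [CMPMatrix-class]).
#' @param meas the measured metabolome ([AbundanceTable-class]).
#' @param nPerm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return A `ProcrustesResult` list: `m12_squared`, `correlation`,
#'   `p_value`, `n_permutations`, `n_samples`.
#' @export
procrustesCompare <- function(pred, meas, nPerm = 999, seed = 1) {
  stopifnot(is(pred, "SummarizedExperiment"), is(meas, "SummarizedExperiment"))
  shared <- intersect(sampleIDs(pred), sampleIDs(meas))
  if (length(shared) < 4) stop("need >= 4 shared samples, got ", length(shared))
  conf <- function(tab) {
    d <- dist(t(abundances(tab)[, shared, drop = FALSE]))
    .pcoa_positive(d)
  }
  X <- conf(pred); Y <- conf(meas)
  set.seed(stageSeed(seed, "procrustes"))
  ## axis-count mismatch between configurations is expected and handled by
  ## zero-padding inside vegan
  pt <- suppressWarnings(vegan::protest(X, Y, permutations = nPerm))
  structure(list(m12_squared = unname(pt$ss),
                 correlation = unname(pt$t0),
                 p_value = unname(pt$signif),
                 n_permutations = pt$permutations,
                 n_samples = length(shared)),
            class = "ProcrustesResult")
}

## classical MDS keeping only positive-eigenvalue axes
.pcoa_positive <- function(d) {
  n <- attr(d, "Size")
  mds <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  keep <- mds$eig > max(mds$eig) * 1e-9
  keep <- keep[seq_len(ncol(mds$points))]
  mds$points[, keep, drop = FALSE]
}

#' @export
print.ProcrustesResult <- function(x, ...) {
  cat(sprintf("Procrustes: m12^2=%.4f corr=%.4f p=%.4g (%d samples, %d permutations)\n",
              x$m12_squared, x$correlation, x$p_value, x$n_samples,
              x$n_permutations))
  invisible(x)
}

.null_distribution <- function(values, observed, larger_is_extreme = TRUE) {
  structure(list(replicates = values, observed = observed,
                 p_value = empiricalP(values, observed, larger_is_extreme),
                 n_null = length(values)),
            class = "NullDistribution")
}

#' @export
print.NullDistribution <- function(x, ...) {
  cat(sprintf("NullDistribution: observed=%.4f, null mean=%.4f (n=%d), empirical p=%.4g\n",
              x$observed, mean(x$replicates), x$n_null, x$p_value))
  invisible(x)
}

#' Random-draw null for occurrence (coverage) evaluation
#'
#' Is a pipeline's occurrence prediction better than chance? Each replicate
#' draws the same number of compounds as the pipeline predicted, uniformly
#' without replacement from the chemical dictionary, and scores the draw
#' against the measured set. The observed metric is compared to the
#' replicate distribution with the add-one empirical-p rule (with 99
#' replicates p lies on the grid 1/100 ... 100/100 and is never 0).
#'
#' @param dictionary the compound universe (character vector).
#' @param k number of compounds to draw per replicate (the observed
#'   prediction's size).
#' @param measured the measured compound set.
#' @param observed the observed pipeline `EvalMetrics` (from
#'   [setMetrics()]); its `metric` entry anchors the empirical p.
#' @param metric which metric the empirical p is computed for.
#' @param nNull replicate count.
#' @param seed integer seed.
#' @return A `NullDistribution` whose `replicates` are the chosen metric;
#'   attributes `precision`, `recall`, `f1` carry all three replicate
#'   vectors.
#' @export
nullCoverage <- function(dictionary, k, measured, observed, metric = "f1",
                         nNull = 99, seed = 1) {
  dictionary <- unique(as.character(dictionary))
  if (k > length(dictionary))
    stop("cannot draw ", k, " compounds from a dictionary of ",
         length(dictionary))
  stopifnot(metric %in% c("precision", "recall", "f1"))
  set.seed(stageSeed(seed, "null_coverage"))
  reps <- replicate(nNull, {
    draw <- sample(dictionary, k, replace = FALSE)
    m <- setMetrics(draw, measured)
    c(precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  obs_value <- if (is.list(observed)) observed[[metric]] else observed
  out <- .null_distribution(unname(reps[metric, ]), obs_value)
  attr(out, "precision") <- unname(reps["precision", ])
  attr(out, "recall") <- unname(reps["recall", ])
  attr(out, "f1") <- unname(reps["f1", ])
  out
}

#' Label-shuffling null for differential-metabolite evaluation
#'
#' The chance baseline for differential prediction, by pipeline type.
#' `"shuffle-genes"` (relationship-table pipelines): the function table's
#' row labels are permuted, the differential-function test and the
#' relationship-table differential prediction are rerun, and the prediction
#' is scored against the measured differential set. `"shuffle-metabolites"`
#' (abundance pipelines): the predicted matrix's compound labels are
#' permuted, the differential test is rerun on the relabelled matrix, and
#' its significant set is scored. The identity relabelling reproduces the
#' observed metric exactly, so the observed analysis and the null share one
#' code path.
#'
#' @param mode `"shuffle-genes"` or `"shuffle-metabolites"`.
#' @param funcs function [AbundanceTable-class] (shuffle-genes mode).
#' @param ref a [ReferenceMap-class] (shuffle-genes mode).
#' @param pred predicted metabolome ([CMPMatrix-class] or
#'   [AbundanceTable-class]; shuffle-metabolites mode).
#' @param test differential test for `pred`: `"ranksum"` (signed scores) or
#'   `"ttest"`.
#' @param measuredDiff character vector: the measured differential
#'   compound set the predictions are scored against.
#' @param observed observed `EvalMetrics` for the pipeline.
#' @param groups,caseLabel,alpha passed to the differential tests.
#' @param prevalence prevalence filter applied to the function table before
#'   testing (shuffle-genes mode).
#' @param metric which metric anchors the empirical p.
#' @param nNull replicate count.
#' @param seed integer seed.
#' @return A `NullDistribution` (replicates of `metric`).
#' @export
nullDifferential <- function(mode = c("shuffle-genes", "shuffle-metabolites"),
                             funcs = NULL, ref = NULL, pred = NULL,
                             test = c("ranksum", "ttest"),
                             measuredDiff, observed, groups = NULL,
                             caseLabel = NULL, alpha = 0.2,
                             prevalence = 0.05, metric = "f1",
                             nNull = 99, seed = 1) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  stopifnot(metric %in% c("precision", "recall", "f1"))
  if (mode == "shuffle-genes") {
    if (is.null(funcs) || is.null(ref))
      stop("shuffle-genes mode needs 'funcs' and 'ref'")
    base <- prevalenceFilter(funcs, prevalence)
    ids <- featureIDs(base)
    one <- function(perm) {
      tab <- base
      rownames(tab) <- ids[perm]
      dt <- nbWaldDiffFunctions(tab, groups = groups, caseLabel = caseLabel,
                                alpha = alpha)
      pred_set <- mangosteenDifferential(differentialFeatures(dt), ref)
      setMetrics(pred_set, measuredDiff)[[metric]]
    }
  } else {
    if (is.null(pred))
      stop("shuffle-metabolites mode needs 'pred'")
    ids <- featureIDs(pred)
    one <- function(perm) {
      tab <- pred
      rownames(tab) <- ids[perm]
      dt <- if (test == "ranksum")
        diffMetabolitesRanksum(tab, groups = groups, caseLabel = caseLabel,
                               alpha = alpha)
      else diffMetabolitesTtest(tab, groups = groups, caseLabel = caseLabel,
                                alpha = alpha)
      setMetrics(differentialFeatures(dt), measuredDiff)[[metric]]
    }
  }
  set.seed(stageSeed(seed, paste0("null_differential:", mode)))
  reps <- vapply(seq_len(nNull), function(i) one(sample(length(ids))),
                 numeric(1))
  obs_value <- if (is.list(observed)) observed[[metric]] else observed
  .null_distribution(reps, obs_value)
}

#' Pairwise signed-rank comparison of pipeline metrics
#'
#' Compares pipelines on a common panel of datasets: for each pipeline
#' pair, a two-sided Wilcoxon signed-rank test on the paired per-dataset
#' metric values (zero differences dropped by convention; exact
#' distribution for n <= 25 untied differences, normal approximation
#' otherwise). Fewer than 2 nonzero paired differences yields `NA`.
#'
#' @param metricTable numeric matrix, pipelines as rows, datasets as
#'   columns; `NA` entries are dropped pairwise.
#' @return Symmetric matrix of two-sided p-values (`NA` diagonal).
#' @export
comparePipelinesSignedRank <- function(metricTable) {
  metricTable <- as.matrix(metricTable)
  np <- nrow(metricTable)
  if (is.null(rownames(metricTable)))
    rownames(metricTable) <- paste0("pipeline", seq_len(np))
  out <- matrix(NA_real_, np, np,
                dimnames = list(rownames(metricTable), rownames(metricTable)))
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i >= j) next
    d <- metricTable[i, ] - metricTable[j, ]
    d <- d[!is.na(d)]
    d <- d[d != 0]
    p <- if (length(d) < 2) NA_real_ else {
      exact <- length(d) <= 25 && !anyDuplicated(abs(d))
      suppressWarnings(wilcox.test(d, exact = exact, correct = !exact)$p.value)
    }
    out[i, j] <- out[j, i] <- p
  }
  out
}
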