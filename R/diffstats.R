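#' Default analysis thresholds
#'
#' One place for every tunable cutoff, serialized with every benchmark run
#' for provenance: BH-adjusted significance level 0.2; 5% prevalence filters
#' for differential-function input and for measured/predicted metabolomes;
#' the stricter 10% prevalence and 0.01% mean relative-abundance filters for
#' regression training; 99 permutation-null repetitions; minimum model size
#' 2 (size-1 models dropped); 999 Procrustes permutations.
#'
#' @param alpha_fdr BH-adjusted p cutoff (inclusive).
#' @param prevalence_functions,prevalence_metabolites prevalence fractions.
#' @param ml_prevalence,ml_mean_relabund regression training filters.
#' @param n_null permutation-null repetitions.
#' @param min_model_size smallest surviving regression model size.
#' @param n_procrustes_perm Procrustes permutation count.
#' @return Named list of validated thresholds.
#' @export
metaboThresholds <- function(alpha_fdr = 0.2,
                             prevalence_functions = 0.05,
                             prevalence_metabolites = 0.05,
                             ml_prevalence = 0.10,
                             ml_mean_relabund = 1e-4,
                             n_null = 99L,
                             min_model_size = 2L,
                             n_procrustes_perm = 999L) {
  th <- list(alpha_fdr = alpha_fdr,
             prevalence_functions = prevalence_functions,
             prevalence_metabolites = prevalence_metabolites,
             ml_prevalence = ml_prevalence,
             ml_mean_relabund = ml_mean_relabund,
             n_null = as.integer(n_null),
             min_model_size = as.integer(min_model_size),
             n_procrustes_perm = as.integer(n_procrustes_perm))
  stopifnot(th$alpha_fdr > 0, th$alpha_fdr <= 1,
            th$prevalence_functions >= 0, th$prevalence_functions <= 1,
            th$prevalence_metabolites >= 0, th$prevalence_metabolites <= 1,
            th$ml_prevalence >= 0, th$ml_prevalence <= 1,
            th$ml_mean_relabund >= 0, th$ml_mean_relabund < 1,
            th$n_null >= 1, th$min_model_size >= 1, th$n_procrustes_perm >= 1)
  th
}

#' Prevalence filter
#'
#' Keeps features detected in at least `minFrac` of samples. "Detected in
#' fewer than the threshold fraction" is what gets removed, so a feature at
#' exactly the threshold is retained. For signed CMP scores, detection means
#' `|value| > 1e-12`.
#'
#' @param table an [AbundanceTable-class] or [CMPMatrix-class].
#' @param minFrac minimum detection fraction in `[0, 1]`.
#' @return The filtered table, same class as the input.
#' @export
prevalenceFilter <- function(table, minFrac = 0.05) {
  stopifnot(is(table, "SummarizedExperiment"), minFrac >= 0, minFrac <= 1)
  m <- abundances(table)
  keep <- .prevalence(m, signed = is(table, "CMPMatrix")) >= minFrac
  table[keep, ]
}

.prevalence <- function(m, signed = FALSE) {
  if (signed) rowMeans(abs(m) > 1e-12) else rowMeans(m > 0)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone with rank.
#'
#' @param pvals numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
  stopifnot(is.numeric(pvals))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors for count tables: the median of each
#' sample's ratios to the per-feature geometric means, computed over
#' features nonzero in every sample, then rescaled so the factors have
#' geometric mean 1.
#'
#' @param counts an [AbundanceTable-class] of counts.
#' @return Named numeric vector of per-sample factors.
#' @export
medianOfRatios <- function(counts) {
  stopifnot(is(counts, "AbundanceTable"))
  m <- abundances(counts)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos))
    stop("no feature is nonzero in every sample; consider adding a pseudocount")
  mm <- m[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(mm)))
  sf <- apply(sweep(mm, 1, geo, "/"), 2, median)
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

.split_groups <- function(table, groups) {
  g <- if (is.null(groups)) sampleGroups(table) else groups
  if (is.null(g)) stop("no group labels: supply 'groups' or colData$group")
  if (is.null(names(g))) names(g) <- sampleIDs(table)
  g <- g[sampleIDs(table)]
  lv <- unique(g)
  if (length(lv) != 2) stop("exactly two groups required, got: ",
                            paste(lv, collapse = ", "))
  g
}

.new_difftable <- function(feature, log2fc, stat, pvalue, alpha) {
  padj <- bhAdjust(pvalue)
  data.frame(feature = feature, log2fc = log2fc, stat = stat,
             pvalue = pvalue, padj = padj,
             significant = !is.na(padj) & padj <= alpha,
             row.names = feature, stringsAsFactors = FALSE)
}

#' Negative-binomial Wald test for differential functions
#'
#' A lightweight differential-abundance test for overdispersed function
#' counts: counts are scaled by [medianOfRatios()] size factors, a per-
#' feature dispersion is estimated by method of moments (pooled within
#' groups), and a Wald z statistic on the log mean ratio (case over
#' control, delta-method standard error) yields a two-sided normal p-value,
#' BH-adjusted and flagged at `alpha`. No dispersion shrinkage or
#' independent filtering is applied; exact results from heavier count
#' pipelines can be injected via [importDifferential()].
#'
#' @param counts an [AbundanceTable-class] of function counts, ideally
#'   already prevalence-filtered (or set `prevalence` to filter here).
#' @param groups optional named group labels; defaults to `colData$group`.
#' @param caseLabel which label is the case group; defaults to the first of
#'   the two labels in a stable sort.
#' @param alpha BH-adjusted significance cutoff (inclusive).
#' @param prevalence optional fraction: apply [prevalenceFilter()] first.
#' @return A DiffTable data.frame: `feature`, `log2fc` (case vs control),
#'   `stat`, `pvalue`, `padj`, `significant`.
#' @export
nbWaldDiffFunctions <- function(counts, groups = NULL, caseLabel = NULL,
                                alpha = 0.2, prevalence = NULL) {
  stopifnot(is(counts, "AbundanceTable"))
  if (!is.null(prevalence)) counts <- prevalenceFilter(counts, prevalence)
  g <- .split_groups(counts, groups)
  lv <- sort(unique(g))
  case <- if (is.null(caseLabel)) lv[1] else caseLabel
  ctrl <- setdiff(lv, case)
  if (!case %in% lv) stop("caseLabel '", case, "' not found in groups")
  if (sum(g == case) < 2 || sum(g == ctrl) < 2)
    stop("each group needs n >= 2")
  m <- abundances(counts)
  sf <- medianOfRatios(counts)
  norm <- sweep(m, 2, sf, "/")
  i1 <- which(g == case); i0 <- which(g == ctrl)
  n1 <- length(i1); n0 <- length(i0)
  mu1 <- rowMeans(norm[, i1, drop = FALSE])
  mu0 <- rowMeans(norm[, i0, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, var)
  v0 <- apply(norm[, i0, drop = FALSE], 1, var)
  ## pooled method-of-moments NB dispersion: Var = mu + a mu^2  =>  a
  pool_mu <- (n1 * mu1 + n0 * mu0) / (n1 + n0)
  pool_ex <- ((n1 - 1) * pmax(v1 - mu1, 0) + (n0 - 1) * pmax(v0 - mu0, 0)) /
    (n1 + n0 - 2)
  disp <- ifelse(pool_mu > 0, pool_ex / pool_mu^2, 0)
  eps <- 0.5 ## pseudo-mean keeps zero-mean groups finite
  b <- log((mu1 + eps)) - log((mu0 + eps))
  se <- sqrt((1 / (mu1 + eps) + disp) / n1 + (1 / (mu0 + eps) + disp) / n0)
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  .new_difftable(rownames(m), b / log(2), z, p, alpha)
}

#' Import externally computed differential functions
#'
#' Consumes a differential-analysis results TSV (e.g. from a full count
#' pipeline run outside this package) and returns the functions passing the
#' adjusted-p cutoff, for use as [mangosteenDifferential()] input.
#'
#' @param path TSV with a feature-ID column (`feature`, or the first
#'   column) and an adjusted-p column (`padj`).
#' @param alpha inclusive adjusted-p cutoff.
#' @return Character vector of function IDs.
#' @export
importDifferential <- function(path, alpha = 0.2) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(character(0))
  idcol <- if ("feature" %in% names(df)) "feature" else names(df)[1]
  if (!"padj" %in% names(df))
    stop("expected an adjusted-p column named 'padj' in ", path)
  sort(unique(as.character(df[[idcol]][!is.na(df$padj) & df$padj <= alpha])))
}

#' Differential metabolites by t-test on log intensities
#'
#' The measured-metabolome (and regression-predicted) differential test:
#' per metabolite, zeros are imputed with that metabolite's minimum nonzero
#' value across all samples, intensities are natural-log transformed, and a
#' two-sided Student's t-test (pooled variance by default) compares case
#' against control, followed by BH adjustment and flagging at `alpha`.
#' All-zero metabolites are excluded with a warning (no minimum nonzero
#' value exists).
#'
#' @param metab an [AbundanceTable-class] of metabolite intensities,
#'   prevalence-filtered upstream.
#' @inheritParams nbWaldDiffFunctions
#' @param pooled use the pooled-variance t-test (`TRUE`, classical
#'   Student's); `FALSE` switches to Welch.
#' @return A DiffTable data.frame (log2fc is the case-control difference of
#'   mean log intensities, rescaled to base 2).
#' @export
diffMetabolitesTtest <- function(metab, groups = NULL, caseLabel = NULL,
                                 alpha = 0.2, pooled = TRUE) {
  stopifnot(is(metab, "AbundanceTable"))
  g <- .split_groups(metab, groups)
  lv <- sort(unique(g))
  case <- if (is.null(caseLabel)) lv[1] else caseLabel
  ctrl <- setdiff(lv, case)
  if (sum(g == case) < 2 || sum(g == ctrl) < 2) stop("each group needs n >= 2")
  m <- abundances(metab)
  allzero <- rowSums(m > 0) == 0
  if (any(allzero)) {
    warning(sprintf("%d all-zero metabolite(s) excluded from the t-test",
                    sum(allzero)))
    m <- m[!allzero, , drop = FALSE]
  }
  if (!nrow(m)) return(.new_difftable(character(0), numeric(0), numeric(0),
                                      numeric(0), alpha))
  ## impute zeros with the per-metabolite minimum nonzero value, then ln
  minnz <- apply(m, 1, function(x) min(x[x > 0]))
  imput <- m
  for (i in seq_len(nrow(m))) imput[i, imput[i, ] == 0] <- minnz[i]
  lx <- log(imput)
  i1 <- which(g == case); i0 <- which(g == ctrl)
  res <- t(apply(lx, 1, function(x) {
    if (sd(x[i1]) == 0 && sd(x[i0]) == 0) {
      ## degenerate: no variance; equal means => no evidence
      d <- mean(x[i1]) - mean(x[i0])
      return(c(d, if (d == 0) 0 else Inf, if (d == 0) 1 else 0))
    }
    tt <- t.test(x[i1], x[i0], var.equal = pooled)
    c(mean(x[i1]) - mean(x[i0]), unname(tt$statistic), tt$p.value)
  }))
  .new_difftable(rownames(m), res[, 1] / log(2), res[, 2], res[, 3], alpha)
}

#' Differential compounds by Wilcoxon rank-sum test
#'
#' The differential test for signed predicted metabolomes (CMP scores mix
#' positive and negative values, so log transformation is unavailable): per
#' compound, a two-sided Wilcoxon rank-sum test of case against control
#' (exact when the combined n is at most 20 and the values are untied;
#' normal approximation with tie correction otherwise), BH adjustment,
#' flagging at `alpha`. A compound whose values are all tied yields p = 1.
#'
#' @param pred a [CMPMatrix-class] (or [AbundanceTable-class]).
#' @inheritParams nbWaldDiffFunctions
#' @return A DiffTable data.frame (`log2fc` is `NA`: rank tests carry no
#'   fold change; `stat` is the rank-sum W).
#' @export
diffMetabolitesRanksum <- function(pred, groups = NULL, caseLabel = NULL,
                                   alpha = 0.2) {
  stopifnot(is(pred, "SummarizedExperiment"))
  g <- .split_groups(pred, groups)
  lv <- sort(unique(g))
  case <- if (is.null(caseLabel)) lv[1] else caseLabel
  ctrl <- setdiff(lv, case)
  if (sum(g == case) < 2 || sum(g == ctrl) < 2) stop("each group needs n >= 2")
  m <- abundances(pred)
  i1 <- which(g == case); i0 <- which(g == ctrl)
  res <- t(apply(m, 1, function(x) {
    if (length(unique(x)) == 1) return(c(length(i1) * length(i0) / 2, 1))
    exact <- (length(i1) + length(i0)) <= 20 && !anyDuplicated(x)
    wt <- suppressWarnings(wilcox.test(x[i1], x[i0], exact = exact,
                                       correct = !exact))
    c(unname(wt$statistic), wt$p.value)
  }))
  .new_difftable(rownames(m), NA_real_, res[, 1], res[, 2], alpha)
}

#' Differential features of a DiffTable
#'
#' @param diff a DiffTable data.frame.
#' @return Character vector of features flagged significant.
#' @export
differentialFeatures <- function(diff) {
  sort(diff$feature[diff$significant])
}

#' Write a DiffTable as TSV
#'
#' @param diff a DiffTable data.frame.
#' @param path file path.
#' @export
writeDiffTable <- function(diff, path) {
  write.table(diff, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
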