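#' Training filters for regression-based metabolite prediction
#'
#' Converts paired metabolite and function tables to per-sample relative
#' abundance (restricted to their shared samples) and keeps features with
#' prevalence strictly over `prevalenceMin` and mean relative abundance
#' strictly over `meanRelabundMin` -- the standard pre-training filters of
#' microbiome-to-metabolome regression (defaults: over 10% prevalence, over
#' 0.01% mean relative abundance).
#'
#' @param metab an [AbundanceTable-class] of metabolite intensities.
#' @param funcs an [AbundanceTable-class] of function abundances.
#' @param prevalenceMin prevalence threshold (strict).
#' @param meanRelabundMin mean relative-abundance threshold (strict).
#' @return List with elements `metab` and `funcs`: filtered tables on the
#'   relative-abundance scale, same sample order.
#' @export
filterTrainingFeatures <- function(metab, funcs, prevalenceMin = 0.10,
                                   meanRelabundMin = 1e-4) {
  stopifnot(is(metab, "AbundanceTable"), is(funcs, "AbundanceTable"))
  shared <- intersect(sampleIDs(metab), sampleIDs(funcs))
  if (!length(shared)) stop("metabolite and function tables share no samples")
  one <- function(tab) {
    tab <- tab[, shared]
    m <- .relabund(abundances(tab))
    keep <- rowMeans(m > 0) > prevalenceMin & rowMeans(m) > meanRelabundMin
    .retable("AbundanceTable", m[keep, , drop = FALSE], tab)
  }
  list(metab = one(metab), funcs = one(funcs))
}

.relabund <- function(m) {
  cs <- colSums(m)
  if (any(cs <= 0)) stop("sample(s) with zero total abundance: ",
                         paste(head(colnames(m)[cs <= 0], 3), collapse = ", "))
  sweep(m, 2, cs, "/")
}

#' Arcsine-square-root variance stabilization
#'
#' Elementwise `asin(sqrt(x))` of relative abundances in `[0, 1]`; the
#' standard variance-stabilizing transform for compositional proportions
#' ahead of linear modelling. `inverseTransformAbundance()` maps
#' transformed-scale values back via `sin(y)^2` after clipping to
#' `[0, pi/2]`, so back-transformed predictions are always in `[0, 1]`.
#'
#' @param table an [AbundanceTable-class] of relative abundances.
#' @return The transformed (or back-transformed) table.
#' @export
transformRelativeAbundance <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  m <- abundances(table)
  if (any(m < 0 | m > 1))
    stop("values must be relative abundances in [0, 1]")
  .retable("AbundanceTable", asin(sqrt(m)), table)
}

#' @rdname transformRelativeAbundance
#' @export
inverseTransformAbundance <- function(table) {
  stopifnot(is(table, "AbundanceTable"))
  m <- abundances(table)
  .retable("AbundanceTable", sin(pmin(pmax(m, 0), pi / 2))^2, table)
}

#' Fit per-metabolite elastic-net models
#'
#' One elastic-net regression per metabolite on paired, filtered,
#' arcsine-square-root transformed tables: the penalty strength is chosen by
#' internal cross-validation (fixed fold assignment derived from the seed,
#' shared across the mixing grid) and the mixing parameter by the smallest
#' cross-validated error over `alphaGrid`. Constant metabolites are skipped
#' with a warning. Models are independent across metabolites, so results
#' never depend on fitting order.
#'
#' @param metab,funcs matched [AbundanceTable-class] objects from
#'   [filterTrainingFeatures()] + [transformRelativeAbundance()].
#' @param seed integer; all cross-validation randomness derives from it.
#' @param alphaGrid elastic-net mixing values to scan.
#' @param nfolds internal cross-validation folds.
#' @return A [ModelSet-class].
#' @export
fitMetaboliteModels <- function(metab, funcs, seed = 1,
                                alphaGrid = c(0.2, 0.5, 0.8, 1),
                                nfolds = 5) {
  stopifnot(is(metab, "AbundanceTable"), is(funcs, "AbundanceTable"))
  if (!identical(sampleIDs(metab), sampleIDs(funcs)))
    funcs <- funcs[, sampleIDs(metab)]
  n <- ncol(metab)
  if (n < 10) stop("need >= 10 samples to fit metabolite models, got ", n)
  if (nrow(funcs) < 2) stop("need >= 2 candidate functions after filtering")
  X <- t(abundances(funcs))
  Y <- abundances(metab)
  models <- list()
  skipped <- character(0)
  for (cpd in rownames(Y)) {
    y <- Y[cpd, ]
    if (sd(y) == 0) { skipped <- c(skipped, cpd); next }
    set.seed(stageSeed(seed, paste0("cv:", cpd)))
    foldid <- sample(rep(seq_len(nfolds), length.out = n))
    best <- NULL
    for (a in alphaGrid) {
      cv <- glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid,
                              family = "gaussian", standardize = TRUE)
      err <- cv$cvm[cv$index["min", 1]]
      if (is.null(best) || err < best$err)
        best <- list(err = err, cv = cv, alpha = a)
    }
    cf <- as.matrix(glmnet::coef.glmnet(best$cv, s = "lambda.min"))[, 1]
    nz <- cf[-1][cf[-1] != 0]
    models[[cpd]] <- list(coefficients = nz, intercept = unname(cf[1]),
                          size = length(nz), alpha = best$alpha,
                          lambda = unname(best$cv$lambda.min))
  }
  if (length(skipped))
    warning(sprintf("%d constant metabolite(s) skipped (e.g. %s)",
                    length(skipped), paste(head(skipped, 3), collapse = ", ")))
  new("ModelSet", models = models, features = rownames(abundances(funcs)),
      provenance = list(seed = seed,
                        studies = unique(unname(sampleStudies(metab)))))
}

#' Prune small metabolite models
#'
#' Drops every model whose size (number of functions with nonzero
#' coefficients) is below `minSize`. The default removes size-1 models:
#' a metabolite predicted by a single function is prone to spurious
#' association.
#'
#' @param models a [ModelSet-class].
#' @param minSize smallest surviving model size.
#' @return The pruned [ModelSet-class].
#' @export
pruneModels <- function(models, minSize = 2L) {
  stopifnot(is(models, "ModelSet"))
  keep <- modelSizes(models) >= minSize
  new("ModelSet", models = models@models[keep], features = models@features,
      provenance = models@provenance)
}

#' Predict a metabolome from fitted models
#'
#' Applies a [ModelSet-class] to a function table: the table is converted
#' to relative abundance, aligned to the models' training features
#' (functions unseen in training are ignored; training functions absent
#' from the table contribute zero), arcsine-square-root transformed, and
#' pushed through each model. Predictions are clipped to the valid
#' transformed range and back-transformed, so the output is a non-negative
#' relative-abundance-scale metabolome.
#'
#' @param models a [ModelSet-class].
#' @param funcs an [AbundanceTable-class] of raw function abundances.
#' @return An [AbundanceTable-class], metabolites by samples.
#' @export
predictMetabolites <- function(models, funcs) {
  stopifnot(is(models, "ModelSet"), is(funcs, "AbundanceTable"))
  m <- .relabund(abundances(funcs))
  X <- matrix(0, length(models@features), ncol(m),
              dimnames = list(models@features, colnames(m)))
  shared <- intersect(models@features, rownames(m))
  X[shared, ] <- m[shared, , drop = FALSE]
  X <- asin(sqrt(X))
  pred <- matrix(0, length(models@models), ncol(m),
                 dimnames = list(names(models@models), colnames(m)))
  for (cpd in names(models@models)) {
    mod <- models@models[[cpd]]
    yhat <- mod$intercept +
      as.numeric(crossprod(X[names(mod$coefficients), , drop = FALSE],
                           mod$coefficients))
    pred[cpd, ] <- sin(pmin(pmax(yhat, 0), pi / 2))^2
  }
  .retable("AbundanceTable", pred, funcs)
}

#' Leave-one-study-out metabolome prediction
#'
#' The multi-study validation protocol: for each study S, models are
#' trained on all other studies (training filters, transform, elastic-net
#' fit, size pruning) and S's metabolome is predicted on the back-
#' transformed relative-abundance scale. Every sample is predicted exactly
#' once; the folds' metabolite sets are unioned (a metabolite unmodelled in
#' some fold predicts 0 there).
#'
#' @param metab,funcs paired [AbundanceTable-class] objects with study IDs
#'   in `colData$study` and shared sample IDs.
#' @param seed integer seed driving all fitting randomness.
#' @param thresholds a [metaboThresholds()] list (training filters and
#'   minimum model size are consumed here).
#' @param alphaGrid,nfolds passed to [fitMetaboliteModels()].
#' @return List: `predicted` (an [AbundanceTable-class] over all samples),
#'   `models` (per-study pruned [ModelSet-class] list), `folds` (study IDs).
#' @export
losoPredict <- function(metab, funcs, seed = 1, thresholds = metaboThresholds(),
                        alphaGrid = c(0.2, 0.5, 0.8, 1), nfolds = 5) {
  stopifnot(is(metab, "AbundanceTable"), is(funcs, "AbundanceTable"))
  shared <- intersect(sampleIDs(metab), sampleIDs(funcs))
  metab <- metab[, shared]; funcs <- funcs[, shared]
  studies <- sampleStudies(metab)
  if (is.null(studies)) stop("colData$study is required for leave-one-study-out")
  folds <- sort(unique(unname(studies)))
  if (length(folds) < 2)
    stop("leave-one-study-out needs >= 2 studies; with a single study use a ",
         "plain train/test split via fitMetaboliteModels()/predictMetabolites()")
  fits <- list()
  preds <- list()
  for (s in folds) {
    train <- names(studies)[studies != s]
    test <- names(studies)[studies == s]
    flt <- filterTrainingFeatures(metab[, train], funcs[, train],
                                  prevalenceMin = thresholds$ml_prevalence,
                                  meanRelabundMin = thresholds$ml_mean_relabund)
    fit <- fitMetaboliteModels(transformRelativeAbundance(flt$metab),
                               transformRelativeAbundance(flt$funcs),
                               seed = stageSeed(seed, paste0("loso:", s)),
                               alphaGrid = alphaGrid, nfolds = nfolds)
    fit <- pruneModels(fit, thresholds$min_model_size)
    fits[[s]] <- fit
    preds[[s]] <- abundances(predictMetabolites(fit, funcs[, test]))
  }
  cpds <- sort(unique(unlist(lapply(preds, rownames), use.names = FALSE)))
  out <- matrix(0, length(cpds), length(shared),
                dimnames = list(cpds, shared))
  for (s in folds)
    out[rownames(preds[[s]]), colnames(preds[[s]])] <- preds[[s]]
  list(predicted = .retable("AbundanceTable", out, metab),
       models = fits, folds = folds)
}
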