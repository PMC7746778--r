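## paired tables where two functions drive one metabolite exactly
linear_cohort <- function(n = 60, n_noise = 8, seed = 101, studies = 2) {
  set.seed(seed)
  f <- matrix(rexp((2 + n_noise) * n, 1), 2 + n_noise, n,
              dimnames = list(c("ko:F1", "ko:F2",
                                sprintf("ko:N%02d", seq_len(n_noise))),
                              sprintf("s%03d", seq_len(n))))
  rel <- sweep(f, 2, colSums(f), "/")
  y <- 0.4 * rel["ko:F1", ] + 0.6 * rel["ko:F2", ]
  ## complement row keeps column sums at 1, so the relative-abundance
  ## conversion inside the filters leaves y itself untouched
  m <- rbind("cpd:Y" = y, "cpd:Z" = 1 - y)
  study <- rep(sprintf("study%d", seq_len(studies)), length.out = n)
  group <- rep(c("case", "control"), length.out = n)
  list(funcs = AbundanceTable(f, group = group, study = study),
       metab = AbundanceTable(m, group = group, study = study))
}

test_that("training filters apply both rules on the relative-abundance scale", {
  m <- matrix(0, 6, 20, dimnames = list(sprintf("ko:K%d", 1:6),
                                        sprintf("s%02d", 1:20)))
  m[1, 1] <- 1          # 5% prevalence: below 10%, removed
  m[2, ] <- 1000        # everywhere, huge: kept
  m[3, 1:3] <- 1        # 15% prevalence but tiny mean relabund
  m[4, ] <- 1           # everywhere, mean relabund ~1e-3: kept
  m[5, 1:19] <- 5       # 95%: kept
  m[6, 1:2] <- 2        # 10% exactly: strict inequality, removed
  mm <- m; rownames(mm) <- sub("ko:K", "cpd:C", rownames(m))
  flt <- filterTrainingFeatures(AbundanceTable(mm), AbundanceTable(m),
                                prevalenceMin = 0.10, meanRelabundMin = 1e-4)
  rel <- sweep(m, 2, colSums(m), "/")
  keep <- rowMeans(rel > 0) > 0.10 & rowMeans(rel) > 1e-4
  expect_setequal(featureIDs(flt$funcs), rownames(m)[keep])
  expect_false("ko:K1" %in% featureIDs(flt$funcs))
  expect_false("ko:K6" %in% featureIDs(flt$funcs))
  expect_true(all(c("ko:K2", "ko:K5") %in% featureIDs(flt$funcs)))
  ## output is on the relative-abundance scale
  expect_equal(unname(colSums(abundances(flt$funcs)) <= 1), rep(TRUE, 20))
  ## disjoint samples error
  odd <- AbundanceTable(matrix(1, 1, 1, dimnames = list("cpd:C1", "other")))
  expect_error(filterTrainingFeatures(odd, AbundanceTable(m)), "no samples")
})

test_that("arcsine-square-root transform matches closed forms and inverts", {
  m <- matrix(c(0, 1, 0.25, 0.5), 2, 2,
              dimnames = list(c("cpd:A", "cpd:B"), c("s1", "s2")))
  tr <- transformRelativeAbundance(AbundanceTable(m))
  expect_equal(abundances(tr)["cpd:A", "s1"], 0)
  expect_equal(abundances(tr)["cpd:B", "s1"], pi / 2)
  expect_equal(abundances(tr)["cpd:A", "s2"], asin(0.5))
  back <- inverseTransformAbundance(tr)
  expect_equal(abundances(back), m, tolerance = 1e-12)
  expect_error(transformRelativeAbundance(AbundanceTable(m * 3)), "\\[0, 1\\]")
})

test_that("an exact linear metabolite is recovered with model size >= 2", {
  lc <- linear_cohort()
  flt <- filterTrainingFeatures(lc$metab, lc$funcs)
  fit <- fitMetaboliteModels(transformRelativeAbundance(flt$metab),
                             transformRelativeAbundance(flt$funcs),
                             seed = 7)
  expect_true("cpd:Y" %in% names(fit@models))
  expect_gte(fit@models[["cpd:Y"]]$size, 2)
  expect_true(all(c("ko:F1", "ko:F2") %in%
                    names(fit@models[["cpd:Y"]]$coefficients)))
  ## determinism: same seed, identical coefficients
  fit2 <- fitMetaboliteModels(transformRelativeAbundance(flt$metab),
                              transformRelativeAbundance(flt$funcs),
                              seed = 7)
  expect_identical(fit@models, fit2@models)
})

test_that("a pure-noise metabolite shows no held-out association", {
  set.seed(55)
  n <- 60
  f <- matrix(rexp(40 * n), 40, n,
              dimnames = list(sprintf("ko:R%02d", 1:40),
                              sprintf("s%03d", 1:n)))
  y <- runif(n, 0, 1e-3)
  m <- matrix(y, 1, n, dimnames = list("cpd:noise", colnames(f)))
  train <- 1:40; test <- 41:60
  fit <- fitMetaboliteModels(
    transformRelativeAbundance(AbundanceTable(m[, train, drop = FALSE])),
    transformRelativeAbundance(
      AbundanceTable(sweep(f[, train], 2, colSums(f[, train]), "/"))),
    seed = 3)
  if ("cpd:noise" %in% names(fit@models) &&
      fit@models[["cpd:noise"]]$size > 0) {
    pred <- predictMetabolites(fit, AbundanceTable(f[, test]))
    r <- suppressWarnings(cor(abundances(pred)["cpd:noise", ], y[test],
                              method = "spearman"))
    if (!is.na(r)) expect_lt(abs(r), 0.6)
  } else succeed("noise metabolite yielded an empty model")
})

test_that("constant metabolites are skipped with a warning", {
  lc <- linear_cohort()
  m <- abundances(lc$metab)
  m["cpd:Z", ] <- 0.001
  flat <- AbundanceTable(m, group = sampleGroups(lc$metab),
                         study = sampleStudies(lc$metab))
  expect_warning(
    fit <- fitMetaboliteModels(
      transformRelativeAbundance(flat),
      transformRelativeAbundance(
        AbundanceTable(sweep(abundances(lc$funcs), 2,
                             colSums(abundances(lc$funcs)), "/"))),
      seed = 2),
    "constant")
  expect_false("cpd:Z" %in% names(fit@models))
})

test_that("pruning drops models below the size threshold", {
  mk <- function(size) list(coefficients = setNames(rep(0.5, size),
                                                    sprintf("ko:K%d", seq_len(size))),
                            intercept = 0.1, size = size)
  ms <- new("ModelSet",
            models = list("cpd:A" = mk(1), "cpd:B" = mk(2), "cpd:C" = mk(5),
                          "cpd:D" = mk(0)),
            features = sprintf("ko:K%d", 1:5),
            provenance = list(seed = 1))
  pruned <- pruneModels(ms, 2)
  expect_setequal(names(pruned@models), c("cpd:B", "cpd:C"))
  sizes <- c("cpd:A" = 1, "cpd:B" = 2, "cpd:C" = 5, "cpd:D" = 0)
  expect_setequal(names(pruneModels(ms, 3)@models), names(sizes)[sizes >= 3])
})

test_that("leave-one-study-out predicts each sample once with high held-out fidelity", {
  lc <- linear_cohort(n = 80, seed = 77)
  loso <- losoPredict(lc$metab, lc$funcs, seed = 5)
  expect_identical(sort(loso$folds), c("study1", "study2"))
  pred <- loso$predicted
  expect_setequal(sampleIDs(pred), sampleIDs(lc$metab))
  expect_true(all(abundances(pred) >= 0))
  expect_true("cpd:Y" %in% featureIDs(pred))
  r <- cor(abundances(pred)["cpd:Y", sampleIDs(lc$metab)],
           abundances(lc$metab)["cpd:Y", ], method = "spearman")
  expect_gte(r, 0.9)
  ## determinism of the whole protocol
  loso2 <- losoPredict(lc$metab, lc$funcs, seed = 5)
  expect_identical(abundances(loso$predicted), abundances(loso2$predicted))
})

test_that("single-study input errors with advice; unseen functions are ignored", {
  lc <- linear_cohort(studies = 1)
  expect_error(losoPredict(lc$metab, lc$funcs, seed = 1), "train/test split")
  ## prediction with extra functions absent from training still works
  lc2 <- linear_cohort()
  flt <- filterTrainingFeatures(lc2$metab, lc2$funcs)
  fit <- fitMetaboliteModels(transformRelativeAbundance(flt$metab),
                             transformRelativeAbundance(flt$funcs), seed = 1)
  f_extra <- rbind(abundances(lc2$funcs),
                   "ko:EXTRA" = rexp(ncol(lc2$funcs)))
  pred <- predictMetabolites(fit, AbundanceTable(f_extra))
  expect_equal(dim(abundances(pred)),
               c(length(fit@models), ncol(f_extra)))
  expect_true(all(is.finite(abundances(pred))))
})
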