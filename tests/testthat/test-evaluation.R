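test_that("set metrics reproduce hand counts and degenerate conventions", {
  m <- setMetrics(c("a", "b", "c", "d"), c("c", "d", "e"))
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 4 / 7)
  perfect <- setMetrics(c("a", "b"), c("b", "a"))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  none <- setMetrics(c("a", "b"), c("c", "d"))
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))
  expect_warning(empty <- setMetrics(character(0), character(0)), "empty")
  expect_equal(c(empty$precision, empty$recall, empty$f1), c(0, 0, 0))
})

test_that("set metrics equal the confusion-matrix oracle on random set pairs", {
  set.seed(13)
  universe <- sprintf("cpd:C%03d", 1:60)
  for (i in 1:1000) {
    pred <- sample(universe, sample(0:30, 1))
    meas <- sample(universe, sample(0:30, 1))
    got <- suppressWarnings(setMetrics(pred, meas))
    want <- set_metrics_oracle(pred, meas)
    expect_identical(got[c("tp", "fp", "fn")], want[c("tp", "fp", "fn")])
    expect_equal(got$f1, want$f1)
    ## F1 never exceeds max(P, R); F1 = 1 iff the sets match and are nonempty
    expect_lte(got$f1, max(got$precision, got$recall) + 1e-12)
    if (got$f1 == 1) expect_setequal(pred, meas)
  }
})

test_that("Procrustes m12^2 vanishes for a configuration and its similarity copy", {
  set.seed(17)
  m <- matrix(rexp(12 * 10), 12, 10,
              dimnames = list(sprintf("cpd:C%02d", 1:12),
                              sprintf("s%02d", 1:10)))
  meas <- AbundanceTable(m)
  self <- procrustesCompare(meas, meas, nPerm = 49, seed = 1)
  expect_lt(self$m12_squared, 1e-10)
  expect_equal(self$correlation, 1, tolerance = 1e-8)
  ## rotate + scale + translate the sample configuration: still m12^2 = 0
  conf <- t(m)
  theta <- 0.7
  R <- diag(nrow(m))
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- 3.7 * conf %*% R + matrix(5, nrow(conf), ncol(conf))
  dimnames(moved) <- dimnames(conf)
  moved_tab <- CMPMatrix(t(moved))
  sim <- procrustesCompare(moved_tab, meas, nPerm = 49, seed = 1)
  expect_lt(sim$m12_squared, 1e-10)
})

test_that("independent random matrices score near-maximal m12^2 without significance", {
  ## m12^2 approaches 1 for unrelated configurations once the sample count
  ## well exceeds the configuration rank (here 60 samples, 10 compounds);
  ## with rank comparable to n, the optimal rotation overfits and m12^2 drops
  set.seed(19)
  a <- matrix(rnorm(10 * 60), 10, 60,
              dimnames = list(sprintf("cpd:A%02d", 1:10),
                              sprintf("s%02d", 1:60)))
  b <- matrix(rnorm(10 * 60), 10, 60,
              dimnames = list(sprintf("cpd:B%02d", 1:10), colnames(a)))
  res <- procrustesCompare(CMPMatrix(a), AbundanceTable(abs(b)),
                           nPerm = 199, seed = 2)
  expect_gt(res$m12_squared, 0.8)
  expect_gt(res$p_value, 0.05)
  expect_equal(res$correlation, sqrt(1 - res$m12_squared), tolerance = 1e-8)
})

test_that("Procrustes is symmetric under argument swap", {
  set.seed(23)
  a <- matrix(rexp(15 * 12), 15, 12,
              dimnames = list(sprintf("cpd:A%02d", 1:15),
                              sprintf("s%02d", 1:12)))
  b <- matrix(rexp(15 * 12), 15, 12,
              dimnames = list(sprintf("cpd:B%02d", 1:15), colnames(a)))
  r1 <- procrustesCompare(AbundanceTable(a), AbundanceTable(b),
                          nPerm = 9, seed = 1)
  r2 <- procrustesCompare(AbundanceTable(b), AbundanceTable(a),
                          nPerm = 9, seed = 1)
  expect_equal(r1$m12_squared, r2$m12_squared, tolerance = 1e-8)
  ## fewer than 4 shared samples is refused
  expect_error(procrustesCompare(AbundanceTable(a[, 1:3]),
                                 AbundanceTable(b[, 1:3]), nPerm = 9),
               ">= 4")
})

test_that("coverage null honours forced cases and the hypergeometric mean", {
  measured <- sprintf("cpd:C%02d", 1:10)
  obs <- setMetrics(measured, measured)
  forced <- nullCoverage(measured, k = 10, measured = measured,
                         observed = obs, nNull = 29, seed = 1)
  expect_true(all(forced$replicates == 1))
  disjoint <- nullCoverage(sprintf("cpd:D%02d", 1:20), k = 5,
                           measured = measured,
                           observed = setMetrics("cpd:D01", measured),
                           nNull = 29, seed = 1)
  expect_true(all(disjoint$replicates == 0))
  ## mean replicate precision ~ |measured| / |dictionary| = 0.1
  dict <- sprintf("cpd:C%03d", 1:100)
  nc <- nullCoverage(dict, k = 10, measured = dict[1:10],
                     observed = setMetrics(dict[1:10], dict[1:10]),
                     nNull = 400, seed = 5)
  expect_lt(abs(mean(attr(nc, "precision")) - 0.1), 0.02)
  expect_error(nullCoverage(dict, k = 200, measured = dict[1:5],
                            observed = obs), "dictionary")
})

test_that("empirical p lies on the add-one grid and is never zero", {
  set.seed(29)
  nulls <- runif(99)
  for (obs in c(-1, 0.5, 2)) {
    p <- empiricalP(nulls, obs)
    expect_true(p %in% (1:100 / 100))
  }
  expect_equal(empiricalP(rep(0, 99), 1), 1 / 100)
  expect_equal(empiricalP(rep(2, 99), 1), 1)
})

test_that("the identity relabelling reproduces the observed differential metric", {
  ref <- makeReference(nKo = 40, nRxn = 30, nCpd = 40, seed = 31)
  sim <- simulatePairedCohort(ref, nCase = 15, nCtrl = 15, nPlanted = 4,
                              foldChange = 6, seed = 32)
  funcs_f <- prevalenceFilter(sim$funcs, 0.05)
  dt <- nbWaldDiffFunctions(funcs_f, caseLabel = "case", alpha = 0.2)
  pred_set <- mangosteenDifferential(differentialFeatures(dt), ref)
  measured_diff <- sprintf("cpd:C%05d", 1:12)
  obs <- setMetrics(pred_set, measured_diff)
  ## rerunning the null machinery with the identity permutation by hand
  tab <- funcs_f
  rownames(tab) <- featureIDs(funcs_f)
  dt2 <- nbWaldDiffFunctions(tab, caseLabel = "case", alpha = 0.2)
  pred2 <- mangosteenDifferential(differentialFeatures(dt2), ref)
  expect_identical(setMetrics(pred2, measured_diff)$f1, obs$f1)
})

test_that("pipeline comparison matches exact signed-rank enumeration", {
  ## all-positive differences 1..6: two-sided exact p = 2/64
  a <- c(0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  b <- a - (1:6) / 10
  tab <- rbind(A = a, B = b)
  p <- comparePipelinesSignedRank(tab)
  expect_equal(p["A", "B"], 2 / 64)
  expect_equal(p["B", "A"], p["A", "B"])  # symmetry under swap
  expect_true(is.na(p["A", "A"]))
  ## identical pipelines: all differences zero, p undefined
  tied <- rbind(A = a, B = a)
  expect_true(is.na(comparePipelinesSignedRank(tied)["A", "B"]))
  ## missing pairs dropped pairwise
  c_ <- c(NA, b[-1])
  p3 <- comparePipelinesSignedRank(rbind(A = a, C = c_))
  expect_false(is.na(p3["A", "C"]))
})
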