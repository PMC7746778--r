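test_that("prevalence filter keeps features at exactly the threshold", {
  m <- matrix(0, 3, 20, dimnames = list(c("cpd:A", "cpd:B", "cpd:C"),
                                        paste0("s", 1:20)))
  m["cpd:A", 1] <- 5      # 1/20 = exactly 5%
  m["cpd:C", 1:3] <- 2    # 15%
  tab <- AbundanceTable(m)
  kept <- featureIDs(prevalenceFilter(tab, 0.05))
  expect_setequal(kept, c("cpd:A", "cpd:C"))  # B (0 samples) removed
  ## brute-force count over a random toy table
  set.seed(4)
  m2 <- matrix(rbinom(200, 1, 0.2) * rexp(200), 10, 20,
               dimnames = list(sprintf("cpd:X%02d", 1:10), paste0("s", 1:20)))
  tab2 <- AbundanceTable(m2)
  expect_setequal(featureIDs(prevalenceFilter(tab2, 0.15)),
                  rownames(m2)[rowSums(m2 > 0) / 20 >= 0.15])
})

test_that("prevalence of signed CMP scores counts |value| above tolerance", {
  ## cpd:A detected in 2/4 samples (1e-15 is below tolerance); cpd:B in 1/4
  m <- matrix(c(-3, 0, 0.5, 0.2, 1e-15, 0, 0, 0), 2, 4,
              dimnames = list(c("cpd:A", "cpd:B"), paste0("s", 1:4)))
  cmp <- CMPMatrix(m)
  expect_identical(featureIDs(prevalenceFilter(cmp, 0.5)), "cpd:A")
})

test_that("BH adjustment matches the independent step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), bh_oracle(p))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("median-of-ratios size factors follow the closed form", {
  m <- matrix(c(2, 4, 8, 4, 8, 16), 3, 2,
              dimnames = list(paste0("ko:K", 1:3), c("s1", "s2")))
  sf <- medianOfRatios(AbundanceTable(m))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  ## identical samples give unit factors
  mm <- cbind(s1 = c(3, 9, 5), s2 = c(3, 9, 5), s3 = c(3, 9, 5))
  rownames(mm) <- paste0("ko:K", 1:3)
  expect_equal(unname(medianOfRatios(AbundanceTable(mm))), rep(1, 3))
  ## brute-force median-of-ratios on a 4-sample toy
  set.seed(5)
  m4 <- matrix(rpois(24, 50) + 1, 6, 4,
               dimnames = list(paste0("ko:K", 1:6), paste0("s", 1:4)))
  geo <- exp(rowMeans(log(m4)))
  raw <- apply(m4 / geo, 2, median)
  expect_equal(unname(medianOfRatios(AbundanceTable(m4))),
               unname(raw / exp(mean(log(raw)))))
  ## all-zero-containing features only
  mz <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(paste0("ko:K", 1:2), c("s1", "s2")))
  expect_error(medianOfRatios(AbundanceTable(mz)), "pseudocount")
})

test_that("NB Wald test recovers planted fold changes with correct direction", {
  ref <- makeReference(nKo = 60, nRxn = 40, nCpd = 50, seed = 21)
  sim <- simulatePairedCohort(ref, nCase = 30, nCtrl = 30, nPlanted = 5,
                              foldChange = 8, seed = 22)
  dt <- nbWaldDiffFunctions(prevalenceFilter(sim$funcs, 0.05),
                            caseLabel = "case", alpha = 0.2)
  hits <- differentialFeatures(dt)
  planted <- sim$truth$planted_functions
  expect_gte(sum(planted %in% hits) / length(planted), 0.9)
  ## planted functions are case-elevated: positive log2 fold change
  expect_true(all(dt[intersect(planted, hits), "log2fc"] > 0))
  ## DiffTable invariants
  expect_true(all(dt$padj >= dt$pvalue - 1e-12))
  expect_true(all(dt$padj >= 0 & dt$padj <= 1))
  expect_identical(dt$significant, dt$padj <= 0.2)
})

test_that("a case-absent function gets a negative effect and is flagged", {
  set.seed(30)
  m <- rbind(matrix(rpois(10 * 12, 40), 10, 12),
             c(rep(0, 6), rpois(6, 200)))
  dimnames(m) <- list(sprintf("ko:K%02d", 1:11), paste0("s", 1:12))
  tab <- AbundanceTable(m, group = rep(c("case", "control"), each = 6))
  dt <- nbWaldDiffFunctions(tab, caseLabel = "case", alpha = 0.2)
  expect_true(dt["ko:K11", "significant"])
  expect_lt(dt["ko:K11", "log2fc"], 0)
})

test_that("imported differential results respect the inclusive threshold", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("feature\tpadj", "ko:K1\t0.1", "ko:K2\t0.3", "ko:K3\t0.2"), p)
  expect_setequal(importDifferential(p, 0.2), c("ko:K1", "ko:K3"))
  writeLines("feature\tpadj", p)
  expect_length(importDifferential(p, 0.2), 0)
  ## 20-row threshold scan against brute force
  set.seed(6)
  padj <- round(runif(20), 3)
  ids <- sprintf("ko:K%02d", 1:20)
  writeLines(c("feature\tpadj", paste(ids, padj, sep = "\t")), p)
  expect_setequal(importDifferential(p, 0.2), ids[padj <= 0.2])
  writeLines(c("feature\twrong", "ko:K1\t0.1"), p)
  expect_error(importDifferential(p), "padj")
})

test_that("metabolite t-test imputes zeros, logs, and matches the closed form", {
  ## {1,1,1} vs {e^2,e^2,e^2} has log difference -2 but zero variance;
  ## perturb minimally so the pooled t has 4 df
  x <- c(1, 1, 1.0001, exp(2), exp(2), exp(2) * 1.0001)
  m <- matrix(x, 1, 6, dimnames = list("cpd:A", paste0("s", 1:6)))
  tab <- AbundanceTable(m)
  g <- rep(c("case", "control"), each = 3)
  dt <- diffMetabolitesTtest(tab, groups = setNames(g, colnames(m)),
                             caseLabel = "case")
  lx <- log(x)
  s2 <- (var(lx[1:3]) + var(lx[4:6])) / 2
  tstat <- (mean(lx[1:3]) - mean(lx[4:6])) / sqrt(s2 * (2 / 3))
  expect_equal(dt$stat, tstat, tolerance = 1e-10)
  expect_equal(dt$pvalue, 2 * pt(-abs(tstat), df = 4), tolerance = 1e-10)
  expect_equal(dt$log2fc, (mean(lx[1:3]) - mean(lx[4:6])) / log(2))
})

test_that("zero imputation uses the per-metabolite minimum nonzero value", {
  set.seed(7)
  m <- matrix(rexp(40), 4, 10,
              dimnames = list(sprintf("cpd:X%d", 1:4), paste0("s", 1:10)))
  m[m < 0.3] <- 0
  m[1, ] <- 0  # all-zero metabolite: excluded with a warning
  tab <- AbundanceTable(m, group = rep(c("case", "control"), 5))
  expect_warning(dt <- diffMetabolitesTtest(tab, caseLabel = "case"),
                 "all-zero")
  expect_setequal(dt$feature, rownames(m)[-1])
  ## scaling a metabolite leaves the t statistic unchanged (log-shift cancels)
  m2 <- m[-1, , drop = FALSE]
  tab2 <- AbundanceTable(m2, group = rep(c("case", "control"), 5))
  tab3 <- AbundanceTable(m2 * 137, group = rep(c("case", "control"), 5))
  expect_equal(diffMetabolitesTtest(tab2, caseLabel = "case")$stat,
               diffMetabolitesTtest(tab3, caseLabel = "case")$stat)
})

test_that("rank-sum test reproduces exact small-sample p-values", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("cpd:A", paste0("s", 1:6)))
  g <- setNames(rep(c("case", "control"), each = 3), colnames(m))
  dt <- diffMetabolitesRanksum(CMPMatrix(m), groups = g, caseLabel = "case")
  expect_equal(dt$pvalue, 0.1)  # exact: 2 * (1/20) extreme arrangements... = 0.1
  ## identical groups: p = 1
  m2 <- matrix(rep(c(5, -2, 7), 2), 1, 6, dimnames = dimnames(m))
  expect_equal(diffMetabolitesRanksum(CMPMatrix(m2), groups = g,
                                      caseLabel = "case")$pvalue, 1)
  ## all tied values: p = 1
  m3 <- matrix(4, 1, 6, dimnames = dimnames(m))
  expect_equal(diffMetabolitesRanksum(CMPMatrix(m3), groups = g,
                                      caseLabel = "case")$pvalue, 1)
  ## sign flip leaves p unchanged
  expect_equal(diffMetabolitesRanksum(CMPMatrix(-m), groups = g,
                                      caseLabel = "case")$pvalue, 0.1)
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(8)
  m <- matrix(rnorm(2 * 30), 2, 30,
              dimnames = list(c("cpd:A", "cpd:B"), paste0("s", 1:30)))
  g <- setNames(rep(c("case", "control"), 15), colnames(m))
  p1 <- diffMetabolitesRanksum(CMPMatrix(m), groups = g,
                               caseLabel = "case")$pvalue
  p2 <- diffMetabolitesRanksum(CMPMatrix(exp(m) + m^3), groups = g,
                               caseLabel = "case")$pvalue
  expect_equal(p1, p2)
})

test_that("thresholds validate their ranges and serialize cleanly", {
  th <- metaboThresholds()
  expect_equal(th$alpha_fdr, 0.2)
  expect_equal(th$prevalence_functions, 0.05)
  expect_equal(th$n_null, 99L)
  expect_equal(th$min_model_size, 2L)
  expect_error(metaboThresholds(alpha_fdr = 1.5))
  expect_error(metaboThresholds(n_null = 0))
})
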