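# metabopredict

Predicting the metabolite profile of a gut microbial community from its
sequencing-derived gene content — and measuring honestly how well any such
prediction works.

Comprehensive metabolomics is costly at cohort scale, while microbiome
function tables (KEGG ortholog or reaction counts) are cheap and plentiful.
`metabopredict` implements the three standard prediction strategies side by
side, behind one evaluation framework:

* **Relationship-table lookup** — a reference graph linking gene families
  (KOs) to compounds through reactions, with an EC-number fallback route
  for KOs lacking direct reaction annotations and manual transporter
  links. Every compound linked to an observed function is predicted
  present; every compound linked to a differential function is predicted
  differential.
* **Community metabolic potential (CMP)** — a signed compounds × samples
  score matrix, `CMP[c,s] = Σ_{r∋c} ξ_cr Σ_{f→r} a_fs`, the
  stoichiometry-weighted (ξ) sum of normalized gene abundances (a), used
  directly as a predicted metabolome (positive = net production, negative
  = net consumption).
* **Per-metabolite elastic-net regression** — trained on paired
  microbiome–metabolome tables after standard prevalence/abundance filters
  and arcsine-square-root transformation, validated leave-one-study-out,
  with single-predictor models pruned.

Predictions are scored against a measured metabolome on **occurrence**
(precision / recall / F1 of prevalence-filtered compound sets),
**abundance** (Procrustes `m12²` on PCoA ordinations of Euclidean
distances, with a sample-label permutation test), and **differential
metabolite identification** (minimum-nonzero imputation + log + Student's
t-test for intensity matrices, Wilcoxon rank-sum for signed CMP scores,
BH-adjusted p ≤ 0.2), with two permutation nulls: random compound draws
from the chemical dictionary (coverage) and gene- or metabolite-label
shuffling (differential), 99 repetitions each, add-one empirical p.
A ground-truth-aware synthetic cohort generator makes the whole pipeline
testable with no reference-database downloads.

## Worked example

```r
library(metabopredict)

## the two canonical linkage routes
fx <- methodsFixture()
compoundsForFunction(fx, "ko:K24443")   # direct reactions
#> [1] "cpd:C00001" "cpd:C00502" "cpd:C00545" "cpd:C01114" "cpd:C02753"
compoundsForFunction(fx, "ko:K00046")   # no direct reaction: EC route
#> [1] "cpd:C00003" "cpd:C00004" "cpd:C00005" "cpd:C00006" "cpd:C00080"
#> [6] "cpd:C00257" "cpd:C01062"

## a synthetic two-study case/control cohort, two pipelines, full evaluation
cfg <- validateRunConfig(list(
  pipelines = c("mangosteen", "cmp"),
  seed = 42,
  thresholds = list(n_null = 99, n_procrustes_perm = 199),
  synthetic = list(nCase = 20, nCtrl = 20, nPlanted = 5, foldChange = 8)))
report <- runBenchmark(cfg)

report$pipelines$mangosteen$occurrence
#> EvalMetrics: P=0.595 R=0.623 F1=0.608 (tp=66 fp=45 fn=40)
report$pipelines$mangosteen$differential
#> EvalMetrics: P=0.321 R=0.964 F1=0.482 (tp=27 fp=57 fn=1)
report$pipelines$mangosteen$null_differential
#> NullDistribution: observed=0.4821, null mean=0.3847 (n=99), empirical p=0.02
report$pipelines$cmp$procrustes
#> Procrustes: m12^2=0.9234 corr=0.2768 p=0.12 (40 samples, 199 permutations)
```

Reading the numbers: the lookup pipeline recovers nearly all measured
differential metabolites (recall 0.96) at modest precision, because every
compound linked to a flagged function is reported — and its F1 of 0.48
beats the gene-label-shuffling null (empirical p = 0.02), i.e. the signal
is real, not an artifact of prediction size. The CMP abundance matrix,
however, resembles the measured metabolome only weakly as a configuration
(`m12²` = 0.92, permutation p = 0.12): occurrence is far easier than
abundance.

The tables are plain S4 containers: `AbundanceTable` / `CMPMatrix` extend
`SummarizedExperiment` (features × samples, `group` and `study` in
`colData`), read and written as TSV via `readAbundanceTable()` /
`writeAbundanceTable()`; the reference graph serializes to sorted-key JSON
via `writeReferenceMap()`. A command-line wrapper with `build-ref`,
`simulate`, `predict` and `benchmark` subcommands ships in
`inst/scripts/metabopredict`.

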