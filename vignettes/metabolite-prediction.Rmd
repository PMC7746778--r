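---
title: "Predicting and benchmarking community metabolite profiles from microbiome function tables"
author: "metabopredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and benchmarking community metabolite profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopredict)
```

## The problem

Untargeted metabolomics of stool or intestinal tissue is expensive and
logistically hard at cohort scale, while microbiome sequencing is cheap and
abundant. If the metabolite pool of a gut community could be predicted from
its gene content alone, sequencing data already sitting in public archives
could power metabolite-level hypothesis generation. Three families of
predictors have been proposed:

* **Relationship-table lookup.** A static map from microbial gene families
  (KEGG orthologs, KOs) and reactions (KEGG or BioCyc RXNs) to the
  compounds those reactions produce or consume. Every compound linked to a
  function observed in the community is predicted present; every compound
  linked to a *differential* function is predicted differential.
* **Community metabolic potential (CMP).** A signed per-sample score per
  compound: the stoichiometry-weighted sum of the (normalized) abundances
  of all genes whose reactions involve that compound. The CMP matrix is
  treated as a predicted metabolome.
* **Per-metabolite regression.** One elastic-net model per metabolite,
  trained on paired microbiome-metabolome cohorts and validated
  leave-one-study-out, predicting metabolite relative abundance from
  function relative abundances with no reference knowledge at all.

This package implements all three, plus the complete evaluation framework
needed to compare them on equal footing, and a synthetic paired-cohort
generator with known ground truth so that every stage is testable without
licensed reference databases or external downloads.

## The relationship graph

`buildRelationshipTable()` assembles a `ReferenceMap` from five kinds of
annotation records: KO→reaction, KO→EC number, EC→reaction,
reaction→compound (optionally with a signed stoichiometric coefficient),
and transporter→compound. Querying follows three routes:

1. a KO with direct reaction annotations resolves through those reactions;
2. a KO with *no* direct reaction falls back to reactions reached through
   its EC numbers — the fallback is exclusive by default, because a curated
   direct annotation is more specific than the enzyme-class route (an
   `ecFallback = "always"` switch unions both);
3. transporter compounds are always added.

`methodsFixture()` encodes the two canonical examples: `ko:K24443` with two
reactions linking five compounds, and `ko:K00046`, reaching seven compounds
only through EC 1.1.1.69.

Reaction directionality is deliberately ignored when forming compound
*sets* — many reactions run in either direction in vivo, so substrates and
products are treated alike for occurrence prediction. Signed coefficients
are kept separately because CMP scoring consumes them:

$$\mathrm{CMP}[c, s] \;=\; \sum_{r \,\ni\, c} \xi_{cr} \sum_{f \to r} a_{fs},$$

where $\xi_{cr}$ is the stoichiometric coefficient of compound $c$ in
reaction $r$ and $a_{fs}$ the abundance of function $f$ in sample $s$.
Positive scores read as net predicted production, negative as net
consumption. Edges lacking a coefficient default to $+1$ with a warning
(switchable to an error). Transporter links carry no stoichiometry and do
not enter CMP. Functions upstream of several reactions contribute to each
with no down-weighting. Abundances should be normalized between samples
first; `singleCopyNormalize()` divides each sample by its median
universal-single-copy-marker abundance, the core of the usual
copies-per-genome correction, and externally normalized tables are accepted
as-is.

## The regression pipeline

Training applies the standard filters (strictly over 10% prevalence and
strictly over 0.01% mean relative abundance, both computed after per-sample
relative-abundance conversion), then the arcsine-square-root transform
$y = \arcsin\sqrt{x}$, the usual variance stabilizer for proportions. One
elastic-net model per metabolite is fitted with `glmnet`: the penalty
$\lambda$ is chosen by internal 5-fold cross-validation with a fold
assignment fixed by the seed, and the mixing parameter over the grid
$\alpha \in \{0.2, 0.5, 0.8, 1\}$ by smallest cross-validated error. Models
whose size (nonzero coefficients) is below 2 are pruned: a metabolite
predicted by a single gene family is prone to spurious association. Only
size pruning is applied by default; a per-metabolite prediction-quality
filter would add a second, unstated selection step, so it is not.

`losoPredict()` runs the leave-one-study-out protocol: for each study,
models are trained on all remaining studies and the held-out study's
metabolome is predicted, so every sample is predicted exactly once.
Predictions are clipped to $[0, \pi/2]$ on the transformed scale and
back-transformed through $\sin^2$, hence always in $[0,1]$ — never
negative. Per-metabolite models are independent, so results cannot depend
on fitting order; with the seed fixed the whole protocol is
bit-reproducible.

## Differential-abundance statistics

* **Functions** (counts): a negative-binomial Wald test on
  median-of-ratios-normalized counts with a pooled method-of-moments
  dispersion per function, two-sided normal p-values. This is a light
  stand-in for heavier count machinery — no dispersion shrinkage, no
  independent filtering — and `importDifferential()` accepts results
  computed elsewhere whenever exact replication of a published analysis
  matters. Under null simulations the raw-p type-I error sits at the
  nominal level (checked in the test suite).
* **Measured and regression-predicted metabolites** (non-negative
  intensities): zeros are imputed with the per-metabolite minimum nonzero
  value across *all* samples (the per-metabolite reading, not per group),
  natural-log transformed, and compared by a two-sided Student's t-test
  with pooled variance (the classical reading of the name; Welch is a
  switch).
* **CMP predictions** (signed scores, so log transforms are unavailable): a
  two-sided Wilcoxon rank-sum test, exact for combined $n \le 20$ without
  ties, normal approximation with tie correction otherwise; all-tied
  compounds get $p = 1$.

All tests are two-sided (no directional hypothesis is stated anywhere in
the design), followed by Benjamini–Hochberg correction with flagging at
adjusted $p \le 0.2$ — inclusive, so a feature exactly at the threshold is
flagged. Prevalence filtering removes features detected in *fewer than* 5%
of samples, so a feature at exactly 5% is retained; for signed CMP scores,
"detected" means $|x| > 10^{-12}$.

## Evaluation framework

**Occurrence** compares predicted and measured compound sets after 5%
prevalence filtering of both: precision $tp/(tp+fp)$, recall $tp/(tp+fn)$,
F1 $2PR/(P+R)$, each defined as 0 when its denominator vanishes. The
relationship-table prediction is already a set; abundance pipelines
contribute the compounds surviving the prevalence filter.

**Abundance similarity** uses Procrustes analysis: each matrix is reduced
to Euclidean distances between shared samples, ordinated by classical
multidimensional scaling (all positive-eigenvalue axes retained;
negative-eigenvalue axes carry no Euclidean structure and are dropped), and
superimposed by symmetric least-squares Procrustes. The squared residual
$m_{12}^2 \in [0,1]$ is 0 for identical configurations;
$\mathrm{corr} = \sqrt{1 - m_{12}^2}$. Significance comes from 999
sample-label permutations (a count chosen here; any value can be set) with
the add-one empirical-p rule. A practical caution verified in the tests:
$m_{12}^2$ for *unrelated* matrices approaches 1 only when the sample count
well exceeds the configuration rank; when rank is comparable to the number
of samples the optimal rotation overfits and $m_{12}^2$ drops well below 1
even for pure noise. The permutation p, not the raw $m_{12}^2$, is the
calibrated quantity.

**Permutation nulls.** The coverage null draws, 99 times, as many compounds
as the pipeline predicted uniformly without replacement from the chemical
dictionary and scores each draw; the mean null precision equals the
hypergeometric expectation, which the tests verify. The differential null
shuffles labels: function labels for the relationship-table pipeline
(rerunning the differential-function test and the lookup), compound labels
of the predicted matrix for the abundance pipelines (rerunning the
differential test). Empirical p uses the add-one rule
$(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$, so with 99 replicates p
lies on $\{0.01, \dots, 1\}$ and is never 0. One subtlety: under a true
null the observed F1 is usually exactly 0 and ties with most replicates, so
the empirical p piles up near 1 — the discrete metric makes the null
*conservative*, never anti-conservative; uniformity is only approached when
the metric varies continuously.

**Cross-pipeline comparison.** `comparePipelinesSignedRank()` applies
two-sided Wilcoxon signed-rank tests to paired per-dataset metric values
(zero differences dropped; exact distribution for $n \le 25$ untied
differences), producing the pairwise p-value table.

## The synthetic cohort generator

`makeReference()` draws a random function→reaction→compound graph (defaults:
60 KOs, 60 reactions, 150 compounds, about 3 reactions per ordinary KO,
15% EC-only functions, 10% transporters) and pads the dictionary with 20%
decoy compounds never linked to anything, mirroring a real chemical
dictionary, which is far larger than the linkable universe.

`simulatePairedCohort()` generates matched tables: function counts are
negative binomial (dispersion 0.3) around per-function lognormal baselines
(meanlog 3, sdlog 1.8) times lognormal library sizes; planted functions are
multiplied by the fold change in cases. Metabolite latents are weighted
sums of *library-size-normalized* function activity plus multiplicative
lognormal noise. The absolute (non-compositional) linkage is deliberate:
driving metabolites from relative abundances lets a planted fold change
ripple through the entire simplex and mark most of the metabolome
differential, a regime no real cohort shows; with absolute activity the
truly differential compounds are exactly those reachable from planted
functions, a realistic minority. Host-derived and decoy compounds on the
measured panel get independent lognormal abundances with per-compound
baselines spanning the detection limit, and the weakest 10% of positive
intensities are truncated to zero, so the 5%/10% prevalence and sparsity
filters are all genuinely exercised. Detection censoring operates on
compounds (a random `detectFrac` subset of the dictionary forms the
measured panel), emulating the limited coverage of untargeted platforms.

What the generator does *not* emulate: taxon-level structure and
correlation between related functions, batch and platform effects between
studies, compositional measurement distortion, missing-not-at-random
censoring within samples, and chemical similarity between compounds.
Passing tests on synthetic cohorts therefore demonstrate the correctness
and internal calibration of the machinery, not field performance on real
cohorts.

## Numerical and design choices

* Thresholds (`metaboThresholds()`): BH level 0.2; 5% prevalence for
  differential-function input and metabolome filtering; 10% prevalence and
  0.01% mean relative abundance for regression training (both strict
  inequalities, "over" read literally); 99 null repetitions; minimum model
  size 2; 999 Procrustes permutations.
* One global seed fans out to per-stage child seeds by a hash of the stage
  name (`stageSeed()`), so adding a stage never perturbs earlier stages.
* Identifiers are namespaced strings (`ko:`, `rxn:`, `cpd:`, `ec:`,
  `biocyc:`); KEGG- and BioCyc-style universes live in separate
  `ReferenceMap`s and queries never cross namespaces implicitly.
* JSON serialization of a `ReferenceMap` sorts all keys, so identical maps
  round-trip byte-identically.
* Degenerate inputs: unknown functions query to the empty set; all-zero
  metabolites are excluded from the t-test (no minimum nonzero value
  exists); all-tied compounds get rank-sum p 1; both-empty set comparisons
  return all-zero metrics with a warning; orphan reactions are logged and
  resolve to nothing.
* Problem sizes in the shipped tests and acceptance script (60 samples,
  60 functions, 150-compound dictionary, 99-replicate nulls) were chosen as
  the smallest cohorts at which every filter, test and null is non-trivially
  exercised.

## Limitations

The count test is a stand-in, not a substitute, for full shrinkage-based
differential machinery; with few samples per group its dispersion estimate
is noisy (use `importDifferential()` to inject externally computed
results). The CMP score inherits the steady-state, well-mixed assumptions
of all potential-based predictors. Regression models transfer across
studies only to the extent that data generation is comparable; the
leave-one-study-out protocol measures exactly that and nothing more. And
all evaluation treats the measured metabolome as truth even though
untargeted panels are themselves incomplete — predicted compounds counted
as false positives may simply be undetected.
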