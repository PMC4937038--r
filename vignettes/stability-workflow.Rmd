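---
title: "Stability-consensus biomarker selection for untargeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-consensus biomarker selection for untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Untargeted LC-MS metabolomics of a case-control cohort yields on the order
of a thousand m/z features for around a hundred subjects. When the goal is
*early predictive* biomarkers — measured years before clinical onset in
subjects who are healthy at sampling — the class effects are subtle, the
features are heavily correlated (a parent ion travels with its in-source
fragments and adducts), and any single selection algorithm overfits
happily. metastab implements a workflow built for exactly this regime,
developed around a 111-subject serum dataset (55 incident type-2-diabetes
cases, 56 matched controls, 1195 features after peak picking and drift
correction): run *many* cheap selection techniques, keep the features they
agree on, and only then build small predictive models.

## The workflow

1. **Scaling** (`uv_scale`). Each feature is divided by its sample standard
   deviation so that scale-sensitive models treat all variables equally.
   Following the source protocol this is applied to the SVM routes only;
   forests and ANOVA are invariant to per-feature monotone affine rescaling
   (a property the test suite checks), so they consume raw intensities.
   Mean-centering is available (`center = TRUE`) but off by default: the
   protocol's transformation is literally divide-by-sd.

2. **Redundancy/dependency filters** (`correlation_filter`,
   `mutual_info_filter`). The correlation filter greedily breaks up feature
   pairs with |r| above 0.95: the member of the worst pair with the larger
   mean |r| to everything else is dropped, until no pair exceeds the
   threshold. This is the classical mean-correlation heuristic (the
   optimal largest admissible subset is NP-hard at p≈1200; a unit test
   verifies the greedy answer against exhaustive search on 5-feature
   instances). The MI filter scores each feature by its *average* mutual
   information to all others under the Gaussian estimator
   MI = −½·ln(1−r²) (nats) and keeps features below 0.02: a feature with
   high average MI is largely predictable from the rest and adds little.

3. **Ten ranking techniques** (`run_technique_suite`). Forest importance
   (permutation/MdAcc and Gini/MdGini) on the raw table and after the
   correlation filter; forest recursive feature elimination (accuracy and
   kappa variants) after the correlation filter; linear-SVM weights on the
   scaled table; SVM-RFE (accuracy/kappa) after the MI filter; one-way
   ANOVA p-values. Forests use 2000 trees and mtry = 2·⌈√p⌉ (double the
   conventional default, taken verbatim from the source protocol), with 50
   replicate forests and the smallest-OOB replicate retained. Each route
   keeps a top set: 178 features for the unfiltered machine-learning
   routes, 200 after a filter, and the p < 0.1 set for ANOVA.

4. **Stability consensus and the concept lattice** (`build_context`,
   `consensus_select`, `derive_concepts`). The ten top sets form a binary
   features × techniques context. A feature's *stability degree* is the
   number of techniques selecting it; features with degree ≥ 6 form the
   consensus subset. Formal concept analysis turns the same context into a
   lattice of (extent, intent) pairs — every maximal group of features
   selected by the same group of techniques — which is how the agreement
   structure is inspected visually. Concepts are enumerated with
   NextClosure (lectic-order closure enumeration), which provably visits
   every closed set exactly once; the suite cross-checks it against brute
   force over all attribute subsets on hundreds of random contexts. The
   lattice exports to `.cxt` (Burmeister) and GraphML.

5. **Prediction** (`rf_predict_nested`, `varsel_rf`, `logistic_pipeline`)
   on the consensus subset: nested forest models on the top 48/40/30/20/10/5
   features ranked by permutation importance, evaluated over 100 stratified
   75/25 splits; backwards variable elimination tracking the OOB error to
   its minimum, repeated 100 times with the across-replicate intersection
   reported as stable; and a four-stage logistic pipeline (univariable
   entry at p < 0.25 → pairwise-correlation pruning to max |r| ≤ 0.5 →
   shortlist of 10 by outcome correlation → stepwise AIC reduction).

6. **Interpretation** (`roc_auc`, `feature_t_tests`, `correlation_network`,
   `discretize_equal_width`, `mine_rules`): empirical (Mann-Whitney) AUC
   with DeLong confidence intervals and the Youden-optimal operating point,
   Welch t-tests, signed Pearson correlation networks at |r| ≥ 0.5, and
   Apriori association rules on 4-range equal-width discretized
   intensities.

## The synthetic-data generator

The original serum table is not public, so the package ships a generator
(`synth_spec`, `generate_dataset`) whose preset `gazel_spec()` emulates the
documented structure of that dataset. Design choices:

* **Log-normal intensities.** MS intensities are positive and
  right-skewed; effects and correlations are defined on the log scale and
  exponentiated. The preset uses log-sd 0.2 (a ~20% coefficient of
  variation, typical for batch-corrected LC-MS features). At this sd the
  exponential map attenuates correlations only mildly, which is why the
  strong blocks use a latent correlation of 0.82 to land near 0.80 on the
  intensity scale.
* **Equicorrelated blocks via one latent factor per cluster** — the
  simplest model of a parent ion plus fragments. The preset has twelve
  48-feature blocks at 0.82 and four 35-feature blocks at 0.6. At n = 111
  this yields ≈2.2% of feature pairs with |r| > 0.5 (documented cohort
  value 2.4%, tolerance ±1 point) and ≈560-575 features with at least one
  partner above 0.8 (documented value 576).
* **Class effects are mean shifts on individual features**, one per block
  first and then on singletons, of `effect_size` standard deviations. The
  preset's 52 informative features at one sd reproduce the documented
  count of ~52 Benjamini-Hochberg-significant features.
* **A deliberate mismatch.** The cohort analysis reports ~107 features
  with ANOVA p < 0.1 *and* 52 BH-significant ones. These two counts cannot
  both hold in expectation for any generator whose null features have
  uniformly distributed p-values: with ~52 strongly significant features
  the expected count below 0.1 is at least 0.1·(1195−52)+52 ≈ 166. The
  observed 107 is best read as a low draw of a count whose variance is
  inflated by the heavy feature correlation. The preset reproduces the
  correlation structure and the BH count; its p < 0.1 count sits near the
  theoretical ≈166, and `summarize_structure` reports it honestly.
* What the generator does **not** emulate: batch/drift artifacts (assumed
  corrected upstream), missing values, retention-time structure, heavy
  tails beyond log-normality, and effect-size heterogeneity. Passing
  recovery tests therefore demonstrate the pipeline's mechanics under a
  favourable, well-specified signal model — not field performance on raw
  cohort data.

## Numerical and design choices

* **Labels** are the literal strings `"1"` (Case) and `"-1"` (Control);
  the Unicode minus form is accepted on input. Ties anywhere (filter
  removals, rank ordering, shortlist elimination) break by lexicographic
  feature id so every run is reproducible.
* **Seeds** fan out from one master seed through a counter scheme
  (`seed + 1000003·counter mod 2³¹−19`), so replicate r is reproducible in
  isolation.
* **OOB error** is the fraction of samples misclassified by the majority
  vote of trees not containing them; samples never out-of-bag (possible
  only at very small tree counts) are excluded from the denominator with a
  message.
* **RF-RFE subset quality** defaults to the forest's own out-of-bag
  accuracy/kappa rather than an outer leave-one-out loop: the OOB estimate
  is the forest's built-in leave-out error and costs one forest per round
  instead of n+1. `cv = "loocv"` is available. SVM-RFE, whose single fits
  are cheap, always uses pooled LOOCV for its per-round metric.
* **Elimination schedule** halves the surviving set each round (keep
  ⌈p/2⌉); `elimination_fraction = 1/p` gives the drop-one variant used in
  the oracle tests. Because elimination order is driven by weights or
  importances while the accuracy/kappa metric only picks the best subset
  size (or best replicate), the Acc and Kappa variants of one RFE route
  can produce identical or near-identical top sets; in the original
  analysis they differed through resampling randomness.
* **Complete separation** in univariable logistic fits is detected
  (non-convergence, |coef| > 15, or saturated fitted values) and refit
  with a ridge penalty of 10⁻⁴ so the recorded p-value is finite. A
  separated feature is *retained* at the entry stage: separation means
  perfect univariable discrimination, and the penalized Wald p-value is
  badly conservative precisely in that case.
* **Stepwise reduction** is bidirectional AIC from the full shortlist
  model (`stats::step`). The stage-3 composite criterion orders by
  |point-biserial outcome correlation| first, univariable p second.
* **Importance** is the unscaled permutation importance (mean decrease in
  OOB accuracy), matching its definition rather than the z-score variant.
* **DeLong intervals** are used for AUC confidence limits because they are
  deterministic; a bootstrap would add simulation noise to a quantity the
  tests compare against exact pair counting.
* **Discretization** is equal-width over the observed range with the
  outer intervals opened to ±∞, the default unsupervised discretizer of
  the workbench tradition this step comes from; interval labels print as
  `(lo - hi]`.

## Scale of the shipped verification

The test suite and the acceptance script run the full ten-technique
pipeline on generated 111×1195 tables with 200-tree forests, 3 forest
replicates, 2 RFE replicates and 10 (tests) or 5 (script) generator seeds,
with 10 stratified splits per prediction evaluation — small enough to run
in minutes, large enough that planted-biomarker recovery (≥8 of 10 planted
features in the consensus) and the consensus-beats-full-table property hold
in essentially every seed. The published-scale defaults (2000 trees, 50
replicates, 100 replications) remain the package defaults for real
analyses.

## Known limitations

* The exact membership of the documented 48-feature consensus and its
  276-concept lattice cannot be recomputed because the cohort's
  supplementary presence/absence table is not redistributable here; the
  shipped 11-biomarker rank table supports a consistency check (all 11
  published biomarkers reach degree ≥ 6) but not the full recount.
* `consensus_select` is the normative rule; the union of extents of
  concepts with intent size ≥ k is *not* equivalent in general and is not
  offered as an alternative.
* Apriori rule mining is exact but deliberately guarded: zero minimum
  support is rejected, and itemsets are explored to length 4 by default.
* The logistic pipeline assumes n in the low hundreds and a consensus of
  ~50 features; it is not built for p ≫ n model fitting without the
  upstream selection stages.
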