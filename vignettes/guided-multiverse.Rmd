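---
title: "Guided multiverse analysis of connectivity pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided multiverse analysis of connectivity pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipespace)
```

## The problem

A single connectivity study hides dozens of defensible analytic choices: how
the data were cleaned, how regions were defined, how connectivity was
estimated, how the resulting network was thresholded and summarised. Any one
pipeline is a point in a combinatorial *multiverse*, and evaluating all of
them is both computationally expensive and statistically corrosive — every
additional look at the data costs power.

`pipespace` implements a guided alternative. The idea has two halves:

1. **Give the multiverse a geometry.** Apply every candidate pipeline to a
   small, dedicated subset of subjects and summarise each pipeline not by its
   predictive performance but by the *pattern of between-subject similarity*
   it induces: the cosine similarity between every unordered pair of
   subjects' pipeline outputs. Each pipeline becomes a signature vector of
   length $n(n-1)/2$, and pipelines whose signatures are close treat
   individual differences similarly. Metric MDS embeds these signatures into
   a low-dimensional space in which distance is meaningful.

2. **Search the geometry instead of the grid.** On a second, disjoint subset
   of subjects, a Gaussian-process regression models predictive performance
   as a smooth function of the embedded coordinates. Bayesian optimisation
   with the upper-confidence-bound (UCB) acquisition
   $\alpha(x) = \mu(x) + \kappa\,\sigma(x)$ chooses which pipeline to
   cross-validate next. With a handful of evaluations the GP posterior mean
   estimates performance for *every* pipeline, sampled or not.

A third, lock-box subset of subjects is touched exactly once, to score the
selected optimum out of sample.

The exploration parameter $\kappa$ is the researcher's dial: large values
(the package default is 10) spread samples to map the whole landscape; small
values (e.g. 0.1) race towards an optimum and accept a poorer global map.

## The two study designs

Two pipeline grids ship as defaults, mirroring the two supervised settings
the framework is typically demonstrated on:

* **Regression** (age-like continuous target): data variant (motion
  regression vs global signal regression) × 17 proportional thresholds
  spanning 0.01–0.4 × 16 nodal graph metrics = **544 pipelines**. Features
  are one value per region (the nodal metric); the evaluator is an RBF
  support vector regression (C = 1, $\varepsilon$ = 0.1) scored by negative
  mean absolute error under 5-fold cross-validation.
* **Classification** (diagnosis-like binary target): 4 preprocessing
  variants × 4 strategies (band-pass filtering × global signal regression) ×
  6 parcellations × 4 connectivity estimators (covariance, correlation,
  partial correlation, tangent projection) = **384 pipelines**. Features are
  the strict lower triangle of the connectivity matrix; the evaluator is an
  L2-penalised logistic regression (C = 1) scored by AUC under stratified
  5-fold cross-validation.

With 50 space-building subjects the regression similarity table is
$544 \times 1225$; with 176 it is $384 \times 15400$ for classification —
the $n(n-1)/2$ column counts are the package's `pair_count()`.

## The synthetic cohort generator

Real multi-variant neuroimaging releases are large external downloads, so the
package ships a generator that emulates their statistical structure and makes
every downstream stage testable from code alone. Per subject it:

1. draws a latent target $y$ (age-like Gaussian, or a balanced binary label);
2. builds a positive-definite base coupling matrix with block-community
   structure (seven contiguous communities by default, standing in for a
   canonical seven-network cortical parcellation) plus a small shared random
   jitter;
3. adds `signal_strength` · standardised $y$ (or a group offset, for
   classification) to a fixed random subset of region pairs
   (`signal_edges_fraction`, default 20 %);
4. samples stationary multivariate-normal time series from that coupling; and
5. derives the data variants: odd-numbered variants retain a shared global
   signal component (sd `global_component_sd`), even-numbered variants have
   it removed — emulating the presence/absence of global signal regression —
   and all variants beyond the first receive independent noise of sd
   `variant_perturbation_sd`.

Design notes, in order of consequence:

* **Coupling scale.** Regional variances are set to 4 with off-diagonal
  couplings an order of magnitude smaller, so the additive target effect
  moves correlations in a near-linear regime. An earlier unit-variance
  parameterisation saturated: strong effects forced frequent
  positive-definiteness repairs whose diagonal loading *shrank* correlations,
  making recovered effect size non-monotone in the planted strength. With
  the current scale the mean recovered correlation is monotone across
  planted strengths 0, 0.25, 0.5 in every tested seed.
* **Positive-definiteness repair.** When the additive effect still breaks
  positive definiteness, the smallest sufficient diagonal loading (in steps
  of $10^{-6}$) is applied and counted; the event is reported once per
  cohort.
* **Stationarity.** Time series are white within regions — no
  autocorrelation, hemodynamics, motion artefacts or image-space structure.
  This is the simplest model satisfying what the method actually assumes
  (per-subject covariance structure observed through noisy variants), and it
  bounds what passing tests show: they validate the machinery, not
  robustness to realistic fMRI noise.
* **Classification factors as data.** The preprocessing × strategy factors
  are realised as 16 distinct perturbation variants of one base simulation;
  the six parcellations are contiguous coarse-grainings of the base regions
  consumed as parcel-mean time series. Real-data loaders could map these
  labels onto actual preprocessing suites and atlases, but nothing in the
  core requires it.
* **Splits.** `split_dataset()` accepts fractions or absolute sizes, with
  absolute sizes taking precedence so canonical splits such as 50/198/50 and
  176/529/177 can be reproduced exactly; stratified splits keep per-class
  counts within one subject of the global proportion.

## Numerical choices

* **Thresholding** keeps the $\lceil s\,E\rceil$ largest off-diagonal
  weights *as weights* (no binarisation): several registry metrics —
  strength above all — are degenerate on binary graphs at fixed density.
  Ties at the cut break by lexicographic $(i, j)$ order, so thresholding is
  a deterministic function of its input.
* **Metric registry.** Sixteen nodal metrics: strength, degree, betweenness,
  eigenvector, harmonic closeness, pagerank, weighted clustering, local
  efficiency, k-coreness, subgraph centrality, participation coefficient,
  module-degree z-score, two gateway coefficients (degree- and
  betweenness-based), within-community strength, and the nodal Louvain
  modularity contribution. Distance-based metrics use edge lengths
  $1/|w|$; harmonic (rather than classical) closeness keeps the value finite
  on the disconnected graphs that low sparsities routinely produce. Louvain
  is stochastic, so its seed derives from (global seed, pipeline id):
  landscapes are reproducible and independent of sampling order.
* **Tangent projection.** The reference is the Euclidean mean of the
  training covariances projected to the positive-definite cone (eigenvalue
  floor $10^{-10}$); an affine-invariant geometric mean is available as an
  option. Covariances with condition number above $10^{12}$ are
  ridge-regularised by $10^{-6}\cdot\overline{\mathrm{diag}}$ before
  inversion or projection.
* **MDS.** Metric MDS is fitted by SMACOF majorisation on the Euclidean
  distances between similarity-table rows, initialised from classical
  scaling — which makes the embedding deterministic without any seed, and
  the final configuration invariant (in its distances) to orthogonal
  transforms of the initialisation. PCA is the second built-in; further
  embeddings (t-SNE, UMAP, …) plug in through a registry without touching
  the core. The neighbourhood-preservation score — mean fraction of each
  pipeline's $k$ original-space neighbours retained after embedding, ties
  broken by pipeline id — quantifies what any embedding must preserve for
  the search to work.
* **Gaussian process.** Matérn $\nu = 2.5$ plus a white-noise kernel by
  default ($\nu$ is a free smoothness choice; 2.5 is smooth but flexible,
  and an RBF kernel is exposed as an option). Hyperparameters (log
  length-scale, log signal sd, log noise sd) maximise the log marginal
  likelihood by L-BFGS-B from a heuristic start (median pairwise distance),
  the previous iteration's optimum, and two seeded random restarts. Scores
  are z-scored before fitting and un-standardised on output, which keeps the
  hyperparameter optimisation well-scaled across objectives.
* **Acquisition.** UCB is maximised continuously over the embedding's
  bounding box with 16 seeded Nelder-Mead starts, then snapped to the
  nearest *unsampled* pipeline (ties by id). Snapping to unsampled points
  guarantees progress: no pipeline is ever evaluated twice, which is also
  what gives the sequential procedure its multiple-comparison economy. On
  moderate grids the continuous-then-snap proposal agrees with the discrete
  argmax of the acquisition in the large majority of seeded trials.
* **Failure policy.** A pipeline whose evaluation throws is recorded at the
  worst observed score minus one sd and flagged, rather than aborting the
  run — failing pipelines should look unattractive, not fatal.
* **Seeding contract.** Cross-validation folds derive from (config seed,
  pipeline id) only. Consequently a pipeline's score is identical whether it
  is evaluated inside a search trace, in another repetition, or during
  exhaustive evaluation — repetitions differ solely in sampling randomness
  (burn-in draw, acquisition starts), which is exactly the variability a
  reliability analysis should measure.

## What the evaluation machinery reports

`exhaustive_evaluate()` computes the ground-truth landscape;
`space_correlation()` reports Spearman's $\rho$ between the GP posterior
mean and that ground truth (average ranks; large-sample t p-value).
`extract_optima()` returns both the GP-estimated and best-sampled optima;
`holdout_score()` refits on the full search split and scores the lock-box
once (refitting on the whole split, not per-fold models, since the holdout
is the final out-of-sample statement). `repeat_search()` runs the loop with
distinct sampling seeds — guaranteed distinct, one per repetition — and
reports optima, holdout scores and $\rho$ per repetition, with failures
reported rather than dropped.

## Problem sizes used in the shipped checks

The package's own tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path while keeping a laptop-class
run comfortable: cohorts of 40–176 subjects, 12–16 regions, 80–120
timepoints; the full 544- and 384-pipeline grids for shape checks; a reduced
128-pipeline grid (2 variants × 8 sparsities × 8 metrics) for end-to-end
searches; and a 144-point analytic two-bump landscape for the
$\kappa$-contrast and optimum-recovery experiments, where the noise-free
evaluator isolates the sampling behaviour from cross-validation noise. At
these sizes the qualitative claims reproduce robustly: exploratory search
($\kappa = 10$) yields a higher estimated-vs-empirical $\rho$ than
exploitative search ($\kappa = 0.1$) in at least 8 of 10 paired seeds, and
its best sample lands in the empirical top decile in at least 8 of 10 seeds.

## Limitations

* The generator's variants are exchangeable perturbations; real
  preprocessing variants differ systematically, so synthetic landscapes are
  flatter across the variant factor than real ones.
* Region counts in the shipped checks are far below real parcellations;
  graph-metric behaviour at 12 regions is a functional test, not a
  neuroscientific statement.
* Only UCB acquisition and exact GP inference are implemented; large grids
  (tens of thousands of pipelines) would need approximations that are out of
  scope.
* The embedding registry ships MDS and PCA only; the comparison of further
  manifold learners is plugin territory.
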