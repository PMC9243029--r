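# pipespace

Guided multiverse analysis of connectivity pipelines via active learning.

## The problem

Connectivity studies — predicting a person's age from resting-state
functional connectivity, or classifying a diagnosis from it — admit hundreds
of defensible analysis pipelines: which noise-corrected version of the data
to use, how to threshold the connectivity matrix, which network metric or
connectivity estimator to extract. Evaluating every pipeline (a *multiverse
analysis*) is computationally expensive, and repeated sequential looks at
the same data erode statistical power.

`pipespace` is for researchers who want the coverage of a multiverse
analysis at a fraction of its cost. It:

1. **builds a low-dimensional space of pipelines** — every pipeline is
   applied to a dedicated subject subset and summarised by the cosine
   similarity between all `n(n-1)/2` subject pairs of its outputs; metric
   MDS embeds these signatures so that nearby pipelines treat individual
   differences similarly;
2. **searches that space with Bayesian optimisation** — a Gaussian process
   (Matérn ν = 2.5 + white-noise kernel, hyperparameters by maximum
   marginal likelihood) models cross-validated predictive performance over
   the embedding, and the upper-confidence-bound acquisition

   α(x) = μ(x) + κ·σ(x)

   selects the next pipeline to evaluate. Exploratory search (κ = 10) maps
   the whole performance landscape; exploitative search (κ = 0.1) races to
   an optimum. After a 10-pipeline burn-in and 50 acquisitions the GP
   posterior estimates performance for *every* pipeline from 60
   evaluations; and
3. **scores the selected optimum once on a lock-box holdout** split that no
   other stage ever touches.

Two default grids ship: a regression design (2 data variants × 17
proportional thresholds × 16 nodal graph metrics = 544 pipelines, scored by
5-fold cross-validated negative MAE with an RBF SVR) and a classification
design (4 preprocessing variants × 4 strategies × 6 parcellations × 4
connectivity estimators = 384 pipelines, scored by AUC with L2 logistic
regression). A seeded synthetic-cohort generator plants a target signal in
region couplings and emits correlated "preprocessing variant" versions of
each subject's time series, so the entire workflow runs without any data
download.

## Worked example

```r
library(pipespace)

# a synthetic cohort: 80 subjects, 14 regions, planted age-like signal
cohort <- generate_cohort(cohort_config(
  n_subjects = 80, n_regions = 14, n_timepoints = 100,
  signal_strength = 0.4, seed = 42))
cohort <- split_dataset(cohort, sizes = c(20, 50, 10), seed = 42)

# a reduced regression multiverse: 2 x 8 x 8 = 128 pipelines
grid <- default_regression_grid(
  sparsities = c(0.05, 0.08, 0.1, 0.15, 0.2, 0.25, 0.3, 0.4),
  graph_metrics = c("strength", "betweenness", "eigenvector", "closeness",
                    "pagerank", "participation", "clustering", "kcoreness"))

# pipeline signatures over the space split, embedded with metric MDS
table <- build_similarity_table(cohort, grid)
space <- embed_pipelines(table)
table
#> <similarity_table> 128 pipelines x 190 participant pairs

# active search: 10 burn-in + 50 UCB acquisitions, exploratory kappa
config <- search_config(kappa = 10, n_burn_in = 10, n_iterations = 50,
                        objective = "neg_mae", seed = 42)
trace <- run_search(cohort, grid, space, config)
trace
#> <search_trace> 60 evaluations (10 burn-in + 50 active), kappa = 10, best = -1.6980

# how well does the 60-evaluation GP estimate the full 128-pipeline landscape?
estimate  <- predict_landscape(trace$gp, space)
empirical <- exhaustive_evaluate(cohort, grid, config)
space_correlation(estimate, empirical)
#> [1] 0.6948132
#> attr(,"p.value")
#> [1] 9.284914e-20

# the selected optima, and the one-shot lock-box score of the sampled optimum
extract_optima(trace, space, grid)
#> # A tibble: 2 x 6
#>   optimum pipeline_id score data_variant             sparsity graph_metric
#>   <chr>         <int> <dbl> <chr>                    <chr>    <chr>
#> 1 gp              106 NA    global_signal_regression 0.25     betweenness
#> 2 sampled          34 -1.70 motion_regression        0.2      betweenness
holdout_score(cohort, grid[grid$pipeline_id == 34, ], config)$value
#> [1] -2.169652
```

Scores are negative mean absolute error in target (age) units, so values
closer to zero are better; the Spearman ρ above says the GP's estimate of
all 128 pipelines from 60 evaluations ranks them in good agreement with the
exhaustive ground truth. `autoplot(space)`, `autoplot(trace)` and
`plot_landscape(space, estimate)` draw the embedded space, the search
evolution and the estimated landscape; `repeat_search()` reruns the loop
with fresh sampling seeds to check that the optima are stable.

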