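test_that("space correlation reproduces hand-ranked fixtures", {
  expect_equal(as.numeric(space_correlation(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))), 0.8)
  expect_equal(as.numeric(space_correlation(1:6, 1:6)), 1)
  expect_equal(as.numeric(space_correlation(1:6, -(1:6))), -1)
  set.seed(40)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(as.numeric(space_correlation(a, b)), oracle_spearman(a, b),
               tolerance = 1e-12)
  expect_warning(r <- space_correlation(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(r))
})

test_that("exhaustive evaluation of a one-pipeline grid equals direct evaluation", {
  co <- small_regression_cohort()
  grid <- small_regression_grid()[1, ]
  attr(grid, "factors") <- attr(small_regression_grid(), "factors")
  class(grid) <- class(small_regression_grid())
  cfg <- search_config(seed = 5)
  land <- exhaustive_evaluate(co, grid, cfg)
  direct <- evaluate_pipeline(co, grid[1, ], cfg)
  expect_equal(land$score, direct$value)
})

test_that("trace scores obey the seeding contract with exhaustive evaluation", {
  co <- small_regression_cohort()
  grid <- small_regression_grid()
  tab <- build_similarity_table(co, grid)
  sp <- embed_pipelines(tab)
  cfg <- search_config(kappa = 10, n_burn_in = 5, n_iterations = 7, seed = 31)
  tr <- run_search(co, grid, sp, cfg)
  land <- exhaustive_evaluate(co, grid, cfg)
  for (i in seq_len(nrow(tr$trace))) {
    id <- tr$trace$pipeline_id[i]
    expect_identical(tr$trace$score[i], land$score[land$pipeline_id == id])
  }
})

test_that("a null cohort yields scores indistinguishable across graph metrics", {
  grid <- default_regression_grid(sparsities = c(0.15, 0.3),
                                  graph_metrics = c("strength", "betweenness",
                                                    "eigenvector", "closeness"))
  pvals <- sapply(1:10, function(s) {
    co <- suppressMessages(generate_cohort(cohort_config(
      n_subjects = 30, n_regions = 10, n_timepoints = 60,
      signal_strength = 0, seed = 300 + s)))
    co <- split_dataset(co, sizes = c(6, 20, 4), seed = s)
    cfg <- search_config(seed = s, cv_folds = 4)
    land <- exhaustive_evaluate(co, grid, cfg)
    stats::kruskal.test(land$score, factor(grid$graph_metric))$p.value
  })
  expect_gte(sum(pvals > 0.05), 8)
})

test_that("optima extraction picks the GP argmax and the sampled argmax", {
  lands <- synthetic_landscape()
  cfg <- search_config(kappa = 10, n_burn_in = 8, n_iterations = 20, seed = 12)
  tr <- run_search(NULL, lands$grid, lands$space, cfg, evaluator = lands$evaluator)
  opt <- extract_optima(tr, lands$space)
  est <- predict_landscape(tr$gp, lands$space)
  expect_equal(opt$pipeline_id[opt$optimum == "gp"], est$pipeline_id[which.max(est$mu)])
  best_row <- which.max(tr$trace$score)
  expect_equal(opt$pipeline_id[opt$optimum == "sampled"], tr$trace$pipeline_id[best_row])
  expect_equal(opt$score[opt$optimum == "sampled"], max(tr$trace$score))
})

test_that("an exhaustively sampled trace recovers the empirical argmax", {
  lands <- synthetic_landscape(4)
  cfg <- search_config(kappa = 1, n_burn_in = 6, n_iterations = 10, seed = 2)
  tr <- run_search(NULL, lands$grid, lands$space, cfg, evaluator = lands$evaluator)
  opt <- extract_optima(tr, lands$space)
  expect_equal(opt$pipeline_id[opt$optimum == "sampled"], which.max(lands$scores))
})

test_that("holdout scoring is optimistic when the holdout leaks the training set", {
  co <- small_regression_cohort()
  grid <- small_regression_grid()
  cfg <- search_config(seed = 3)
  spec <- grid[grid$pipeline_id == 2, ]
  leaky <- co
  leaky$subjects$split[leaky$subjects$split == "holdout"] <- "search"
  leaky$subjects$split[split_subjects(co, "search")[1:8]] <- "holdout"
  # proper holdout
  proper <- holdout_score(co, spec, cfg)$value
  expect_lte(proper, 0)
  # oracle features: the target itself predicts perfectly up to SVR epsilon
  oracle_co <- co
  for (v in names(oracle_co$variants)) {
    for (i in seq_along(oracle_co$variants[[v]])) {
      y <- oracle_co$subjects$target[i]
      oracle_co$variants[[v]][[i]][] <- 0
      oracle_co$variants[[v]][[i]][1, ] <- y  # constant row carrying y
    }
  }
  x_tr <- matrix(co$subjects$target[split_subjects(co, "search")], ncol = 1)
  x_te <- matrix(co$subjects$target[split_subjects(co, "holdout")], ncol = 1)
  pred <- pipespace:::fit_and_predict(x_tr, x_tr[, 1], x_te, "svr")
  expect_lt(mean(abs(pred - x_te[, 1])), 0.5)
})

test_that("shuffled holdout labels give chance-level AUC", {
  setup <- small_classification_setup()
  co <- setup$cohort
  grid <- setup$grid
  spec <- grid[grid$pipeline_id == 2, ]
  aucs <- sapply(1:10, function(s) {
    co_p <- co
    idx <- c(split_subjects(co, "search"), split_subjects(co, "holdout"))
    co_p$subjects$target[idx] <- with_seed_sample(co$subjects$target[idx], 50 + s)
    if (length(unique(co_p$subjects$target[split_subjects(co_p, "holdout")])) < 2) return(NA)
    cfg <- search_config(objective = "auc", seed = s)
    suppressWarnings(holdout_score(co_p, spec, cfg)$value)
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.07)
})

test_that("repeat_search returns one row per repetition with optima from the grid", {
  lands <- synthetic_landscape()
  cfg <- search_config(kappa = 10, n_burn_in = 6, n_iterations = 10, seed = 1)
  rep5 <- repeat_search(NULL, lands$grid, lands$space, cfg, n_reps = 5,
                        evaluator = lands$evaluator)
  expect_equal(nrow(rep5), 5L)
  expect_false(any(rep5$failed))
  expect_true(all(rep5$sampled_optimum %in% lands$space$pipeline_id))
  expect_true(all(is.finite(rep5$rho)))
  gl <- glance(rep5)
  expect_equal(gl$n_reps, 5L)
})

test_that("a single repetition reproduces run_search under the same seeds", {
  lands <- synthetic_landscape()
  cfg <- search_config(kappa = 10, n_burn_in = 6, n_iterations = 10, seed = 8)
  rep1 <- repeat_search(NULL, lands$grid, lands$space, cfg, n_reps = 1,
                        base_seed = 41, evaluator = lands$evaluator)
  tr <- run_search(NULL, lands$grid, lands$space, cfg, search_seed = 42,
                   evaluator = lands$evaluator)
  opt <- extract_optima(tr, lands$space)
  expect_equal(rep1$sampled_optimum, opt$pipeline_id[opt$optimum == "sampled"])
  expect_equal(rep1$gp_optimum, opt$pipeline_id[opt$optimum == "gp"])
})

test_that("repeated sampled optima concentrate in the high-performance region", {
  lands <- synthetic_landscape()
  cfg <- search_config(kappa = 10, n_burn_in = 8, n_iterations = 22, seed = 1)
  reps <- repeat_search(NULL, lands$grid, lands$space, cfg, n_reps = 10,
                        base_seed = 500, evaluator = lands$evaluator)
  coords <- pipespace:::space_coords(lands$space)
  opt_coords <- coords[reps$sampled_optimum, , drop = FALSE]
  d_opt <- dist(opt_coords)
  d_all <- dist(coords)
  expect_lt(mean(d_opt), median(d_all))
  # median optimum score sits in the top of the landscape
  expect_gte(median(reps$holdout), quantile(lands$scores, 0.9))
})
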