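#' Search configuration
#'
#' @param kappa Non-negative UCB exploration weight (10 maps the space, 0.1
#'   races to an optimum).
#' @param n_burn_in Random pipelines evaluated before active learning starts.
#' @param n_iterations Active acquisition steps.
#' @param cv_folds Cross-validation folds for pipeline evaluation.
#' @param objective `"neg_mae"` (regression) or `"auc"` (classification).
#' @param estimator `"svr"` (RBF support vector regression, C = 1,
#'   epsilon = 0.1) or `"logistic"` (L2-penalised logistic regression, C = 1).
#' @param seed Global seed: per-pipeline CV folds are derived from
#'   (seed, pipeline id) so scores are independent of sampling order.
#' @param kernel GP kernel spec (see [fit_gp()]).
#' @return A `search_config` list.
#' @export
search_config <- function(kappa = 10, n_burn_in = 10L, n_iterations = 50L,
                          cv_folds = 5L, objective = c("neg_mae", "auc"),
                          estimator = NULL, seed = 1L,
                          kernel = list(name = "matern", nu = 2.5, white = TRUE)) {
  objective <- match.arg(objective)
  if (is.null(estimator)) {
    estimator <- if (objective == "neg_mae") "svr" else "logistic"
  }
  estimator <- match.arg(estimator, c("svr", "logistic"))
  if (!is_scalar_num(kappa) || kappa < 0) abort("`kappa` must be non-negative.")
  if (!is_count(n_burn_in, 1L) || !is_count(n_iterations, 1L)) {
    abort("`n_burn_in` and `n_iterations` must be positive integers.")
  }
  if (!is_count(cv_folds, 2L)) abort("`cv_folds` must be >= 2.")
  structure(
    list(kappa = kappa, n_burn_in = as.integer(n_burn_in),
         n_iterations = as.integer(n_iterations),
         cv_folds = as.integer(cv_folds), objective = objective,
         estimator = estimator, seed = as.integer(seed),
         kernel = modifyList(list(name = "matern", nu = 2.5, white = TRUE), kernel)),
    class = "search_config"
  )
}

# ---- scoring primitives ----------------------------------------------------

mae_score <- function(truth, pred) mean(abs(truth - pred))

# Rank (Mann-Whitney) AUC; ties get average rank.
auc_score <- function(truth, prob) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

drop_constant_columns <- function(x) {
  keep <- apply(x, 2L, function(col) stats::sd(col) > 0)
  x[, keep, drop = FALSE]
}

fit_and_predict <- function(x_train, y_train, x_test, estimator) {
  x_train <- as.matrix(x_train)
  x_test <- as.matrix(x_test)
  keep <- apply(x_train, 2L, function(col) stats::sd(col) > 0)
  if (!any(keep)) {
    # all features constant: fall back to the training-mean predictor
    return(rep(if (estimator == "svr") mean(y_train) else mean(y_train == 1L),
               nrow(x_test)))
  }
  x_train <- x_train[, keep, drop = FALSE]
  x_test <- x_test[, keep, drop = FALSE]
  if (estimator == "svr") {
    fit <- e1071::svm(x_train, y_train, type = "eps-regression",
                      kernel = "radial", cost = 1, epsilon = 0.1)
    as.numeric(stats::predict(fit, x_test))
  } else {
    # L2 logistic with C = 1 (lambda = 1/(C * n)); ridge, no CV over lambda
    if (ncol(x_train) == 1L) {
      x_train <- cbind(x_train, 0)
      x_test <- cbind(x_test, 0)
    }
    fit <- glmnet::glmnet(x_train, factor(y_train, levels = c(0, 1)),
                          family = "binomial", alpha = 0,
                          lambda = 1 / nrow(x_train), standardize = TRUE)
    as.numeric(stats::predict(fit, x_test, type = "response"))
  }
}

# Seeded fold assignment; stratified for classification. Degenerate folds
# (a training fold missing a class) are re-drawn with an incremented seed.
make_folds <- function(y, k, seed, stratify) {
  for (try in 0:9) {
    folds <- with_preserved_seed(seed + try, {
      f <- integer(length(y))
      if (stratify) {
        for (cl in unique(y)) {
          idx <- sample(which(y == cl))
          f[idx] <- rep_len(seq_len(k), length(idx))
        }
      } else {
        f <- sample(rep_len(seq_len(k), length(y)))
      }
      f
    })
    ok <- !stratify || all(vapply(seq_len(k), function(i) {
      length(unique(y[folds != i])) == 2L && sum(folds == i) > 0L
    }, logical(1)))
    if (ok) {
      if (try > 0L) inform("Degenerate fold: folds re-drawn with incremented seed.")
      return(folds)
    }
  }
  abort("Could not draw folds with both classes in every training set.")
}

#' Cross-validated evaluation of one pipeline
#'
#' Extracts the pipeline's features on the search split and scores them by
#' k-fold cross-validated prediction of the target: negative mean absolute
#' error (SVR) for regression, AUC (logistic regression) for classification.
#' Fold assignment is seeded from (config seed, pipeline id), making each
#' pipeline's score independent of when in a search it is evaluated.
#'
#' @param cohort A `subject_cohort` with splits assigned.
#' @param spec Pipeline spec (single grid row or named list).
#' @param config A [search_config()].
#' @param subjects Subject indices (defaults to the `"search"` split).
#' @param cache Optional shared feature cache.
#' @return A `pipeline_score` list: `pipeline_id`, `value`, `folds`
#'   (per-fold values), `objective`, `seed`.
#' @export
evaluate_pipeline <- function(cohort, spec, config, subjects = NULL, cache = NULL) {
  spec <- as.list(spec)
  if (is.null(subjects)) subjects <- split_subjects(cohort, "search")
  y <- cohort$subjects$target[subjects]
  classify <- config$objective == "auc"
  if (classify && length(unique(y)) < 2L) {
    abort("Classification evaluation requires both classes in the search split.")
  }
  pid <- spec$pipeline_id %||% 0L
  eval_seed <- derive_seed(config$seed, pid)
  x <- subject_features(cohort, spec, subjects, seed = config$seed, cache = cache)
  folds <- make_folds(y, config$cv_folds, eval_seed, stratify = classify)
  fold_vals <- vapply(seq_len(config$cv_folds), function(f) {
    tr <- folds != f
    pred <- fit_and_predict(x[tr, , drop = FALSE], y[tr],
                            x[!tr, , drop = FALSE], config$estimator)
    if (classify) auc_score(y[!tr], pred) else -mae_score(y[!tr], pred)
  }, numeric(1))
  structure(
    list(pipeline_id = pid, value = mean(fold_vals), folds = fold_vals,
         objective = config$objective, seed = eval_seed),
    class = "pipeline_score"
  )
}

# ---- acquisition -----------------------------------------------------------

#' Propose the next pipeline to evaluate
#'
#' Maximises the UCB acquisition over the embedding's bounding box with
#' seeded multi-start Nelder-Mead, then snaps the continuous maximiser to the
#' nearest pipeline coordinate that has not yet been sampled (ties broken by
#' pipeline id).
#'
#' @param gp A fitted `gp_model`.
#' @param space An `embedded_space`.
#' @param sampled Integer vector of already-sampled pipeline ids.
#' @param kappa UCB exploration weight.
#' @param seed Seed for the multi-start locations.
#' @param n_starts Number of optimisation starts.
#' @return List: `pipeline_id`, `x_star` (continuous maximiser),
#'   `acquisition` (UCB at the snapped pipeline's coordinates).
#' @export
propose_next <- function(gp, space, sampled, kappa, seed = 1L, n_starts = 16L) {
  coords <- space_coords(space)
  unsampled <- setdiff(space$pipeline_id, sampled)
  if (length(unsampled) == 0L) abort("Space exhausted: all pipelines sampled.")
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  acq <- function(x) {
    x <- pmin(pmax(x, lo), hi)
    p <- gp_posterior(gp, matrix(x, nrow = 1L))
    p$mu + kappa * p$sigma
  }
  starts <- with_preserved_seed(derive_seed(seed, 29L), {
    lapply(seq_len(n_starts), function(i) lo + runif(length(lo)) * (hi - lo))
  })
  # seed one start at the most promising unsampled candidate so the
  # continuous maximiser is anchored near the discrete acquisition argmax
  cand_coords <- coords[match(unsampled, space$pipeline_id), , drop = FALSE]
  p_cand <- gp_posterior(gp, cand_coords)
  starts <- c(starts,
              list(cand_coords[which.max(p_cand$mu + kappa * p_cand$sigma), ]))
  best_x <- starts[[1L]]
  best_v <- -Inf
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, function(x) -acq(x), method = "Nelder-Mead",
                   control = list(maxit = 100L, reltol = 1e-6)),
      error = function(e) NULL)
    if (!is.null(fit) && -fit$value > best_v) {
      best_v <- -fit$value
      best_x <- pmin(pmax(fit$par, lo), hi)
    }
  }
  cand <- coords[match(unsampled, space$pipeline_id), , drop = FALSE]
  d2 <- colSums((t(cand) - best_x)^2)
  pick <- unsampled[order(d2, unsampled)[1L]]
  p <- gp_posterior(gp, coords[match(pick, space$pipeline_id), , drop = FALSE])
  list(pipeline_id = pick, x_star = best_x,
       acquisition = ucb(p$mu, p$sigma, kappa))
}

# ---- the closed loop -------------------------------------------------------

default_evaluator <- function(cohort, config, cache) {
  force(cohort); force(config); force(cache)
  function(spec) evaluate_pipeline(cohort, spec, config, cache = cache)$value
}

#' Run the active-learning search over the pipeline space
#'
#' Closed-loop Bayesian optimisation: a burn-in of uniformly sampled
#' pipelines, then repeated (GP fit, UCB acquisition, snap to nearest
#' unsampled pipeline, evaluate) steps. No pipeline is evaluated twice. A
#' failing pipeline evaluation is imputed as the worst observed score minus
#' one sd and flagged.
#'
#' @param cohort A `subject_cohort` with splits assigned (ignored when a
#'   custom `evaluator` is supplied).
#' @param grid The `pipeline_grid`.
#' @param space The `embedded_space` over the grid.
#' @param config A [search_config()].
#' @param evaluator Optional function `f(spec) -> score` replacing the
#'   cross-validated evaluator (used for synthetic landscapes).
#' @param search_seed Seed for the sampling randomness (burn-in draw and
#'   acquisition starts); defaults to `config$seed`. Evaluation seeds always
#'   derive from `config$seed`, so scores match exhaustive evaluation.
#' @param cache Optional shared feature cache.
#' @return A `search_trace` list: `trace` tibble (iteration, pipeline_id,
#'   phase, score, acquisition, coordinates, flagged), final `gp`, `config`,
#'   `search_seed`.
#' @export
run_search <- function(cohort, grid, space, config, evaluator = NULL,
                       search_seed = NULL, cache = NULL) {
  stopifnot(inherits(space, "embedded_space"))
  p_total <- nrow(space)
  budget <- config$n_burn_in + config$n_iterations
  if (budget > p_total) {
    abort(sprintf("Budget %d exceeds grid size %d.", budget, p_total))
  }
  search_seed <- search_seed %||% config$seed
  if (is.null(evaluator)) {
    cache <- cache %||% new_feature_cache()
    evaluator <- default_evaluator(cohort, config, cache)
  }
  coords <- space_coords(space)
  get_spec <- function(id) {
    if (inherits(grid, "pipeline_grid")) pipeline_spec(grid, id) else list(pipeline_id = id)
  }

  safe_eval <- function(id, worst, sd_obs) {
    tryCatch(list(score = evaluator(get_spec(id)), flagged = FALSE),
             error = function(e) {
               inform(sprintf("Pipeline %d failed (%s); imputing worst - 1 sd.",
                              id, conditionMessage(e)))
               list(score = worst - sd_obs, flagged = TRUE)
             })
  }

  burn_ids <- with_preserved_seed(derive_seed(search_seed, 1L), {
    sample(space$pipeline_id, config$n_burn_in)
  })

  rows <- vector("list", budget)
  scores <- numeric(0)
  ids <- integer(0)
  for (b in seq_along(burn_ids)) {
    ev <- safe_eval(burn_ids[b],
                    worst = if (length(scores)) min(scores) else 0,
                    sd_obs = if (length(scores) > 1L) stats::sd(scores) else 1)
    ids <- c(ids, burn_ids[b])
    scores <- c(scores, ev$score)
    rows[[b]] <- tibble(iteration = b, pipeline_id = burn_ids[b],
                        phase = "burn_in", score = ev$score,
                        acquisition = NA_real_, flagged = ev$flagged)
  }

  gp <- NULL
  theta_prev <- NULL
  for (it in seq_len(config$n_iterations)) {
    xs <- coords[match(ids, space$pipeline_id), , drop = FALSE]
    gp <- fit_gp(xs, scores, kernel = config$kernel,
                 seed = derive_seed(search_seed, 100L + it),
                 prev_theta = theta_prev)
    theta_prev <- gp$theta
    prop <- propose_next(gp, space, sampled = ids, kappa = config$kappa,
                         seed = derive_seed(search_seed, 200L + it))
    ev <- safe_eval(prop$pipeline_id, worst = min(scores),
                    sd_obs = max(stats::sd(scores), 1e-8))
    ids <- c(ids, prop$pipeline_id)
    scores <- c(scores, ev$score)
    rows[[config$n_burn_in + it]] <- tibble(
      iteration = config$n_burn_in + it, pipeline_id = prop$pipeline_id,
      phase = "active", score = ev$score, acquisition = prop$acquisition,
      flagged = ev$flagged)
  }
  # final refit including the last evaluation
  xs <- coords[match(ids, space$pipeline_id), , drop = FALSE]
  gp <- fit_gp(xs, scores, kernel = config$kernel,
               seed = derive_seed(search_seed, 999L), prev_theta = theta_prev)

  trace <- dplyr::bind_rows(rows)
  trace <- dplyr::left_join(trace, as_tibble(space), by = "pipeline_id")
  structure(list(trace = trace, gp = gp, config = config,
                 search_seed = search_seed),
            class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace> %d evaluations (%d burn-in + %d active), kappa = %g, best = %.4f\n",
              nrow(x$trace), sum(x$trace$phase == "burn_in"),
              sum(x$trace$phase == "active"), x$config$kappa,
              max(x$trace$score)))
  invisible(x)
}

#' GP-estimated performance landscape over all pipelines
#'
#' @param gp A fitted `gp_model` (e.g. `trace$gp`).
#' @param space The `embedded_space`.
#' @return A `landscape_estimate` tibble: `pipeline_id`, `mu`, `sigma`.
#' @export
predict_landscape <- function(gp, space) {
  p <- predict(gp, space)
  structure(dplyr::bind_cols(tibble(pipeline_id = space$pipeline_id), p),
            class = c("landscape_estimate", class(p)))
}

#' @method tidy search_trace
#' @export
tidy.search_trace <- function(x, ...) x$trace

#' @method glance search_trace
#' @export
glance.search_trace <- function(x, ...) {
  tibble(
    n_evaluated = nrow(x$trace),
    n_burn_in = sum(x$trace$phase == "burn_in"),
    kappa = x$config$kappa,
    objective = x$config$objective,
    best_score = max(x$trace$score),
    best_pipeline_id = x$trace$pipeline_id[which.max(x$trace$score)]
  )
}
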