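#' Exhaustive (ground-truth) evaluation of the whole grid
#'
#' Evaluates every pipeline with the same seeded cross-validation as the
#' search loop, so any pipeline's score here is identical to its score in a
#' search trace run with the same config seed.
#'
#' @param cohort A `subject_cohort` with splits assigned.
#' @param grid The `pipeline_grid`.
#' @param config A [search_config()].
#' @param evaluator Optional `f(spec) -> score` override (synthetic
#'   landscapes).
#' @param cache Optional shared feature cache.
#' @return An `empirical_landscape` tibble: `pipeline_id`, `score`.
#' @export
exhaustive_evaluate <- function(cohort, grid, config, evaluator = NULL,
                                cache = NULL) {
  if (nrow(grid) == 0L) abort("The grid is empty.")
  if (is.null(evaluator)) {
    cache <- cache %||% new_feature_cache()
    evaluator <- default_evaluator(cohort, config, cache)
  }
  scores <- vapply(grid$pipeline_id, function(id) {
    spec <- if (inherits(grid, "pipeline_grid")) pipeline_spec(grid, id) else list(pipeline_id = id)
    tryCatch(evaluator(spec), error = function(e) {
      abort(sprintf("Pipeline %d failed during exhaustive evaluation: %s",
                    id, conditionMessage(e)))
    })
  }, numeric(1))
  structure(tibble(pipeline_id = grid$pipeline_id, score = scores),
            objective = config$objective,
            class = c("empirical_landscape", class(tibble())))
}

#' Spearman correlation between estimated and empirical landscapes
#'
#' Rank correlation (average ranks on ties) between the GP posterior mean and
#' the exhaustively measured scores, with a large-sample t-approximation
#' p-value attached as attribute `"p.value"`. A constant input yields a
#' flagged missing value.
#'
#' @param estimate A `landscape_estimate` (or numeric vector of estimates).
#' @param empirical An `empirical_landscape` (or numeric vector of scores).
#' @return Spearman rho (scalar) with attribute `p.value`.
#' @export
space_correlation <- function(estimate, empirical) {
  mu <- if (is.numeric(estimate)) estimate else {
    stopifnot(all(estimate$pipeline_id == empirical$pipeline_id))
    estimate$mu
  }
  emp <- if (is.numeric(empirical)) empirical else empirical$score
  if (length(mu) != length(emp)) abort("Landscapes cover different pipeline sets.")
  if (stats::sd(mu) == 0 || stats::sd(emp) == 0) {
    warn("Constant landscape: Spearman correlation undefined.")
    out <- NA_real_
    attr(out, "p.value") <- NA_real_
    return(out)
  }
  rho <- stats::cor(mu, emp, method = "spearman")
  n <- length(mu)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  attr(rho, "p.value") <- p
  rho
}

#' Extract the GP-estimated and best-sampled optima from a trace
#'
#' @param trace A `search_trace`.
#' @param space The `embedded_space`.
#' @param grid Optional grid; when given, factor levels of the optima are
#'   included.
#' @return Tibble with one row per optimum type (`"gp"`, `"sampled"`),
#'   `pipeline_id` and, for the sampled optimum, the observed score.
#' @export
extract_optima <- function(trace, space, grid = NULL) {
  est <- predict_landscape(trace$gp, space)
  gp_id <- est$pipeline_id[order(-est$mu, est$pipeline_id)[1L]]
  tr <- trace$trace
  samp_id <- tr$pipeline_id[order(-tr$score, tr$pipeline_id)[1L]]
  out <- tibble(
    optimum = c("gp", "sampled"),
    pipeline_id = c(gp_id, samp_id),
    score = c(NA_real_, max(tr$score))
  )
  if (!is.null(grid)) {
    out <- dplyr::left_join(out, as_tibble(grid), by = "pipeline_id")
  }
  out
}

#' Lock-box hold-out score of a pipeline
#'
#' Refits the estimator on the entire search split and scores it once on the
#' untouched holdout split.
#'
#' @param cohort A `subject_cohort` with splits assigned.
#' @param spec Pipeline spec.
#' @param config A [search_config()].
#' @param cache Optional shared feature cache.
#' @return A `pipeline_score` (single holdout value; `folds` has length 1).
#' @export
holdout_score <- function(cohort, spec, config, cache = NULL) {
  spec <- as.list(spec)
  tr_idx <- split_subjects(cohort, "search")
  te_idx <- split_subjects(cohort, "holdout")
  y_tr <- cohort$subjects$target[tr_idx]
  y_te <- cohort$subjects$target[te_idx]
  classify <- config$objective == "auc"
  if (classify && length(unique(y_te)) < 2L) {
    abort("Holdout split must contain both classes for classification scoring.")
  }
  x_tr <- subject_features(cohort, spec, tr_idx, seed = config$seed, cache = cache)
  x_te <- subject_features(cohort, spec, te_idx, seed = config$seed, cache = cache)
  pred <- fit_and_predict(x_tr, y_tr, x_te, config$estimator)
  val <- if (classify) auc_score(y_te, pred) else -mae_score(y_te, pred)
  structure(
    list(pipeline_id = spec$pipeline_id %||% 0L, value = val, folds = val,
         objective = config$objective, seed = config$seed),
    class = "pipeline_score"
  )
}

#' Repeated searches for reliability assessment
#'
#' Runs the full search `n_reps` times with distinct sampling seeds (burn-in
#' and acquisition randomness vary; per-pipeline evaluation seeds stay tied
#' to the config seed), and reports per repetition the GP-estimated optimum,
#' the best-sampled optimum, its lock-box holdout score and the Spearman
#' correlation between the estimated and empirical landscapes.
#'
#' @param cohort A `subject_cohort` with splits assigned.
#' @param grid The `pipeline_grid`.
#' @param space The `embedded_space`.
#' @param config A [search_config()].
#' @param n_reps Number of repetitions (the conventional reliability check
#'   uses 20).
#' @param base_seed First sampling seed; repetition r uses `base_seed + r`.
#' @param empirical Optional precomputed `empirical_landscape` (computed once
#'   otherwise).
#' @param evaluator Optional evaluator override (synthetic landscapes); when
#'   given, holdout scores are the evaluator's value at the sampled optimum.
#' @param cache Optional shared feature cache.
#' @return A `repetition_report` tibble: `rep`, `seed`, `gp_optimum`,
#'   `sampled_optimum`, `sampled_score`, `holdout`, `rho`, `failed`,
#'   `message`.
#' @export
repeat_search <- function(cohort, grid, space, config, n_reps = 20L,
                          base_seed = NULL, empirical = NULL,
                          evaluator = NULL, cache = NULL) {
  if (!is_count(n_reps, 1L)) abort("`n_reps` must be a positive integer.")
  base_seed <- base_seed %||% config$seed
  if (is.null(cache) && is.null(evaluator)) cache <- new_feature_cache()
  if (is.null(empirical)) {
    empirical <- exhaustive_evaluate(cohort, grid, config,
                                     evaluator = evaluator, cache = cache)
  }
  rows <- lapply(seq_len(n_reps), function(r) {
    seed_r <- base_seed + r
    tryCatch({
      tr <- run_search(cohort, grid, space, config, evaluator = evaluator,
                       search_seed = seed_r, cache = cache)
      opt <- extract_optima(tr, space)
      est <- predict_landscape(tr$gp, space)
      rho <- space_correlation(est, empirical)
      samp_id <- opt$pipeline_id[opt$optimum == "sampled"]
      ho <- if (is.null(evaluator)) {
        holdout_score(cohort, pipeline_spec(grid, samp_id), config,
                      cache = cache)$value
      } else {
        empirical$score[empirical$pipeline_id == samp_id]
      }
      tibble(rep = r, seed = seed_r,
             gp_optimum = opt$pipeline_id[opt$optimum == "gp"],
             sampled_optimum = samp_id,
             sampled_score = opt$score[opt$optimum == "sampled"],
             holdout = ho, rho = as.numeric(rho),
             failed = FALSE, message = NA_character_)
    }, error = function(e) {
      tibble(rep = r, seed = seed_r, gp_optimum = NA_integer_,
             sampled_optimum = NA_integer_, sampled_score = NA_real_,
             holdout = NA_real_, rho = NA_real_,
             failed = TRUE, message = conditionMessage(e))
    })
  })
  structure(dplyr::bind_rows(rows), empirical = empirical,
            class = c("repetition_report", class(tibble())))
}

#' @method glance repetition_report
#' @export
glance.repetition_report <- function(x, ...) {
  ok <- x[!x$failed, ]
  tibble(
    n_reps = nrow(x), n_failed = sum(x$failed),
    mean_rho = mean(ok$rho), sd_rho = stats::sd(ok$rho),
    mean_holdout = mean(ok$holdout), sd_holdout = stats::sd(ok$holdout),
    n_distinct_optima = dplyr::n_distinct(ok$sampled_optimum)
  )
}
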