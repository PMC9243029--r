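# Shared fixtures are built once per test run and memoised here; everything
# is generated in code under fixed seeds.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- build()
  fixture_env[[key]]
}

small_regression_cohort <- function() {
  memo("reg_cohort", function() {
    co <- suppressMessages(generate_cohort(cohort_config(
      n_subjects = 40, n_regions = 14, n_timepoints = 100,
      signal_strength = 0.4, seed = 101)))
    split_dataset(co, sizes = c(14, 18, 8), seed = 7)
  })
}

small_regression_grid <- function() {
  memo("reg_grid", function() {
    default_regression_grid(
      sparsities = c(0.05, 0.1, 0.2, 0.3),
      graph_metrics = c("strength", "betweenness", "eigenvector",
                        "participation", "closeness", "clustering"))
  })
}

small_classification_setup <- function() {
  memo("cls_setup", function() {
    grid <- default_classification_grid(
      preproc_variants = c("ccs", "cpac"),
      strategies = c("filt_global", "nofilt_noglobal"),
      parcellations = c("ho", "tt"),
      fc_metrics = c("covariance", "correlation", "partial_correlation", "tangent"))
    co <- suppressMessages(generate_cohort(cohort_config(
      n_subjects = 48, n_regions = 12, n_timepoints = 80, n_variants = 4,
      task = "classification", signal_strength = 0.35, seed = 202,
      variant_labels = classification_variant_labels(grid))))
    co <- add_parcellations(co, c(ho = 12, tt = 8))
    co <- split_dataset(co, sizes = c(16, 20, 12), stratify = TRUE, seed = 3)
    list(cohort = co, grid = grid)
  })
}

# Small embedded space + analytic landscape used for search-loop tests:
# pipelines on a grid of coordinates with a smooth two-bump score surface.
synthetic_landscape <- function(p_side = 8) {
  memo(sprintf("landscape_%d", p_side), function() {
    gxy <- expand.grid(x = seq(0, 1, length.out = p_side),
                       y = seq(0, 1, length.out = p_side))
    coords <- as.matrix(gxy)
    space <- structure(
      tibble::tibble(pipeline_id = seq_len(nrow(coords)),
                     dim1 = coords[, 1], dim2 = coords[, 2]),
      method = "fixture", seed = 0L, stress = NA_real_,
      params = list(d = 2L), class = c("embedded_space", "tbl_df", "tbl", "data.frame"))
    f <- function(x, y) {
      exp(-((x - 0.75)^2 + (y - 0.7)^2) / 0.02) +
        0.6 * exp(-((x - 0.2)^2 + (y - 0.25)^2) / 0.06)
    }
    scores <- f(coords[, 1], coords[, 2])
    grid <- structure(
      tibble::tibble(pipeline_id = seq_len(nrow(coords))),
      factors = list(), class = c("tbl_df", "tbl", "data.frame"))
    list(space = space, scores = scores,
         evaluator = function(spec) scores[spec$pipeline_id],
         grid = grid)
  })
}

# ---- independent oracles ---------------------------------------------------

# Partial correlation of each pair given all other regions, via regression
# residuals.
oracle_partial_correlation <- function(ts) {
  x <- t(ts)
  n <- ncol(x)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      others <- x[, -c(i, j), drop = FALSE]
      ri <- stats::resid(stats::lm(x[, i] ~ others))
      rj <- stats::resid(stats::lm(x[, j] ~ others))
      out[i, j] <- out[j, i] <- stats::cor(ri, rj)
    }
  }
  out
}

# Eigenvector centrality by shifted power iteration on |A| (the shift
# prevents oscillation on bipartite graphs such as stars and paths).
oracle_eigenvector <- function(a, iters = 5000) {
  a <- abs(a); diag(a) <- 0
  shift <- max(rowSums(a))
  m <- a + diag(shift, nrow(a))
  v <- rep(1, nrow(a))
  for (i in seq_len(iters)) {
    v2 <- m %*% v
    v <- as.numeric(v2 / sqrt(sum(v2^2)))
  }
  v / max(v)
}

oracle_cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# Spearman rho from the rank formula (no ties assumed).
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  1 - 6 * sum(d^2) / (length(a) * (length(a)^2 - 1))
}

# Participation coefficient by direct formula.
oracle_participation <- function(a, comm) {
  a <- abs(a); diag(a) <- 0
  k <- rowSums(a)
  sapply(seq_len(nrow(a)), function(i) {
    if (k[i] == 0) return(0)
    1 - sum(sapply(unique(comm), function(m) {
      (sum(a[i, comm == m]) / k[i])^2
    }))
  })
}

with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(x)
}

with_preserved_sample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(n, k)
}
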