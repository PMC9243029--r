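#' Build a pipeline grid from factor declarations
#'
#' The multiverse of pipelines is the Cartesian product of the declared factor
#' levels, in deterministic order with the last factor varying fastest, with
#' stable ids `1..P`.
#'
#' @param factors Named list: factor name -> character vector of level labels.
#' @return A `pipeline_grid` tibble with a `pipeline_id` column and one column
#'   per factor; the level declaration is kept in the `"factors"` attribute.
#' @export
#' @examples
#' build_grid(list(a = c("x", "y"), b = c("1", "2", "3")))
build_grid <- function(factors) {
  if (!is.list(factors) || length(factors) < 1L || is.null(names(factors)) ||
      any(names(factors) == "")) {
    abort("`factors` must be a non-empty named list of level vectors.")
  }
  for (nm in names(factors)) {
    lv <- factors[[nm]]
    if (length(lv) < 1L) abort(sprintf("Factor '%s' has no levels.", nm))
    if (anyDuplicated(lv)) {
      abort(sprintf("Factor '%s' has duplicate level labels.", nm))
    }
    factors[[nm]] <- as.character(lv)
  }
  # expand.grid varies the first column fastest; feed factors reversed so the
  # declared LAST factor is fastest, then restore column order.
  g <- expand.grid(rev(factors), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(factors)), drop = FALSE]
  out <- as_tibble(g)
  out <- dplyr::bind_cols(tibble(pipeline_id = seq_len(nrow(out))), out)
  structure(out, factors = factors,
            class = c("pipeline_grid", class(out)))
}

#' Default proportional-threshold (sparsity) levels
#'
#' Seventeen values spanning 0.01 (highly sparse) to 0.4 (dense), the range
#' conventionally explored for proportional thresholding of functional
#' connectomes.
#' @return Numeric vector of length 17.
#' @export
default_sparsities <- function() {
  c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10, 0.125, 0.15,
    0.175, 0.20, 0.225, 0.25, 0.275, 0.30, 0.40)
}

#' Default grid for the regression (age-prediction) design
#'
#' Two data variants (motion regression vs global signal regression), 17
#' proportional thresholds and 16 nodal graph metrics: 544 pipelines.
#'
#' @param data_variants,sparsities,graph_metrics Optional overrides of the
#'   factor levels.
#' @return A `pipeline_grid`.
#' @export
default_regression_grid <- function(data_variants = c("motion_regression",
                                                      "global_signal_regression"),
                                    sparsities = default_sparsities(),
                                    graph_metrics = names(default_metric_registry())) {
  build_grid(list(
    data_variant = data_variants,
    sparsity = format(sparsities, trim = TRUE, drop0trailing = TRUE),
    graph_metric = graph_metrics
  ))
}

#' Default grid for the classification (diagnosis) design
#'
#' Four preprocessing variants, four processing strategies (band-pass
#' filtering x global signal regression), six parcellations and four
#' functional-connectivity estimators: 384 pipelines.
#'
#' @param preproc_variants,strategies,parcellations,fc_metrics Optional
#'   overrides of the factor levels.
#' @return A `pipeline_grid`.
#' @export
default_classification_grid <- function(preproc_variants = c("ccs", "cpac", "dparsf", "niak"),
                                        strategies = c("filt_global", "filt_noglobal",
                                                       "nofilt_global", "nofilt_noglobal"),
                                        parcellations = c("dosenbach160", "cc200", "cc400",
                                                          "ez", "ho", "tt"),
                                        fc_metrics = c("covariance", "correlation",
                                                       "partial_correlation", "tangent")) {
  build_grid(list(
    preproc_variant = preproc_variants,
    strategy = strategies,
    parcellation = parcellations,
    fc_metric = fc_metrics
  ))
}

grid_factors <- function(grid) attr(grid, "factors")

# Which study design does a grid/spec describe?
grid_design <- function(x) {
  nms <- if (inherits(x, "pipeline_grid")) names(grid_factors(x)) else names(x)
  if ("graph_metric" %in% nms) return("regression")
  if ("fc_metric" %in% nms) return("classification")
  abort("Cannot infer the design: expected a `graph_metric` or `fc_metric` factor.")
}

# One grid row as a named list (a PipelineSpec).
pipeline_spec <- function(grid, id) {
  row <- grid[grid$pipeline_id == id, , drop = FALSE]
  if (nrow(row) != 1L) abort(sprintf("Unknown pipeline id %s.", id))
  as.list(row)
}
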