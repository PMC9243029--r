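# Feature extraction: one pipeline applied end-to-end to a set of subjects.
#
# Regression design: Pearson correlation FC on the spec's data variant ->
# proportional threshold at sparsity s -> nodal graph metric -> one value per
# region. Classification design: select variant (preproc x strategy) and
# parcellation -> connectivity estimator -> strict lower triangle of the FC
# matrix.
#
# An environment-based cache keyed on intermediate products (per-subject FC,
# thresholded graphs, parcel covariances, tangent references) is shared
# across pipelines by build_similarity_table() and the evaluators, since
# those intermediates are pipeline-factor-specific, not pipeline-specific.

new_feature_cache <- function() new.env(parent = emptyenv())

cache_get <- function(cache, key, compute) {
  if (is.null(cache)) return(compute())
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- compute()
  cache[[key]] <- val
  val
}

classification_variant_label <- function(preproc, strategy) {
  paste(preproc, strategy, sep = ".")
}

#' Classification variant labels for a grid
#'
#' The classification design realises the preprocessing and strategy factors
#' as distinct data variants; this helper enumerates the variant labels a
#' cohort must provide for a given grid (`preproc.strategy`).
#' @param grid A classification `pipeline_grid`.
#' @return Character vector of variant labels.
#' @export
classification_variant_labels <- function(grid) {
  f <- grid_factors(grid)
  as.vector(outer(f$preproc_variant, f$strategy,
                  classification_variant_label))
}

# Parcel-mean time series.
aggregate_regions <- function(ts, parcel_map) {
  agg <- rowsum(ts, parcel_map)
  agg / as.vector(table(parcel_map))
}

subject_features <- function(cohort, spec, subject_idx, seed = 1L,
                             cache = NULL) {
  design <- grid_design(spec)
  if (design == "regression") {
    variant <- spec$data_variant
    if (!variant %in% names(cohort$variants)) {
      abort(sprintf("Data variant '%s' not present in the cohort.", variant))
    }
    s <- as.numeric(spec$sparsity)
    mats <- lapply(subject_idx, function(i) {
      key <- sprintf("thr|%s|%s|%d", variant, spec$sparsity, i)
      cache_get(cache, key, function() {
        fc <- cache_get(cache, sprintf("fc|%s|%d", variant, i), function() {
          compute_fc(cohort$variants[[variant]][[i]], "correlation")
        })
        proportional_threshold(fc, s)
      })
    })
    met_seed <- derive_seed(seed, spec$pipeline_id %||% 0L)
    feats <- lapply(mats, function(a) {
      nodal_metric(a, spec$graph_metric, communities = cohort$communities,
                   seed = met_seed)
    })
  } else {
    variant <- classification_variant_label(spec$preproc_variant, spec$strategy)
    if (!variant %in% names(cohort$variants)) {
      abort(sprintf("Data variant '%s' not present in the cohort.", variant))
    }
    if (is.null(cohort$parcellations) ||
        !spec$parcellation %in% names(cohort$parcellations)) {
      abort(sprintf("Parcellation '%s' not attached to the cohort.", spec$parcellation))
    }
    pm <- cohort$parcellations[[spec$parcellation]]
    covs <- lapply(subject_idx, function(i) {
      cache_get(cache, sprintf("cov|%s|%s|%d", variant, spec$parcellation, i),
                function() {
        ts <- aggregate_regions(cohort$variants[[variant]][[i]], pm)
        stats::cov(t(ts))
      })
    })
    fcs <- switch(spec$fc_metric,
      covariance = covs,
      correlation = lapply(covs, stats::cov2cor),
      partial_correlation = lapply(covs, partial_correlation),
      tangent = {
        ref <- cache_get(cache,
          sprintf("ref|%s|%s|%s", variant, spec$parcellation,
                  paste(c(range(subject_idx), length(subject_idx)), collapse = ":")),
          function() tangent_reference(covs))
        lapply(covs, tangent_project, reference = ref)
      },
      abort(sprintf("Unknown fc_metric '%s'.", spec$fc_metric))
    )
    feats <- lapply(fcs, function(m) m[lower.tri(m)])
  }
  out <- do.call(rbind, feats)
  rownames(out) <- cohort$subjects$subject_id[subject_idx]
  out
}

#' Apply one pipeline to a set of subjects
#'
#' Runs a pipeline end-to-end (connectivity estimation, thresholding, graph
#' metric or FC vectorisation, per design) and returns one feature vector per
#' subject.
#'
#' @param cohort A `subject_cohort`.
#' @param spec A single-row `pipeline_grid` subset, or a named list with the
#'   design's factor levels and a `pipeline_id`.
#' @param subjects Integer subject indices (default: all subjects).
#' @param seed Base seed from which stochastic metric seeds are derived per
#'   pipeline id.
#' @return A tibble with `subject_id`, `pipeline_id`, and a `features`
#'   list-column of numeric vectors (constant length within the pipeline).
#' @export
apply_pipeline <- function(cohort, spec, subjects = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "subject_cohort"))
  spec <- as.list(spec)
  if (is.null(subjects)) subjects <- seq_len(nrow(cohort$subjects))
  fm <- subject_features(cohort, spec, subjects, seed = seed)
  tibble(
    subject_id = rownames(fm),
    pipeline_id = spec$pipeline_id %||% NA_integer_,
    features = lapply(seq_len(nrow(fm)), function(i) fm[i, ])
  )
}

#' Stack a feature tibble into a subjects x features matrix
#' @param features Output of [apply_pipeline()].
#' @return Numeric matrix with subject ids as row names.
#' @export
features_matrix <- function(features) {
  m <- do.call(rbind, features$features)
  rownames(m) <- features$subject_id
  m
}
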