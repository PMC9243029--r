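#' Number of unordered participant pairs
#'
#' The similarity signature of a pipeline has one entry per unordered subject
#' pair: n(n-1)/2 (self-pairs are ignored).
#' @param n_subjects Positive integer.
#' @return Non-negative integer.
#' @export
#' @examples
#' pair_count(50)   # 1225
#' pair_count(176)  # 15400
pair_count <- function(n_subjects) {
  if (!is_count(n_subjects, min = 1L)) abort("`n_subjects` must be a positive integer.")
  as.integer(n_subjects * (n_subjects - 1) / 2)
}

#' Cosine similarity over all subject pairs
#'
#' Computes the cosine similarity between every unordered pair of subjects'
#' feature vectors, in lexicographic (i, j) pair order. A zero-norm feature
#' vector yields similarity 0 with every other subject.
#'
#' @param features Subjects x features numeric matrix, or the tibble returned
#'   by [apply_pipeline()].
#' @return Numeric vector of length n(n-1)/2 with values in \[-1, 1\].
#' @export
#' @examples
#' subject_similarity(rbind(c(1, 2, 3), c(3, 2, 1)))  # 10/14
subject_similarity <- function(features) {
  m <- if (is.matrix(features)) features else features_matrix(features)
  if (nrow(m) < 2L) abort("At least two subjects are required.")
  if (!all(is.finite(m))) abort("Feature vectors must be finite.")
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  if (any(zero)) {
    log_note("%d zero-norm feature vector(s): similarities set to 0.", sum(zero))
    nrm[zero] <- 1
  }
  x <- m / nrm
  s <- tcrossprod(x)
  s[zero, ] <- 0
  s[, zero] <- 0
  pmin(pmax(upper_pairs(s), -1), 1)
}

#' Build the pipelines x participant-pairs similarity table
#'
#' Applies every pipeline in the grid to the space-split subjects and stores
#' each pipeline's between-participant cosine-similarity signature as one row:
#' a P x n(n-1)/2 matrix, the high-dimensional representation from which the
#' low-dimensional pipeline space is embedded.
#'
#' @param cohort A `subject_cohort` with splits assigned (or `subjects` given).
#' @param grid A `pipeline_grid`.
#' @param subjects Integer subject indices; defaults to the `"space"` split.
#' @param seed Base seed for stochastic pipeline components.
#' @return A `similarity_table` list: `matrix` (pipelines x pairs),
#'   `pipeline_id`, `pairs` (tibble of subject index pairs), `subject_id`.
#' @export
build_similarity_table <- function(cohort, grid, subjects = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "subject_cohort"), inherits(grid, "pipeline_grid"))
  if (is.null(subjects)) subjects <- split_subjects(cohort, "space")
  if (length(subjects) < 2L) abort("The space split must contain >= 2 subjects.")
  cache <- new_feature_cache()
  specs <- lapply(grid$pipeline_id, function(id) pipeline_spec(grid, id))
  rows <- lapply(specs, function(spec) {
    tryCatch({
      fm <- subject_features(cohort, spec, subjects, seed = seed, cache = cache)
      subject_similarity(fm)
    }, error = function(e) {
      abort(sprintf("Pipeline %d (%s) failed: %s", spec$pipeline_id,
                    paste(unlist(spec[-1]), collapse = "/"), conditionMessage(e)))
    })
  })
  structure(
    list(matrix = do.call(rbind, rows),
         pipeline_id = grid$pipeline_id,
         pairs = pair_index_tbl(length(subjects)),
         subject_id = cohort$subjects$subject_id[subjects]),
    class = "similarity_table"
  )
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> %d pipelines x %d participant pairs\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

table_dissimilarity <- function(table, dissimilarity = c("euclidean", "correlation")) {
  dissimilarity <- match.arg(dissimilarity)
  m <- if (inherits(table, "similarity_table")) table$matrix else as.matrix(table)
  if (dissimilarity == "euclidean") {
    stats::dist(m)
  } else {
    stats::as.dist(1 - stats::cor(t(m)))
  }
}

# Metric MDS by SMACOF majorisation, initialised from classical scaling
# (deterministic). Returns coords plus normalised stress-1.
smacof_mds <- function(d, k = 2L, max_iter = 300L, tol = 1e-9, init = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  x <- if (is.null(init)) {
    x0 <- suppressWarnings(stats::cmdscale(d, k = k))
    if (ncol(x0) < k) x0 <- cbind(x0, matrix(0, n, k - ncol(x0)))
    x0
  } else init
  dhat <- dm
  stress_of <- function(x) {
    dd <- as.matrix(stats::dist(x))
    sqrt(sum((dhat - dd)[upper.tri(dd)]^2) / sum(dhat[upper.tri(dhat)]^2))
  }
  s_prev <- stress_of(x)
  for (it in seq_len(max_iter)) {
    dd <- as.matrix(stats::dist(x))
    ratio <- ifelse(dd > 0, dhat / dd, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- b %*% x / n
    s <- stress_of(x)
    if (abs(s_prev - s) < tol) break
    s_prev <- s
  }
  list(coords = x, stress = stress_of(x))
}

#' Embed the similarity table into a low-dimensional pipeline space
#'
#' Metric MDS (SMACOF, minimising stress over the Euclidean distances between
#' similarity-table rows; classical-scaling initialisation, so deterministic)
#' or PCA (top-d principal coordinates of the row-centred table). Further
#' embedding methods can be registered via `registry`.
#'
#' @param table A `similarity_table` (or plain matrix of pipeline signatures).
#' @param method `"mds"` (default) or `"pca"`, or a registered plugin name.
#' @param d Embedding dimension (>= 2; all downstream machinery is
#'   dimension-agnostic but 2 is the standard choice).
#' @param seed Seed recorded in the result and forwarded to plugin methods;
#'   the built-in methods are deterministic.
#' @param dissimilarity Pipeline-pair dissimilarity for MDS: `"euclidean"`
#'   distance between table rows (default) or `"correlation"` distance.
#' @param registry Named list of extra embedding functions
#'   `f(table_matrix, d, seed)` returning a coordinate matrix.
#' @param init Optional MDS initialisation matrix (P x d); default classical
#'   scaling.
#' @return An `embedded_space` tibble (`pipeline_id`, `dim1`, ..., `dimd`)
#'   with attributes `method`, `seed`, `stress` (MDS) and `params`.
#' @export
embed_pipelines <- function(table, method = "mds", d = 2L, seed = 1L,
                            dissimilarity = c("euclidean", "correlation"),
                            registry = list(), init = NULL) {
  dissimilarity <- match.arg(dissimilarity)
  m <- if (inherits(table, "similarity_table")) table$matrix else as.matrix(table)
  ids <- if (inherits(table, "similarity_table")) table$pipeline_id else seq_len(nrow(m))
  if (!is_count(d, min = 2L)) abort("`d` must be an integer >= 2.")
  stress <- NA_real_
  if (method == "mds") {
    dd <- table_dissimilarity(table, dissimilarity)
    fit <- smacof_mds(dd, k = d, init = init)
    coords <- fit$coords
    stress <- fit$stress
  } else if (method == "pca") {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    coords <- pc$x[, seq_len(min(d, ncol(pc$x))), drop = FALSE]
    if (ncol(coords) < d) coords <- cbind(coords, matrix(0, nrow(m), d - ncol(coords)))
  } else if (method %in% names(registry)) {
    coords <- registry[[method]](m, d, seed)
  } else {
    abort(sprintf("Unknown embedding method '%s'. Available: %s", method,
                  paste(c("mds", "pca", names(registry)), collapse = ", ")))
  }
  out <- as_tibble(setNames(as.data.frame(coords),
                            paste0("dim", seq_len(ncol(coords)))))
  out <- dplyr::bind_cols(tibble(pipeline_id = ids), out)
  structure(out, method = method, seed = seed, stress = stress,
            params = list(d = d, dissimilarity = dissimilarity),
            class = c("embedded_space", class(out)))
}

space_coords <- function(space) {
  as.matrix(space[, grep("^dim", names(space)), drop = FALSE])
}

#' Neighbourhood-preservation score of an embedding
#'
#' For each pipeline, the fraction of its k nearest neighbours in the
#' original (high-dimensional) dissimilarity that remain among its k nearest
#' neighbours after embedding, averaged over pipelines. 1 means perfect
#' neighbourhood preservation; the complementary dissimilarity score is
#' `1 - score`. Ties are broken by pipeline id.
#'
#' @param table A `similarity_table` (or matrix of signatures).
#' @param space An `embedded_space` over the same pipelines.
#' @param k Neighbour count, in \[1, P-1\].
#' @param dissimilarity Original-space dissimilarity (as in
#'   [embed_pipelines()]).
#' @return Score in \[0, 1\].
#' @export
neighborhood_preservation <- function(table, space, k,
                                      dissimilarity = c("euclidean", "correlation")) {
  d_orig <- as.matrix(table_dissimilarity(table, match.arg(dissimilarity)))
  d_emb <- as.matrix(stats::dist(space_coords(space)))
  p <- nrow(d_orig)
  if (!is_count(k, min = 1L) || k > p - 1L) abort("`k` must lie in [1, P-1].")
  knn <- function(dm) {
    lapply(seq_len(p), function(i) {
      ord <- order(dm[i, ], seq_len(p))
      setdiff(ord, i)[seq_len(k)]
    })
  }
  a <- knn(d_orig)
  b <- knn(d_emb)
  mean(vapply(seq_len(p), function(i) length(intersect(a[[i]], b[[i]])) / k, 0))
}
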