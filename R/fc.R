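#' Functional connectivity estimators
#'
#' Computes a symmetric region x region connectivity matrix from a
#' region x time matrix. Supported estimators: `covariance`, (Pearson)
#' `correlation`, `partial_correlation` (from the precision matrix, with the
#' standard sign and normalisation -Omega_ij / sqrt(Omega_ii Omega_jj)), and
#' `tangent` (projection of the covariance into the tangent space at a
#' reference: logm(ref^{-1/2} C ref^{-1/2})).
#'
#' Near-singular covariances for the precision-based estimators are ridge
#' regularised by adding `1e-6 * mean(diag)` to the diagonal when the
#' condition number exceeds 1e12.
#'
#' @param timeseries Region x time numeric matrix with at least 3 timepoints.
#' @param metric Estimator label.
#' @param reference Symmetric positive-definite reference covariance; required
#'   for `tangent` (see [tangent_reference()]).
#' @return Symmetric region x region matrix.
#' @export
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5, 50)
#' range(compute_fc(ts, "correlation"))
compute_fc <- function(timeseries,
                       metric = c("correlation", "covariance",
                                  "partial_correlation", "tangent"),
                       reference = NULL) {
  metric <- match.arg(metric)
  if (!is.matrix(timeseries) || ncol(timeseries) < 3L) {
    abort("`timeseries` must be a region x time matrix with >= 3 timepoints.")
  }
  cmat <- switch(metric,
    correlation = stats::cor(t(timeseries)),
    covariance = stats::cov(t(timeseries)),
    partial_correlation = partial_correlation(stats::cov(t(timeseries))),
    tangent = {
      if (is.null(reference)) abort("`tangent` requires a `reference` matrix.")
      tangent_project(stats::cov(t(timeseries)), reference)
    }
  )
  (cmat + t(cmat)) / 2
}

ridge_if_singular <- function(covmat) {
  ev <- eigen(covmat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.xmin) > 1e12) {
    lam <- 1e-6 * mean(diag(covmat))
    log_note("Ill-conditioned covariance: ridge-regularised with lambda = %.3g.", lam)
    covmat <- covmat + diag(lam, nrow(covmat))
  }
  covmat
}

partial_correlation <- function(covmat) {
  covmat <- ridge_if_singular(covmat)
  omega <- solve(covmat)
  d <- sqrt(diag(omega))
  p <- -omega / tcrossprod(d)
  diag(p) <- 1
  p
}

# Symmetric matrix functions via eigendecomposition.
sym_fun <- function(m, f) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

tangent_project <- function(covmat, reference) {
  covmat <- ridge_if_singular(covmat)
  wref <- sym_fun(reference, function(v) 1 / sqrt(pmax(v, 1e-10)))
  m <- wref %*% covmat %*% wref
  sym_fun(m, function(v) log(pmax(v, 1e-12)))
}

#' Reference covariance for the tangent projection
#'
#' Default: the Euclidean mean of the covariances, projected onto the
#' positive-definite cone by flooring eigenvalues at 1e-10. A geometric
#' (affine-invariant Karcher) mean is available as an option.
#'
#' @param covariances List of same-sized symmetric positive-definite matrices.
#' @param method `"euclidean"` (default) or `"geometric"`.
#' @param tol,max_iter Convergence controls for the geometric mean.
#' @return Symmetric positive-definite matrix.
#' @export
tangent_reference <- function(covariances, method = c("euclidean", "geometric"),
                              tol = 1e-10, max_iter = 50L) {
  method <- match.arg(method)
  if (!is.list(covariances) || length(covariances) < 1L) {
    abort("`covariances` must be a non-empty list of matrices.")
  }
  dims <- vapply(covariances, function(m) dim(m), integer(2))
  if (length(unique(dims[1, ])) != 1L || any(dims[1, ] != dims[2, ])) {
    abort("All covariance matrices must be square and the same size.")
  }
  emean <- Reduce(`+`, covariances) / length(covariances)
  emean <- sym_fun(emean, function(v) pmax(v, 1e-10))
  if (method == "euclidean") return((emean + t(emean)) / 2)

  ref <- emean
  for (it in seq_len(max_iter)) {
    wr <- sym_fun(ref, function(v) 1 / sqrt(pmax(v, 1e-10)))
    rs <- sym_fun(ref, function(v) sqrt(pmax(v, 1e-10)))
    logs <- lapply(covariances, function(cmat) {
      sym_fun(wr %*% cmat %*% wr, function(v) log(pmax(v, 1e-12)))
    })
    step <- Reduce(`+`, logs) / length(logs)
    if (max(abs(step)) < tol) break
    ref <- rs %*% sym_fun(step, exp) %*% rs
    ref <- (ref + t(ref)) / 2
  }
  ref
}

#' Proportional threshold of a connectivity matrix
#'
#' Retains the `ceiling(s * E)` largest off-diagonal weights (E = n(n-1)/2
#' unique pairs) and zeroes the rest, keeping retained weights (no
#' binarisation). Ties at the cut are broken deterministically by
#' lexicographic (i, j) pair order. The diagonal is ignored and zeroed.
#'
#' @param fc Symmetric numeric matrix.
#' @param s Sparsity in (0, 1]: the fraction of strongest edges kept.
#' @return Symmetric weighted matrix with zero diagonal.
#' @export
#' @examples
#' m <- abs(cor(matrix(rnorm(80), 20, 4)))
#' sum(proportional_threshold(m, 0.5)[upper.tri(m)] != 0)
proportional_threshold <- function(fc, s) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) abort("`fc` must be square.")
  if (!is_scalar_num(s) || s <= 0 || s > 1) abort("`s` must lie in (0, 1].")
  n <- nrow(fc)
  idx <- which(upper.tri(fc), arr.ind = TRUE)
  w <- fc[idx]
  if (all(w == 0)) {
    warn("All off-diagonal weights are zero; matrix returned unchanged.")
    out <- fc
    diag(out) <- 0
    return(out)
  }
  k <- ceiling(s * nrow(idx))
  keep <- order(-w, idx[, 1L], idx[, 2L])[seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(fc))
  kept <- idx[keep, , drop = FALSE]
  out[kept] <- w[keep]
  out[kept[, 2:1, drop = FALSE]] <- w[keep]
  out
}
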