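# Nodal graph metrics over weighted, symmetric adjacency matrices.
#
# Distance-based metrics interpret edge lengths as 1/|w| (stronger coupling =
# shorter path); spectral metrics use |w| where non-negativity is required.
# Community-dependent metrics take the cohort's region communities.

graph_from_adj <- function(adjacency, absolute = FALSE) {
  a <- adjacency
  if (absolute) a <- abs(a)
  diag(a) <- 0
  igraph::graph_from_adjacency_matrix(a, mode = "undirected", weighted = TRUE)
}

edge_lengths <- function(g) 1 / abs(igraph::E(g)$weight)

node_strength <- function(adjacency, ...) rowSums(adjacency) - diag(adjacency)

node_degree <- function(adjacency, ...) {
  a <- adjacency
  diag(a) <- 0
  rowSums(a != 0)
}

metric_betweenness <- function(adjacency, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  unname(igraph::betweenness(g, weights = edge_lengths(g), normalized = FALSE))
}

# Leading eigenvector of |A| via a full symmetric eigendecomposition:
# deterministic (ARPACK-based routines use a random start vector, which
# would break bit-reproducibility of pipeline signatures).
metric_eigenvector <- function(adjacency, ...) {
  a <- abs(adjacency)
  diag(a) <- 0
  if (all(a == 0)) return(rep(0, nrow(a)))
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, 1L]
  v <- abs(v)  # Perron vector of a non-negative matrix is sign-definite
  v / max(v)
}

# Harmonic closeness: finite on disconnected graphs, which proportional
# thresholding routinely produces at low sparsity.
metric_closeness <- function(adjacency, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  if (igraph::ecount(g) == 0L) return(rep(0, nrow(adjacency)))
  unname(igraph::harmonic_centrality(g, weights = edge_lengths(g),
                                     normalized = TRUE))
}

metric_pagerank <- function(adjacency, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  unname(igraph::page_rank(g, weights = igraph::E(g)$weight)$vector)
}

metric_clustering <- function(adjacency, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  v <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  v[!is.finite(v)] <- 0
  unname(v)
}

metric_local_efficiency <- function(adjacency, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  if (igraph::ecount(g) == 0L) return(rep(0, nrow(adjacency)))
  v <- igraph::local_efficiency(g, weights = edge_lengths(g))
  v[!is.finite(v)] <- 0
  unname(v)
}

metric_coreness <- function(adjacency, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  unname(igraph::coreness(g))
}

# Weighted subgraph centrality: sum_j V_ij^2 exp(lambda_j), computed from the
# eigendecomposition of the (weight-rescaled) adjacency for numerical range.
metric_subgraph <- function(adjacency, ...) {
  a <- abs(adjacency)
  diag(a) <- 0
  mx <- max(a)
  if (mx > 0) a <- a / mx
  e <- eigen(a, symmetric = TRUE)
  rowSums(e$vectors^2 * rep(exp(e$values), each = nrow(a)))
}

comm_strengths <- function(adjacency, communities) {
  a <- abs(adjacency)
  diag(a) <- 0
  vapply(sort(unique(communities)), function(m) {
    rowSums(a[, communities == m, drop = FALSE])
  }, numeric(nrow(a)))
}

metric_participation <- function(adjacency, communities, ...) {
  ks <- comm_strengths(adjacency, communities)
  k <- rowSums(ks)
  p <- 1 - rowSums((ks / pmax(k, .Machine$double.eps))^2)
  p[k == 0] <- 0
  p
}

metric_module_zscore <- function(adjacency, communities, ...) {
  ks <- comm_strengths(adjacency, communities)
  comm_levels <- sort(unique(communities))
  own <- ks[cbind(seq_along(communities), match(communities, comm_levels))]
  z <- numeric(length(communities))
  for (m in comm_levels) {
    idx <- communities == m
    mu <- mean(own[idx])
    sg <- stats::sd(own[idx])
    z[idx] <- if (is.na(sg) || sg == 0) 0 else (own[idx] - mu) / sg
  }
  z
}

metric_within_community_strength <- function(adjacency, communities, ...) {
  a <- abs(adjacency)
  diag(a) <- 0
  same <- outer(communities, communities, "==")
  rowSums(a * same)
}

# Gateway coefficient: like the participation coefficient, but each
# between-module connection is weighted by how critical the node's links are
# for its target module, with node importance measured by degree/strength or
# betweenness centrality.
gateway_coefficient <- function(adjacency, communities, centrality = c("degree", "betweenness")) {
  centrality <- match.arg(centrality)
  a <- abs(adjacency)
  diag(a) <- 0
  n <- nrow(a)
  comm_levels <- sort(unique(communities))
  M <- length(comm_levels)
  k <- rowSums(a)
  cent <- if (centrality == "degree") k else metric_betweenness(a)
  ks <- comm_strengths(a, communities)                 # node -> module strength
  # total strength entering module m (from all nodes), for normalising ks
  kjs <- matrix(0, n, M)
  for (mi in seq_len(M)) {
    idx <- communities == comm_levels[mi]
    tot <- colSums(ks[idx, , drop = FALSE])            # module mi -> each module
    kjs[, mi] <- tot[mi]
    kjs[idx, mi] <- kjs[idx, mi] / 2                   # within-module counted once
  }
  # centrality mass of each module reachable through i's neighbours
  csm <- matrix(0, n, M)
  for (i in seq_len(n)) {
    nb <- a[i, ] > 0
    for (mi in seq_len(M)) {
      csm[i, mi] <- sum(cent[nb & communities == comm_levels[mi]])
    }
  }
  mcn <- max(vapply(comm_levels, function(m) sum(cent[communities == m]), 0))
  ksm <- ks / pmax(kjs, .Machine$double.eps)
  gs <- (1 - ksm * csm / max(mcn, .Machine$double.eps))^2
  gw <- 1 - rowSums((ks / pmax(k, .Machine$double.eps))^2 * gs)
  gw[k == 0] <- 0
  pmax(gw, 0)
}

metric_gateway_degree <- function(adjacency, communities, ...) {
  gateway_coefficient(adjacency, communities, "degree")
}

metric_gateway_betweenness <- function(adjacency, communities, ...) {
  gateway_coefficient(adjacency, communities, "betweenness")
}

# Per-node contribution to Louvain modularity: q_i = (1/2m) * sum_{j in c_i}
# (A_ij - k_i k_j / 2m). The Louvain partition is stochastic, so it runs under
# a caller-supplied seed for reproducible landscapes.
metric_modularity_louvain <- function(adjacency, communities, seed = 1L, ...) {
  g <- graph_from_adj(adjacency, absolute = TRUE)
  n <- nrow(adjacency)
  if (igraph::ecount(g) == 0L) return(rep(0, n))
  cl <- with_preserved_seed(seed, {
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  })
  memb <- igraph::membership(cl)
  a <- abs(adjacency)
  diag(a) <- 0
  k <- rowSums(a)
  two_m <- sum(k)
  same <- outer(memb, memb, "==")
  q <- rowSums((a - tcrossprod(k) / two_m) * same) / two_m
  unname(q)
}

#' Default registry of 16 nodal graph metrics
#'
#' Simple and higher-level nodal features of weighted network organisation:
#' strength, degree, betweenness centrality, eigenvector centrality,
#' (harmonic) closeness centrality, pagerank centrality, weighted clustering
#' coefficient, local efficiency, k-coreness, subgraph centrality,
#' participation coefficient, module-degree z-score, gateway coefficients
#' (degree- and betweenness-based), within-community strength, and the nodal
#' Louvain-modularity contribution. Community-dependent metrics use the
#' cohort's region communities.
#'
#' @return Named list of functions `f(adjacency, communities, seed)`.
#' @export
default_metric_registry <- function() {
  list(
    strength = node_strength,
    degree = node_degree,
    betweenness = metric_betweenness,
    eigenvector = metric_eigenvector,
    closeness = metric_closeness,
    pagerank = metric_pagerank,
    clustering = metric_clustering,
    local_efficiency = metric_local_efficiency,
    kcoreness = metric_coreness,
    subgraph_centrality = metric_subgraph,
    participation = metric_participation,
    module_degree_zscore = metric_module_zscore,
    gateway_degree = metric_gateway_degree,
    gateway_betweenness = metric_gateway_betweenness,
    within_community_strength = metric_within_community_strength,
    modularity_louvain = metric_modularity_louvain
  )
}

community_dependent_metrics <- function() {
  c("participation", "module_degree_zscore", "gateway_degree",
    "gateway_betweenness", "within_community_strength")
}

#' Compute one nodal metric
#'
#' @param adjacency Symmetric weighted adjacency matrix (typically the output
#'   of [proportional_threshold()]).
#' @param metric Metric label from the registry.
#' @param communities Per-node community ids; required for
#'   community-dependent metrics.
#' @param seed Seed for stochastic metrics (Louvain community detection).
#' @param registry Metric registry (defaults to [default_metric_registry()]).
#' @return Numeric vector, one finite value per node.
#' @export
#' @examples
#' line <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' nodal_metric(line, "strength")
nodal_metric <- function(adjacency, metric, communities = NULL, seed = 1L,
                         registry = default_metric_registry()) {
  if (!metric %in% names(registry)) {
    abort(sprintf("Unknown metric '%s'. Registry: %s", metric,
                  paste(names(registry), collapse = ", ")))
  }
  if (metric %in% community_dependent_metrics() && is.null(communities)) {
    abort(sprintf("Metric '%s' requires `communities`.", metric))
  }
  v <- registry[[metric]](adjacency, communities = communities, seed = seed)
  v[!is.finite(v)] <- 0
  as.numeric(v)
}
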