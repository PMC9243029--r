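test_that("pair counts match brute-force enumeration", {
  expect_equal(pair_count(50), 1225L)
  expect_equal(pair_count(176), 15400L)
  expect_equal(pair_count(2), 1L)
  for (n in c(3, 7, 50, 121, 200)) {
    expect_equal(pair_count(n), nrow(t(utils::combn(n, 2))))
  }
})

test_that("cosine similarity matches hand arithmetic and handles zero vectors", {
  expect_equal(subject_similarity(rbind(c(2, 2), c(2, 2))), 1)
  expect_equal(subject_similarity(rbind(c(1, 0), c(0, 1))), 0)
  expect_equal(subject_similarity(rbind(c(1, 2, 3), c(3, 2, 1))), 10 / 14)
  set.seed(12)
  m <- matrix(rnorm(12), 4, 3)
  sims <- subject_similarity(m)
  pairs <- t(utils::combn(4, 2))
  expect_equal(sims, apply(pairs, 1, function(p) oracle_cosine(m[p[1], ], m[p[2], ])))
  m[2, ] <- 0
  sims0 <- subject_similarity(m)
  expect_true(all(sims0[pairs[, 1] == 2 | pairs[, 2] == 2] == 0))
})

test_that("similarity tables have pipelines-by-pairs shape with duplicated rows for duplicated pipelines", {
  co <- small_regression_cohort()
  grid <- build_grid(list(
    data_variant = c("motion_regression"),
    sparsity = c("0.1", "0.2"),
    graph_metric = c("strength", "strength2")))
  # alias a duplicate metric to force two identical pipelines
  grid$graph_metric[grid$graph_metric == "strength2"] <- "strength"
  tab <- build_similarity_table(co, grid)
  expect_equal(dim(tab$matrix), c(4L, pair_count(14)))
  expect_equal(tab$matrix[1, ], tab$matrix[2, ])
  expect_true(all(tab$matrix >= -1 & tab$matrix <= 1))
})

test_that("similarity signatures are invariant to subject ordering up to pair reindexing", {
  co <- small_regression_cohort()
  grid <- small_regression_grid()
  spec <- pipespace:::pipeline_spec(grid, 10L)
  subjects <- pipespace::split_subjects(co, "space")
  fm <- pipespace:::subject_features(co, spec, subjects)
  sims <- subject_similarity(fm)
  perm <- rev(seq_along(subjects))
  sims_perm <- subject_similarity(fm[perm, ])
  # map: pair (i,j) under permutation
  pairs <- t(utils::combn(length(subjects), 2))
  key <- function(p) paste(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  orig_key <- key(pairs)
  perm_pairs <- cbind(perm[pairs[, 1]], perm[pairs[, 2]])
  perm_key <- key(perm_pairs)
  expect_equal(sims_perm[match(orig_key, perm_key)], sims, tolerance = 1e-12)
})

test_that("three mutually equidistant signatures embed as an equilateral triangle", {
  m <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  sp <- embed_pipelines(m, method = "mds")
  d <- dist(as.matrix(sp[, c("dim1", "dim2")]))
  expect_lt(max(d) - min(d), 1e-6)
})

test_that("an exactly 2-D configuration is recovered by MDS with near-zero stress", {
  set.seed(13)
  true_coords <- matrix(runif(20), 10, 2)
  # rotate into 6-D: distances unchanged
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:2]
  m <- true_coords %*% t(q)
  sp <- embed_pipelines(m, method = "mds")
  expect_lt(attr(sp, "stress"), 1e-4)
  d_true <- dist(true_coords)
  d_emb <- dist(as.matrix(sp[, c("dim1", "dim2")]))
  expect_equal(as.numeric(d_emb), as.numeric(d_true), tolerance = 1e-4)
})

test_that("embeddings are bit-stable across repeated calls", {
  set.seed(14)
  m <- matrix(rnorm(60), 10, 6)
  a <- embed_pipelines(m, method = "mds", seed = 3)
  b <- embed_pipelines(m, method = "mds", seed = 3)
  expect_identical(a, b)
  p1 <- embed_pipelines(m, method = "pca", seed = 3)
  p2 <- embed_pipelines(m, method = "pca", seed = 3)
  expect_identical(p1, p2)
})

test_that("MDS distances are invariant to orthogonal transforms of the initialisation", {
  set.seed(15)
  m <- matrix(rnorm(80), 16, 5)
  base <- embed_pipelines(m, method = "mds")
  init <- suppressWarnings(stats::cmdscale(dist(m), k = 2))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  rotated <- embed_pipelines(m, method = "mds", init = init %*% rot)
  d0 <- as.numeric(dist(as.matrix(base[, c("dim1", "dim2")])))
  d1 <- as.numeric(dist(as.matrix(rotated[, c("dim1", "dim2")])))
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("unknown embedding methods error and plugins are callable", {
  m <- matrix(rnorm(40), 10, 4)
  expect_error(embed_pipelines(m, method = "umap"), "Unknown embedding")
  plug <- list(first2 = function(mat, d, seed) mat[, seq_len(d)])
  sp <- embed_pipelines(m, method = "first2", registry = plug)
  expect_equal(attr(sp, "method"), "first2")
  expect_equal(as.numeric(sp$dim1), m[, 1])
})

test_that("neighbourhood preservation is 1 for isometries and k = P - 1", {
  set.seed(16)
  m <- matrix(rnorm(60), 12, 5)
  tab <- m
  # isometric "embedding": any rigid motion of an exact 5-D configuration in
  # 5 dims; here use the configuration itself as coords
  sp <- structure(
    tibble::tibble(pipeline_id = 1:12,
                   dim1 = m[, 1], dim2 = m[, 2], dim3 = m[, 3],
                   dim4 = m[, 4], dim5 = m[, 5]),
    class = c("embedded_space", "tbl_df", "tbl", "data.frame"))
  expect_equal(neighborhood_preservation(tab, sp, k = 3), 1)
  sp_rand <- embed_pipelines(m, method = "pca")
  expect_equal(neighborhood_preservation(tab, sp_rand, k = 11), 1)
})

test_that("random coordinate permutations give chance-level preservation", {
  set.seed(17)
  p <- 100
  m <- matrix(rnorm(p * 6), p, 6)
  sp <- embed_pipelines(m, method = "pca")
  coords <- as.matrix(sp[, c("dim1", "dim2")])
  scores <- sapply(1:50, function(i) {
    perm <- sample(p)
    sp_perm <- structure(
      tibble::tibble(pipeline_id = 1:p, dim1 = coords[perm, 1],
                     dim2 = coords[perm, 2]),
      class = c("embedded_space", "tbl_df", "tbl", "data.frame"))
    neighborhood_preservation(m, sp_perm, k = 10)
  })
  expect_lt(abs(mean(scores) - 10 / 99), 0.03)
})

test_that("pipelines sharing a graph metric cluster in the embedded space", {
  co <- small_regression_cohort()
  grid <- small_regression_grid()
  tab <- build_similarity_table(co, grid)
  sp <- embed_pipelines(tab)
  coords <- as.matrix(sp[, c("dim1", "dim2")])
  dmat <- as.matrix(dist(coords))
  grand <- mean(dmat[upper.tri(dmat)])
  groups <- split(seq_len(nrow(grid)), grid$graph_metric)
  within <- mean(sapply(groups, function(idx) {
    dd <- dmat[idx, idx]
    mean(dd[upper.tri(dd)])
  }))
  expect_lt(within, grand)
})
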