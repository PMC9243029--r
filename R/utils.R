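#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows left_join group_by summarise ungroup
#' @importFrom stats cor cov sd rnorm runif quantile median optim dist prcomp predict pt setNames aggregate
#' @importFrom utils head modifyList
NULL

# Derive a reproducible 32-bit sub-seed from a base seed and an integer tag.
# Kept strictly below 2^31 so set.seed() never overflows.
derive_seed <- function(seed, tag) {
  s <- (abs(as.numeric(seed)) %% 1000003) * 69069 + abs(as.numeric(tag)) * 7919 + 1
  as.integer(s %% 2147483647)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream (the global .Random.seed is restored on exit).
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Lexicographically ordered unordered pairs (i < j), matching combn() order.
pair_index_tbl <- function(n) {
  if (n < 2) {
    return(tibble(i = integer(), j = integer()))
  }
  cmb <- utils::combn(n, 2L)
  tibble(i = cmb[1L, ], j = cmb[2L, ])
}

# Extract the strict upper triangle of a symmetric matrix in lexicographic
# (i, j) pair order, i.e. the order produced by pair_index_tbl().
upper_pairs <- function(m) {
  idx <- which(upper.tri(m), arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  m[idx[ord, , drop = FALSE]]
}

# Package-level diagnostic logging: emitted via inform() only when
# options(pipespace.verbose = TRUE) (the CLI turns this on); quiet in
# programmatic use so large table builds are not drowned in notes.
log_note <- function(...) {
  if (isTRUE(getOption("pipespace.verbose", FALSE))) inform(sprintf(...))
  invisible(NULL)
}
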