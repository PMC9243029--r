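#' Configuration for a synthetic connectivity cohort
#'
#' Defines the statistical regime the generator emulates: a cohort of subjects
#' whose regional time series arise from a multivariate normal whose coupling
#' matrix carries a planted, target-dependent signal on a fixed subset of
#' region pairs, observed under several correlated "preprocessing variant"
#' versions that differ by structured perturbations (a shared global component
#' retained or removed, plus independent noise).
#'
#' @param n_subjects,n_regions,n_timepoints,n_variants Cohort dimensions; all
#'   must be at least 2.
#' @param signal_edges_fraction Fraction in (0, 1] of region pairs that carry
#'   the target signal.
#' @param signal_strength Non-negative slope from the (standardised) target to
#'   the coupling of signal edges; for classification, an additive group
#'   offset on those couplings.
#' @param variant_perturbation_sd Standard deviation of the independent noise
#'   added to variants beyond the first.
#' @param global_component_sd Standard deviation of the shared global signal
#'   component; odd-numbered variants retain it, even-numbered variants have
#'   it removed (emulating global signal regression).
#' @param task `"regression"` (continuous, age-like target) or
#'   `"classification"` (binary, diagnosis-like target).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @param variant_labels Optional character vector of length `n_variants`
#'   naming the data variants. Defaults to `"motion_regression"` /
#'   `"global_signal_regression"` when `n_variants == 2`.
#' @param n_communities Number of contiguous region communities (emulating a
#'   seven-network cortical parcellation used for community-dependent graph
#'   metrics).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 100L,
                          n_regions = 30L,
                          n_timepoints = 200L,
                          n_variants = 2L,
                          signal_edges_fraction = 0.2,
                          signal_strength = 0.5,
                          variant_perturbation_sd = 0.2,
                          global_component_sd = 0.5,
                          task = c("regression", "classification"),
                          seed = 1L,
                          variant_labels = NULL,
                          n_communities = 7L) {
  task <- match.arg(task)
  for (nm in c("n_subjects", "n_regions", "n_timepoints", "n_variants")) {
    if (!is_count(get(nm), min = 2L)) {
      abort(sprintf("`%s` must be an integer >= 2.", nm))
    }
  }
  if (!is_scalar_num(signal_edges_fraction) ||
      signal_edges_fraction <= 0 || signal_edges_fraction > 1) {
    abort("`signal_edges_fraction` must lie in (0, 1].")
  }
  for (nm in c("signal_strength", "variant_perturbation_sd",
               "global_component_sd")) {
    if (!is_scalar_num(get(nm)) || get(nm) < 0) {
      abort(sprintf("`%s` must be a non-negative number.", nm))
    }
  }
  if (!is_count(abs(seed), min = 0)) abort("`seed` must be an integer.")
  n_pairs <- n_regions * (n_regions - 1) / 2
  if (signal_edges_fraction * n_pairs < 1) {
    abort("Impossible config: `signal_edges_fraction` selects no region pair.")
  }
  if (is.null(variant_labels)) {
    variant_labels <- if (n_variants == 2L) {
      c("motion_regression", "global_signal_regression")
    } else {
      sprintf("variant_%02d", seq_len(n_variants))
    }
  }
  if (length(variant_labels) != n_variants || anyDuplicated(variant_labels)) {
    abort("`variant_labels` must be `n_variants` distinct labels.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_regions = as.integer(n_regions),
      n_timepoints = as.integer(n_timepoints),
      n_variants = as.integer(n_variants),
      signal_edges_fraction = signal_edges_fraction,
      signal_strength = signal_strength,
      variant_perturbation_sd = variant_perturbation_sd,
      global_component_sd = global_component_sd,
      task = task,
      seed = as.integer(seed),
      variant_labels = variant_labels,
      n_communities = as.integer(min(n_communities, n_regions))
    ),
    class = "cohort_config"
  )
}

# Smallest diagonal loading (in steps of `step`) making `m` positive definite
# with minimum eigenvalue >= floor. Returns the repaired matrix with the
# number of loading steps recorded in attr "pd_repair_steps".
repair_positive_definite <- function(m, floor = 1e-8, step = 1e-6) {
  ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  steps <- 0L
  if (ev_min < floor) {
    steps <- as.integer(ceiling((floor - ev_min) / step))
    m <- m + diag(steps * step, nrow(m))
  }
  attr(m, "pd_repair_steps") <- steps
  m
}

#' Generate a seeded synthetic cohort
#'
#' Draws a latent target per subject, builds a positive-definite base coupling
#' matrix with community structure, adds `signal_strength` times the
#' (standardised) target — or a group offset for classification — to a fixed
#' random subset of couplings, samples stationary multivariate-normal time
#' series from the implied coupling, and produces `n_variants` correlated data
#' variants: odd variants retain a shared global component, even variants have
#' it removed, and variants beyond the first receive independent noise of sd
#' `variant_perturbation_sd`.
#'
#' @param config A [cohort_config()].
#' @return A `subject_cohort` list with elements `subjects` (tibble:
#'   `subject_id`, `target`, `split`), `variants` (named list of per-subject
#'   region x time matrices), `communities` (per-region community id),
#'   `signal_edges` (two-column matrix of planted pairs), `parcellations`
#'   (optional named list of region-aggregation maps) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 10, n_regions = 8,
#'                                         n_timepoints = 40, seed = 1))
#' dim(cohort$variants[[1]][[1]])
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must be created with cohort_config().")
  }
  R <- config$n_regions
  n <- config$n_subjects
  tt <- config$n_timepoints

  with_preserved_seed(config$seed, {
    communities <- sort(rep_len(seq_len(config$n_communities), R))

    # Base coupling (covariance scale): modest baseline dependence, stronger
    # within communities, plus a small random symmetric jitter shared by all
    # subjects. The regional variance is kept well above the off-diagonal
    # couplings so that the additive target effect perturbs correlations in a
    # near-linear regime rather than saturating them.
    same <- outer(communities, communities, "==")
    base <- 0.4 + 0.6 * same
    jit <- matrix(rnorm(R * R, sd = 0.15), R, R)
    jit <- (jit + t(jit)) / 2
    base <- base + jit
    diag(base) <- 4

    n_pairs <- R * (R - 1) / 2
    n_signal <- ceiling(config$signal_edges_fraction * n_pairs)
    all_pairs <- t(utils::combn(R, 2L))
    signal_edges <- all_pairs[sample.int(n_pairs, n_signal), , drop = FALSE]

    if (config$task == "regression") {
      z <- rnorm(n)
      target <- 19.2 + 2.9 * z            # age-like scale
      effect <- config$signal_strength * as.numeric(scale(z))
    } else {
      grp <- sample(rep_len(c(0L, 1L), n))
      target <- grp
      effect <- config$signal_strength * grp
    }

    repairs <- 0L
    make_sigma <- function(eff) {
      s <- base
      s[signal_edges] <- s[signal_edges] + eff
      s[signal_edges[, 2:1, drop = FALSE]] <- s[signal_edges]
      s <- repair_positive_definite(s)
      repairs <<- repairs + (attr(s, "pd_repair_steps") > 0L)
      s
    }

    variants <- lapply(config$variant_labels, function(v) vector("list", n))
    names(variants) <- config$variant_labels
    for (i in seq_len(n)) {
      sigma <- make_sigma(effect[i])
      L <- t(chol(sigma))
      xs <- L %*% matrix(rnorm(R * tt), R, tt)
      g <- rnorm(tt, sd = config$global_component_sd)
      for (v in seq_len(config$n_variants)) {
        x <- xs
        if (v %% 2L == 1L) x <- x + rep(g, each = R)  # global retained
        if (v > 1L) {
          x <- x + matrix(rnorm(R * tt, sd = config$variant_perturbation_sd),
                          R, tt)
        }
        dimnames(x) <- list(sprintf("region_%03d", seq_len(R)), NULL)
        variants[[v]][[i]] <- x
      }
    }
    if (repairs > 0L) {
      inform(sprintf("Repaired %d non-positive-definite coupling matrices by diagonal loading.", repairs))
    }

    subjects <- tibble(
      subject_id = sprintf("sub_%04d", seq_len(n)),
      target = target,
      split = NA_character_
    )
    for (v in seq_along(variants)) names(variants[[v]]) <- subjects$subject_id

    structure(
      list(subjects = subjects, variants = variants,
           communities = communities, signal_edges = signal_edges,
           parcellations = NULL, config = config),
      class = "subject_cohort"
    )
  })
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat(sprintf(
    "<subject_cohort> %d subjects, %d regions, %d timepoints, %d variant(s), task = %s\n",
    x$config$n_subjects, x$config$n_regions, x$config$n_timepoints,
    length(x$variants), x$config$task))
  if (!all(is.na(x$subjects$split))) {
    print(table(x$subjects$split))
  }
  invisible(x)
}

#' Attach region-aggregation parcellations to a cohort
#'
#' For the classification design, the "parcellation" pipeline factor is
#' realised as coarse-grainings of the simulated base regions: each
#' parcellation maps the base regions onto fewer parcels by contiguous
#' grouping, and pipelines consume parcel-mean time series.
#'
#' @param cohort A `subject_cohort`.
#' @param sizes Named integer vector: parcellation label -> parcel count
#'   (each at most the base region count).
#' @return The cohort with a `parcellations` element (named list of length-R
#'   integer maps).
#' @export
add_parcellations <- function(cohort, sizes) {
  stopifnot(inherits(cohort, "subject_cohort"))
  if (is.null(names(sizes)) || anyDuplicated(names(sizes))) {
    abort("`sizes` must be a uniquely named vector of parcel counts.")
  }
  R <- cohort$config$n_regions
  if (any(sizes < 2L) || any(sizes > R)) {
    abort("Parcel counts must lie in [2, n_regions].")
  }
  cohort$parcellations <- lapply(sizes, function(k) {
    as.integer(cut(seq_len(R), breaks = k, labels = FALSE))
  })
  names(cohort$parcellations) <- names(sizes)
  cohort
}

#' Assign space / search / holdout split labels
#'
#' Splits subjects into the three roles the workflow uses: a split to build
#' the low-dimensional space, a split driving the active search, and a
#' lock-box holdout used once for final scoring. Splits may be given as
#' absolute sizes (which take precedence) or fractions; a stratified split
#' keeps per-class proportions within one subject of the global proportion.
#'
#' @param cohort A `subject_cohort`.
#' @param fractions Numeric length-3 vector summing to 1 (space, search,
#'   holdout).
#' @param sizes Optional integer length-3 vector of absolute sizes summing to
#'   the subject count; overrides `fractions`.
#' @param stratify Stratify by class (classification targets only).
#' @param seed Integer seed for the random assignment.
#' @return The cohort with `subjects$split` filled in.
#' @export
split_dataset <- function(cohort, fractions = c(0.2, 0.6, 0.2), sizes = NULL,
                          stratify = FALSE, seed = 1L) {
  stopifnot(inherits(cohort, "subject_cohort"))
  n <- nrow(cohort$subjects)
  labels <- c("space", "search", "holdout")
  if (is.null(sizes)) {
    if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9) {
      abort("`fractions` must be three values summing to 1.")
    }
    sizes <- floor(fractions * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
  }
  if (length(sizes) != 3L || sum(sizes) != n) {
    abort("`sizes` must be three counts summing to the subject count.")
  }
  if (any(sizes == 0L)) abort("Every split must be non-empty.")

  split <- character(n)
  with_preserved_seed(seed, {
    if (stratify) {
      if (cohort$config$task != "classification") {
        abort("Stratified splits require a classification cohort.")
      }
      cls <- cohort$subjects$target
      for (k in unique(cls)) {
        idx <- sample(which(cls == k))
        # largest-remainder allocation of this class across the three splits
        quota <- sizes * length(idx) / n
        take <- floor(quota)
        rem <- length(idx) - sum(take)
        if (rem > 0) {
          extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
          take[extra] <- take[extra] + 1L
        }
        start <- cumsum(c(0L, take))
        for (s in 1:3) {
          if (take[s] > 0) {
            split[idx[(start[s] + 1L):start[s + 1L]]] <- labels[s]
          }
        }
      }
      # stratified remainders can drift from the requested absolute sizes by
      # one; rebalance by moving random subjects between splits
      for (s in 1:3) {
        excess <- sum(split == labels[s]) - sizes[s]
        while (excess > 0) {
          short <- which(tabulate(factor(split, labels), 3L) < sizes)[1L]
          mv <- sample(which(split == labels[s]), 1L)
          split[mv] <- labels[short]
          excess <- excess - 1L
        }
      }
    } else {
      idx <- sample.int(n)
      start <- cumsum(c(0L, sizes))
      for (s in 1:3) split[idx[(start[s] + 1L):start[s + 1L]]] <- labels[s]
    }
  })
  cohort$subjects$split <- split
  if (cohort$config$task == "classification") {
    per <- table(cohort$subjects$split, cohort$subjects$target)
    if (any(per == 0)) {
      abort("Every split must contain both classes; use `stratify = TRUE`.")
    }
  }
  cohort
}

#' Subject indices belonging to a split
#' @param cohort A `subject_cohort`.
#' @param split One of `"space"`, `"search"`, `"holdout"`, or `NULL` for all.
#' @return Integer vector of subject row indices.
#' @export
split_subjects <- function(cohort, split = NULL) {
  if (is.null(split)) return(seq_len(nrow(cohort$subjects)))
  idx <- which(cohort$subjects$split == split)
  if (length(idx) == 0L) {
    abort(sprintf("Split '%s' is empty or unassigned; call split_dataset() first.", split))
  }
  idx
}
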