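#' Minimization image of objective vectors
#'
#' The search minimizes all four objectives internally: the channel count
#' as-is and the three maximized rates negated as `1 - accuracy`,
#' `1 - TAR`, `1 - TRR`. Reports re-invert for presentation.
#'
#' @param objectives Data frame / tibble with columns `n_channels`,
#'   `accuracy`, `tar`, `trr`.
#' @return Numeric matrix with one row per candidate and columns
#'   `n_channels`, `inv_accuracy`, `inv_tar`, `inv_trr`.
#' @export
minimization_image <- function(objectives) {
  m <- cbind(
    n_channels = objectives$n_channels,
    inv_accuracy = 1 - objectives$accuracy,
    inv_tar = 1 - objectives$tar,
    inv_trr = 1 - objectives$trr
  )
  as.matrix(m)
}

# a weakly dominates b (minimization) when a is <= everywhere and < somewhere
dominates <- function(a, b) all(a <= b) && any(a < b)

#' Keep the non-dominated subset of candidates
#'
#' Brute-force O(n^2) non-domination filter in the minimization image:
#' keeps exactly the candidates not dominated by any other; exact duplicate
#' objective vectors collapse to one representative (the first).
#'
#' @param objectives Tibble with columns `n_channels`, `accuracy`, `tar`,
#'   `trr` (extra columns are carried through), or a numeric matrix already
#'   in the minimization image.
#' @return The non-dominated rows, same type as the input.
#' @export
pareto_filter <- function(objectives) {
  if (is.matrix(objectives)) {
    M <- objectives
  } else {
    if (nrow(objectives) == 0L) stop("empty candidate list")
    M <- minimization_image(objectives)
  }
  if (nrow(M) == 0L) stop("empty candidate list")
  keep <- pareto_keep(M)
  if (is.matrix(objectives)) objectives[keep, , drop = FALSE]
  else objectives[keep, ]
}

# Pairwise weak-domination matrix: dom[i, j] = TRUE when row i dominates
# row j (minimization). Vectorized over objectives.
domination_matrix <- function(M) {
  n <- nrow(M)
  all_le <- matrix(TRUE, n, n)
  any_lt <- matrix(FALSE, n, n)
  for (k in seq_len(ncol(M))) {
    cmp <- outer(M[, k], M[, k], "<=")
    all_le <- all_le & cmp
    any_lt <- any_lt | outer(M[, k], M[, k], "<")
  }
  all_le & any_lt
}

# indices of non-dominated, duplicate-collapsed rows of a minimization matrix
pareto_keep <- function(M) {
  dom <- domination_matrix(M)
  which(colSums(dom) == 0L & !duplicated(M))
}

# Fast non-dominated sorting (NSGA-II): list of fronts, each a vector of
# row indices of M (minimization image).
nondominated_sort <- function(M) {
  dom <- domination_matrix(M)
  dom_count <- colSums(dom)
  fronts <- list()
  current <- which(dom_count == 0L)
  assigned <- logical(nrow(M))
  while (length(current) > 0L) {
    fronts[[length(fronts) + 1L]] <- current
    assigned[current] <- TRUE
    dom_count <- dom_count - colSums(dom[current, , drop = FALSE])
    current <- which(dom_count == 0L & !assigned)
  }
  fronts
}

# NSGA-II crowding distance within one front.
crowding_distance <- function(M) {
  n <- nrow(M)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(M))) {
    ord <- order(M[, m])
    rng <- M[ord[n], m] - M[ord[1L], m]
    d[ord[c(1L, n)]] <- Inf
    if (rng > 0) {
      d[ord[2:(n - 1L)]] <- d[ord[2:(n - 1L)]] +
        (M[ord[3:n], m] - M[ord[1:(n - 2L)], m]) / rng
    }
  }
  d
}

#' Generate random 50/50 non-intruder / intruder subject splits
#'
#' Validation protocol for subject-level generalization: subjects are
#' repeatedly partitioned at random into half non-intruders and half
#' intruders (10 splits by default); with an odd subject count the extra
#' subject goes to the non-intruder side. Reproducible under the seed.
#'
#' @param subjects Character vector of subject ids (>= 2).
#' @param n_splits Number of random partitions (default 10).
#' @param seed RNG seed.
#' @return List of [subject_split()] objects of length `n_splits`.
#' @export
random_subject_splits <- function(subjects, n_splits = 10, seed = 1) {
  subjects <- as.character(subjects)
  if (length(subjects) < 2L) stop("need at least 2 subjects to split")
  stopifnot(n_splits >= 1)
  n_in <- ceiling(length(subjects) / 2)
  withr::with_seed(seed, {
    lapply(seq_len(n_splits), function(i) {
      perm <- sample(subjects)
      subject_split(perm[seq_len(n_in)], perm[-seq_len(n_in)])
    })
  })
}
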