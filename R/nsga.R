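#' Configuration for the evolutionary channel-selection search
#'
#' Defaults follow the study configuration: population of 30 candidates per
#' generation, at most 500 generations, and early termination when the
#' movement of the (ideal/nadir-normalized) non-dominated front between
#' checkpoints taken every 10 generations falls below an objective-space
#' tolerance of 1e-4. Genetic operators are standard binary-GA choices:
#' binary tournament mating selection, two-point crossover (probability
#' 0.9) and per-gene bit-flip mutation (probability `1/n_genes`).
#'
#' @param variant `"nsga2"` (crowding-distance survival) or `"nsga3"`
#'   (reference-point niching survival).
#' @param population_size Candidates per generation (>= 4, default 30).
#' @param max_generations Hard cap on generations (default 500).
#' @param tolerance Objective-space movement threshold for early
#'   termination (default 1e-4).
#' @param tolerance_check_period Generations between termination checks
#'   (default 10).
#' @param crossover_prob Two-point crossover probability (default 0.9).
#' @param mutation_prob Per-gene bit-flip probability; `NULL` means
#'   `1/n_genes`.
#' @param n_divisions Divisions per objective for the systematic
#'   (Das-Dennis) reference points of NSGA-III; 4 divisions over 4
#'   objectives place 35 points on the normalized hyperplane.
#' @param seed RNG seed driving the whole run.
#' @param memoize Cache evaluations by chromosome (evaluators must be
#'   deterministic; default `TRUE`).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(variant = c("nsga2", "nsga3"), population_size = 30,
                      max_generations = 500, tolerance = 1e-4,
                      tolerance_check_period = 10, crossover_prob = 0.9,
                      mutation_prob = NULL, n_divisions = 4, seed = 1,
                      memoize = TRUE) {
  variant <- match.arg(variant)
  stopifnot(population_size >= 4, tolerance > 0, max_generations >= 1,
            tolerance_check_period >= 1,
            crossover_prob >= 0, crossover_prob <= 1)
  structure(list(variant = variant,
                 population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 tolerance = tolerance,
                 tolerance_check_period = as.integer(tolerance_check_period),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 n_divisions = as.integer(n_divisions),
                 seed = seed, memoize = isTRUE(memoize)),
            class = "ga_config")
}

#' Systematic reference points on the normalized hyperplane
#'
#' Das-Dennis construction: all non-negative integer compositions of
#' `divisions` into `n_obj` parts, scaled to sum to 1. The points lie on
#' the hyperplane equally inclined to all objective axes and intersecting
#' each axis at 1.
#'
#' @param n_obj Number of objectives.
#' @param divisions Divisions per objective.
#' @return Matrix of reference points (rows sum to 1).
#' @export
reference_points <- function(n_obj = 4, divisions = 4) {
  rec <- function(left, parts) {
    if (parts == 1L) return(matrix(left, ncol = 1))
    do.call(rbind, lapply(0:left, function(v) {
      cbind(v, rec(left - v, parts - 1L))
    }))
  }
  unname(rec(divisions, n_obj) / divisions)
}

two_point_crossover <- function(a, b) {
  n <- length(a)
  pts <- sort(sample.int(n - 1L, 2L, replace = TRUE))
  if (pts[1] < pts[2]) {
    seg <- (pts[1] + 1L):pts[2]
    tmp <- a[seg]; a[seg] <- b[seg]; b[seg] <- tmp
  }
  list(a, b)
}

bitflip <- function(genes, p) {
  flip <- runif(length(genes)) < p
  genes[flip] <- 1L - genes[flip]
  genes
}

normalize_points <- function(M, lo, hi) {
  rng <- pmax(hi - lo, 1e-12)
  sweep(sweep(M, 2L, lo, "-"), 2L, rng, "/")
}

# mean distance from each point of A to its nearest point of B
front_movement <- function(A, B) {
  mean(apply(A, 1L, function(a) {
    min(sqrt(colSums((t(B) - a)^2)))
  }))
}

# --- NSGA-III niching ------------------------------------------------------

asf_extremes <- function(Fp) {
  m <- ncol(Fp)
  vapply(seq_len(m), function(j) {
    w <- rep(1e-6, m); w[j] <- 1
    which.min(apply(sweep(Fp, 2L, w, "/"), 1L, max))
  }, integer(1))
}

plane_intercepts <- function(Fp, front1) {
  m <- ncol(Fp)
  F1 <- Fp[front1, , drop = FALSE]
  ext <- F1[asf_extremes(F1), , drop = FALSE]
  a <- tryCatch({
    b <- solve(ext, rep(1, m))
    ai <- 1 / b
    if (any(!is.finite(ai)) || any(ai <= 1e-12)) stop("degenerate")
    ai
  }, error = function(e) NULL)
  if (is.null(a)) {
    a <- apply(Fp[front1, , drop = FALSE], 2L, max)
    a[a <= 1e-12] <- 1
  }
  a
}

# nearest reference line (perpendicular distance) for each normalized point
associate_refs <- function(Fn, Z) {
  Zn <- Z / sqrt(rowSums(Z^2))
  t(apply(Fn, 1L, function(f) {
    proj <- as.vector(Zn %*% f)                 # f . z_hat per reference
    d2 <- rowSums((Zn * proj - matrix(f, nrow(Zn), length(f),
                                      byrow = TRUE))^2)
    j <- which.min(d2)
    c(j, sqrt(max(d2[j], 0)))
  }))
}

niching_select <- function(M, fronts, N, Z) {
  st_fronts <- list(); total <- 0L
  for (fr in fronts) {
    st_fronts[[length(st_fronts) + 1L]] <- fr
    total <- total + length(fr)
    if (total >= N) break
  }
  St <- unlist(st_fronts)
  if (total == N) return(St)
  last <- st_fronts[[length(st_fronts)]]
  prev <- setdiff(St, last)
  k_need <- N - length(prev)

  ideal <- apply(M[St, , drop = FALSE], 2L, min)
  Fp <- sweep(M[St, , drop = FALSE], 2L, ideal, "-")
  front1_local <- match(st_fronts[[1L]], St)
  a <- plane_intercepts(Fp, front1_local)
  Fn <- sweep(Fp, 2L, a, "/")
  assoc <- associate_refs(Fn, Z)
  ref_of <- assoc[, 1L]; dist_of <- assoc[, 2L]
  names(ref_of) <- names(dist_of) <- as.character(St)

  rho <- tabulate(ref_of[as.character(prev)], nbins = nrow(Z))
  pool <- last
  chosen <- integer(0)
  while (length(chosen) < k_need && length(pool) > 0L) {
    pool_refs <- unique(ref_of[as.character(pool)])
    jmin <- pool_refs[rho[pool_refs] == min(rho[pool_refs])]
    j <- if (length(jmin) > 1L) sample(jmin, 1L) else jmin
    members <- pool[ref_of[as.character(pool)] == j]
    pick <- if (rho[j] == 0L) {
      members[which.min(dist_of[as.character(members)])]
    } else if (length(members) > 1L) sample(members, 1L) else members
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
    rho[j] <- rho[j] + 1L
  }
  c(prev, chosen)
}

# --- driver ----------------------------------------------------------------

#' Run the four-objective NSGA channel-selection search
#'
#' Evolves binary chromosomes (channel mask + nu/gamma index fields) under
#' elitist non-dominated sorting: NSGA-II uses crowding-distance survival,
#' NSGA-III reference-point niching on the normalized hyperplane. Every
#' candidate is scored by `evaluator` on the four objectives (channel
#' count, identification accuracy, TAR, TRR); maximized objectives are
#' negated internally so all four are minimized. The run stops early when
#' the normalized non-dominated front moves less than `tolerance` between
#' checks made every `tolerance_check_period` generations, and always after
#' `max_generations`.
#'
#' The returned front is computed over the elitist archive of *all*
#' candidates evaluated during the run: survival truncation can displace a
#' non-dominated member from the fixed-size working population, but the
#' archive never forgets it, so on exhaustively searchable instances the
#' front converges to the true Pareto front.
#'
#' @param evaluator Function taking a gene vector and returning a one-row
#'   data frame / named list with `n_channels`, `accuracy`, `tar`, `trr`
#'   and optionally `nu`, `gamma` (see [make_evaluator()]).
#' @param n_genes Chromosome length (channel genes + 8 parameter genes).
#' @param config A [ga_config()].
#' @param freeze Optional list `(positions, values)` pinning genes (e.g.
#'   the nu/gamma fields) to fixed values throughout the run.
#' @param montage Optional channel labels used to annotate front members.
#' @return An object of class `pareto_front`: `members` (tibble with the
#'   chromosome, the four objectives, nu/gamma and channel labels),
#'   `generations` (per-generation summary log), `evaluations` (full
#'   evaluation log), `n_generations`, `converged`, `config`.
#' @export
run_nsga <- function(evaluator, n_genes, config = ga_config(),
                     freeze = NULL, montage = NULL) {
  stopifnot(inherits(config, "ga_config"))
  set.seed(config$seed)
  N <- config$population_size
  p_mut <- if (is.null(config$mutation_prob)) 1 / n_genes else
    config$mutation_prob
  Z <- if (config$variant == "nsga3") {
    reference_points(4L, config$n_divisions)
  } else NULL

  apply_freeze <- function(genes) {
    if (!is.null(freeze)) genes[freeze$positions] <- as.integer(freeze$values)
    genes
  }

  memo <- new.env(parent = emptyenv())
  eval_log <- list()
  evaluate <- function(genes, generation) {
    key <- paste(genes, collapse = "")
    res <- if (config$memoize && !is.null(memo[[key]])) {
      memo[[key]]
    } else {
      r <- tibble::as_tibble(as.list(unlist(evaluator(genes))))
      if (config$memoize) memo[[key]] <- r
      r
    }
    eval_log[[length(eval_log) + 1L]] <<- dplyr::bind_cols(
      tibble::tibble(generation = generation, chromosome = key), res
    )
    res
  }

  evaluate_pop <- function(P, generation) {
    dplyr::bind_rows(lapply(seq_len(nrow(P)), function(i) {
      evaluate(P[i, ], generation)
    }))
  }

  pop <- matrix(as.integer(runif(N * n_genes) > 0.5), N, n_genes)
  pop <- t(apply(pop, 1L, apply_freeze))
  obj <- evaluate_pop(pop, 0L)

  gen_log <- list()
  log_generation <- function(gen, obj) {
    M <- minimization_image(obj)
    fr <- pareto_keep(M)
    gen_log[[length(gen_log) + 1L]] <<- tibble::tibble(
      generation = gen, front_size = length(fr),
      min_channels = min(obj$n_channels), max_accuracy = max(obj$accuracy),
      max_tar = max(obj$tar), max_trr = max(obj$trr)
    )
  }
  log_generation(0L, obj)

  tournament <- function(rank, crowd) {
    i <- sample.int(N, 1L); j <- sample.int(N, 1L)
    if (rank[i] < rank[j]) return(i)
    if (rank[j] < rank[i]) return(j)
    if (crowd[i] > crowd[j]) return(i)
    if (crowd[j] > crowd[i]) return(j)
    if (runif(1) < 0.5) i else j
  }

  prev_front <- NULL
  converged <- FALSE
  gen <- 0L
  while (gen < config$max_generations) {
    gen <- gen + 1L
    M <- minimization_image(obj)
    fronts <- nondominated_sort(M)
    rank <- integer(N); crowd <- numeric(N)
    for (k in seq_along(fronts)) {
      fr <- fronts[[k]]
      rank[fr] <- k
      crowd[fr] <- crowding_distance(M[fr, , drop = FALSE])
    }
    # variation: tournament mating, two-point crossover, bit-flip mutation
    children <- matrix(0L, N, n_genes)
    i <- 1L
    while (i <= N) {
      p1 <- pop[tournament(rank, crowd), ]
      p2 <- pop[tournament(rank, crowd), ]
      if (runif(1) < config$crossover_prob) {
        cr <- two_point_crossover(p1, p2)
        p1 <- cr[[1L]]; p2 <- cr[[2L]]
      }
      children[i, ] <- apply_freeze(bitflip(p1, p_mut))
      if (i + 1L <= N) children[i + 1L, ] <- apply_freeze(bitflip(p2, p_mut))
      i <- i + 2L
    }
    child_obj <- evaluate_pop(children, gen)

    comb_pop <- rbind(pop, children)
    comb_obj <- dplyr::bind_rows(obj, child_obj)
    Mc <- minimization_image(comb_obj)
    fronts_c <- nondominated_sort(Mc)
    sel <- if (config$variant == "nsga2") {
      chosen <- integer(0)
      for (fr in fronts_c) {
        if (length(chosen) + length(fr) <= N) {
          chosen <- c(chosen, fr)
        } else {
          cd <- crowding_distance(Mc[fr, , drop = FALSE])
          chosen <- c(chosen, fr[order(-cd)][seq_len(N - length(chosen))])
          break
        }
        if (length(chosen) == N) break
      }
      chosen
    } else {
      niching_select(Mc, fronts_c, N, Z)
    }
    pop <- comb_pop[sel, , drop = FALSE]
    obj <- comb_obj[sel, ]
    log_generation(gen, obj)

    if (gen %% config$tolerance_check_period == 0L) {
      M <- minimization_image(obj)
      front <- M[pareto_keep(M), , drop = FALSE]
      if (!is.null(prev_front)) {
        both <- rbind(front, prev_front)
        lo <- apply(both, 2L, min); hi <- apply(both, 2L, max)
        move <- front_movement(normalize_points(front, lo, hi),
                               normalize_points(prev_front, lo, hi))
        if (move < config$tolerance) {
          converged <- TRUE
          break
        }
      }
      prev_front <- front
    }
  }

  # Final front from the elitist archive: the non-dominated set over every
  # candidate evaluated during the run, not just the final population —
  # survival truncation can displace front members from the working
  # population, but nothing evaluated is forgotten.
  evals <- dplyr::bind_rows(eval_log)
  archive <- evals[!duplicated(evals$chromosome), , drop = FALSE]
  Ma <- minimization_image(archive)
  keep <- pareto_keep(Ma)
  members <- archive[keep, setdiff(names(archive),
                                   c("generation", "chromosome"))]
  genes_of <- function(key) as.integer(strsplit(key, "")[[1]])
  members$chromosome <- lapply(archive$chromosome[keep], genes_of)
  members$channels <- lapply(members$chromosome, function(g) {
    idx <- which(g[seq_len(n_genes - 8L)] == 1L)
    if (is.null(montage)) as.character(idx) else montage[idx]
  })
  members <- dplyr::arrange(members, .data$n_channels,
                            dplyr::desc(.data$accuracy))
  structure(
    list(members = members,
         generations = dplyr::bind_rows(gen_log),
         evaluations = evals,
         n_generations = gen, converged = converged, config = config,
         montage = montage),
    class = "pareto_front"
  )
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf(
    "<pareto_front> %d members after %d generations (%s, %sconverged)\n",
    nrow(x$members), x$n_generations, x$config$variant,
    if (x$converged) "" else "not "
  ))
  invisible(x)
}
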