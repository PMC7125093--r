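#' Write a Pareto-front report
#'
#' One row per front member with the columns of the study's result tables:
#' number of channels, identification accuracy, TAR, TRR, nu, gamma, and
#' the selected channel labels (comma-separated montage labels, never raw
#' indices). Rows are sorted by channel count ascending. Tab-separated.
#'
#' @param front A `pareto_front` from [run_nsga()], or a tibble with
#'   columns `n_channels`, `accuracy`, `tar`, `trr`, `nu`, `gamma`,
#'   `channels` (list-column of labels).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pareto_report <- function(front, path) {
  tab <- if (inherits(front, "pareto_front")) front$members else
    tibble::as_tibble(front)
  if (nrow(tab) == 0L) stop("empty front")
  out <- tibble::tibble(
    n_channels = tab$n_channels,
    accuracy = tab$accuracy,
    tar = tab$tar,
    trr = tab$trr,
    nu = tab$nu,
    gamma = tab$gamma,
    channels = vapply(tab$channels, paste, character(1), collapse = ",")
  )
  out <- dplyr::arrange(out, .data$n_channels, dplyr::desc(.data$accuracy))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a Pareto-front report
#' @param path Report file written by [write_pareto_report()].
#' @return Tibble with the report columns; `channels` is a list-column of
#'   labels.
#' @export
read_pareto_report <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tab$channels <- strsplit(as.character(tab$channels), ",", fixed = TRUE)
  tab
}

#' Channel-membership counts across subsets
#'
#' Textual replacement for a Venn diagram: given several channel subsets
#' (e.g. the selections of different runs or splits), tabulates how many
#' subsets each channel label belongs to.
#'
#' @param subsets List of at least 2 character vectors of channel labels.
#' @return Tibble with `channel` and `n_subsets`, sorted by decreasing
#'   count then label; every label in at least one subset appears.
#' @export
channel_overlap_summary <- function(subsets) {
  if (!is.list(subsets) || length(subsets) < 2L) {
    stop("need at least 2 channel subsets")
  }
  tallies <- table(unlist(lapply(subsets, unique)))
  out <- tibble::tibble(channel = names(tallies),
                        n_subsets = as.integer(tallies))
  dplyr::arrange(out, dplyr::desc(.data$n_subsets), .data$channel)
}

#' Summarize Pareto fronts over random subject splits
#'
#' Pools the front members of several runs (one per random 50/50 subject
#' split) and reports mean and standard deviation of accuracy, TAR and TRR
#' per channel count — the aggregate validation view over random
#' subdivisions.
#'
#' @param fronts List of `pareto_front` objects (or member tibbles).
#' @return Tibble with `n_channels`, `n_members`, and mean/sd columns for
#'   accuracy, TAR and TRR.
#' @export
summarize_split_fronts <- function(fronts) {
  stopifnot(length(fronts) >= 1L)
  members <- purrr::imap_dfr(fronts, function(f, i) {
    tab <- if (inherits(f, "pareto_front")) f$members else
      tibble::as_tibble(f)
    dplyr::mutate(
      tab[c("n_channels", "accuracy", "tar", "trr")], split = i
    )
  })
  dplyr::summarise(
    dplyr::group_by(members, .data$n_channels),
    n_members = dplyr::n(),
    mean_accuracy = mean(.data$accuracy), sd_accuracy = sd(.data$accuracy),
    mean_tar = mean(.data$tar), sd_tar = sd(.data$tar),
    mean_trr = mean(.data$trr), sd_trr = sd(.data$trr),
    .groups = "drop"
  )
}

#' Tidy a Pareto front into its member table
#'
#' @param x A `pareto_front`.
#' @param ... Unused.
#' @return Tibble with one row per front member: the four objectives,
#'   nu/gamma and channel labels.
#' @export
tidy.pareto_front <- function(x, ...) {
  dplyr::select(x$members, "n_channels", "accuracy", "tar", "trr",
                "nu", "gamma", "channels")
}

#' One-row summary of an NSGA run
#'
#' @param x A `pareto_front`.
#' @param ... Unused.
#' @return One-row tibble: variant, front size, generations run,
#'   convergence flag, total evaluations, and the best value reached per
#'   objective.
#' @export
glance.pareto_front <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    front_size = nrow(x$members),
    n_generations = x$n_generations,
    converged = x$converged,
    n_evaluations = nrow(x$evaluations),
    min_channels = min(x$members$n_channels),
    max_accuracy = max(x$members$accuracy),
    max_tar = max(x$members$tar),
    max_trr = max(x$members$trr)
  )
}

#' Plot a Pareto front: objective rates versus channel count
#'
#' @param object A `pareto_front`.
#' @param ... Unused.
#' @return A ggplot: accuracy, TAR and TRR of each front member against
#'   its number of channels.
#' @export
autoplot.pareto_front <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$members, "n_channels", "accuracy", "tar", "trr"),
    cols = c("accuracy", "tar", "trr"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_channels, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Number of channels", y = "Rate",
                  colour = NULL,
                  title = "Pareto front: rates vs channel count") +
    ggplot2::theme_minimal()
}

#' Plot per-generation search progress
#'
#' @param front A `pareto_front` with its generation log.
#' @return A ggplot of front size and best-per-objective values by
#'   generation.
#' @export
plot_search_progress <- function(front) {
  stopifnot(inherits(front, "pareto_front"))
  long <- tidyr::pivot_longer(front$generations, -"generation",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Generation", y = NULL,
                  title = "Search progress") +
    ggplot2::theme_minimal()
}
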