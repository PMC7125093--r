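#' Evaluation protocol configuration
#'
#' Fixes the session protocol and cross-validation settings used to score
#' every candidate: the one-class authentication model is trained on the
#' non-intruder instances of the training session and validated on the
#' test session (TAR on non-intruders, TRR on intruders), while the
#' identification accuracy is the stratified k-fold cross-validated
#' accuracy of a linear multi-class SVM over the non-intruder instances of
#' the training session. One fixed fold assignment (under `cv_seed`) is
#' reused for every candidate so objective differences reflect channels
#' and parameters, not fold shuffling.
#'
#' @param train_session Session used for training (default 1).
#' @param test_session Session used for authentication validation
#'   (default 2).
#' @param cv_folds Identification cross-validation folds (default 10).
#' @param cv_seed Fold-assignment seed (default 1).
#' @param linear_cost Linear-SVM regularization constant (default 1).
#' @param param_table nu/gamma lookup table
#'   ([default_parameter_table()]).
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(train_session = 1L, test_session = 2L,
                        cv_folds = 10L, cv_seed = 1L, linear_cost = 1,
                        param_table = default_parameter_table()) {
  validate_parameter_table(param_table)
  structure(list(train_session = as.integer(train_session),
                 test_session = as.integer(test_session),
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed),
                 linear_cost = linear_cost,
                 param_table = param_table),
            class = "eval_config")
}

sentinel_objectives <- function(n_channels_total, nu = NA_real_,
                                gamma = NA_real_) {
  # worst objective vector for infeasible candidates: one more channel than
  # exists, and zero for every maximized rate (minimization image
  # (n_ch + 1, 1, 1, 1)); penalization keeps the evaluation total without
  # repairing masks the search never chose.
  tibble::tibble(n_channels = n_channels_total + 1L,
                 accuracy = 0, tar = 0, trr = 0, nu = nu, gamma = gamma)
}

#' Score one chromosome on the four objectives
#'
#' Decodes the chromosome into a channel mask and (nu, gamma), builds the
#' masked instance vectors from the feature cache, trains the one-class
#' authentication model on the non-intruder training-session instances,
#' measures TAR / TRR on the test session, and the identification accuracy
#' by stratified k-fold cross-validation of a linear SVM. An all-zero
#' channel mask is penalized with a sentinel worst objective vector rather
#' than raising, so the optimizer's evaluation is total.
#'
#' @param genes Chromosome (`n_channels + 8` binary genes).
#' @param cache A `feature_cache` (or compiled cache) covering all
#'   channels and both sessions.
#' @param split A [subject_split()].
#' @param config An [eval_config()].
#' @return One-row tibble: `n_channels`, `accuracy`, `tar`, `trr`, `nu`,
#'   `gamma`.
#' @export
evaluate_candidate <- function(genes, cache, split, config = eval_config()) {
  cm <- compile_cache(cache)
  n_ch <- cm$n_channels
  dec <- decode_chromosome(genes, config$param_table, n_channels = n_ch)
  if (length(dec$channels) == 0L) {
    return(sentinel_objectives(n_ch, dec$nu, dec$gamma))
  }
  evaluate_configuration(dec$channels, dec$nu, dec$gamma, cm, split, config)
}

#' Score an explicit (channel set, nu, gamma) configuration
#'
#' Same protocol as [evaluate_candidate()] but for an explicit channel
#' index set and parameter values (e.g. the all-channel baseline or a
#' configuration read off a report).
#'
#' @param channels Integer montage indices (1-based), non-empty.
#' @param nu,gamma One-class SVM parameters.
#' @inheritParams evaluate_candidate
#' @return One-row tibble: `n_channels`, `accuracy`, `tar`, `trr`, `nu`,
#'   `gamma`.
#' @export
evaluate_configuration <- function(channels, nu, gamma, cache, split,
                                   config = eval_config()) {
  cm <- compile_cache(cache)
  train <- instance_matrix(cm, channels, subjects = split$non_intruders,
                           sessions = config$train_session)
  genuine <- instance_matrix(cm, channels, subjects = split$non_intruders,
                             sessions = config$test_session)
  intruder <- instance_matrix(cm, channels, subjects = split$intruders,
                              sessions = config$test_session)
  res <- tryCatch({
    model <- train_one_class(train$X, nu, gamma)
    auth <- evaluate_authentication(model, genuine$X, intruder$X)
    cv <- crossval_identification(train$X, train$meta$subject,
                                  k = config$cv_folds,
                                  seed = config$cv_seed,
                                  cost = config$linear_cost)
    tibble::tibble(n_channels = length(unique(channels)),
                   accuracy = cv$mean_accuracy,
                   tar = auth$tar, trr = auth$trr,
                   nu = nu, gamma = gamma)
  }, error = function(e) NULL)
  if (is.null(res)) return(sentinel_objectives(cm$n_channels, nu, gamma))
  res
}

#' Build an NSGA evaluator closed over a dataset and split
#'
#' Compiles the feature cache once and returns the deterministic
#' candidate-scoring function handed to [run_nsga()].
#'
#' @inheritParams evaluate_candidate
#' @return Function mapping a gene vector to the one-row objective tibble
#'   of [evaluate_candidate()].
#' @export
make_evaluator <- function(cache, split, config = eval_config()) {
  cm <- compile_cache(cache)
  function(genes) evaluate_candidate(genes, cm, split, config)
}
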