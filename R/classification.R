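#' Train the one-class authentication model
#'
#' Fits a one-class SVM with RBF kernel on the pooled instance vectors of
#' the enrolled (non-intruder) subjects. `nu` is an upper bound on the
#' fraction of training errors and a lower bound on the fraction of support
#' vectors; `gamma` sets the RBF kernel width (the larger, the more local
#' each training example's influence). Acceptance uses the decision
#' function's natural zero boundary; no offset is tuned.
#'
#' libsvm cannot solve the degenerate `nu = 1` problem, so `nu` is clamped
#' to `[1e-6, 1 - 1e-6]` at fit time; the requested value is kept in the
#' model metadata.
#'
#' @param features Numeric matrix, instances x features, with >= 2 rows.
#' @param nu One-class nu parameter in (0, 1].
#' @param gamma RBF kernel width, > 0.
#' @param meta Optional list of training metadata (subjects, session,
#'   channel mask) carried on the model.
#' @return An object of class `auth_model`.
#' @export
train_one_class <- function(features, nu, gamma, meta = list()) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 training instances")
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1) {
    stop("nu must be in (0, 1]")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be > 0")
  }
  fit <- e1071::svm(features, y = NULL, type = "one-classification",
                    kernel = "radial",
                    nu = min(max(nu, 1e-6), 1 - 1e-6),
                    gamma = gamma, scale = FALSE)
  structure(list(fit = fit, nu = nu, gamma = gamma,
                 n_features = ncol(features), meta = meta),
            class = "auth_model")
}

#' @export
print.auth_model <- function(x, ...) {
  cat(sprintf("<auth_model> one-class RBF SVM, nu = %g, gamma = %g, %d features\n",
              x$nu, x$gamma, x$n_features))
  invisible(x)
}

#' Accept/reject instances with a trained authentication model
#'
#' @param object An `auth_model`.
#' @param newdata Numeric matrix (or vector for a single instance) with the
#'   training feature dimension.
#' @param ... Unused.
#' @return Logical vector: `TRUE` = accepted as enrolled.
#' @export
predict.auth_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 object$n_features, ncol(newdata)))
  }
  as.logical(predict(object$fit, newdata))
}

#' Authentication metrics: TAR, FAR, TRR
#'
#' Counts acceptance per instance (epoch): the true acceptance rate is the
#' fraction of genuine (enrolled-subject) instances accepted, the true
#' rejection rate the fraction of intruder instances rejected, and the
#' false acceptance rate is `1 - TRR` by construction.
#'
#' @param model An `auth_model`.
#' @param genuine Instance matrix of enrolled subjects (non-empty).
#' @param intruder Instance matrix of intruders (non-empty).
#' @return One-row tibble with `tar`, `far`, `trr` and the underlying
#'   counts (`n_genuine`, `genuine_accepted`, `n_intruder`,
#'   `intruder_rejected`).
#' @export
evaluate_authentication <- function(model, genuine, intruder) {
  if (is.null(dim(genuine))) genuine <- matrix(genuine, nrow = 1L)
  if (is.null(dim(intruder))) intruder <- matrix(intruder, nrow = 1L)
  if (nrow(genuine) == 0L) stop("genuine instance set is empty")
  if (nrow(intruder) == 0L) stop("intruder instance set is empty")
  acc_g <- predict(model, genuine)
  acc_i <- predict(model, intruder)
  tar <- mean(acc_g)
  trr <- mean(!acc_i)
  tibble::tibble(
    tar = tar, far = 1 - trr, trr = trr,
    n_genuine = length(acc_g), genuine_accepted = sum(acc_g),
    n_intruder = length(acc_i), intruder_rejected = sum(!acc_i)
  )
}

# Stratified fold assignment: within each class, instances are shuffled
# under the seed and dealt to folds cyclically.
stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' K-fold cross-validated subject identification accuracy
#'
#' Accuracy of a multi-class linear SVM identifying the subject from the
#' instance vectors, estimated by stratified k-fold cross-validation
#' (default 10-fold). Fold assignment shuffles within each class under a
#' fixed seed, so the estimate is deterministic and comparable across
#' candidate channel masks.
#'
#' @param features Instance matrix (instances x features).
#' @param labels Subject id per instance.
#' @param k Number of folds (>= 2, default 10); every class must have at
#'   least `k` instances.
#' @param seed Shuffle seed for fold assignment.
#' @param cost Linear-SVM regularization constant (default 1).
#' @return One-row tibble with `mean_accuracy`, `sd_accuracy`, `k`.
#' @export
crossval_identification <- function(features, labels, k = 10, seed = 1,
                                    cost = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  counts <- table(labels)
  if (any(counts < k)) {
    small <- names(counts)[counts < k][1]
    stop(sprintf(
      "class '%s' has %d instances, fewer than %d folds; use a smaller k",
      small, counts[small], k
    ))
  }
  fold <- stratified_folds(as.character(labels), k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- e1071::svm(features[tr, , drop = FALSE],
                      droplevels(labels[tr]),
                      kernel = "linear", cost = cost, scale = FALSE)
    mean(as.character(predict(fit, features[!tr, , drop = FALSE])) ==
           as.character(labels[!tr]))
  }, numeric(1))
  tibble::tibble(mean_accuracy = mean(acc), sd_accuracy = sd(acc), k = k)
}

#' Two-layer authenticate-then-identify decision
#'
#' The deployment flow of the system: an incoming instance is first checked
#' by the one-class authentication layer; only accepted instances are
#' passed to the multi-class identification layer, rejected ones are
#' labelled as intruders and never identified.
#'
#' @param auth_model An `auth_model`.
#' @param id_model A fitted multi-class SVM (e.g. from
#'   [train_identifier()]).
#' @param newdata Instance matrix.
#' @return Tibble with `accepted` (logical) and `identity` (subject id, or
#'   `NA` for rejected instances).
#' @export
authenticate_identify <- function(auth_model, id_model, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  accepted <- predict(auth_model, newdata)
  identity <- rep(NA_character_, nrow(newdata))
  if (any(accepted)) {
    identity[accepted] <- as.character(
      predict(id_model, newdata[accepted, , drop = FALSE])
    )
  }
  tibble::tibble(accepted = accepted, identity = identity)
}

#' Fit the multi-class identification SVM
#'
#' @param features Instance matrix.
#' @param labels Subject id per instance.
#' @param cost Linear-SVM regularization constant (default 1).
#' @return A fitted `e1071::svm` object.
#' @export
train_identifier <- function(features, labels, cost = 1) {
  e1071::svm(as.matrix(features), factor(labels), kernel = "linear",
             cost = cost, scale = FALSE)
}
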