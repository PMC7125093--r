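#' Common average reference
#'
#' Re-references a single epoch by subtracting, at every sample, the mean
#' across all recorded channels: `out[i, t] = x[i, t] - mean(x[, t])`. This
#' removes the information common to all electrodes and improves the
#' signal-to-noise ratio of spatially local activity. After CAR the channel
#' sum at every sample is zero (to numerical tolerance), and the operator is
#' linear and idempotent.
#'
#' CAR is always computed over the full montage, before any channel
#' selection, so that per-channel features cached once remain valid for
#' every channel mask.
#'
#' @param epoch Numeric matrix, channels x samples, with at least 2 rows.
#' @return Matrix of the same shape, re-referenced to the common average.
#' @export
#' @examples
#' common_average_reference(matrix(c(1, 3, 5, 2, 4, 6), nrow = 3))
common_average_reference <- function(epoch) {
  if (!is.matrix(epoch) || !is.numeric(epoch)) {
    stop("epoch must be a numeric matrix (channels x samples)")
  }
  if (nrow(epoch) < 2L) {
    stop("common average reference requires at least 2 channels")
  }
  if (!all(is.finite(epoch))) stop("epoch contains non-finite values")
  sweep(epoch, 2L, colMeans(epoch), "-")
}

#' Apply the common average reference to every epoch of an epoch set
#'
#' @param x An [epoch_set()].
#' @param apply If `FALSE`, the epoch set is returned unchanged (ablation
#'   switch).
#' @return An `epoch_set` with each epoch re-referenced.
#' @export
car_epochset <- function(x, apply = TRUE) {
  validate_epoch_set(x)
  if (!apply) return(x)
  x$epochs$data <- lapply(x$epochs$data, common_average_reference)
  x
}
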