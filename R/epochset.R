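#' Construct an epoch set
#'
#' An epoch set is the package's raw-data container: a collection of
#' fixed-length multi-channel EEG epochs (channels x samples, microvolts)
#' indexed by subject and session, together with the montage (ordered
#' channel-label list) and the sampling rate. The montage order is the
#' canonical mapping between channel labels and gene positions in the
#' channel-selection chromosome.
#'
#' @param epochs A tibble with columns `subject` (character), `session`
#'   (integer), `epoch` (integer, 1-based within session) and `data`
#'   (list-column of numeric matrices, channels x samples).
#' @param montage Character vector of channel labels; row `i` of every epoch
#'   matrix is channel `montage[i]`.
#' @param sampling_rate Sampling rate in Hz, a single positive number.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, montage, sampling_rate) {
  epochs <- tibble::as_tibble(epochs)
  out <- structure(
    list(
      epochs = epochs,
      montage = as.character(montage),
      sampling_rate = as.numeric(sampling_rate)
    ),
    class = "epoch_set"
  )
  validate_epoch_set(out)
}

#' Validate an epoch set
#'
#' Checks the structural invariants: every epoch matrix has exactly
#' `length(montage)` rows and a common number of samples, the sampling rate
#' is positive, and every (subject, session) pair has at least one epoch.
#'
#' @param x An `epoch_set`.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_epoch_set <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  ep <- x$epochs
  required <- c("subject", "session", "epoch", "data")
  if (!all(required %in% names(ep))) {
    stop("epoch table must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(ep) == 0L) stop("epoch set contains no epochs")
  if (length(x$sampling_rate) != 1L || !is.finite(x$sampling_rate) ||
      x$sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (anyDuplicated(x$montage)) stop("montage labels must be unique")
  n_ch <- length(x$montage)
  dims <- vapply(ep$data, dim, integer(2))
  if (any(dims[1, ] != n_ch)) {
    bad <- which(dims[1, ] != n_ch)[1]
    stop(sprintf(
      "channel-count mismatch: epoch %d of subject %s session %d has %d rows, montage has %d",
      ep$epoch[bad], ep$subject[bad], ep$session[bad], dims[1, bad], n_ch
    ))
  }
  if (length(unique(dims[2, ])) != 1L) {
    stop("epoch length mismatch: all epochs must share a common sample count")
  }
  x
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d subjects, %d epochs, %d channels x %d samples @ %g Hz\n",
    length(unique(x$epochs$subject)), nrow(x$epochs),
    length(x$montage), n_samples(x), x$sampling_rate
  ))
  invisible(x)
}

#' Number of samples per epoch
#' @param x An `epoch_set`.
#' @return Integer sample count shared by all epochs.
#' @export
n_samples <- function(x) ncol(x$epochs$data[[1]])

#' Subject identifiers of an epoch set
#' @param x An `epoch_set`.
#' @return Character vector of unique subject ids, in order of appearance.
#' @export
subjects <- function(x) unique(x$epochs$subject)

session_file_name <- function(subject, session) {
  sprintf("epochs_%s_session%d.tsv", subject, session)
}

#' Save an epoch set to a dataset directory
#'
#' Writes a plain-text dataset: a `manifest.yml` with the montage, sampling
#' rate and subject/session index, plus one TSV per (subject, session) with
#' one row per channel per epoch (columns `epoch`, `channel`, `s0` ...
#' `s{L-1}`). The format round-trips numeric content exactly via
#' [load_epochset()].
#'
#' @param epochs An `epoch_set`.
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
save_epochset <- function(epochs, path) {
  validate_epoch_set(epochs)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create dataset directory: ", path)
  idx <- dplyr::distinct(epochs$epochs, .data$subject, .data$session)
  L <- n_samples(epochs)
  sessions <- purrr::pmap(idx, function(subject, session) {
    rows <- dplyr::filter(
      epochs$epochs,
      .data$subject == !!subject, .data$session == !!session
    )
    tab <- purrr::map2_dfr(rows$epoch, rows$data, function(e, m) {
      # %.17g guarantees the doubles survive the text round trip bitwise
      txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
      wide <- tibble::as_tibble(txt,
                                .name_repair = ~ paste0("s", seq_along(.x) - 1))
      dplyr::bind_cols(
        tibble::tibble(epoch = e, channel = epochs$montage), wide
      )
    })
    f <- session_file_name(subject, session)
    readr::write_tsv(tab, file.path(path, f), progress = FALSE)
    list(subject = subject, session = session,
         file = f, n_epochs = nrow(rows))
  })
  manifest <- list(
    format = "eegselect-dataset-v1",
    montage = as.list(epochs$montage),
    sampling_rate = epochs$sampling_rate,
    n_samples = L,
    sessions = sessions
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yml"))
  invisible(path)
}

#' Load an epoch set from a dataset directory
#'
#' Reads a directory written by [save_epochset()]. The montage order is taken
#' from the manifest verbatim. Validation failures name the offending file:
#' a missing manifest, a channel count different from the montage length, and
#' an epoch length different from the manifest's sample count each raise a
#' distinct error.
#'
#' @param path Dataset directory.
#' @return An `epoch_set`.
#' @export
load_epochset <- function(path) {
  mf <- file.path(path, "manifest.yml")
  if (!file.exists(mf)) stop("missing manifest: ", mf)
  manifest <- yaml::read_yaml(mf)
  montage <- as.character(unlist(manifest$montage))
  L <- manifest$n_samples
  n_ch <- length(montage)
  rows <- purrr::map_dfr(manifest$sessions, function(s) {
    f <- file.path(path, s$file)
    if (!file.exists(f)) stop("missing session file: ", f)
    # base read.delim: correctly rounded double parsing for exact round trips
    tab <- utils::read.delim(f, check.names = FALSE,
                             colClasses = c(epoch = "integer",
                                            channel = "character"))
    if (ncol(tab) - 2L != L) {
      stop(sprintf("epoch length mismatch in %s: %d samples, manifest says %d",
                   s$file, ncol(tab) - 2L, L))
    }
    mats <- lapply(split(tab, tab$epoch), function(block) {
      if (nrow(block) != n_ch) {
        stop(sprintf(
          "channel-count mismatch in %s: epoch %s has %d rows, montage has %d",
          s$file, block$epoch[1], nrow(block), n_ch
        ))
      }
      block <- block[match(montage, block$channel), ]
      as.matrix(block[, -(1:2)], rownames.force = FALSE) |>
        unname() |>
        matrix(nrow = n_ch)
    })
    tibble::tibble(
      subject = as.character(s$subject),
      session = as.integer(s$session),
      epoch = as.integer(names(mats)),
      data = unname(mats)
    )
  })
  rows <- dplyr::arrange(rows, .data$subject, .data$session, .data$epoch)
  epoch_set(rows, montage, manifest$sampling_rate)
}

#' Define a non-intruder / intruder subject split
#'
#' Partitions subjects into an enrolled ("non-intruder") group used to train
#' the authentication layer and an intruder group used only at evaluation
#' time. The two sets must be disjoint and non-empty.
#'
#' @param non_intruders Character vector of enrolled subject ids.
#' @param intruders Character vector of intruder subject ids.
#' @return An object of class `subject_split`.
#' @export
subject_split <- function(non_intruders, intruders) {
  non_intruders <- as.character(non_intruders)
  intruders <- as.character(intruders)
  if (length(non_intruders) == 0L || length(intruders) == 0L) {
    stop("both subject groups must be non-empty")
  }
  if (length(intersect(non_intruders, intruders)) > 0L) {
    stop("non-intruder and intruder sets must be disjoint")
  }
  structure(list(non_intruders = non_intruders, intruders = intruders),
            class = "subject_split")
}

#' @export
print.subject_split <- function(x, ...) {
  cat(sprintf("<subject_split> %d non-intruders / %d intruders\n",
              length(x$non_intruders), length(x$intruders)))
  invisible(x)
}

#' Default 56-channel montage
#'
#' A 56-label extended 10-20 montage used as the default channel list for
#' full-scale synthetic datasets. The label set is a stand-in: all package
#' logic is label-agnostic and any montage of unique labels works.
#'
#' @return Character vector of 56 channel labels.
#' @export
default_montage_56 <- function() {
  c("FP1", "FP2", "AF7", "AF3", "AF4", "AF8", "F7", "F5", "F3", "F1",
    "FZ", "F2", "F4", "F6", "F8", "FT7", "FC5", "FC3", "FC1", "FCZ",
    "FC2", "FC4", "FC6", "FT8", "T7", "C5", "C3", "C1", "CZ", "C2",
    "C4", "C6", "T8", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4",
    "CP6", "TP8", "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6",
    "P8", "PO7", "PO3", "POZ", "PO4", "O1")
}
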