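#' Feature-extraction configuration
#'
#' Bundles every tunable of the per-channel feature path: the Minkowski
#' order used to rank IMFs against the raw signal, the maximum lag of the
#' Higuchi curve-length construction, the floor applied before taking
#' log10 of an energy (guards zero-energy IMFs), and the EMD sifting
#' settings. All values are recorded in the feature cache provenance.
#'
#' @param minkowski_p Minkowski order for IMF selection (> 0, default 2).
#' @param higuchi_kmax Maximum segment lag for the Higuchi fractal
#'   dimension (integer >= 2, default 10).
#' @param log_floor Lower bound applied inside `log10` for the two energy
#'   features (> 0, default 1e-12).
#' @param emd List of sifting settings: `sd_threshold` (default 0.2),
#'   `max_siftings` (default 50), `max_imfs` (default 10).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(minkowski_p = 2, higuchi_kmax = 10,
                           log_floor = 1e-12,
                           emd = list(sd_threshold = 0.2,
                                      max_siftings = 50,
                                      max_imfs = 10)) {
  stopifnot(minkowski_p > 0, higuchi_kmax >= 2, log_floor > 0)
  emd <- modifyList(
    list(sd_threshold = 0.2, max_siftings = 50, max_imfs = 10), emd
  )
  structure(list(minkowski_p = minkowski_p,
                 higuchi_kmax = as.integer(higuchi_kmax),
                 log_floor = log_floor, emd = emd),
            class = "feature_config")
}

#' Instantaneous energy of a series
#'
#' `log10` of the mean squared amplitude, floored at `log_floor`; a compact
#' description of the energy carried by an IMF. Scales as
#' `IE(a*x) = IE(x) + 2*log10(|a|)` above the floor.
#'
#' @param x Non-empty numeric vector.
#' @param log_floor Floor applied before `log10` (default 1e-12).
#' @return A scalar.
#' @export
instantaneous_energy <- function(x, log_floor = 1e-12) {
  if (length(x) == 0L) stop("empty series")
  log10(max(mean(x^2), log_floor))
}

#' Teager energy of a series
#'
#' `log10` of the mean absolute Teager-Kaiser operator
#' `x[n]^2 - x[n-1]*x[n+1]`, floored at `log_floor`. The operator tracks
#' variations in both amplitude and frequency: for a sinusoid
#' `A*sin(Omega*n)` it equals `A^2 * sin(Omega)^2` at every interior sample.
#'
#' @param x Numeric vector of length >= 3.
#' @param log_floor Floor applied before `log10` (default 1e-12).
#' @return A scalar.
#' @export
teager_energy <- function(x, log_floor = 1e-12) {
  n <- length(x)
  if (n < 3L) stop("Teager energy requires at least 3 samples")
  psi <- x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
  log10(max(mean(abs(psi)), log_floor))
}

#' Higuchi fractal dimension
#'
#' Estimates the fractal dimension of a series directly in the time domain
#' from the scaling of its mean curve length: for each lag `k = 1..k_max`
#' and offset `m = 1..k`, the normalized curve length
#' `L_m(k) = (sum |x(m+ik) - x(m+(i-1)k)|) * (N-1) / (floor((N-m)/k) * k^2)`
#' is averaged over offsets to `L(k)`, and the dimension is the negated
#' least-squares slope of `log L(k)` against `log k`. Values lie near 1 for
#' smooth curves and near 2 for white noise; the estimate is invariant to
#' affine transforms `a*x + b` (a != 0).
#'
#' A series whose curve length vanishes at some lag (e.g. a constant) falls
#' back to dimension 1, the dimension of a degenerate flat curve.
#'
#' @param x Numeric vector with `length(x) >= 2 * k_max`.
#' @param k_max Maximum lag (integer >= 2, default 10).
#' @return A scalar, typically in `[1, 2]` for real signals.
#' @export
higuchi_fd <- function(x, k_max = 10) {
  N <- length(x)
  k_max <- as.integer(k_max)
  if (k_max < 2L) stop("k_max must be >= 2")
  if (N < 2L * k_max) stop("series too short for k_max = ", k_max)
  Lk <- vapply(seq_len(k_max), function(k) {
    Lm <- vapply(seq_len(k), function(m) {
      xi <- x[seq.int(m, N, by = k)]
      nm <- length(xi) - 1L
      sum(abs(diff(xi))) * (N - 1) / (nm * k * k)
    }, numeric(1))
    mean(Lm)
  }, numeric(1))
  ok <- Lk > 0
  if (sum(ok) < 2L) return(1.0)
  fit <- lm(log(Lk[ok]) ~ log(seq_len(k_max)[ok]))
  -unname(coef(fit)[2])
}

#' Petrosian fractal dimension
#'
#' A fast complexity estimate from the sign pattern of the first
#' difference: with `N` the series length and `N_delta` the number of sign
#' changes in `diff(x)` (zero differences carry the previous sign),
#' `PFD = log10(N) / (log10(N) + log10(N / (N + 0.4 * N_delta)))`.
#' A strictly monotone series has no sign changes and PFD exactly 1;
#' the value is invariant to positive scaling.
#'
#' @param x Numeric vector of length >= 3.
#' @return A scalar >= 1.
#' @export
petrosian_fd <- function(x) {
  N <- length(x)
  if (N < 3L) stop("Petrosian dimension requires at least 3 samples")
  s <- sign(diff(x))
  # zeros in the difference carry the previous sign
  for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  nz <- s != 0
  s <- s[nz]
  n_delta <- if (length(s) < 2L) 0L else sum(s[-1L] != s[-length(s)])
  log10(N) / (log10(N) + log10(N / (N + 0.4 * n_delta)))
}

imf_feature_block <- function(x, cfg) {
  c(instantaneous_energy(x, cfg$log_floor),
    teager_energy(x, cfg$log_floor),
    higuchi_fd(x, cfg$higuchi_kmax),
    petrosian_fd(x))
}

#' Names of the 8 per-channel features, in cache/vector order
#' @return Character vector of length 8.
#' @export
feature_names <- function() {
  paste0(rep(c("ie", "te", "hfd", "pfd"), 2), rep(1:2, each = 4))
}

#' Extract the 8-feature block of one channel
#'
#' Runs the full per-channel feature path: EMD of the (already
#' re-referenced) single-channel series, selection of the two IMFs closest
#' to the raw signal by Minkowski distance, then four features per selected
#' IMF in fixed order (instantaneous energy, Teager energy, Higuchi fractal
#' dimension, Petrosian fractal dimension), concatenated in ascending
#' distance order. The block length is always exactly 8: when sifting
#' yields a single IMF its four features are duplicated, and when it yields
#' none (constant-like signal) the residual stands in — classifiers require
#' a fixed dimension.
#'
#' @param x Numeric vector, one channel of one epoch.
#' @param cfg A [feature_config()].
#' @return Named numeric vector of length 8 (names from [feature_names()]),
#'   all values finite.
#' @export
extract_channel_features <- function(x, cfg = feature_config()) {
  dec <- emd_decompose(x, cfg)
  cand <- if (length(dec$imfs) > 0L) dec$imfs else list(dec$residual)
  sel <- if (length(dec$imfs) > 0L) {
    select_imfs_minkowski(dec, cfg$minkowski_p)
  } else 1L
  if (length(sel) < 2L) sel <- rep(sel[1L], 2L)
  block <- c(imf_feature_block(cand[[sel[1L]]], cfg),
             imf_feature_block(cand[[sel[2L]]], cfg))
  names(block) <- feature_names()
  block
}

#' Precompute the feature cache of an epoch set
#'
#' Computes the 8-feature block of every channel of every epoch once and
#' stores it in a tidy table, so the evolutionary search can evaluate any
#' channel mask by row selection instead of recomputation. CAR is applied
#' over the full montage first (by default), which is what keeps the cached
#' per-channel features valid for every mask.
#'
#' @param x An [epoch_set()].
#' @param cfg A [feature_config()].
#' @param car Apply the common average reference before extraction
#'   (default `TRUE`).
#' @return A tibble of class `feature_cache` with columns `subject`,
#'   `session`, `epoch`, `channel_index`, `channel` and the 8 feature
#'   columns of [feature_names()]; provenance (montage, sampling rate,
#'   config, CAR flag) is stored in attributes.
#' @export
build_feature_cache <- function(x, cfg = feature_config(), car = TRUE) {
  validate_epoch_set(x)
  xs <- car_epochset(x, apply = car)
  n_ch <- length(xs$montage)
  rows <- purrr::pmap_dfr(
    xs$epochs,
    function(subject, session, epoch, data) {
      blocks <- t(apply(data, 1L, extract_channel_features, cfg = cfg))
      colnames(blocks) <- feature_names()
      dplyr::bind_cols(
        tibble::tibble(subject = subject, session = session, epoch = epoch,
                       channel_index = seq_len(n_ch),
                       channel = xs$montage),
        tibble::as_tibble(blocks)
      )
    }
  )
  if (!all(is.finite(as.matrix(rows[feature_names()])))) {
    stop("non-finite feature value in cache")
  }
  structure(
    rows,
    class = c("feature_cache", class(rows)),
    provenance = list(
      feature_order = feature_names(),
      config = cfg,
      car = car,
      montage = xs$montage,
      sampling_rate = xs$sampling_rate
    )
  )
}

#' Provenance metadata of a feature cache
#' @param cache A `feature_cache`.
#' @return List with `feature_order`, `config`, `car`, `montage`,
#'   `sampling_rate`.
#' @export
cache_provenance <- function(cache) attr(cache, "provenance")

# Wide view of the cache: one row per instance, 8 * n_channels columns in
# montage order. Idempotent: a compiled cache passes through, so hot paths
# can compile once and reuse.
compile_cache <- function(cache) {
  if (inherits(cache, "compiled_cache")) return(cache)
  prov <- cache_provenance(cache)
  n_ch <- length(prov$montage)
  tab <- dplyr::arrange(tibble::as_tibble(cache),
                        .data$subject, .data$session, .data$epoch,
                        .data$channel_index)
  meta <- dplyr::distinct(tab, .data$subject, .data$session, .data$epoch)
  fm <- as.matrix(tab[feature_names()])
  n_inst <- nrow(meta)
  stopifnot(nrow(fm) == n_inst * n_ch)
  # row blocks of n_ch channels -> one wide row of 8 * n_ch values
  X <- matrix(0, n_inst, 8L * n_ch)
  for (ch in seq_len(n_ch)) {
    X[, (ch - 1L) * 8L + 1:8] <- fm[seq.int(ch, nrow(fm), by = n_ch), ,
                                    drop = FALSE]
  }
  structure(list(meta = meta, X = X, n_channels = n_ch,
                 provenance = prov),
            class = "compiled_cache")
}

# Column indices of a channel mask in the compiled wide matrix.
mask_columns <- function(mask, n_channels) {
  mask <- sort(unique(as.integer(mask)))
  stopifnot(all(mask >= 1L), all(mask <= n_channels))
  as.vector(vapply(mask, function(ch) (ch - 1L) * 8L + 1:8, integer(8)))
}

#' Build one instance's feature vector from a channel mask
#'
#' Concatenates the 8-feature blocks of the masked channels, in montage
#' order, into the instance vector fed to the classifiers: the length is
#' always `8 * length(mask)`. Blocks are served from a feature cache when
#' one is supplied, otherwise computed directly from the epoch matrix.
#'
#' @param epoch Channels x samples matrix, or `NULL` when serving from
#'   `cache`.
#' @param mask Integer vector of channel indices (montage positions,
#'   1-based), non-empty.
#' @param cfg A [feature_config()] (direct computation path).
#' @param cache Optional `feature_cache`; requires `subject`, `session`
#'   and `epoch_index` to locate the instance.
#' @param subject,session,epoch_index Instance coordinates in the cache.
#' @param car Apply CAR before direct extraction (default `TRUE`); ignored
#'   when serving from cache.
#' @return Numeric vector of length `8 * length(mask)`.
#' @export
build_instance_vector <- function(epoch = NULL, mask, cfg = feature_config(),
                                  cache = NULL, subject = NULL,
                                  session = NULL, epoch_index = NULL,
                                  car = TRUE) {
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) == 0L) stop("empty channel mask")
  if (!is.null(cache)) {
    cm <- compile_cache(cache)
    row <- which(cm$meta$subject == subject &
                   cm$meta$session == session &
                   cm$meta$epoch == epoch_index)
    if (length(row) != 1L) stop("instance not found in cache")
    return(as.numeric(cm$X[row, mask_columns(mask, cm$n_channels)]))
  }
  stopifnot(is.matrix(epoch))
  if (any(mask > nrow(epoch))) stop("mask index exceeds channel count")
  ep <- if (car && nrow(epoch) >= 2L) common_average_reference(epoch) else epoch
  # vapply gives an 8 x |mask| matrix; column-major flattening concatenates
  # the per-channel blocks in (sorted) mask order
  as.numeric(vapply(mask, function(ch) {
    extract_channel_features(ep[ch, ], cfg)
  }, numeric(8)))
}

#' Instance matrix for a subject/session pool and channel mask
#'
#' Serves, from the feature cache, the full design matrix of masked feature
#' vectors for a pool of instances (rows ordered by subject, session,
#' epoch).
#'
#' @param cache A `feature_cache`.
#' @param mask Integer channel indices, non-empty.
#' @param subjects Optional subject filter.
#' @param sessions Optional session filter.
#' @return List with `X` (instances x `8*length(mask)` matrix) and `meta`
#'   (tibble of `subject`, `session`, `epoch`).
#' @export
instance_matrix <- function(cache, mask, subjects = NULL, sessions = NULL) {
  if (length(mask) == 0L) stop("empty channel mask")
  cm <- compile_cache(cache)
  keep <- rep(TRUE, nrow(cm$meta))
  if (!is.null(subjects)) keep <- keep & cm$meta$subject %in% subjects
  if (!is.null(sessions)) keep <- keep & cm$meta$session %in% sessions
  list(X = cm$X[keep, mask_columns(mask, cm$n_channels), drop = FALSE],
       meta = cm$meta[keep, ])
}

#' Save / load a feature cache as delimited text
#'
#' The cache is a single TSV with a YAML provenance sidecar recording the
#' feature order, EMD settings, Minkowski order, CAR flag and montage.
#'
#' @param cache A `feature_cache`.
#' @param path File path for the TSV (the sidecar adds `.provenance.yml`).
#' @return `path` invisibly (`save_feature_cache`); a `feature_cache`
#'   (`load_feature_cache`).
#' @export
save_feature_cache <- function(cache, path) {
  readr::write_tsv(tibble::as_tibble(cache), path, progress = FALSE)
  prov <- cache_provenance(cache)
  prov$config <- unclass(prov$config)
  yaml::write_yaml(prov, paste0(path, ".provenance.yml"))
  invisible(path)
}

#' @rdname save_feature_cache
#' @export
load_feature_cache <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  pf <- paste0(path, ".provenance.yml")
  if (!file.exists(pf)) stop("missing cache provenance: ", pf)
  prov <- yaml::read_yaml(pf)
  prov$montage <- as.character(unlist(prov$montage))
  prov$feature_order <- as.character(unlist(prov$feature_order))
  cfgl <- prov$config
  prov$config <- feature_config(minkowski_p = cfgl$minkowski_p,
                                higuchi_kmax = cfgl$higuchi_kmax,
                                log_floor = cfgl$log_floor,
                                emd = cfgl$emd)
  tab$session <- as.integer(tab$session)
  tab$epoch <- as.integer(tab$epoch)
  tab$channel_index <- as.integer(tab$channel_index)
  tab$subject <- as.character(tab$subject)
  structure(tab, class = c("feature_cache", class(tab)), provenance = prov)
}
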