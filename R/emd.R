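#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' sifting: at each step the mean of the upper and lower cubic-spline
#' envelopes (through local maxima and minima, with mirrored extrema
#' extension at the boundaries) is subtracted until a Cauchy-type stopping
#' criterion is met. The first IMF carries the fastest oscillations;
#' extraction stops when the residual has fewer than two maxima or two
#' minima (is monotone-like) or `max_imfs` is reached.
#'
#' By construction `original = sum(imfs) + residual` exactly; the
#' decomposition of a constant or too-short signal has zero IMFs and a
#' residual equal to the input (no error: downstream feature extraction has
#' a documented fallback).
#'
#' @param x Numeric vector, the signal to decompose.
#' @param cfg A [feature_config()]; its `emd` element supplies
#'   `sd_threshold` (Cauchy sifting threshold, default 0.2),
#'   `max_siftings` (per IMF, default 50) and `max_imfs` (default 10).
#' @return An object of class `imf_set`: a list with `original`, `imfs`
#'   (list of numeric vectors, possibly empty) and `residual`.
#' @export
emd_decompose <- function(x, cfg = feature_config()) {
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  ecfg <- cfg$emd
  imfs <- list()
  residual <- x
  if (length(x) >= 16L) {
    while (length(imfs) < ecfg$max_imfs) {
      imf <- sift_imf(residual, ecfg$sd_threshold, ecfg$max_siftings)
      if (is.null(imf)) break
      imfs[[length(imfs) + 1L]] <- imf
      residual <- residual - imf
    }
  }
  structure(list(original = x, imfs = imfs, residual = residual),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs, length %d\n", length(x$imfs),
              length(x$original)))
  invisible(x)
}

# Local extrema indices with plateau handling: a run of equal values at a
# turning point yields its midpoint.
find_extrema <- function(x) {
  d <- diff(x)
  nz <- which(d != 0)
  empty <- list(maxima = integer(0), minima = integer(0))
  if (length(nz) < 2L) return(empty)
  s <- sign(d[nz])
  ch <- which(s[-1L] != s[-length(s)])
  if (length(ch) == 0L) return(empty)
  idx <- (nz[ch] + 1L + nz[ch + 1L]) %/% 2L
  list(maxima = idx[s[ch] > 0], minima = idx[s[ch] < 0])
}

# Spline envelope through extrema, with up to two extrema mirrored around
# each end of the series so the envelope is anchored beyond the boundaries.
envelope <- function(idx, val, n) {
  k <- min(2L, length(idx))
  left_t <- 2L - rev(idx[seq_len(k)])          # reflect about t = 1
  left_v <- rev(val[seq_len(k)])
  tail_i <- seq(length(idx) - k + 1L, length(idx))
  right_t <- 2L * n - rev(idx[tail_i])          # reflect about t = n
  right_v <- rev(val[tail_i])
  f <- splinefun(c(left_t, idx, right_t), c(left_v, val, right_v),
                 method = "natural")
  f(seq_len(n))
}

# One full sifting pass; NULL when the residual is monotone-like.
sift_imf <- function(x, sd_threshold, max_siftings) {
  n <- length(x)
  h <- x
  for (it in seq_len(max_siftings)) {
    ext <- find_extrema(h)
    if (length(ext$maxima) < 2L || length(ext$minima) < 2L) {
      if (it == 1L) return(NULL)
      break
    }
    upper <- envelope(ext$maxima, h[ext$maxima], n)
    lower <- envelope(ext$minima, h[ext$minima], n)
    m <- (upper + lower) / 2
    h_new <- h - m
    sd_it <- sum((h - h_new)^2) / (sum(h^2) + .Machine$double.eps)
    h <- h_new
    if (sd_it < sd_threshold) break
  }
  h
}

#' Select the two IMFs closest to the original signal
#'
#' Redundant IMFs produced by sifting differ in shape and frequency content
#' from the raw signal and show large Minkowski distances to it; the two
#' IMFs with the *smallest* Minkowski-p distance to the original are the
#' informative pair used for feature extraction. Ties are broken in favour
#' of the lower IMF index.
#'
#' @param imfset An `imf_set` from [emd_decompose()].
#' @param p Minkowski order (positive real, default 2 = Euclidean).
#' @return Integer vector of IMF indices ordered by ascending distance;
#'   length `min(2, number of IMFs)` (the fixed-dimension fallback for
#'   fewer than two IMFs lives in [extract_channel_features()]).
#' @export
select_imfs_minkowski <- function(imfset, p = 2) {
  stopifnot(inherits(imfset, "imf_set"), p > 0)
  k <- length(imfset$imfs)
  if (k <= 2L) return(seq_len(k))
  d <- vapply(imfset$imfs, minkowski_distance, numeric(1),
              y = imfset$original, p = p)
  ord <- order(d, seq_along(d))   # ties -> lower index first
  ord[1:2]
}

#' Minkowski distance between two equal-length series
#' @param x,y Numeric vectors of equal length.
#' @param p Order of the distance (p > 0).
#' @return `(sum(|x - y|^p))^(1/p)`.
#' @export
minkowski_distance <- function(x, y, p = 2) {
  stopifnot(length(x) == length(y), p > 0)
  sum(abs(x - y)^p)^(1 / p)
}
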