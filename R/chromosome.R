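#' The 16-entry nu/gamma lookup table
#'
#' Candidate values for the one-class SVM's `nu` and `gamma` parameters,
#' indexed 0-15 by the 4-bit fields of the chromosome. The same table
#' serves both parameters.
#'
#' @return Numeric vector of length 16, named by index `"0"`..`"15"`.
#' @export
default_parameter_table <- function() {
  v <- c(0.000001, 0.0001, 0.0005, 0.001, 0.005, 0.01, 0.1, 0.2,
         0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  names(v) <- as.character(0:15)
  v
}

validate_parameter_table <- function(table) {
  if (length(table) != 16L) stop("parameter table must have exactly 16 entries")
  if (any(table <= 0)) stop("parameter table values must be strictly positive")
  table
}

#' Convert a bit vector (most-significant bit first) to an integer
#' @param bits Vector of 0/1 values.
#' @return Non-negative integer.
#' @export
bits_to_int <- function(bits) {
  stopifnot(all(bits %in% c(0L, 1L)))
  sum(bits * 2L^((length(bits) - 1L):0L))
}

#' Decode a channel-selection chromosome
#'
#' A chromosome of `n_channels + 8` binary genes encodes one candidate
#' configuration: the first `n_channels` genes are the channel mask (gene
#' `i` selects montage channel `i`), the next 4 genes index the `nu` value
#' and the last 4 genes the `gamma` value in the 16-entry lookup table
#' (most-significant bit first). With the full 56-channel montage this is
#' the 64-gene chromosome of the search.
#'
#' @param genes Vector of `n_channels + 8` values in \{0, 1\}.
#' @param table Lookup table for nu and gamma
#'   ([default_parameter_table()]).
#' @param n_channels Number of channel genes (default 56).
#' @return List with `channels` (integer montage indices, 1-based), `nu`,
#'   `gamma`, `nu_index`, `gamma_index` (0-based table positions).
#' @export
decode_chromosome <- function(genes, table = default_parameter_table(),
                              n_channels = length(genes) - 8L) {
  genes <- as.integer(genes)
  if (length(genes) != n_channels + 8L) {
    stop(sprintf("chromosome must have %d genes, got %d",
                 n_channels + 8L, length(genes)))
  }
  if (!all(genes %in% c(0L, 1L))) stop("genes must be binary")
  validate_parameter_table(table)
  nu_index <- bits_to_int(genes[n_channels + 1:4])
  gamma_index <- bits_to_int(genes[n_channels + 5:8])
  list(
    channels = which(genes[seq_len(n_channels)] == 1L),
    nu = unname(table[nu_index + 1L]),
    gamma = unname(table[gamma_index + 1L]),
    nu_index = nu_index,
    gamma_index = gamma_index
  )
}

#' Encode a chromosome from a channel mask and parameter indices
#'
#' Inverse of [decode_chromosome()], mainly for constructing explicit
#' candidates to evaluate.
#'
#' @param channels Integer montage indices (1-based) to switch on.
#' @param nu_index,gamma_index 0-based positions in the parameter table.
#' @param n_channels Number of channel genes (default 56).
#' @return Integer vector of `n_channels + 8` genes.
#' @export
encode_chromosome <- function(channels, nu_index, gamma_index,
                              n_channels = 56L) {
  stopifnot(all(channels >= 1L), all(channels <= n_channels),
            nu_index >= 0L, nu_index <= 15L,
            gamma_index >= 0L, gamma_index <= 15L)
  genes <- integer(n_channels + 8L)
  genes[as.integer(channels)] <- 1L
  genes[n_channels + 1:4] <- int_to_bits4(nu_index)
  genes[n_channels + 5:8] <- int_to_bits4(gamma_index)
  genes
}

int_to_bits4 <- function(v) {
  as.integer(intToBits(v))[4:1]
}
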