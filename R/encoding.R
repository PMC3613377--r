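# One-hot encoding of regulatory sequences.
#
# Each base maps to a 4-bit block, A = {1,0,0,0}, G = {0,1,0,0},
# C = {0,0,1,0}, T = {0,0,0,1}, concatenated base-major, so an L-nt sequence
# becomes a 0/1 vector of length 4L (224 nt -> 896, the network input width).

#' Encode a nucleotide sequence as a one-hot bit vector
#'
#' Converts a DNA string over {A,C,G,T} into the fixed binary representation
#' used as network input: per base a 4-bit block in the order (A, G, C, T),
#' blocks concatenated in sequence order. `"ATTGCC"` encodes to
#' `1,0,0,0, 0,0,0,1, 0,0,0,1, 0,1,0,0, 0,0,1,0, 0,0,1,0`.
#'
#' @param seq single nucleotide string; case-insensitive. IUPAC ambiguity
#'   codes, gaps and any other characters are rejected (the encoding rule is
#'   defined for A/G/C/T only).
#' @return integer vector of 0/1 of length `4 * nchar(seq)`.
#' @seealso [decode_vector()], [encode_library()]
#' @export
#' @examples
#' encode_sequence("ATTGCC")
encode_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    fail("`seq` must be a single character string")
  seq <- toupper(seq)
  if (nchar(seq) == 0L) fail("empty sequence cannot be encoded")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, BASES)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    fail("invalid character '%s' at position %d: only A/C/G/T are encodable",
         chars[bad], bad)
  }
  L <- length(idx)
  bits <- integer(4L * L)
  bits[4L * (seq_len(L) - 1L) + idx] <- 1L
  bits
}

#' Encode a set of equal-length sequences as a design matrix
#'
#' Row i of the result is `encode_sequence(seqs[i])`; row order is preserved.
#' All sequences must share one length L, giving an n x 4L binary matrix.
#'
#' @param seqs character vector of nucleotide strings, optionally named.
#' @return integer matrix (n x 4L) with rownames taken from `names(seqs)`.
#' @export
#' @examples
#' encode_library(c("AA", "AC"))
encode_library <- function(seqs) {
  if (length(seqs) == 0L) fail("empty sequence set cannot be encoded")
  if (!is.character(seqs)) fail("`seqs` must be a character vector")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    off <- which(lens != lens[1L])[1L]
    lab <- if (!is.null(names(seqs))) names(seqs)[off] else as.character(off)
    fail("sequences must share one length: record '%s' has %d nt, expected %d",
         lab, lens[off], lens[1L])
  }
  X <- t(vapply(seqs, encode_sequence, integer(4L * lens[1L]), USE.NAMES = FALSE))
  rownames(X) <- names(seqs)
  X
}

#' Decode a one-hot bit vector back to a nucleotide string
#'
#' Inverse of [encode_sequence()]: each consecutive 4-bit block must be
#' one-hot over (A, G, C, T).
#'
#' @param bits numeric/integer vector of 0s and 1s, length divisible by 4.
#' @return single nucleotide string.
#' @export
#' @examples
#' decode_vector(c(1, 0, 0, 0, 0, 0, 0, 1))  # "AT"
decode_vector <- function(bits) {
  if (!is.numeric(bits) || length(bits) == 0L)
    fail("`bits` must be a non-empty numeric vector")
  if (length(bits) %% 4L != 0L)
    fail("bit vector length %d is not divisible by 4", length(bits))
  if (!all(bits %in% c(0, 1))) fail("bit vector must contain only 0s and 1s")
  m <- matrix(as.integer(bits), ncol = 4L, byrow = TRUE)
  ones <- rowSums(m)
  if (any(ones != 1L)) {
    bad <- which(ones != 1L)[1L]
    fail("block %d is not one-hot (contains %d ones)", bad, ones[bad])
  }
  paste(BASES[max.col(m)], collapse = "")
}
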