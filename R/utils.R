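# IUPAC machinery, Phred helpers, reverse complement.
#
# IUPAC codes are manipulated as 4-bit masks (A=1, C=2, G=4, T=8) so that
# merging two ambiguous bases is a bitwise OR. The 256-slot lookup tables are
# indexed by raw byte value, which keeps the per-position merge vectorised.

.iupac_bits <- local({
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L,
             R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
             B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
  tab <- integer(256)
  tab[utf8ToInt(paste(names(codes), collapse = "")) + 1L] <- unname(codes)
  tab
})

.bits_iupac <- local({
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L,
             R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
             B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
  tab <- raw(16)
  tab[codes + 1L] <- as.raw(utf8ToInt(paste(names(codes), collapse = "")))
  tab
})

#' Expand an IUPAC nucleotide code to its concrete bases
#'
#' @param code Single IUPAC character (e.g. `"K"`).
#' @return Character vector of the concrete bases the code stands for
#'   (`"K"` -> `c("G","T")`).
#' @export
#' @examples
#' iupac_expand("K")
#' iupac_expand("N")
iupac_expand <- function(code) {
  bits <- .iupac_bits[utf8ToInt(toupper(code)) + 1L]
  if (bits == 0L) stop("not an IUPAC nucleotide code: ", code, call. = FALSE)
  c("A", "C", "G", "T")[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
}

#' IUPAC code for a set of bases
#'
#' @param bases Character vector of concrete bases and/or IUPAC codes.
#' @return The single IUPAC character covering the union of all base sets.
#' @export
#' @examples
#' iupac_union(c("G", "T"))  # "K"
iupac_union <- function(bases) {
  bits <- .iupac_bits[utf8ToInt(paste(toupper(bases), collapse = "")) + 1L]
  if (any(bits == 0L)) stop("not IUPAC nucleotide codes: ",
                            paste(bases, collapse = ","), call. = FALSE)
  rawToChar(.bits_iupac[Reduce(bitwOr, bits) + 1L])
}

# vectorised union on raw byte vectors (internal hot path)
iupac_union_raw <- function(a, b) {
  bits <- bitwOr(.iupac_bits[as.integer(a) + 1L], .iupac_bits[as.integer(b) + 1L])
  .bits_iupac[bits + 1L]
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Error probability implied by a Phred score
#'
#' The Phred scale defines the probability that a base call is wrong as
#' \eqn{10^{-Q/10}}; Q30 corresponds to 99.9\% base accuracy.
#'
#' @param q Numeric vector of Phred scores (>= 0).
#' @return Error probabilities in `[0, 1]`.
#' @export
#' @examples
#' phred_error(30)   # 0.001
#' phred_error(32)   # ~6.31e-4
phred_error <- function(q) {
  stopifnot(all(q >= 0))
  10^(-q / 10)
}

# Phred+33 encode/decode -------------------------------------------------

phred_decode <- function(qual_string) utf8ToInt(qual_string) - 33L

phred_encode <- function(q) intToUtf8(pmin(q, 93L) + 33L)

# Median with the lower-middle convention for even-length inputs: the paper's
# filter does not define the even case, so the conservative (lower) middle
# value is used throughout.
median_lower <- function(x) sort(x)[ceiling(length(x) / 2)]

random_dna <- function(n_strings, len) {
  vapply(seq_len(n_strings), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
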