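# FASTQ / FASTA / TSV I/O. All sequence I/O goes through Biostrings; the
# tibble representation (one row per read) is the package's working format.

#' Read a FASTQ file into a read tibble
#'
#' @param path Path to an uncompressed or gzipped FASTQ file (Sanger
#'   Phred+33 qualities).
#' @param mate Optional mate label (`"R1"` or `"R2"`) attached to every read.
#' @param index Optional index label (e.g. `"i1"`) attached to every read.
#' @return A tibble with columns `id`, `bases`, `quals` (Phred+33 string) and,
#'   if given, `mate` and `index`.
#' @export
read_fastq <- function(path, mate = NULL, index = NULL) {
  # the reader warns about dropping (empty) metadata columns
  xs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  out <- tibble::tibble(
    id = sub("\\s.*$", "", names(xs)),
    bases = unname(as.character(xs)),
    quals = unname(as.character(Biostrings::quality(xs)))
  )
  if (!is.null(mate)) out$mate <- mate
  if (!is.null(index)) out$index <- index
  out
}

#' Write a read tibble to FASTQ
#'
#' @param reads Tibble with columns `id`, `bases`, `quals`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "bases", "quals") %in% names(reads)))
  # QualityScaledDNAStringSet warns about dropping (empty) metadata columns
  xs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$bases),
    Biostrings::PhredQuality(reads$quals)
  ))
  names(xs) <- reads$id
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(xs, path))
  invisible(path)
}

#' Read a single-sequence FASTA reference
#'
#' @param path Path to a FASTA file holding one sequence.
#' @return The sequence as a character scalar, named by its FASTA header.
#' @export
read_reference <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  if (length(xs) != 1)
    stop("expected a single reference sequence, found ", length(xs),
         call. = FALSE)
  setNames(as.character(xs[[1]]), names(xs))
}

#' Write a named set of sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  xs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Write / read a per-cycle error profile as TSV
#'
#' The TSV (`mate`, `cycle`, `pct_mismatch`, `n`) is the exchange format for
#' precomputed profiles, the alternative to raw Phi-X reads.
#'
#' @param profile An error-profile tibble (see [compute_phix_profile()]).
#' @param path File path.
#' @return `write_error_profile()` returns `path` invisibly;
#'   `read_error_profile()` returns the profile tibble.
#' @export
write_error_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_error_profile
#' @export
read_error_profile <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    mate = readr::col_character(),
    cycle = readr::col_integer(),
    pct_mismatch = readr::col_double(),
    n = readr::col_integer()
  ))
}
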