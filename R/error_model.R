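# Error model: per-cycle empirical error rates from Phi-X control reads,
# combined with per-base Phred scores into per-position unreliable flags.
#
# The rationale: reported Phred quality alone is not sufficient to identify
# an error (calibration fails in the early cycles), and the Phi-X-derived
# cycle error rate alone is only a per-cycle aggregate — so a position is
# trusted only if it passes both checks.

#' Flagging thresholds
#'
#' A position is flagged unreliable if its Phred score is below `min_phred`
#' (default 32) OR the Phi-X-measured error rate of its sequencing cycle
#' exceeds `max_cycle_error` percent (default 1).
#'
#' @param min_phred Minimum trusted Phred score.
#' @param max_cycle_error Maximum trusted cycle error rate, in percent.
#' @return A `flag_thresholds` list.
#' @export
flag_thresholds <- function(min_phred = 32L, max_cycle_error = 1) {
  stopifnot(min_phred >= 0, max_cycle_error >= 0)
  structure(list(min_phred = as.integer(min_phred),
                 max_cycle_error = max_cycle_error),
            class = "flag_thresholds")
}

#' Measure the per-cycle error profile from Phi-X control reads
#'
#' Places each control read on the reference at its best ungapped offset
#' (both strands, found via exact k-mer anchors), discards reads whose best
#' placement falls below `min_identity` (non-Phi-X contaminants), and counts
#' mismatches per sequencing cycle. Cycles with no observations are absent
#' from the result, never zero-filled.
#'
#' @param phix_reads Read tibble (`id`, `bases`, `quals`, `mate`).
#' @param reference The control reference sequence (character scalar or the
#'   result of [read_reference()]).
#' @param min_identity Identity cutoff below which a read is excluded
#'   (default 0.7).
#' @param k,anchor_step K-mer anchor length and spacing for placement.
#' @return An `error_profile` tibble: `mate`, `cycle`, `pct_mismatch`, `n`
#'   (aligned bases observed at that cycle), with attribute `n_excluded`.
#' @export
compute_phix_profile <- function(phix_reads, reference, min_identity = 0.7,
                                 k = 16L, anchor_step = 25L) {
  if (nrow(phix_reads) == 0)
    stop("no Phi-X reads supplied; provide control reads or a precomputed ",
         "profile via read_error_profile()", call. = FALSE)
  ref <- unname(reference)
  ref_rc <- revcomp(ref)
  n_excluded <- 0L
  out <- list()
  for (m in unique(phix_reads$mate)) {
    rd <- phix_reads[phix_reads$mate == m, , drop = FALSE]
    pl <- cpp_place_reads(rd$bases, ref, ref_rc, as.integer(k),
                          as.integer(anchor_step))
    identity <- 1 - pl$mismatches / pmax(pl$aligned_len, 1L)
    bad <- is.na(pl$offset) | identity < min_identity
    n_excluded <- n_excluded + sum(bad)
    pl$offset[bad] <- NA_integer_
    max_cycle <- max(nchar(rd$bases))
    cm <- cpp_cycle_mismatches(rd$bases, ref, ref_rc,
                               pl$offset, pl$strand, max_cycle)
    keep <- cm$n > 0
    out[[m]] <- tibble::tibble(
      mate = m,
      cycle = which(keep),
      pct_mismatch = 100 * cm$mismatches[keep] / cm$n[keep],
      n = cm$n[keep]
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("error_profile", class(res))
  res
}

#' Flag unreliable positions of pseudo-reads
#'
#' A position is flagged iff its Phred score is below `min_phred`, OR the
#' error profile at its (mate, cycle) exceeds `max_cycle_error` percent, OR
#' the base is an N / ambiguity code. Cycles absent from the profile are
#' flagged (fail-unsafe), with a single warning.
#'
#' @param pseudo Pseudo-read tibble from [join_pseudo_reads()] or
#'   [merge_overlapping()].
#' @param profile An [compute_phix_profile()] result (or a profile read back
#'   with [read_error_profile()]).
#' @param thresholds A [flag_thresholds()].
#' @return `pseudo` with an added list-column `flags` (logical per position).
#' @export
flag_unreliable <- function(pseudo, profile, thresholds = flag_thresholds()) {
  if (nrow(pseudo) == 0) {
    pseudo$flags <- list()
    return(pseudo)
  }
  lut <- setNames(profile$pct_mismatch,
                  paste0(profile$mate, "_", profile$cycle))
  missing_cycles <- 0L
  cycle_bad <- function(mates, cycles) {
    err <- unname(lut[paste0(mates, "_", cycles)])
    miss <- is.na(err)
    missing_cycles <<- missing_cycles + sum(miss)
    miss | err > thresholds$max_cycle_error
  }
  acgt <- charToRaw("ACGT")
  flags <- vector("list", nrow(pseudo))
  if (pseudo$mode[1] == "scfv") {
    # the (mate, cycle) map is shared within an index: compute it once each
    for (ix in unique(pseudo$index)) {
      rows <- which(pseudo$index == ix)
      cmap <- pseudo_cycle_map(pseudo[rows[1], , drop = FALSE])
      cbad <- cycle_bad(cmap$mate, cmap$cycle)
      for (i in rows) {
        q <- utf8ToInt(pseudo$quals[i]) - 33L
        b <- charToRaw(pseudo$bases[i])
        flags[[i]] <- q < thresholds$min_phred | cbad | !(b %in% acgt)
      }
    }
  } else {
    for (i in seq_len(nrow(pseudo))) {
      mates <- c("R1", "R2")[pseudo$mate_map[[i]]]
      cbad <- cycle_bad(mates, pseudo$cycle_map[[i]])
      q <- utf8ToInt(pseudo$quals[i]) - 33L
      b <- charToRaw(pseudo$bases[i])
      flags[[i]] <- q < thresholds$min_phred | cbad | !(b %in% acgt)
    }
  }
  if (missing_cycles > 0)
    warning(missing_cycles, " position lookups hit cycles absent from the ",
            "error profile; those positions were flagged", call. = FALSE)
  pseudo$flags <- flags
  pseudo
}
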