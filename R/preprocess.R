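# Preprocessing: raw demultiplexed paired FASTQ -> fixed-length pseudo-reads
# (scFv mode) or overlap-merged reads (VH mode).
#
# All functions take and return read tibbles (id, bases, quals, mate, index).
# Reads removed by a step are counted in a "dropped" attribute so the
# pipeline's conservation law (input pairs = kept + sum of drop reasons) can
# be checked.

drop_count <- function(x) attr(x, "dropped") %||% 0L

#' Remove per-index shifter bases from read starts
#'
#' Each index's adapter carries a different number of shifter bases before
#' the insert; they are discarded so reads from all indexes align to the same
#' insert coordinates. Cycle provenance is preserved: position p of a trimmed
#' read corresponds to sequencing cycle p + offset.
#'
#' @param reads Read tibble with `mate` and `index` columns.
#' @param cfg A [run_config()].
#' @return The trimmed tibble. Reads with an unrecognized index are routed
#'   out and counted in attributes `dropped` and `unclassified`.
#' @export
trim_shifter <- function(reads, cfg = run_config()) {
  known <- reads$index %in% names(cfg$index_barcodes)
  out <- reads[known, , drop = FALSE]
  off <- ifelse(out$mate == "R1",
                cfg$shifter_offsets_r1[out$index],
                cfg$shifter_offsets_r2[out$index])
  out$bases <- substr(out$bases, off + 1L, nchar(out$bases))
  out$quals <- substr(out$quals, off + 1L, nchar(out$quals))
  out$shifter_offset <- as.integer(off)
  attr(out, "dropped") <- sum(!known)
  attr(out, "unclassified") <- sum(!known)
  out
}

#' Purge adapter-dimer reads
#'
#' Drops reads whose first bases match an adapter sequence with at most
#' `max_mismatch` mismatches — the minimal dimer heuristic this pipeline
#' uses in place of a general-purpose adapter trimmer.
#'
#' @param reads Read tibble.
#' @param adapter Adapter sequence to screen for (its first `width` bases are
#'   compared against each read start).
#' @param max_mismatch Mismatch tolerance (default 1).
#' @param width Prefix length compared (default 12).
#' @return The surviving reads, with a `dropped` attribute.
#' @export
purge_adapter_dimers <- function(reads, adapter, max_mismatch = 1L,
                                 width = 12L) {
  width <- min(width, nchar(adapter))
  ad <- strsplit(substr(adapter, 1, width), "")[[1]]
  pre <- strsplit(substr(reads$bases, 1, width), "", fixed = TRUE)
  mm <- vapply(pre, function(p) sum(p != ad[seq_along(p)]), integer(1))
  keep <- mm > max_mismatch
  out <- reads[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Filter reads on median Phred quality
#'
#' Keeps a read iff the median of its per-base Phred scores is at least
#' `min_median` (default 32, i.e. base-call accuracy above 99.937%). For
#' even-length quality lists the lower middle value is used — the
#' conservative convention.
#'
#' @param reads Read tibble.
#' @param min_median Median Phred threshold.
#' @return Surviving reads, with a `dropped` attribute.
#' @export
filter_median_quality <- function(reads, min_median = 32L) {
  med <- vapply(reads$quals,
                function(s) median_lower(utf8ToInt(s) - 33L), integer(1),
                USE.NAMES = FALSE)
  keep <- med >= min_median
  out <- reads[keep, , drop = FALSE]
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Trim reads to a fixed length
#'
#' Retains the first `length` bases; shorter reads are dropped and counted.
#'
#' @param reads Read tibble.
#' @param length Target length.
#' @return Trimmed reads, with a `dropped` attribute.
#' @export
trim_fixed <- function(reads, length) {
  keep <- nchar(reads$bases) >= length
  out <- reads[keep, , drop = FALSE]
  out$bases <- substr(out$bases, 1, length)
  out$quals <- substr(out$quals, 1, length)
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Synchronize mate streams, removing orphans
#'
#' Emits only read ids present in both streams, in the order of the first
#' stream (order-stable). Duplicate ids within a stream are an error.
#'
#' @param r1,r2 Read tibbles sharing an `id` key.
#' @return A list `(r1, r2)` of equal-height tibbles in matching id order,
#'   with attributes `orphans_r1` / `orphans_r2`.
#' @export
sync_pairs <- function(r1, r2) {
  if (anyDuplicated(r1$id)) stop("duplicate read ids in R1 stream",
                                 call. = FALSE)
  if (anyDuplicated(r2$id)) stop("duplicate read ids in R2 stream",
                                 call. = FALSE)
  shared <- r1$id[r1$id %in% r2$id]
  out <- list(
    r1 = r1[match(shared, r1$id), , drop = FALSE],
    r2 = r2[match(shared, r2$id), , drop = FALSE]
  )
  attr(out, "orphans_r1") <- nrow(r1) - length(shared)
  attr(out, "orphans_r2") <- nrow(r2) - length(shared)
  out
}

reverse_qual_string <- function(s) {
  vapply(s, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
         USE.NAMES = FALSE)
}

#' Join trimmed mates into fixed-length pseudo-reads (scFv mode)
#'
#' Concatenates the forward read with the reverse complement of the reverse
#' read: bases `r1 + revcomp(r2)`, qualities `r1 + reverse(r2)`. With the
#' default 320 + 220 trim this yields 540-nt pseudo-reads. Cycle provenance:
#' position p <= trim_r1 maps to R1 cycle p + shifter offset; position
#' p > trim_r1 maps to R2 cycle offset + trim_r2 - (p - trim_r1) + 1
#' (reverse-complementing reverses cycle order, so the last sequenced R2 base
#' lands first).
#'
#' @param r1,r2 Synchronized, trimmed read tibbles (equal heights, matching
#'   ids).
#' @param cfg A [run_config()] (supplies the expected trim lengths).
#' @return A pseudo-read tibble: `id`, `index`, `bases`, `quals`,
#'   `r1_offset`, `r2_offset`, `r1_len`, `r2_len`, `mode = "scfv"`.
#' @export
join_pseudo_reads <- function(r1, r2, cfg = run_config()) {
  stopifnot(nrow(r1) == nrow(r2), all(r1$id == r2$id))
  if (nrow(r1) > 0 && (any(nchar(r1$bases) != cfg$trim_r1) ||
                       any(nchar(r2$bases) != cfg$trim_r2)))
    stop("reads not trimmed to the configured lengths (",
         cfg$trim_r1, "/", cfg$trim_r2, ")", call. = FALSE)
  tibble::tibble(
    id = r1$id,
    index = r1$index %||% NA_character_,
    bases = paste0(r1$bases, revcomp(r2$bases)),
    quals = paste0(r1$quals, reverse_qual_string(r2$quals)),
    r1_offset = as.integer(r1$shifter_offset %||% 0L),
    r2_offset = as.integer(r2$shifter_offset %||% 0L),
    r1_len = cfg$trim_r1,
    r2_len = cfg$trim_r2,
    mode = "scfv"
  )
}

#' Merge overlapping mates into full-length reads (VH mode)
#'
#' For short constructs whose mates overlap, finds the best-scoring ungapped
#' offset (score = matches - mismatches) between the forward read and the
#' reverse-complemented reverse read. In the overlap, concordant positions
#' keep the base with the maximum of the two qualities; discordant positions
#' take the higher-quality base with its quality; on a quality tie the
#' forward base is kept and the position gets the minimum quality, so it is
#' likely flagged downstream. Pairs with no acceptable overlap are discarded
#' and counted.
#'
#' @param r1,r2 Synchronized read tibbles (shifter-trimmed).
#' @param min_overlap Minimum acceptable overlap (default 30 nt).
#' @param max_mismatch_rate Maximum mismatch fraction in the best overlap
#'   (default 0.1); beyond it the pair is discarded.
#' @return A pseudo-read tibble with `id`, `index`, `bases`, `quals`,
#'   `mode = "vh"` and list-columns `mate_map` (1 = R1, 2 = R2) and
#'   `cycle_map` (original sequencing cycle per position). Attribute
#'   `dropped` counts discarded pairs.
#' @export
merge_overlapping <- function(r1, r2, min_overlap = 30L,
                              max_mismatch_rate = 0.1) {
  stopifnot(nrow(r1) == nrow(r2), all(r1$id == r2$id))
  n <- nrow(r1)
  b_all <- revcomp(r2$bases)
  out_bases <- character(n)
  out_quals <- character(n)
  mate_map <- vector("list", n)
  cycle_map <- vector("list", n)
  ok <- logical(n)
  k1 <- as.integer(r1$shifter_offset %||% rep(0L, n))
  k2 <- as.integer(r2$shifter_offset %||% rep(0L, n))

  for (i in seq_len(n)) {
    a <- r1$bases[i]; b <- b_all[i]
    na <- nchar(a); nb <- nchar(b)
    hit <- cpp_best_overlap(a, b, as.integer(min_overlap))
    if (hit$offset < 0 || hit$mismatches / hit$overlap_len > max_mismatch_rate)
      next
    off <- hit$offset
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    qa <- utf8ToInt(r1$quals[i]) - 33L
    qb <- rev(utf8ToInt(r2$quals[i]) - 33L)  # b coordinates
    mlen <- max(na, off + nb)
    bases <- character(mlen); qual <- integer(mlen)
    mate <- integer(mlen); cyc <- integer(mlen)
    # forward-only head
    if (off > 0) {
      bases[1:off] <- av[1:off]; qual[1:off] <- qa[1:off]
      mate[1:off] <- 1L; cyc[1:off] <- k1[i] + 1:off
    }
    # overlap
    ov_end <- min(na, off + nb)
    p <- (off + 1L):ov_end
    j <- p - off
    conc <- av[p] == bv[j]
    use_b <- (!conc & qb[j] > qa[p]) | (conc & qb[j] > qa[p])
    bases[p] <- ifelse(use_b, bv[j], av[p])
    qual[p] <- ifelse(conc, pmax(qa[p], qb[j]),
                      ifelse(qb[j] > qa[p], qb[j],
                             ifelse(qa[p] > qb[j], qa[p],
                                    pmin(qa[p], qb[j]))))
    mate[p] <- ifelse(use_b, 2L, 1L)
    cyc[p] <- ifelse(use_b, k2[i] + (nb - j + 1L), k1[i] + p)
    # reverse-only tail
    if (off + nb > na) {
      pt <- (na + 1L):(off + nb); jt <- pt - off
      bases[pt] <- bv[jt]; qual[pt] <- qb[jt]
      mate[pt] <- 2L; cyc[pt] <- k2[i] + (nb - jt + 1L)
    } else if (na > off + nb) {
      pt <- (off + nb + 1L):na
      bases[pt] <- av[pt]; qual[pt] <- qa[pt]
      mate[pt] <- 1L; cyc[pt] <- k1[i] + pt
    }
    out_bases[i] <- paste(bases, collapse = "")
    out_quals[i] <- intToUtf8(pmin(qual, 93L) + 33L)
    mate_map[[i]] <- mate
    cycle_map[[i]] <- cyc
    ok[i] <- TRUE
  }
  out <- tibble::tibble(
    id = r1$id[ok],
    index = (r1$index %||% rep(NA_character_, n))[ok],
    bases = out_bases[ok],
    quals = out_quals[ok],
    mate_map = mate_map[ok],
    cycle_map = cycle_map[ok],
    mode = "vh"
  )
  attr(out, "dropped") <- sum(!ok)
  out
}

#' Run the full preprocessing pipeline
#'
#' scFv mode: shifter removal, optional adapter-dimer purge, median-quality
#' filter, fixed-length trim, orphan removal, pseudo-read joining.
#' VH mode: shifter removal, optional purge, median-quality filter, orphan
#' removal, overlap merging.
#'
#' @param r1,r2 Raw demultiplexed read tibbles (with `mate`, `index`).
#' @param cfg A [run_config()].
#' @param mode `"scfv"` or `"vh"`.
#' @param adapter Optional adapter sequence for the dimer purge.
#' @param min_overlap,max_mismatch_rate VH-mode merge parameters.
#' @return A list: `pseudo` (pseudo-read tibble) and `log` (tibble of stage
#'   counts satisfying input = kept + sum of drops).
#' @export
preprocess_run <- function(r1, r2, cfg = run_config(),
                           mode = c("scfv", "vh"), adapter = NULL,
                           min_overlap = 30L, max_mismatch_rate = 0.1) {
  mode <- match.arg(mode)
  log <- list(input_pairs = nrow(r1))

  r1 <- trim_shifter(r1, cfg); r2 <- trim_shifter(r2, cfg)
  log$unclassified_r1 <- drop_count(r1)
  log$unclassified_r2 <- drop_count(r2)

  if (!is.null(adapter)) {
    r1 <- purge_adapter_dimers(r1, adapter)
    r2 <- purge_adapter_dimers(r2, adapter)
    log$adapter_dimers_r1 <- drop_count(r1)
    log$adapter_dimers_r2 <- drop_count(r2)
  }

  r1 <- filter_median_quality(r1, cfg$min_median_phred)
  r2 <- filter_median_quality(r2, cfg$min_median_phred)
  log$low_quality_r1 <- drop_count(r1)
  log$low_quality_r2 <- drop_count(r2)

  if (mode == "scfv") {
    r1 <- trim_fixed(r1, cfg$trim_r1)
    r2 <- trim_fixed(r2, cfg$trim_r2)
    log$too_short_r1 <- drop_count(r1)
    log$too_short_r2 <- drop_count(r2)
  }

  pairs <- sync_pairs(r1, r2)
  log$orphans_r1 <- attr(pairs, "orphans_r1")
  log$orphans_r2 <- attr(pairs, "orphans_r2")

  if (mode == "scfv") {
    pseudo <- join_pseudo_reads(pairs$r1, pairs$r2, cfg)
  } else {
    pseudo <- merge_overlapping(pairs$r1, pairs$r2, min_overlap,
                                max_mismatch_rate)
    log$merge_failed <- drop_count(pseudo)
  }
  log$kept_pairs <- nrow(pseudo)

  list(pseudo = pseudo,
       log = tibble::tibble(stage = names(log),
                            n = unlist(log, use.names = FALSE)))
}

#' Per-position cycle provenance of a pseudo-read
#'
#' Resolves, for one pseudo-read row, which mate and original sequencing
#' cycle each position came from. For scFv pseudo-reads this is computed from
#' the join geometry; VH reads carry explicit maps from the merge step.
#'
#' @param pseudo One-row slice of a pseudo-read tibble.
#' @return A tibble `pos`, `mate` (`"R1"`/`"R2"`), `cycle`.
#' @export
pseudo_cycle_map <- function(pseudo) {
  stopifnot(nrow(pseudo) == 1)
  if (pseudo$mode == "vh") {
    mm <- pseudo$mate_map[[1]]
    return(tibble::tibble(pos = seq_along(mm),
                          mate = c("R1", "R2")[mm],
                          cycle = pseudo$cycle_map[[1]]))
  }
  l1 <- pseudo$r1_len; l2 <- pseudo$r2_len
  tibble::tibble(
    pos = seq_len(l1 + l2),
    mate = rep(c("R1", "R2"), c(l1, l2)),
    cycle = c(pseudo$r1_offset + seq_len(l1),
              pseudo$r2_offset + rev(seq_len(l2)))
  )
}
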