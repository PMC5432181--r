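# DEAL: quality-aware sequence-identity collapse.
#
# Step 1 ("seeding") partitions reads by exact identity of a short seed taken
# from the CDR3 region(s); step 2 compares each read against the existing
# cluster consensi of its seed group, position by position, with flag-aware
# merge rules:
#   (i)  both sides unflagged and bases differ        -> MISMATCH (no merge)
#   (ii) exactly one side flagged                     -> the unflagged side's
#        base is kept and the position is unflagged
#   (iii) both sides flagged                          -> IUPAC code of the
#        union of the two base sets, position stays flagged
# The total number of clusters is the sample complexity.

#' Seed specification
#'
#' Intervals are 1-based, end-exclusive: the scFv default
#' `(280,300) + (470,490)` takes two 20-nt stretches (one per CDR3) and
#' concatenates them into a 40-nt seed; the VH default takes `(280,300)`
#' only.
#'
#' @param regions List of `c(start, end)` pairs, ordered, non-overlapping.
#' @return A `seed_spec` list.
#' @export
seed_spec <- function(regions = list(c(280L, 300L), c(470L, 490L))) {
  if (is.numeric(regions)) regions <- list(regions)
  starts <- vapply(regions, `[`, numeric(1), 1)
  ends <- vapply(regions, `[`, numeric(1), 2)
  stopifnot(all(starts >= 1), all(ends > starts),
            all(diff(as.vector(rbind(starts, ends))) >= 0))
  structure(list(regions = lapply(regions, as.integer)), class = "seed_spec")
}

#' @rdname seed_spec
#' @export
seed_spec_vh <- function() seed_spec(list(c(280L, 300L)))

#' Extract the seed of each pseudo-read
#'
#' Concatenates the configured region substrings in order. Reads too short to
#' cover all regions get `NA` (they are excluded from clustering and
#' counted).
#'
#' @param pseudo Pseudo-read tibble (or any tibble with a `bases` column).
#' @param spec A [seed_spec()].
#' @return Character vector of seeds, `NA` for short reads.
#' @export
extract_seed <- function(pseudo, spec = seed_spec()) {
  need <- max(vapply(spec$regions, `[`, integer(1), 2)) - 1L
  seeds <- rep("", nrow(pseudo))
  for (r in spec$regions) {
    seeds <- paste0(seeds, substr(pseudo$bases, r[1], r[2] - 1L))
  }
  seeds[nchar(pseudo$bases) < need] <- NA_character_
  seeds
}

#' Partition reads into seed groups
#'
#' Exact-identity partition on the seed string. The group count is the seed
#' complexity.
#'
#' @param pseudo Pseudo-read tibble.
#' @param spec A [seed_spec()].
#' @return `pseudo` with a `seed` column added, short reads removed (counted
#'   in attribute `dropped_short`).
#' @export
group_by_seed <- function(pseudo, spec = seed_spec()) {
  seeds <- extract_seed(pseudo, spec)
  out <- pseudo[!is.na(seeds), , drop = FALSE]
  out$seed <- seeds[!is.na(seeds)]
  attr(out, "dropped_short") <- sum(is.na(seeds))
  out
}

#' Flag-aware binary comparison of a read against a cluster consensus
#'
#' Applies the three merge scenarios position by position. Length mismatch is
#' an error for direct calls; [run_deal()] in variable-length (VH) mode never
#' compares different lengths.
#'
#' @param cons Consensus bases (character scalar, IUPAC alphabet).
#' @param cons_flags Logical vector of consensus flags.
#' @param read Read bases (character scalar).
#' @param read_flags Logical vector of read flags.
#' @return `NULL` on MISMATCH; otherwise a list `(bases, flags)` of the
#'   merged consensus.
#' @export
merge_pair <- function(cons, cons_flags, read, read_flags) {
  a <- charToRaw(cons); b <- charToRaw(read)
  if (length(a) != length(b))
    stop("merge_pair requires equal-length sequences", call. = FALSE)
  .merge_pair_raw(a, cons_flags, b, read_flags, as_strings = TRUE)
}

.merge_pair_raw <- function(a, af, b, bf, as_strings = FALSE) {
  differ <- a != b
  if (any(differ & !af & !bf)) return(NULL)
  out <- a
  out_f <- af
  # (ii) exactly one side flagged: unflagged side's base, flag cleared
  only_a <- af & !bf
  if (any(only_a)) { out[only_a] <- b[only_a]; out_f[only_a] <- FALSE }
  # consensus unflagged & read flagged: consensus base stands, stays unflagged
  # (iii) both flagged: IUPAC union, stays flagged
  both <- af & bf
  if (any(both)) out[both] <- iupac_union_raw(a[both], b[both])
  if (as_strings) list(bases = rawToChar(out), flags = out_f)
  else list(bases = out, flags = out_f)
}

# Greedy sequential clustering of one seed group (raw vectors + flag lists).
# Returns list of clusters: list(bases=raw, flags=logical, members=int ids).
.cluster_group_raw <- function(braw, flags, ids) {
  clusters <- list()
  lens <- lengths(braw)
  for (i in seq_along(braw)) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (length(cl$bases) != lens[i]) next
      m <- .merge_pair_raw(cl$bases, cl$flags, braw[[i]], flags[[i]])
      if (!is.null(m)) {
        clusters[[ci]] <- list(bases = m$bases, flags = m$flags,
                               members = c(cl$members, ids[i]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <-
        list(bases = braw[[i]], flags = flags[[i]], members = ids[i])
    }
  }
  clusters
}

#' Cluster one seed group by flag-aware identity collapse
#'
#' Greedy sequential pass in input order: each read is tried against the
#' existing clusters in creation order, joins the first match, otherwise
#' founds a new cluster. Exposed mainly for testing; [run_deal()] drives it
#' over all groups.
#'
#' @param bases Character vector of equal-seed read sequences, in input
#'   order.
#' @param flags List of logical flag vectors, parallel to `bases`.
#' @return Tibble: `consensus`, `flags` (list), `cardinality`, `members`
#'   (list of input indices).
#' @export
cluster_group <- function(bases, flags) {
  cl <- .cluster_group_raw(lapply(bases, charToRaw), flags,
                           seq_along(bases))
  tibble::tibble(
    consensus = vapply(cl, function(x) rawToChar(x$bases), character(1)),
    flags = lapply(cl, `[[`, "flags"),
    cardinality = vapply(cl, function(x) length(x$members), integer(1)),
    members = lapply(cl, `[[`, "members")
  )
}

#' Run the DEAL clustering on flagged pseudo-reads
#'
#' Seeds, groups and clusters all reads; the total cluster count is the
#' sample complexity. Input order is preserved from the tibble row order and
#' is part of the contract (greedy first-match assignment is
#' order-dependent).
#'
#' @param pseudo Pseudo-read tibble carrying a `flags` list-column (from
#'   [flag_unreliable()]). If `flags` is absent, all positions are treated as
#'   reliable and DEAL degenerates to exact deduplication.
#' @param spec A [seed_spec()].
#' @return A `deal_result` list: `clusters` (tibble `cluster_id`, `seed`,
#'   `consensus`, `flags`, `cardinality`, `members`), `complexity` (total
#'   cluster count), `seed_complexity` (seed group count), `n_reads`,
#'   `dropped_short`, and `group_sizes`.
#' @export
run_deal <- function(pseudo, spec = seed_spec()) {
  if (nrow(pseudo) == 0) {
    warning("no input reads; complexity is 0", call. = FALSE)
    return(structure(list(
      clusters = tibble::tibble(cluster_id = integer(0), seed = character(0),
                                consensus = character(0), flags = list(),
                                cardinality = integer(0), members = list()),
      complexity = 0L, seed_complexity = 0L, n_reads = 0L,
      dropped_short = 0L, group_sizes = integer(0)
    ), class = "deal_result"))
  }
  if (!"flags" %in% names(pseudo)) {
    pseudo$flags <- lapply(nchar(pseudo$bases), function(L) rep(FALSE, L))
  }
  grouped <- group_by_seed(pseudo, spec)
  dropped_short <- attr(grouped, "dropped_short")
  braw <- lapply(grouped$bases, charToRaw)
  groups <- split(seq_len(nrow(grouped)), factor(grouped$seed,
                                                 levels = unique(grouped$seed)))
  res <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    cl <- .cluster_group_raw(braw[rows], grouped$flags[rows], rows)
    res[[g]] <- cl
  }
  all_cl <- unlist(res, recursive = FALSE)
  clusters <- tibble::tibble(
    cluster_id = seq_along(all_cl),
    seed = rep(names(groups), vapply(res, length, integer(1))),
    consensus = vapply(all_cl, function(x) rawToChar(x$bases), character(1)),
    flags = lapply(all_cl, `[[`, "flags"),
    cardinality = vapply(all_cl, function(x) length(x$members), integer(1)),
    members = lapply(all_cl, function(x) grouped$id[x$members])
  )
  structure(list(
    clusters = clusters,
    complexity = nrow(clusters),
    seed_complexity = length(groups),
    n_reads = nrow(grouped),
    dropped_short = dropped_short,
    group_sizes = unname(lengths(groups))
  ), class = "deal_result")
}

#' @export
print.deal_result <- function(x, ...) {
  cat("DEAL result\n")
  cat("  reads clustered:   ", x$n_reads, "\n")
  cat("  seed complexity:   ", x$seed_complexity, "\n")
  cat("  sample complexity: ", x$complexity, " clusters\n")
  cat("  minimal complexity:", minimal_complexity(cardinality_histogram(x)),
      " (cardinality >= 2)\n")
  invisible(x)
}
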