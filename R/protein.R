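# Protein-level diversity: frame classification, stop-codon detection under
# IUPAC ambiguity, in-silico translation of cluster consensi, synonym
# collapse, and functional-complexity ranges.
#
# Frame class comes from sequence length alone: the construct geometry fixes
# the first codon base at anchor_offset + 1, so (length - anchor_offset)
# mod 3 of 0/1/2 maps to in_frame/+1/+2. Stop codons are scanned only inside
# the CDS (after the 5' anchor, before the terminal anchor): a codon is a
# "definite" stop if every expansion of its ambiguity codes is a stop, a
# "possible" stop if some but not all expansions are.

.codon_env <- new.env(parent = emptyenv())

codon_info <- function(codons) {
  uc <- unique(codons)
  known <- vapply(uc, function(cd) !is.null(.codon_env[[cd]]), logical(1))
  for (cd in uc[!known]) {
    sets <- lapply(strsplit(cd, "")[[1]], function(b) {
      if (b %in% c("A", "C", "G", "T")) b else iupac_expand(b)
    })
    ex <- expand.grid(sets, stringsAsFactors = FALSE)
    aas <- unname(Biostrings::GENETIC_CODE[paste0(ex[[1]], ex[[2]], ex[[3]])])
    n_stop <- sum(aas == "*")
    status <- if (n_stop == length(aas)) "definite"
              else if (n_stop > 0) "possible" else "none"
    # translate with maximum information: if all non-stop expansions agree on
    # one residue, that residue is certain whenever the codon is not a stop
    aa_set <- unique(aas[aas != "*"])
    aa <- if (status == "definite") "*"
          else if (length(aa_set) == 1) aa_set
          else "X"
    .codon_env[[cd]] <- list(status = status, aa = aa)
  }
  lapply(codons, function(cd) .codon_env[[cd]])
}

#' Classify reading frame from sequence length
#'
#' @param nt_length Integer vector of sequence lengths.
#' @param anchor_offset Bases before the first codon (from the construct
#'   geometry; the simulator records 10).
#' @return Factor-like character vector: `"in_frame"`, `"plus1"`, `"plus2"`.
#' @export
frame_classify <- function(nt_length, anchor_offset = 10L) {
  if (any(nt_length <= anchor_offset))
    stop("sequences shorter than the anchor offset", call. = FALSE)
  c("in_frame", "plus1", "plus2")[(nt_length - anchor_offset) %% 3L + 1L]
}

#' Scan a consensus for stop codons under IUPAC ambiguity
#'
#' @param consensus Nucleotide string (IUPAC alphabet).
#' @param anchor_offset Bases before codon 1.
#' @param cds_tail Terminal-anchor length excluded from the scan.
#' @return `"definite"` if some codon's every expansion is a stop,
#'   `"possible"` if some codon has at least one stop and one non-stop
#'   expansion, else `"none"`.
#' @export
scan_stops <- function(consensus, anchor_offset = 10L, cds_tail = 8L) {
  cds <- substr(consensus, anchor_offset + 1L, nchar(consensus) - cds_tail)
  L <- nchar(cds)
  if (L < 3) return("none")
  starts <- seq(1L, L - 2L, by = 3L)
  info <- codon_info(substring(cds, starts, starts + 2L))
  status <- vapply(info, `[[`, character(1), "status")
  if (any(status == "definite")) "definite"
  else if (any(status == "possible")) "possible"
  else "none"
}

translate_cds <- function(consensus, anchor_offset = 10L, cds_tail = 8L) {
  cds <- substr(consensus, anchor_offset + 1L, nchar(consensus) - cds_tail)
  L <- nchar(cds)
  starts <- seq(1L, L - 2L, by = 3L)
  info <- codon_info(substring(cds, starts, starts + 2L))
  paste(vapply(info, `[[`, character(1), "aa"), collapse = "")
}

#' Translate DEAL clusters and classify frame / stop status
#'
#' Adds per-cluster length, frame class, stop status (in-frame clusters
#' only), and the deduced amino-acid sequence of the CDS, with `X` at codons
#' whose ambiguity expansions disagree at the amino-acid level.
#'
#' @param clusters Clusters tibble from a `deal_result`.
#' @param anchor_offset,cds_tail Construct geometry (see [frame_classify()]
#'   and [scan_stops()]).
#' @return The tibble with columns `nt_length`, `frame_class`, `stop_status`,
#'   `aa` added (`NA` for out-of-frame clusters).
#' @export
translate_clusters <- function(clusters, anchor_offset = 10L, cds_tail = 8L) {
  out <- clusters
  out$nt_length <- nchar(out$consensus)
  out$frame_class <- frame_classify(out$nt_length, anchor_offset)
  inf <- out$frame_class == "in_frame"
  out$stop_status <- NA_character_
  out$aa <- NA_character_
  out$stop_status[inf] <- vapply(out$consensus[inf], scan_stops,
                                 character(1), anchor_offset, cds_tail,
                                 USE.NAMES = FALSE)
  out$aa[inf] <- vapply(out$consensus[inf], translate_cds, character(1),
                        anchor_offset, cds_tail, USE.NAMES = FALSE)
  out
}

# Greedy X-wildcard grouping of amino-acid strings (first-match, input
# order). Two strings match iff equal length and at every position the
# residues agree or either is X. Returns the group index per input.
.group_aa_wildcard <- function(aa, strict = FALSE) {
  n <- length(aa)
  group <- integer(n)
  if (strict || !any(grepl("X", aa, fixed = TRUE))) {
    return(match(aa, unique(aa)))
  }
  has_x <- grepl("X", aa, fixed = TRUE)
  reps <- character(0)     # group representative strings
  reps_raw <- list()
  exact <- new.env(parent = emptyenv())  # X-free rep -> group id
  for (i in seq_len(n)) {
    if (!has_x[i] && !is.null(exact[[aa[i]]])) {
      group[i] <- exact[[aa[i]]]
      next
    }
    placed <- FALSE
    ri <- charToRaw(aa[i])
    if (has_x[i]) {
      xr <- charToRaw("X")
      st <- charToRaw("*")
      for (g in seq_along(reps)) {
        rg <- reps_raw[[g]]
        if (length(rg) != length(ri)) next
        # X stands for an unresolved residue, never for a stop
        ok <- all(rg == ri | (rg == xr & ri != st) | (ri == xr & rg != st))
        if (ok) { group[i] <- g; placed <- TRUE; break }
      }
    }
    if (!placed) {
      g <- length(reps) + 1L
      reps[g] <- aa[i]
      reps_raw[[g]] <- ri
      if (!has_x[i]) exact[[aa[i]]] <- g
      group[i] <- g
    }
  }
  group
}

#' Protein-level complexity report
#'
#' Aggregates synonymous nucleotide clusters (identical deduced amino-acid
#' sequences, `X` matching any single residue unless `strict`), and reports
#' protein complexity with functional ranges. The functional upper bound
#' excludes only definite stop codons; the lower bound also excludes
#' possible (ambiguity-covered) stops. Protein-cluster cardinality is the
#' total read count of its member nucleotide clusters.
#'
#' @param translated A [translate_clusters()] result.
#' @param strict If `TRUE`, group by exact amino-acid identity (no X
#'   wildcard).
#' @return A `protein_report` list: `protein_clusters` (tibble), `summary`
#'   (one-row tibble with the eight report columns), and the fractions used.
#' @export
protein_clusters <- function(translated, strict = FALSE) {
  total_reads <- sum(translated$cardinality)
  inf <- translated[translated$frame_class == "in_frame", , drop = FALSE]
  in_frame_fraction <- sum(inf$cardinality) / max(total_reads, 1L)

  grp <- .group_aa_wildcard(inf$aa, strict = strict)
  pc <- inf |>
    dplyr::mutate(protein_group = grp) |>
    dplyr::group_by(.data$protein_group) |>
    dplyr::summarise(
      aa = dplyr::first(.data$aa),
      cardinality = sum(.data$cardinality),
      n_nt_clusters = dplyr::n(),
      stop_status = dplyr::case_when(
        any(.data$stop_status == "definite") ~ "definite",
        any(.data$stop_status == "possible") ~ "possible",
        .default = "none"
      ),
      .groups = "drop"
    )

  n_prot <- nrow(pc)
  no_def <- pc$stop_status != "definite"
  no_any <- pc$stop_status == "none"
  min_mask <- pc$cardinality >= 2L

  # read-weighted stop fractions over in-frame sequences
  w <- inf$cardinality / max(sum(inf$cardinality), 1L)
  frac_def_stop <- sum(w[inf$stop_status == "definite"])
  frac_any_stop <- sum(w[inf$stop_status != "none"])

  summary <- tibble::tibble(
    total_reads = total_reads,
    pct_in_frame = 100 * in_frame_fraction,
    pct_no_stop_upper = 100 * (1 - frac_def_stop),
    pct_no_stop_lower = 100 * (1 - frac_any_stop),
    pct_full_cds_upper = 100 * in_frame_fraction * (1 - frac_def_stop),
    pct_full_cds_lower = 100 * in_frame_fraction * (1 - frac_any_stop),
    protein_complexity = n_prot,
    functional_complexity_upper = sum(no_def),
    functional_complexity_lower = sum(no_any),
    minimal_protein_complexity = sum(min_mask),
    minimal_functional_upper = sum(min_mask & no_def),
    minimal_functional_lower = sum(min_mask & no_any)
  )
  structure(list(
    protein_clusters = pc,
    summary = summary,
    in_frame_fraction = in_frame_fraction,
    definite_stop_fraction = frac_def_stop,
    any_stop_fraction = frac_any_stop
  ), class = "protein_report")
}

#' @export
print.protein_report <- function(x, ...) {
  s <- x$summary
  cat("Protein complexity report\n")
  cat(sprintf("  in-frame: %.2f%% of reads\n", s$pct_in_frame))
  cat(sprintf("  without stop codons: %.1f-%.1f%%\n",
              s$pct_no_stop_lower, s$pct_no_stop_upper))
  cat(sprintf("  full-length CDS: %.1f-%.1f%%\n",
              s$pct_full_cds_lower, s$pct_full_cds_upper))
  cat(sprintf("  protein complexity: %d (functional %d-%d)\n",
              s$protein_complexity, s$functional_complexity_lower,
              s$functional_complexity_upper))
  cat(sprintf("  minimal protein complexity: %d (functional %d-%d)\n",
              s$minimal_protein_complexity, s$minimal_functional_lower,
              s$minimal_functional_upper))
  f <- s$functional_complexity_lower / max(s$protein_complexity, 1L)
  cat(sprintf(paste0("  expected two-chain (scFv) functional fraction, ",
                     "independence assumption: %.1f%%\n"),
              100 * scfv_functional_expectation(f)))
  invisible(x)
}

#' Expected two-chain functional fraction under independence
#'
#' If both chains of an scFv independently have per-chain functional
#' fraction `f`, the expected fraction of constructs with both chains
#' functional is `f^2`. Reported as an explicit independence assumption.
#'
#' @param per_chain_fraction Per-chain functional fraction in `[0, 1]`.
#' @return The product `per_chain_fraction^2`.
#' @export
scfv_functional_expectation <- function(per_chain_fraction) {
  stopifnot(per_chain_fraction >= 0, per_chain_fraction <= 1)
  per_chain_fraction^2
}
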