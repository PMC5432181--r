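# Synthetic antibody-library sequencing simulator.
#
# The generator builds a repertoire of distinct constructs with a fixed
# scaffold geometry (restriction-site anchor, forward primer site, constant
# framework, hypervariable CDR3 stretch(es), reverse primer site, terminal
# anchor), then simulates an Illumina paired-end run over it: per-index
# shifter bases, cycle-indexed substitution errors, imperfectly calibrated
# Phred reporting, optional backbone contamination and a Phi-X-like spike-in.
# Every read carries truth (source sequence, injected error positions).

# Construct geometry (1-based construct coordinates):
#   anchor5 (10 nt) | fwd primer (24) | FR-H (236) | CDR-H3 (variable) |
#   FR4-H (36) | [scfv only: linker (45) | FR-L (295) | CDR-L3 (24) |
#   FR4-L (20)] | rev primer (22) | anchor3 (8)
# Codon 1 starts at position 11 (anchor_offset = 10). CDR-H3 starts at 271 so
# the 280-300 seed window falls inside it; for scfv the CDR-L3 sits 50-73 nt
# from the 3' end so the second seed window (pseudo-read 470-490) falls
# inside it. All constant blocks are free of in-frame stop codons; random
# CDR3 codons are sampled stop-free unless a stop is deliberately planted.

.dealr_env <- new.env(parent = emptyenv())

with_preserved_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# stop-free codons whose first base is never T, for constant regions
.safe_codons <- c("GCA", "GCC", "GGC", "CAG", "CTG", "AGC", "ACC", "GAA",
                  "GAC", "CCG", "GTG", "CGC", "AAC", "ATC", "CAC", "GGA")

.random_safe_run <- function(n_bases) {
  # constant block: full safe codons plus a T-free partial codon if needed
  n_cod <- n_bases %/% 3
  rest <- n_bases %% 3
  s <- paste(sample(.safe_codons, n_cod, replace = TRUE), collapse = "")
  if (rest > 0)
    s <- paste0(s, paste(sample(c("G", "C", "A"), rest, replace = TRUE),
                         collapse = ""))
  s
}

construct_constants <- function() {
  if (!is.null(.dealr_env$constants)) return(.dealr_env$constants)
  k <- with_preserved_seed(20150517, list(
    anchor5 = "GCGCGCCAGG",          # 10 nt; anchor_offset = 10
    fr_h = .random_safe_run(236),
    fr4_h = .random_safe_run(36),
    linker = .random_safe_run(45),
    fr_l = .random_safe_run(295),
    fr4_l = paste0("CC", .random_safe_run(18)),  # "CC" guards the frame joint
    anchor3 = "GGCCAGCC"             # 8 nt terminal anchor (outside the CDS)
  ))
  .dealr_env$constants <- k
  k
}

# CDR-H3 length pools by frame class (construct length mod 3 relative to the
# anchor is fixed by the constant blocks, so L_h mod 3 sets the frame)
.lh_pool <- list(
  in_frame = c(28L, 31L, 34L, 37L, 40L, 43L, 46L),
  plus1    = c(29L, 32L, 35L, 38L, 41L, 44L),
  plus2    = c(30L, 33L, 36L, 39L, 42L, 45L)
)

.stop_codons <- c("TAA", "TAG", "TGA")

.random_nonstop_codons <- function(n_codons) {
  if (n_codons == 0) return(character(0))
  cods <- paste0(sample(c("A", "C", "G", "T"), n_codons, TRUE),
                 sample(c("A", "C", "G", "T"), n_codons, TRUE),
                 sample(c("A", "C", "G", "T"), n_codons, TRUE))
  bad <- cods %in% .stop_codons
  while (any(bad)) {
    n_bad <- sum(bad)
    cods[bad] <- paste0(sample(c("A", "C", "G", "T"), n_bad, TRUE),
                        sample(c("A", "C", "G", "T"), n_bad, TRUE),
                        sample(c("A", "C", "G", "T"), n_bad, TRUE))
    bad <- cods %in% .stop_codons
  }
  cods
}

# CDR-H3 for one sequence. In-frame layout: 1 base completing the boundary
# codon, then full codons (stop-free, or with one stop planted).
.make_cdrh3 <- function(l_h, in_frame, plant_stop) {
  if (!in_frame) {
    return(paste(sample(c("A", "C", "G", "T"), l_h, replace = TRUE),
                 collapse = ""))
  }
  n_cod <- (l_h - 1L) %/% 3L
  cods <- .random_nonstop_codons(n_cod)
  if (plant_stop) cods[sample.int(n_cod, 1)] <- sample(.stop_codons, 1)
  paste0(sample(c("A", "C", "G", "T"), 1), paste(cods, collapse = ""))
}

# CDR-L3 (scfv, fixed 24 nt): 2 boundary bases + 7 stop-free codons + 1 base
.make_cdrl3 <- function() {
  paste0(paste(sample(c("A", "C", "G", "T"), 2, TRUE), collapse = ""),
         paste(.random_nonstop_codons(7), collapse = ""),
         sample(c("A", "C", "G", "T"), 1))
}

.default_v_probs <- c(0.22, 0.20, 0.25, 0.15, 0.03, 0.15)
.default_j_probs <- c(0.15, 0.35, 0.30, 0.20)

#' Generate a synthetic library repertoire
#'
#' Builds `n_unique` pairwise-distinct construct sequences with attached truth
#' (V class, J class, frame class, stop flag, abundance weight) plus a single
#' plasmid-backbone contaminant sequence, according to the geometry described
#' in the package vignette. Reproducible: the RNG is seeded from
#' `config$rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A `true_repertoire` list: `sequences` (tibble with columns
#'   `source_id`, `sequence`, `v_class`, `j_class`, `frame_class`, `in_frame`,
#'   `has_stop`, `weight`), `backbone` (contaminant sequence),
#'   `anchor_offset`, `cds_tail` (length of the terminal anchor excluded from
#'   stop scanning), and the `config`.
#' @export
generate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  k <- construct_constants()
  lib <- config$primers
  n <- config$n_unique
  v_names <- names(lib$forward)
  j_names <- names(lib$reverse)
  v_probs <- rep_len(.default_v_probs, length(v_names))
  j_probs <- rep_len(.default_j_probs, length(j_names))

  # combinatorial capacity guard: distinct CDR3 fillings at the smallest
  # in-frame CDR-H3 dominate the floor
  min_codons <- (min(.lh_pool$in_frame) - 1L) %/% 3L
  capacity <- length(v_names) * length(j_names) * 61^min_codons
  if (n > capacity / 10)
    stop("n_unique = ", n, " exceeds the combinatorial capacity of the ",
         "CDR3 design (~", signif(capacity, 3), ")", call. = FALSE)

  v_idx <- sample.int(length(v_names), n, replace = TRUE, prob = v_probs)
  j_idx <- if (config$class_assortment == "linked") {
    (v_idx - 1L) %% length(j_names) + 1L
  } else {
    sample.int(length(j_names), n, replace = TRUE, prob = j_probs)
  }
  frame_class <- sample(c("in_frame", "plus1", "plus2"), n, replace = TRUE,
                        prob = c(1 - config$frameshift_fraction,
                                 config$frameshift_fraction / 2,
                                 config$frameshift_fraction / 2))
  in_frame <- frame_class == "in_frame"
  has_stop <- in_frame & (runif(n) < config$stop_fraction)

  build_one <- function(i) {
    l_h <- sample(.lh_pool[[frame_class[i]]], 1)
    cdrh3 <- .make_cdrh3(l_h, in_frame[i], has_stop[i])
    if (config$construct == "vh") {
      paste0(k$anchor5, lib$forward[[v_idx[i]]], k$fr_h, cdrh3, k$fr4_h,
             lib$reverse[[j_idx[i]]], k$anchor3)
    } else {
      paste0(k$anchor5, lib$forward[[v_idx[i]]], k$fr_h, cdrh3, k$fr4_h,
             k$linker, k$fr_l, .make_cdrl3(), k$fr4_l,
             lib$reverse[[j_idx[i]]], k$anchor3)
    }
  }
  seqs <- vapply(seq_len(n), build_one, character(1))
  # enforce pairwise distinctness by regenerating collisions
  for (tries in 1:50) {
    dup <- duplicated(seqs)
    if (!any(dup)) break
    seqs[dup] <- vapply(which(dup), build_one, character(1))
  }
  if (anyDuplicated(seqs))
    stop("could not generate ", n, " distinct sequences", call. = FALSE)

  w <- switch(config$abundance_model$model,
    negative_binomial = {
      kk <- rnbinom(n, size = config$abundance_model$s,
                    prob = config$abundance_model$p)
      while (any(kk == 0))  # zero-truncated: every library member exists
        kk[kk == 0] <- rnbinom(sum(kk == 0), size = config$abundance_model$s,
                               prob = config$abundance_model$p)
      kk / sum(kk)
    },
    lognormal = {
      kk <- rlnorm(n, config$abundance_model$mu, config$abundance_model$sigma)
      kk / sum(kk)
    },
    uniform = rep(1 / n, n)
  )

  backbone_len <- if (config$construct == "vh") 370L else 720L
  backbone <- random_dna(1, backbone_len)

  structure(list(
    sequences = tibble::tibble(
      source_id = sprintf("seq%05d", seq_len(n)),
      sequence = seqs,
      v_class = v_names[v_idx],
      j_class = j_names[j_idx],
      frame_class = frame_class,
      in_frame = in_frame,
      has_stop = has_stop,
      weight = w
    ),
    backbone = backbone,
    anchor_offset = 10L,
    cds_tail = nchar(k$anchor3),
    config = config
  ), class = "true_repertoire")
}

# -- error/quality machinery ---------------------------------------------

cycle_rate_vector <- function(error_spec, mate, n_cycles) {
  rate <- rep(error_spec$baseline, n_cycles)
  for (sp in error_spec$spikes) {
    if (sp$mate != mate) next
    cyc <- sp$cycles[sp$cycles <= n_cycles]
    rate[cyc] <- sp$rate
  }
  rate
}

# substitute bases in a char matrix at `idx` (linear indices), uniformly to a
# different base
.substitute_at <- function(mat, idx) {
  if (length(idx) == 0) return(mat)
  bases <- c("A", "C", "G", "T")
  cur <- match(mat[idx], bases)
  mat[idx] <- bases[(cur - 1L + sample.int(3, length(idx), replace = TRUE)) %% 4L + 1L]
  mat
}

.collapse_rows <- function(mat) {
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

# Inject cycle-indexed substitution errors and build reported qualities for a
# block of same-length reads. Returns bases, quals and per-read error
# positions (read coordinates == cycles).
inject_run_errors <- function(bases, mate, error_spec, phred_spec) {
  n <- length(bases)
  if (n == 0) {
    return(list(bases = character(0), quals = character(0),
                err_pos = list()))
  }
  L <- nchar(bases[1])
  mat <- matrix(unlist(strsplit(bases, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  rate <- cycle_rate_vector(error_spec, mate, L)
  err <- matrix(runif(n * L), n, L) < matrix(rate, n, L, byrow = TRUE)

  # sporadic low-quality positions: visibly bad Phred, elevated error
  lowq <- if (phred_spec$lowq_fraction > 0) {
    matrix(runif(n * L), n, L) < phred_spec$lowq_fraction
  } else matrix(FALSE, n, L)
  if (any(lowq) && phred_spec$lowq_error_rate > 0) {
    err_lowq <- lowq & (matrix(runif(n * L), n, L) < phred_spec$lowq_error_rate)
    err <- err | err_lowq
  }
  mat <- .substitute_at(mat, which(err))

  q <- matrix(phred_spec$baseline_q, n, L)
  win <- phred_spec$miscal_window
  wcols <- seq(max(1L, win[1]), min(L, win[2]))
  if (length(wcols) > 0) {
    q[, wcols] <- sample(seq(phred_spec$window_q[1], phred_spec$window_q[2]),
                         n * length(wcols), replace = TRUE)
  }
  q[lowq] <- phred_spec$lowq_q

  qchr <- matrix(intToUtf8(pmin(q, 93L) + 33L, multiple = TRUE), n, L)
  arr <- which(err, arr.ind = TRUE)
  err_pos <- rep(list(integer(0)), n)
  if (nrow(arr) > 0) {
    byrow <- split(arr[, 2], arr[, 1])
    err_pos[as.integer(names(byrow))] <- lapply(byrow, sort)
  }
  list(bases = .collapse_rows(mat), quals = .collapse_rows(qchr),
       err_pos = err_pos)
}

# fixed per-index shifter strings (deterministic, T-free so they never create
# spurious primer matches)
shifter_string <- function(index, mate, offsets) {
  k <- offsets[[index]]
  if (k == 0) return("")
  pad <- "GACGGACCAGGCA"  # 13 nt, longest offset used
  substr(pad, 1, k)
}

#' Simulate a paired-end sequencing run over a repertoire
#'
#' Draws `n_reads` read pairs from the repertoire proportional to abundance
#' (plus `backbone_copies` pairs from the contaminant), assigns each pair an
#' index, prepends the index-specific shifter bases, injects cycle-indexed
#' substitution errors and reports Phred scores per the configured
#' calibration model. Deterministic given config + seed.
#'
#' @param repertoire A [generate_repertoire()] result.
#' @param config The same [simulation_config()].
#' @return A list: `r1`, `r2` (read tibbles with `id`, `bases`, `quals`,
#'   `mate`, `index`) and `truth` (tibble: `read_id`, `source_id`, `index`,
#'   `is_backbone`, `error_positions_r1`, `error_positions_r2` as
#'   comma-separated cycle lists).
#' @export
simulate_reads <- function(repertoire, config = repertoire$config) {
  stopifnot(inherits(repertoire, "true_repertoire"))
  set.seed(config$rng_seed + 1L)
  run <- config$run
  reps <- repertoire$sequences
  if (any(nchar(reps$sequence) < run$read_len_r1 - min(run$shifter_offsets_r1) &
          config$construct == "scfv"))
    warning("reads longer than some constructs; reads truncated")

  n <- config$n_reads
  src <- sample.int(nrow(reps), n, replace = TRUE, prob = reps$weight)
  src_id <- reps$source_id[src]
  seqs <- reps$sequence[src]
  if (config$backbone_copies > 0) {
    src_id <- c(src_id, rep("backbone", config$backbone_copies))
    seqs <- c(seqs, rep(repertoire$backbone, config$backbone_copies))
  }
  n_tot <- length(seqs)
  idx_names <- names(run$index_barcodes)
  index <- sample(idx_names, n_tot, replace = TRUE)
  read_id <- sprintf("read%07d", seq_len(n_tot))

  r1_raw <- character(n_tot)
  r2_raw <- character(n_tot)
  rc <- revcomp(seqs)
  for (ix in idx_names) {
    sel <- index == ix
    if (!any(sel)) next
    s1 <- shifter_string(ix, "R1", run$shifter_offsets_r1)
    s2 <- shifter_string(ix, "R2", run$shifter_offsets_r2)
    r1_raw[sel] <- substr(paste0(s1, seqs[sel]), 1, run$read_len_r1)
    r2_raw[sel] <- substr(paste0(s2, rc[sel]), 1, run$read_len_r2)
  }
  # pad short reads (vh constructs shorter than the cycle count never occur
  # with the default geometry, but guard anyway)
  pad_to <- function(x, L) {
    short <- nchar(x) < L
    if (any(short))
      x[short] <- vapply(x[short], function(s)
        paste0(s, paste(rep("A", L - nchar(s)), collapse = "")), character(1))
    x
  }
  r1_raw <- pad_to(r1_raw, run$read_len_r1)
  r2_raw <- pad_to(r2_raw, run$read_len_r2)

  e1 <- inject_run_errors(r1_raw, "R1", config$error_spec, config$phred_spec)
  e2 <- inject_run_errors(r2_raw, "R2", config$error_spec, config$phred_spec)

  fmt_pos <- function(p) vapply(p, function(x) paste(x, collapse = ","),
                                character(1))
  list(
    r1 = tibble::tibble(id = read_id, bases = e1$bases, quals = e1$quals,
                        mate = "R1", index = index),
    r2 = tibble::tibble(id = read_id, bases = e2$bases, quals = e2$quals,
                        mate = "R2", index = index),
    truth = tibble::tibble(
      read_id = read_id, source_id = src_id, index = index,
      is_backbone = src_id == "backbone",
      error_positions_r1 = fmt_pos(e1$err_pos),
      error_positions_r2 = fmt_pos(e2$err_pos)
    )
  )
}

#' Synthetic Phi-X-like control reference
#'
#' A fixed 5386-nt random sequence standing in for the Phi-X174 control
#' genome. It is synthetic (not the real Phi-X sequence); what matters for
#' error profiling is only that it is a known, constant reference the control
#' reads can be placed on.
#'
#' @return Named character scalar (name `"phix_like"`).
#' @export
phix_like_reference <- function() {
  if (is.null(.dealr_env$phix_ref)) {
    .dealr_env$phix_ref <- with_preserved_seed(
      5386L, setNames(random_dna(1, 5386L), "phix_like"))
  }
  .dealr_env$phix_ref
}

#' Simulate Phi-X control spike-in reads
#'
#' Draws reads from the fixed control reference (both strands, uniform start
#' positions) and pushes them through the same cycle-indexed error process as
#' the library reads, so the profile measured from them estimates the
#' injected one.
#'
#' @param config A [simulation_config()] (supplies `error_spec`, `phred_spec`,
#'   read lengths and the seed).
#' @param n_reads Number of control reads per mate.
#' @return A list: `reads` (tibble `id`, `bases`, `quals`, `mate`) and
#'   `reference` (named character scalar).
#' @export
simulate_phix <- function(config, n_reads = 10000L) {
  stopifnot(inherits(config, "simulation_config"), n_reads >= 1)
  set.seed(config$rng_seed + 2L)
  ref <- phix_like_reference()
  ref_rc <- revcomp(ref)
  run <- config$run

  one_mate <- function(mate, n, L) {
    strand <- sample(c(TRUE, FALSE), n, replace = TRUE)
    start <- sample.int(nchar(ref) - L + 1L, n, replace = TRUE)
    tmpl <- ifelse(strand, substr(rep(unname(ref), n), start, start + L - 1L),
                   substr(rep(ref_rc, n), start, start + L - 1L))
    e <- inject_run_errors(tmpl, mate, config$error_spec, config$phred_spec)
    tibble::tibble(
      id = sprintf("phix_%s_%06d", tolower(mate), seq_len(n)),
      bases = e$bases, quals = e$quals, mate = mate
    )
  }
  reads <- dplyr::bind_rows(
    one_mate("R1", n_reads, run$read_len_r1),
    one_mate("R2", n_reads, run$read_len_r2)
  )
  list(reads = reads, reference = ref)
}

#' Write a simulated run to disk
#'
#' Emits per-index R1/R2 FASTQ files and the truth table TSV, the on-disk
#' form a real demultiplexed run would arrive in.
#'
#' @param sim A [simulate_reads()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulated_run <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ix in unique(sim$r1$index)) {
    p1 <- file.path(dir, paste0(ix, "_R1.fastq"))
    p2 <- file.path(dir, paste0(ix, "_R2.fastq"))
    write_fastq(dplyr::filter(sim$r1, .data$index == ix), p1)
    write_fastq(dplyr::filter(sim$r2, .data$index == ix), p2)
    paths[[paste0(ix, "_R1")]] <- p1
    paths[[paste0(ix, "_R2")]] <- p2
  }
  pt <- file.path(dir, "truth.tsv")
  readr::write_tsv(sim$truth, pt)
  paths$truth <- pt
  invisible(paths)
}
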