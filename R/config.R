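# Run and simulation configuration objects.

#' Sequencing-run configuration
#'
#' Holds the demultiplexing and trimming parameters of a run: the four index
#' barcodes, the per-index shifter offsets that must be discarded from the
#' start of each mate, the fixed trim lengths, and the median-quality filter
#' threshold. Defaults are the MiSeq run layout this pipeline was designed
#' around: barcodes i1=TCAGCG, i2=GATCAC, i3=CTGAGA, i4=AGCTTT; R1 shifter
#' offsets 0/1/7/8 and R2 offsets 13/12/11/10 for i1..i4; R1 trimmed to 320 nt
#' and R2 to 220 nt (so a joined pseudo-read is 540 nt); reads kept only if
#' their median Phred score is at least 32.
#'
#' @param index_barcodes Named character vector, index label -> barcode.
#' @param shifter_offsets_r1,shifter_offsets_r2 Named integer vectors, index
#'   label -> number of shifter bases to discard from the read start.
#' @param trim_r1,trim_r2 Fixed lengths the mates are trimmed to after shifter
#'   removal.
#' @param min_median_phred Median Phred threshold for the quality filter.
#' @param read_len_r1,read_len_r2 Sequencer read lengths (cycles per mate).
#' @return A `run_config` list.
#' @export
run_config <- function(index_barcodes = c(i1 = "TCAGCG", i2 = "GATCAC",
                                          i3 = "CTGAGA", i4 = "AGCTTT"),
                       shifter_offsets_r1 = c(i1 = 0L, i2 = 1L, i3 = 7L, i4 = 8L),
                       shifter_offsets_r2 = c(i1 = 13L, i2 = 12L, i3 = 11L, i4 = 10L),
                       trim_r1 = 320L, trim_r2 = 220L,
                       min_median_phred = 32L,
                       read_len_r1 = 350L, read_len_r2 = 250L) {
  stopifnot(
    length(index_barcodes) >= 1,
    setequal(names(index_barcodes), names(shifter_offsets_r1)),
    setequal(names(index_barcodes), names(shifter_offsets_r2)),
    all(shifter_offsets_r1 >= 0), all(shifter_offsets_r2 >= 0),
    trim_r1 + max(shifter_offsets_r1) <= read_len_r1,
    trim_r2 + max(shifter_offsets_r2) <= read_len_r2,
    min_median_phred >= 0
  )
  structure(list(
    index_barcodes = index_barcodes,
    shifter_offsets_r1 = shifter_offsets_r1,
    shifter_offsets_r2 = shifter_offsets_r2,
    trim_r1 = as.integer(trim_r1), trim_r2 = as.integer(trim_r2),
    min_median_phred = as.integer(min_median_phred),
    read_len_r1 = as.integer(read_len_r1),
    read_len_r2 = as.integer(read_len_r2)
  ), class = "run_config")
}

#' Default primer library (synthetic)
#'
#' A small built-in table of primer recognition sequences in the style of
#' framework-annealing V-gene (forward, 5' end) and J-gene (reverse, 3' end)
#' primer sets. The sequences are synthetic stand-ins invented for this
#' package — they are NOT the published human V/J primer sequences — but they
#' reproduce the structural properties that matter here: one class per V/J
#' family, equal length within each direction, and pairwise distances well
#' above the mismatch tolerance. Reverse-class sequences are stored as they
#' appear on the sense (coding) strand at the 3' end of the construct.
#'
#' @param max_mismatch Mismatch tolerance used by [assign_primer()].
#' @return A `primer_library` list with elements `forward`, `reverse`
#'   (named character vectors) and `max_mismatch`.
#' @export
primer_library_default <- function(max_mismatch = 2L) {
  forward <- c(
    VH1 = "CAGGCACAGCACCTGCAACAGAGC",
    VH2 = "CAGACCGCCCTGCGCGAATCCGGC",
    VH3 = "GAAGCGCAACTGGCCGAACCGGGC",
    VH4 = "CAGGCGCTGCAACTGCAGCAATCG",
    VH5 = "GAGGCGCAGCTGGTGCAGAGCGGC",
    VH6 = "CAGAGCGGCCCGGGCCTGGTGAAG"
  )
  reverse <- c(
    JH1 = "CCCAGACCACCGTCACCGCCAG",
    JH2 = "CCAAGGGACAATGGTCACCGTC",
    JH3 = "CCCAAGGCACCCTGGTCACCGT",
    JH4 = "CCCAGGGAACCCTGGTCACCGG"
  )
  primer_library(forward, reverse, max_mismatch)
}

#' Build a primer library
#'
#' @param forward,reverse Named character vectors: class name -> recognition
#'   sequence (IUPAC degenerate bases allowed). Forward sequences are matched
#'   anchored at the 5' end of a sequence, reverse ones at the 3' end (sense
#'   strand orientation).
#' @param max_mismatch Mismatch tolerance used by [assign_primer()].
#' @return A `primer_library` list.
#' @export
primer_library <- function(forward, reverse, max_mismatch = 2L) {
  stopifnot(
    length(forward) >= 1, length(reverse) >= 1,
    !is.null(names(forward)), !is.null(names(reverse)),
    !anyDuplicated(names(forward)), !anyDuplicated(names(reverse)),
    all(nchar(forward) > 0), all(nchar(reverse) > 0),
    max_mismatch >= 0
  )
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_library")
}

#' Simulation configuration
#'
#' Defines a synthetic antibody-library sequencing experiment: the repertoire
#' (how many distinct sequences, their abundance law, construct geometry,
#' frameshift/stop composition, optional plasmid-backbone contaminant) and the
#' sequencing-error structure (per-cycle substitution spikes over a baseline
#' rate, and a Phred reporting model with a miscalibrated early-cycle window
#' in which the reported quality carries no information about the true error
#' rate).
#'
#' @param n_unique Number of distinct library sequences.
#' @param abundance_model One of `abundance_negbin()`, `abundance_lognormal()`,
#'   `abundance_uniform()`.
#' @param n_reads Total read pairs drawn from the library.
#' @param construct `"scfv"` (~750 nt, non-overlapping mates) or `"vh"`
#'   (~364-382 nt, overlapping mates).
#' @param frameshift_fraction Proportion of sequences whose length is not a
#'   multiple of 3 relative to the reading-frame anchor.
#' @param stop_fraction Proportion of in-frame sequences carrying a stop codon
#'   in the CDS.
#' @param backbone_copies Number of reads drawn from a single contaminant
#'   (vector backbone) sequence, on top of `n_reads`.
#' @param error_spec List: `baseline` per-base substitution rate and `spikes`,
#'   a list of `list(mate=, cycles=, rate=)` per-cycle rate overrides.
#' @param phred_spec List: `baseline_q` reported quality for well-behaved
#'   positions; `miscal_window` cycle range in which reported Q is drawn
#'   uniformly from `window_q` independent of the true error rate;
#'   `lowq_fraction`/`lowq_q`/`lowq_error_rate` describe sporadic positions
#'   that are both error-prone and visibly low-quality.
#' @param run The `run_config()` (indexes, shifters, read lengths).
#' @param primers The `primer_library()` the repertoire scaffolds draw from.
#' @param class_assortment `"independent"` (V and J classes drawn
#'   independently) or `"linked"` (J class determined by V class; used to
#'   exercise the assortment diagnostic).
#' @param rng_seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_unique = 5000L,
                              abundance_model = abundance_negbin(0.3, 1.5),
                              n_reads = 30000L,
                              construct = c("scfv", "vh"),
                              frameshift_fraction = 0.134,
                              stop_fraction = 0.10,
                              backbone_copies = 0L,
                              error_spec = error_spec_default(),
                              phred_spec = phred_spec_default(),
                              run = run_config(),
                              primers = primer_library_default(),
                              class_assortment = c("independent", "linked"),
                              rng_seed = 1L) {
  construct <- match.arg(construct)
  class_assortment <- match.arg(class_assortment)
  stopifnot(
    n_unique >= 1, n_unique == floor(n_unique),
    n_reads >= 0, backbone_copies >= 0,
    frameshift_fraction >= 0, frameshift_fraction <= 1,
    stop_fraction >= 0, stop_fraction <= 1,
    error_spec$baseline >= 0, error_spec$baseline <= 1,
    rng_seed == as.integer(rng_seed)
  )
  for (sp in error_spec$spikes) {
    stopifnot(sp$mate %in% c("R1", "R2"), all(sp$cycles >= 1),
              sp$rate >= 0, sp$rate <= 1)
  }
  structure(list(
    n_unique = as.numeric(n_unique), abundance_model = abundance_model,
    n_reads = as.integer(n_reads), construct = construct,
    frameshift_fraction = frameshift_fraction, stop_fraction = stop_fraction,
    backbone_copies = as.integer(backbone_copies),
    error_spec = error_spec, phred_spec = phred_spec,
    run = run, primers = primers, class_assortment = class_assortment,
    rng_seed = as.integer(rng_seed)
  ), class = "simulation_config")
}

#' Abundance models for the simulated repertoire
#'
#' The true abundance law of a real library is unknown; the simulator exposes
#' it as a choice. `abundance_negbin()` draws per-sequence copy numbers from a
#' zero-truncated negative binomial (the family the complexity fit assumes),
#' `abundance_lognormal()` draws log-normal weights, `abundance_uniform()`
#' gives every sequence equal weight.
#'
#' @param p,s Negative-binomial probability and size parameters.
#' @param mu,sigma Log-normal location and scale.
#' @return An `abundance_model` list.
#' @export
abundance_negbin <- function(p = 0.3, s = 1.5) {
  stopifnot(p > 0, p < 1, s > 0)
  structure(list(model = "negative_binomial", p = p, s = s),
            class = "abundance_model")
}

#' @rdname abundance_negbin
#' @export
abundance_lognormal <- function(mu = 0, sigma = 1) {
  stopifnot(sigma > 0)
  structure(list(model = "lognormal", mu = mu, sigma = sigma),
            class = "abundance_model")
}

#' @rdname abundance_negbin
#' @export
abundance_uniform <- function() {
  structure(list(model = "uniform"), class = "abundance_model")
}

#' @rdname simulation_config
#' @param baseline Baseline per-base substitution rate.
#' @param spikes List of `list(mate=, cycles=, rate=)` cycle-range overrides.
#' @export
error_spec_default <- function(baseline = 0.0034,
                               spikes = list(
                                 list(mate = "R1", cycles = 15:20, rate = 0.02),
                                 list(mate = "R2", cycles = 10:14, rate = 0.02)
                               )) {
  list(baseline = baseline, spikes = spikes)
}

#' @rdname simulation_config
#' @param baseline_q,miscal_window,window_q,lowq_fraction,lowq_q,lowq_error_rate
#'   See the `phred_spec` argument.
#' @export
phred_spec_default <- function(baseline_q = 38L, miscal_window = c(1L, 40L),
                               window_q = c(32L, 40L), lowq_fraction = 0,
                               lowq_q = 20L, lowq_error_rate = 0) {
  stopifnot(baseline_q >= 0, lowq_fraction >= 0, lowq_fraction <= 1,
            lowq_error_rate >= 0, lowq_error_rate <= 1)
  list(baseline_q = as.integer(baseline_q),
       miscal_window = as.integer(miscal_window),
       window_q = as.integer(window_q),
       lowq_fraction = lowq_fraction, lowq_q = as.integer(lowq_q),
       lowq_error_rate = lowq_error_rate)
}
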