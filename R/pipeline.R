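# End-to-end pipeline: simulate (or load) a run, profile errors, preprocess,
# cluster, and report. Stages persist their outputs under a run directory so
# reruns are reproducible and individually inspectable.

#' Run the full analysis pipeline on a simulated run
#'
#' Executes every stage in order — simulate reads and Phi-X control, measure
#' the error profile, preprocess to pseudo-reads, flag unreliable positions,
#' DEAL clustering, complexity histogram + truncated NB fit, protein report
#' (VH mode), primer assortment — writing each stage's table under
#' `out_dir`. Identical config and seed give identical outputs.
#'
#' @param out_dir Run directory (created).
#' @param config A [simulation_config()].
#' @param n_phix_reads Control reads per mate for the error profile.
#' @param thresholds A [flag_thresholds()].
#' @param x_min Smallest cardinality in the NB fit (default 2).
#' @param transformant_count Optional upper-cap complexity for the summary.
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`sim`, `profile`, `pre`, `deal`, `histogram`, `fit`, `summary`,
#'   `protein`, `assortment`, `paths`).
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         n_phix_reads = 5000L,
                         thresholds = flag_thresholds(),
                         x_min = 2L, transformant_count = NA_real_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  say <- function(...) message("[dealr] ", ...)

  say("simulating repertoire and run")
  rep <- generate_repertoire(config)
  sim <- simulate_reads(rep, config)
  paths <- c(paths, write_simulated_run(sim, file.path(out_dir, "raw")))

  say("measuring Phi-X error profile")
  phix <- simulate_phix(config, n_phix_reads)
  write_fastq(phix$reads, file.path(out_dir, "raw", "phix.fastq"))
  write_fasta(phix$reference, file.path(out_dir, "raw", "phix_ref.fasta"))
  profile <- compute_phix_profile(phix$reads, phix$reference)
  paths$profile <- write_error_profile(
    profile, file.path(out_dir, "error_profile.tsv"))

  say("preprocessing")
  pre <- preprocess_run(sim$r1, sim$r2, config$run, mode = config$construct)
  readr::write_tsv(pre$log, file.path(out_dir, "preprocess_log.tsv"))
  pseudo <- flag_unreliable(pre$pseudo, profile, thresholds)

  say("DEAL clustering")
  spec <- if (config$construct == "vh") seed_spec_vh() else seed_spec()
  deal <- run_deal(pseudo, spec)
  readr::write_tsv(
    dplyr::mutate(tidy(deal),
                  flags_rle = vapply(deal$clusters$flags, function(f)
                    paste(rle(f)$lengths, rle(f)$values, sep = ":",
                          collapse = ";"), character(1))),
    file.path(out_dir, "clusters.tsv"))
  readr::write_tsv(
    tibble::tibble(
      cluster_id = rep(deal$clusters$cluster_id,
                       lengths(deal$clusters$members)),
      read_id = unlist(deal$clusters$members)),
    file.path(out_dir, "members.tsv"))

  say("complexity estimation")
  h <- cardinality_histogram(deal)
  readr::write_tsv(h, file.path(out_dir, "cardinality_histogram.tsv"))
  outl <- detect_outliers(deal$clusters, backbone = rep$backbone)
  h_fit <- exclude_outliers(h, outl)
  fit <- tryCatch(fit_truncated_negbin(h_fit, x_min = x_min),
                  error = function(e) {
                    say("NB fit not possible: ", conditionMessage(e))
                    NULL
                  })
  if (!is.null(fit))
    readr::write_tsv(glance(fit), file.path(out_dir, "negbin_fit.tsv"))
  summary <- complexity_summary(deal, fit, transformant_count)
  readr::write_tsv(summary, file.path(out_dir, "complexity_summary.tsv"))

  protein <- NULL
  if (config$construct == "vh") {
    say("protein-level report")
    translated <- translate_clusters(deal$clusters, rep$anchor_offset,
                                     rep$cds_tail)
    protein <- protein_clusters(translated)
    readr::write_tsv(protein$summary, file.path(out_dir, "protein_report.tsv"))
  }

  say("primer assortment")
  asg <- tibble::tibble(
    fwd = assign_primer(deal$clusters$consensus, config$primers, "5prime",
                        offset = rep$anchor_offset),
    rev = assign_primer(deal$clusters$consensus, config$primers, "3prime",
                        offset = rep$cds_tail))
  asst <- assortment(asg)
  readr::write_tsv(
    as.data.frame.table(asst$observed, responseName = "freq"),
    file.path(out_dir, "assortment_observed.tsv"))
  readr::write_tsv(
    as.data.frame.table(asst$expected, responseName = "freq"),
    file.path(out_dir, "assortment_expected.tsv"))

  manifest <- tibble::tibble(file = list.files(out_dir, recursive = TRUE))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  say("done: ", out_dir)
  invisible(list(sim = sim, repertoire = rep, profile = profile, pre = pre,
                 deal = deal, histogram = h, fit = fit, summary = summary,
                 protein = protein, assortment = asst, paths = paths))
}
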