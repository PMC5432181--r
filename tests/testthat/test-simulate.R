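test_that("repertoire has exactly n_unique distinct sequences with primer scaffolds", {
  cfg <- simulation_config(n_unique = 100, n_reads = 10,
                           error_spec = clean_error_spec(), rng_seed = 1)
  rep <- generate_repertoire(cfg)
  expect_identical(nrow(rep$sequences), 100L)
  expect_identical(anyDuplicated(rep$sequences$sequence), 0L)
  # every sequence starts with the 5' anchor + its forward primer and ends
  # with its reverse primer + 3' anchor
  lib <- cfg$primers
  seqs <- rep$sequences$sequence
  fwd <- substr(seqs, 11, 34)
  expect_identical(unname(fwd), unname(lib$forward[rep$sequences$v_class]))
  L <- nchar(seqs)
  rev_site <- substr(seqs, L - 29, L - 8)
  expect_identical(unname(rev_site),
                   unname(lib$reverse[rep$sequences$j_class]))
  expect_true(all(abs(rep$sequences$weight) > 0))
  expect_equal(sum(rep$sequences$weight), 1)
})

test_that("brute-force all-pairs comparison finds no duplicates (vh)", {
  cfg <- simulation_config(n_unique = 300, n_reads = 10, construct = "vh",
                           error_spec = clean_error_spec(), rng_seed = 5)
  rep <- generate_repertoire(cfg)
  seqs <- rep$sequences$sequence
  dup <- FALSE
  for (i in seq_along(seqs)[-1]) {
    if (any(seqs[seq_len(i - 1)] == seqs[i])) { dup <- TRUE; break }
  }
  expect_false(dup)
  # larger repertoire checked by hashing
  cfg2 <- simulation_config(n_unique = 5000, n_reads = 10, construct = "vh",
                            error_spec = clean_error_spec(), rng_seed = 6)
  expect_identical(anyDuplicated(generate_repertoire(cfg2)$sequences$sequence),
                   0L)
})

test_that("frameshift_fraction = 0 gives only in-frame lengths", {
  cfg <- simulation_config(n_unique = 200, n_reads = 10,
                           frameshift_fraction = 0, construct = "vh",
                           error_spec = clean_error_spec(), rng_seed = 2)
  rep <- generate_repertoire(cfg)
  expect_true(all((nchar(rep$sequences$sequence) - rep$anchor_offset) %% 3 == 0))
  expect_true(all(rep$sequences$frame_class == "in_frame"))
})

test_that("realized frameshift fraction is within 2 binomial SD of target", {
  cfg <- simulation_config(n_unique = 2000, n_reads = 10,
                           frameshift_fraction = 0.134, construct = "vh",
                           error_spec = clean_error_spec(), rng_seed = 3)
  rep <- generate_repertoire(cfg)
  f <- mean(!rep$sequences$in_frame)
  se <- sqrt(0.134 * (1 - 0.134) / 2000)
  expect_lt(abs(f - 0.134), 2 * se + 1e-9)
})

test_that("excessive n_unique fails with a capacity error", {
  expect_error(simulation_config(n_unique = 1e17),
               NA)  # config itself is fine
  cfg <- simulation_config(n_unique = 1e17)
  expect_error(generate_repertoire(cfg), "capacity")
})

test_that("zero-error reads substring-match their source", {
  fx <- scfv_clean()
  tr <- fx$sim$truth
  src <- fx$rep$sequences$sequence[match(tr$source_id,
                                         fx$rep$sequences$source_id)]
  off1 <- fx$cfg$run$shifter_offsets_r1[tr$index]
  body1 <- substr(fx$sim$r1$bases, off1 + 1, nchar(fx$sim$r1$bases))
  expect_true(all(substr(src, 1, nchar(body1)) == body1))
  expect_true(all(tr$error_positions_r1 == "" & tr$error_positions_r2 == ""))
})

test_that("read counts follow the abundance multinomial (chi-square)", {
  cfg <- simulation_config(n_unique = 100, n_reads = 10000,
                           abundance_model = abundance_uniform(),
                           error_spec = clean_error_spec(), rng_seed = 9)
  rep <- generate_repertoire(cfg)
  sim <- simulate_reads(rep, cfg)
  counts <- table(factor(sim$truth$source_id,
                         levels = rep$sequences$source_id))
  p <- suppressWarnings(chisq.test(as.integer(counts),
                                   p = rep(1 / 100, 100))$p.value)
  expect_gt(p, 0.001)
})

test_that("backbone_copies reads are present and labelled exactly", {
  cfg <- simulation_config(n_unique = 30, n_reads = 200,
                           backbone_copies = 57,
                           error_spec = clean_error_spec(), rng_seed = 4)
  rep <- generate_repertoire(cfg)
  sim <- simulate_reads(rep, cfg)
  expect_identical(sum(sim$truth$is_backbone), 57L)
  expect_identical(nrow(sim$truth), 257L)
})

test_that("truth-table error positions are exactly the read/source mismatches", {
  cfg <- simulation_config(n_unique = 40, n_reads = 300, construct = "scfv",
                           error_spec = error_spec_default(baseline = 0.01,
                                                           spikes = list()),
                           rng_seed = 12)
  rep <- generate_repertoire(cfg)
  sim <- simulate_reads(rep, cfg)
  tr <- sim$truth
  src <- rep$sequences$sequence[match(tr$source_id, rep$sequences$source_id)]
  off1 <- cfg$run$shifter_offsets_r1[tr$index]
  for (i in sample.int(nrow(tr), 40)) {
    clean <- substr(paste0(substr("GACGGACCAGGCA", 1, off1[i]), src[i]),
                    1, cfg$run$read_len_r1)
    got <- strsplit(sim$r1$bases[i], "")[[1]]
    want <- strsplit(clean, "")[[1]]
    mism <- which(got != want)
    stated <- as.integer(strsplit(tr$error_positions_r1[i], ",")[[1]])
    if (length(stated) == 0) stated <- integer(0)
    expect_identical(mism, stated)
  }
})

test_that("identical config and seed give byte-identical FASTQ output", {
  cfg <- simulation_config(n_unique = 25, n_reads = 120, rng_seed = 77)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_run(simulate_reads(generate_repertoire(cfg), cfg), d1)
  write_simulated_run(simulate_reads(generate_repertoire(cfg), cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     info = f)
  }
})

test_that("phix reads carry the injected per-cycle error structure", {
  cfg <- simulation_config(error_spec = clean_error_spec(), rng_seed = 21)
  px <- simulate_phix(cfg, 300)
  prof0 <- compute_phix_profile(px$reads, px$reference)
  expect_true(all(prof0$pct_mismatch == 0))

  cfg2 <- simulation_config(
    error_spec = error_spec_default(baseline = 0, spikes = list(
      list(mate = "R1", cycles = 10:12, rate = 0.05))),
    rng_seed = 22)
  px2 <- simulate_phix(cfg2, 5000)
  prof2 <- compute_phix_profile(px2$reads, px2$reference)
  spike <- dplyr::filter(prof2, mate == "R1", cycle %in% 10:12)
  se <- 100 * sqrt(0.05 * 0.95 / 5000)
  expect_true(all(abs(spike$pct_mismatch - 5) < 3 * se))
  rest <- dplyr::filter(prof2, !(mate == "R1" & cycle %in% 10:12))
  expect_true(all(rest$pct_mismatch == 0))

  cfg3 <- simulation_config(
    error_spec = error_spec_default(baseline = 0.003, spikes = list()),
    rng_seed = 23)
  px3 <- simulate_phix(cfg3, 2000)
  prof3 <- compute_phix_profile(px3$reads, px3$reference)
  expect_equal(mean(prof3$pct_mismatch), 0.3, tolerance = 0.1)
})
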