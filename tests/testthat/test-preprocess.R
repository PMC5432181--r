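test_that("shifter trimming removes the per-index offsets", {
  cfg <- run_config()
  r_i3 <- make_read("AAACCCGGGTTTAAACCCGGG", mate = "R1", index = "i3")
  out <- trim_shifter(r_i3, cfg)
  expect_identical(out$bases, "GGTTTAAACCCGGG")  # first 7 dropped
  r_i1 <- make_read("AAACCCGGGTTT", mate = "R1", index = "i1")
  expect_identical(trim_shifter(r_i1, cfg)$bases, "AAACCCGGGTTT")  # offset 0
  r2_i1 <- make_read("AAACCCGGGTTTAAACCCG", mate = "R2", index = "i1")
  expect_identical(trim_shifter(r2_i1, cfg)$bases, "AACCCG")  # first 13
  # unknown index routed out and counted
  r_bad <- make_read("ACGTACGT", index = "i9")
  out2 <- trim_shifter(r_bad, cfg)
  expect_identical(nrow(out2), 0L)
  expect_identical(attr(out2, "unclassified"), 1L)
})

test_that("median-quality filter keeps >= 32 with lower-middle convention", {
  keep <- filter_median_quality(make_read("ACGTA", q = 40), 32)
  expect_identical(nrow(keep), 1L)
  drop <- filter_median_quality(make_read("ACGTA", q = 31), 32)
  expect_identical(nrow(drop), 0L)
  expect_identical(attr(drop, "dropped"), 1L)
  # quals [30,32,32,40]: lower-middle median = 32 -> keep
  r <- tibble::tibble(id = "x", bases = "ACGT",
                      quals = intToUtf8(c(30, 32, 32, 40) + 33),
                      mate = "R1", index = "i1")
  expect_identical(nrow(filter_median_quality(r, 32)), 1L)
})

test_that("fixed-length trim keeps prefixes and drops short reads", {
  r <- make_read(strrep("ACGTA", 70))  # 350 nt
  expect_identical(nchar(trim_fixed(r, 320)$bases), 320L)
  r2 <- make_read(strrep("AC", 125))   # 250 nt
  expect_identical(nchar(trim_fixed(r2, 220)$bases), 220L)
  short <- trim_fixed(make_read(strrep("A", 210)), 220)
  expect_identical(nrow(short), 0L)
  expect_identical(attr(short, "dropped"), 1L)
})

test_that("pair synchronization keeps the id intersection, order-stable", {
  mk <- function(ids) make_read(rep("ACGT", length(ids)), id = ids)
  out <- sync_pairs(mk(c("a", "b", "c")), mk(c("b", "c", "d")))
  expect_identical(out$r1$id, c("b", "c"))
  expect_identical(out$r2$id, c("b", "c"))
  expect_identical(attr(out, "orphans_r1"), 1L)
  empty <- sync_pairs(mk(c("a", "b")), mk(c("x", "y")))
  expect_identical(nrow(empty$r1), 0L)
  all_shared <- sync_pairs(mk(c("p", "q")), mk(c("q", "p")))
  expect_identical(all_shared$r1$id, all_shared$r2$id)
  expect_error(sync_pairs(mk(c("a", "a")), mk("a")), "duplicate")
})

test_that("pseudo-read joining concatenates r1 + revcomp(r2) with reversed quals", {
  cfg <- run_config(trim_r1 = 6L, trim_r2 = 4L, read_len_r1 = 20L,
                    read_len_r2 = 20L)
  r1 <- tibble::tibble(id = "p", bases = "AACCGG",
                       quals = intToUtf8(c(40, 40, 40, 40, 40, 40) + 33),
                       mate = "R1", index = "i1", shifter_offset = 0L)
  r2 <- tibble::tibble(id = "p", bases = "ACGT",
                       quals = intToUtf8(c(10, 20, 30, 39) + 33),
                       mate = "R2", index = "i1", shifter_offset = 0L)
  ps <- join_pseudo_reads(r1, r2, cfg)
  expect_identical(ps$bases, paste0("AACCGG", oracle_revcomp("ACGT")))
  expect_identical(utf8ToInt(ps$quals) - 33L,
                   c(40L, 40L, 40L, 40L, 40L, 40L, 39L, 30L, 20L, 10L))
  # cycle provenance: first position after the R1 block is the LAST R2 cycle
  cm <- pseudo_cycle_map(ps)
  expect_identical(cm$mate[7], "R2")
  expect_identical(cm$cycle[7], 4L)
  expect_identical(cm$cycle[1:6], 1:6)
  # length mismatch vs config is an error
  expect_error(join_pseudo_reads(r1, r1, cfg), "trimmed")
})

test_that("540 nt pseudo-reads arise from 320 + 220 trims and cycles map through shifters", {
  fx <- scfv_clean()
  expect_true(all(nchar(fx$pre$pseudo$bases) == 540))
  expect_true(all(nchar(fx$pre$pseudo$quals) == 540))
  # position 321 maps to the R2 trim length plus that index's shifter offset
  one <- fx$pre$pseudo[1, ]
  cm <- pseudo_cycle_map(one)
  expect_identical(cm$mate[321], "R2")
  expect_identical(cm$cycle[321],
                   220L + unname(fx$cfg$run$shifter_offsets_r2[one$index]))
  # cycle map is a bijection onto retained R1/R2 cycles
  expect_identical(anyDuplicated(cm[c("mate", "cycle")]), 0L)
})

test_that("zero-error preprocessing output substring-matches the truth", {
  fx <- scfv_clean()
  tr <- fx$sim$truth[match(fx$pre$pseudo$id, fx$sim$truth$read_id), ]
  src <- fx$rep$sequences$sequence[match(tr$source_id,
                                         fx$rep$sequences$source_id)]
  expect_identical(substr(fx$pre$pseudo$bases, 1, 320), substr(src, 1, 320))
  L <- nchar(src)
  expect_identical(substr(fx$pre$pseudo$bases, 321, 540),
                   substr(src, L - 219, L))
})

test_that("overlap merging resolves discordance by quality with forward tie-break", {
  cfg <- run_config(read_len_r1 = 40L, read_len_r2 = 40L, trim_r1 = 20L,
                    trim_r2 = 20L)
  set.seed(42)
  construct <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  a <- substr(construct, 1, 40)
  b_rc <- substr(construct, 21, 60)   # overlap = 20
  r1 <- tibble::tibble(id = "m", bases = a,
                       quals = intToUtf8(rep(38 + 33, 40)),
                       mate = "R1", index = "i1", shifter_offset = 0L)
  r2 <- tibble::tibble(id = "m", bases = oracle_revcomp(b_rc),
                       quals = intToUtf8(rep(38 + 33, 40)),
                       mate = "R2", index = "i1", shifter_offset = 0L)
  m <- merge_overlapping(r1, r2, min_overlap = 10)
  expect_identical(m$bases, construct)          # exact reconstruction
  expect_identical(nchar(m$bases), 40L + 40L - 20L)

  # discordant position: Q38 vs Q20 keeps the Q38 base
  bad <- b_rc
  substr(bad, 5, 5) <- if (substr(bad, 5, 5) == "A") "C" else "A"
  q2 <- rep(38L, 40); q2[40 - 5 + 1] <- 20L  # b position 5 = r2 cycle 36
  r2b <- tibble::tibble(id = "m", bases = oracle_revcomp(bad),
                        quals = intToUtf8(rev(q2) + 33),
                        mate = "R2", index = "i1", shifter_offset = 0L)
  m2 <- merge_overlapping(r1, r2b, min_overlap = 10)
  expect_identical(m2$bases, construct)         # error corrected
  # equal qualities, discordant: forward base kept, min quality assigned
  r2c <- tibble::tibble(id = "m", bases = oracle_revcomp(bad),
                        quals = intToUtf8(rep(38 + 33, 40)),
                        mate = "R2", index = "i1", shifter_offset = 0L)
  m3 <- merge_overlapping(r1, r2c, min_overlap = 10)
  expect_identical(substr(m3$bases, 25, 25), substr(construct, 25, 25))
  expect_identical(utf8ToInt(m3$quals)[25] - 33L, 38L)
  # no acceptable overlap -> pair discarded and counted
  r2far <- tibble::tibble(id = "m",
                          bases = paste(rep("A", 40), collapse = ""),
                          quals = intToUtf8(rep(38 + 33, 40)),
                          mate = "R2", index = "i1", shifter_offset = 0L)
  m4 <- merge_overlapping(r1, r2far, min_overlap = 35)
  expect_identical(nrow(m4), 0L)
  expect_identical(attr(m4, "dropped"), 1L)
})

test_that("adapter-dimer purge drops near-exact adapter prefixes", {
  adapter <- "GATCGGAAGAGC"
  dimer <- make_read(paste0(adapter, "ACGTACGT"), id = "d")
  one_mm <- dimer
  substr(one_mm$bases, 3, 3) <- "A"
  clean <- make_read(strrep("CA", 12), id = "c")
  out <- purge_adapter_dimers(dplyr::bind_rows(dimer, one_mm, clean), adapter)
  expect_identical(out$id, "c")
  expect_identical(attr(out, "dropped"), 2L)
})

test_that("pipeline conserves reads across drop reasons", {
  fx <- vh_spiky()
  log <- fx$pre$log
  n_in <- log$n[log$stage == "input_pairs"]
  kept <- log$n[log$stage == "kept_pairs"]
  # a pair is lost when its R1 is dropped (unclassified/low-quality), when
  # only its R2 is dropped (the R1 becomes an orphan), or when merging fails
  drops <- sum(log$n[log$stage %in% c("unclassified_r1", "low_quality_r1",
                                      "orphans_r1", "merge_failed")])
  expect_identical(n_in, kept + drops)
})
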