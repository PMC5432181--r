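test_that("seed extraction follows the 1-based end-exclusive convention", {
  ps <- tibble::tibble(bases = strrep("ACGTAACCGGTTACGATCGA", 30))  # 600 nt
  s <- extract_seed(ps, seed_spec())  # (280,300)+(470,490)
  expect_identical(nchar(s), 40L)
  expect_identical(s, paste0(substr(ps$bases, 280, 299),
                             substr(ps$bases, 470, 489)))
  s1 <- extract_seed(ps, seed_spec(list(c(280L, 300L))))
  expect_identical(nchar(s1), 20L)
  # region covering the whole read degenerates to exact dedup on the read
  whole <- extract_seed(tibble::tibble(bases = "ACGTACGT"),
                        seed_spec(list(c(1L, 9L))))
  expect_identical(whole, "ACGTACGT")
  # short reads excluded
  shorty <- extract_seed(tibble::tibble(bases = "ACGT"), seed_spec())
  expect_true(is.na(shorty))
})

test_that("seed grouping equals a brute-force dictionary partition", {
  set.seed(7)
  seeds <- sample(c("AAAA", "CCCC", "GGGG"), 50, TRUE)
  bases <- paste0(seeds, replicate(50, paste(
    sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")))
  ps <- tibble::tibble(id = as.character(1:50), bases = bases)
  g <- group_by_seed(ps, seed_spec(list(c(1L, 5L))))
  oracle <- split(ps$id, substr(ps$bases, 1, 4))
  got <- split(g$id, g$seed)
  expect_identical(got[order(names(got))], oracle[order(names(oracle))])
  # degenerate partitions
  all_same <- run_deal(tibble::tibble(id = as.character(1:5),
                                      bases = rep("AAAATTTT", 5)),
                       seed_spec(list(c(1L, 5L))))
  expect_identical(all_same$seed_complexity, 1L)
  all_diff <- run_deal(tibble::tibble(id = as.character(1:4),
                                      bases = c("AAAA", "CCCC", "GGGG",
                                                "TTTT")),
                       seed_spec(list(c(1L, 5L))))
  expect_identical(all_diff$complexity, 4L)
})

test_that("the three merge scenarios behave as specified", {
  n4 <- rep(FALSE, 4)
  # mismatching: one unflagged discordant position -> no grouping
  expect_null(merge_pair("ACGT", n4, "ACTT", n4))
  # one side flagged: resolved to the unflagged base, flag cleared
  m <- merge_pair("ACGT", n4, "ACTT", c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(m$bases, "ACGT")
  expect_identical(m$flags, n4)
  # flagged consensus against unflagged read resolves the other way too
  m2 <- merge_pair("ACGT", c(FALSE, FALSE, TRUE, FALSE), "ACTT", n4)
  expect_identical(m2$bases, "ACTT")
  expect_identical(m2$flags, n4)
  # both flagged: IUPAC union, position stays flagged (G u T = K)
  m3 <- merge_pair("ACGT", c(FALSE, FALSE, TRUE, FALSE),
                   "ACTT", c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(m3$bases, "ACKT")
  expect_identical(m3$flags, c(FALSE, FALSE, TRUE, FALSE))
  # accumulating a third base widens the ambiguity code ({G,T} u A = D)
  m4 <- merge_pair(m3$bases, m3$flags, "ACAT",
                   c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(m4$bases, "ACDT")
  expect_identical(m4$flags, c(FALSE, FALSE, TRUE, FALSE))
  # a later reliable conflicting base forces a split (flag was cleared)
  expect_null(merge_pair(m$bases, m$flags, "ACTT", n4))
  expect_error(merge_pair("ACGT", n4, "ACG", rep(FALSE, 3)), "equal-length")
})

test_that("additional flags never turn a MATCH into a MISMATCH", {
  set.seed(31)
  for (case in 1:60) {
    L <- 12
    a <- sample(c("A", "C", "G", "T"), L, TRUE)
    b <- a
    flip <- sample.int(L, sample(0:3, 1))
    b[flip] <- sample(c("A", "C", "G", "T"), length(flip), TRUE)
    af <- runif(L) < 0.3
    bf <- runif(L) < 0.3
    # make it a MATCH: flag every genuinely discordant position on one side
    disc <- a != b
    bf[disc] <- TRUE
    res <- merge_pair(paste(a, collapse = ""), af,
                      paste(b, collapse = ""), bf)
    expect_false(is.null(res))
    # add extra flags anywhere: still a MATCH
    af2 <- af | (runif(L) < 0.4)
    bf2 <- bf | (runif(L) < 0.4)
    expect_false(is.null(merge_pair(paste(a, collapse = ""), af2,
                                    paste(b, collapse = ""), bf2)))
  }
})

test_that("clustering with no flags equals exact deduplication", {
  set.seed(13)
  pool <- replicate(30, paste(sample(c("A", "C", "G", "T"), 25, TRUE),
                              collapse = ""))
  bases <- sample(pool, 400, TRUE)
  cl <- cluster_group(bases, lapply(1:400, function(i) rep(FALSE, 25)))
  expect_identical(sort(cl$consensus), sort(unique(bases)))
  expect_identical(sum(cl$cardinality), 400L)
  tab <- table(bases)
  expect_identical(cl$cardinality[match(names(tab), cl$consensus)],
                   as.integer(tab))
})

test_that("run_deal conserves reads and separates seed groups", {
  fx <- vh_spiky()
  d <- run_deal(fx$pseudo, seed_spec_vh())
  expect_identical(sum(d$clusters$cardinality), d$n_reads)
  expect_identical(sum(d$group_sizes), d$n_reads)
  # reads in different seed groups never share a cluster
  expect_identical(anyDuplicated(unlist(d$clusters$members)), 0L)
  # consensus invariants: ambiguity codes only at flagged positions
  for (i in seq_len(nrow(d$clusters))) {
    amb <- !(charToRaw(d$clusters$consensus[i]) %in% charToRaw("ACGT"))
    expect_true(all(d$clusters$flags[[i]][amb]))
  }
})

test_that("error compensation recovers the true complexity exactly", {
  fx <- vh_spiky()
  d <- run_deal(fx$pseudo, seed_spec_vh())
  truth <- length(unique(fx$sim$truth$source_id))
  expect_identical(d$complexity, truth)
  # without flag information the same reads over-split
  naive <- run_deal(dplyr::select(fx$pseudo, -"flags"), seed_spec_vh())
  expect_gt(naive$complexity, truth)
})

test_that("unflagged errors only ever inflate the estimate, as singletons", {
  cfg <- simulation_config(
    n_unique = 150, n_reads = 1200, construct = "scfv",
    abundance_model = abundance_uniform(),
    error_spec = error_spec_default(baseline = 1e-3, spikes = list()),
    rng_seed = 303)
  rep <- generate_repertoire(cfg)
  sim <- simulate_reads(rep, cfg)
  pre <- preprocess_run(sim$r1, sim$r2, cfg$run, mode = "scfv")
  d <- run_deal(pre$pseudo, seed_spec())  # no flags at all
  truth <- length(unique(sim$truth$source_id))
  expect_gte(d$complexity, truth)
  h <- cardinality_histogram(d)
  expect_lte(minimal_complexity(h), truth)
  excess <- d$complexity - truth
  singles <- sum(h$n_clusters[h$cardinality == 1])
  expect_gte(singles, 0.95 * excess)
})

test_that("deal is deterministic given input order and order-sensitive by contract", {
  fx <- vh_spiky()
  d1 <- run_deal(fx$pseudo, seed_spec_vh())
  d2 <- run_deal(fx$pseudo, seed_spec_vh())
  expect_identical(d1$clusters$consensus, d2$clusters$consensus)
  expect_identical(d1$complexity, d2$complexity)
})

test_that("empty input yields zero complexity with a warning", {
  expect_warning(d <- run_deal(tibble::tibble(id = character(0),
                                              bases = character(0))),
                 "no input")
  expect_identical(d$complexity, 0L)
})
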