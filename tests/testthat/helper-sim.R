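# Shared fixtures, built in code and memoised per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# error spec whose substitutions are confined to spiked cycles (all > 1%),
# away from the seed-region cycles
spiky_error_spec <- function(rate = 0.05) {
  error_spec_default(baseline = 0, spikes = list(
    list(mate = "R1", cycles = 15:20, rate = rate),
    list(mate = "R2", cycles = 10:14, rate = rate)
  ))
}

clean_error_spec <- function() error_spec_default(baseline = 0, spikes = list())

# tiny error-free scFv run + preprocessing
scfv_clean <- function() fixture("scfv_clean", function() {
  cfg <- simulation_config(n_unique = 60, n_reads = 500, construct = "scfv",
                           abundance_model = abundance_uniform(),
                           error_spec = clean_error_spec(), rng_seed = 101)
  rep <- generate_repertoire(cfg)
  sim <- simulate_reads(rep, cfg)
  pre <- preprocess_run(sim$r1, sim$r2, cfg$run, mode = "scfv")
  list(cfg = cfg, rep = rep, sim = sim, pre = pre)
})

# tiny VH run with spike-confined errors, plus measured profile
vh_spiky <- function() fixture("vh_spiky", function() {
  cfg <- simulation_config(n_unique = 120, n_reads = 800, construct = "vh",
                           abundance_model = abundance_uniform(),
                           error_spec = spiky_error_spec(), rng_seed = 202)
  rep <- generate_repertoire(cfg)
  sim <- simulate_reads(rep, cfg)
  phix <- simulate_phix(cfg, 3000)
  profile <- compute_phix_profile(phix$reads, phix$reference)
  pre <- preprocess_run(sim$r1, sim$r2, cfg$run, mode = "vh")
  pseudo <- flag_unreliable(pre$pseudo, profile)
  list(cfg = cfg, rep = rep, sim = sim, profile = profile, pre = pre,
       pseudo = pseudo)
})

# independent reverse-complement oracle (rev + chartr, no Biostrings)
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# flat error profile at a given percent for both mates
flat_profile <- function(pct, max_cycle = 600) {
  p <- dplyr::bind_rows(
    tibble::tibble(mate = "R1", cycle = 1:max_cycle, pct_mismatch = pct,
                   n = 1000L),
    tibble::tibble(mate = "R2", cycle = 1:max_cycle, pct_mismatch = pct,
                   n = 1000L))
  class(p) <- c("error_profile", class(p))
  p
}

make_read <- function(bases, q = 40, id = "r1", mate = "R1", index = "i1") {
  tibble::tibble(id = id, bases = bases,
                 quals = vapply(nchar(bases), function(L)
                   intToUtf8(rep(q + 33L, L)), character(1)),
                 mate = mate, index = index)
}
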