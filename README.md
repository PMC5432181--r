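# dealr — error-compensated diversity estimation for antibody libraries

`dealr` estimates the complexity (diversity) of an antibody library — the
number of distinct coding sequences it contains — from paired-end Illumina
sequencing, while compensating for technical sequencing error. It is aimed
at groups building and quality-controlling display libraries (scFv,
single-domain VH) who need a defensible complexity number rather than a
naive distinct-read count.

## The method

Deduplicating reads of a library with no genome reference fails in both
directions: exact deduplication inflates complexity (nearly every long read
carries a miscalled base), and percent-identity clustering erases genuine
point diversity. `dealr` instead collapses reads by *flag-aware identity*:

1. **Flagging.** A position is unreliable iff its Phred score is below 32
   (error probability above 10^-3.2), or the empirical error rate of its
   sequencing cycle — measured by aligning Phi-X control spike-in reads to
   their known reference — exceeds 1%, or the base is an N/ambiguity code.
   Both signals are required because reported Phred is miscalibrated in the
   early cycles while the Phi-X profile is only a per-cycle aggregate.
2. **Seeding.** Reads are partitioned by exact identity of a short seed
   taken from the hypervariable CDR3 window(s) (default 280–300 and 470–490
   on the 540-nt scFv pseudo-read; 280–300 for VH).
3. **Flag-aware collapse.** Within a seed group each read is compared
   position-wise against existing cluster consensi: a disagreement between
   two *unflagged* bases is a real mismatch; if exactly one side is flagged
   the reliable base wins and the flag is cleared; if both are flagged the
   consensus records the IUPAC union (e.g. G ∪ T → K) and stays flagged.

The cluster count is the sample complexity; clusters of cardinality ≥ 2 are
the *minimal* complexity (singletons absorb uncorrectable errors). Writing
`Nseq(x)` for the number of clusters of cardinality `x`, the *theoretical*
complexity `C` — including the unsampled part of the library — is estimated
by nonlinear least squares on the truncated model

    Nseq(x) ~ C * NB_{p,s}(x),     x ≥ 2

with the negative-binomial mass function `NB_{p,s}`. Protein-level
complexity (VH mode) is obtained by in-silico translation of cluster
consensi with frame classification by length, definite/possible stop-codon
calls under IUPAC expansion, and synonym collapse with `X` wildcards.
Primer-class assignment and observed-vs-expected (product of marginals)
assortment tables diagnose chain/VDJ independence.

A synthetic read simulator with full truth tables (repertoire generator,
cycle-indexed error spikes, miscalibrated Phred reporting, Phi-X-like
control, vector-backbone contaminant) makes every stage testable; see the
methods vignette (`vignettes/diversity-estimation.Rmd`).

## A worked example

```r
library(dealr)

cfg <- simulation_config(n_unique = 100, n_reads = 600, construct = "vh",
                         error_spec = error_spec_default(baseline = 0,
                           spikes = list(list(mate = "R1", cycles = 15:20, rate = 0.05),
                                         list(mate = "R2", cycles = 10:14, rate = 0.05))),
                         rng_seed = 3)
res <- run_pipeline("vh-demo", cfg)
res$deal
```

```
DEAL result
  reads clustered:    600 
  seed complexity:    96 
  sample complexity:  96  clusters
  minimal complexity: 86  (cardinality >= 2)
```

600 reads drawn from 96 distinct sampled sequences, carrying ~5%
substitution errors confined to spiked cycles, collapse to exactly 96
clusters: every error sits on a flagged position and is absorbed during
merging (a naive exact dedup of the same reads yields several hundred
"distinct" sequences). The 86 clusters seen at least twice form the lower
bound; the remaining 10 sampled sequences happened to be read once.

```r
res$fit        # truncated negative-binomial complexity estimate
glance(res$deal); autoplot(res$histogram); autoplot(res$assortment)
```

For a full-scale VH analysis (`n_unique = 5000`, 30k reads) the same
pipeline recovers the sampled complexity exactly and reports an in-frame
fraction of ~86.7% and a stop-free upper bound of ~89.7% under the default
composition (13.4% frameshifted, 10% stop-carrying).

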