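---
title: "Error-compensated diversity estimation for antibody libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-compensated diversity estimation for antibody libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dealr)
library(dplyr)
```

## The problem

The key quality parameter of an antibody library — phage/yeast display, scFv
or single-domain — is its *complexity*: the number of distinct coding
sequences it contains, which governs the probability that a selection will
yield a binder of useful affinity. Deep sequencing can in principle count
distinct sequences directly, but two obstacles intervene:

1. **Technical error.** At per-base error rates of a few per mille, almost
   every read of a 400–750 nt construct carries at least one miscalled base.
   Naive deduplication therefore overestimates complexity severely, while
   similarity-threshold clustering (e.g. 96% identity) erases genuine
   point diversity, which in an antibody library is biologically meaningful
   anywhere in the V region.
2. **No reference.** V(D)J-rearranged sequences have no genome to correct
   against, so errors cannot be fixed by alignment.

`dealr` implements a quality-aware identity collapse (DEAL): positions whose
base call cannot be trusted are *flagged* and excluded from the
identical/different decision, while every unflagged position must match
exactly. Two independent signals decide trust, because neither suffices
alone:

* the per-base **Phred score** (threshold: Q < 32, i.e. error probability
  above $10^{-3.2}$), which is a per-base but unreliably calibrated signal —
  in the early cycles of a run the reported Q carries little information
  about the true error rate; and
* the **per-cycle empirical error rate** measured from Phi-X control
  spike-in reads aligned to their known reference (threshold: > 1%
  mismatches at that cycle), which is well calibrated but only a per-cycle
  aggregate.

A position is unreliable if it fails either check, or if its base is an N or
an ambiguity code.

## The DEAL procedure

Reads are first partitioned by a short *seed* — the concatenation of one or
two windows placed over the hypervariable CDR3 region(s) (defaults:
positions 280–300 and 470–490 of the 540-nt scFv pseudo-read; 280–300 alone
for VH). Intervals are 1-based and end-exclusive, so each default window
contributes 20 nt. Seeding is exact-match partitioning (the original
implementation uses a binary tree; any exact partition is equivalent) and
deliberately ignores flags: an error inside a seed makes that read found its
own group, where it ends up as a singleton — a conservative failure mode.

Within a seed group, each read is compared to the existing cluster consensi
in creation order and joins the first match (greedy, order-dependent, with
input order preserved from file order as part of the contract). The
position-wise comparison has three outcomes:

* both sides unflagged and different → **mismatch**, no merge;
* exactly one side flagged → merge, the position takes the *unflagged*
  side's base and the flag is cleared (any previously accumulated ambiguity
  at that position is resolved by the reliable observation — a later
  reliable conflict then forces a split rather than silently widening the
  ambiguity);
* both sides flagged → merge, the position takes the IUPAC code of the
  union of the two base sets and stays flagged. Three or more accumulated
  bases extend naturally to B/D/H/V/N.

The total cluster count is the sample complexity. The cluster count with
cardinality ≥ 2 is the *minimal* complexity: singletons mix genuine rare
members with reads whose errors were not accompanied by any quality signal
and which therefore cannot cluster, so they are excluded from the lower
bound.

An incoming read is compared against the merged *consensus*, not against
every individual prior member; the published description is ambiguous on
this point and the consensus choice is the scalable one.

## Theoretical complexity

Sampling depth rarely covers an entire library, so observed clusters
undercount. Writing $N_{seq}(x)$ for the number of clusters of cardinality
$x$, the package models

$$N_{seq}(x) \sim C \cdot \mathrm{NB}_{p,s}(x)$$

with the (untruncated) negative-binomial mass function, and estimates
$(C, p, s)$ by nonlinear least squares on the counts over
$x \in [x_{\min}, x_{\max}]$. Because the mass function includes the
unobserved zero class, $\hat C$ estimates *total* complexity, and may
legitimately exceed the observed cluster count. Numerical choices:

* $x_{\min} = 2$ by default — the inflated singleton class would otherwise
  bias $C$ upward ($x_{\min} = 1$ is available and demonstrably worse on
  singleton-inflated simulations);
* Levenberg–Marquardt (`minpack.lm::nls.lm`) on the unconstrained
  parametrization $(\log C, \log s, \mathrm{logit}\, p)$, multi-started
  from a coarse 5 × 5 grid over $p \in [0.1, 0.9]$, $s \in [0.5, 6]$, best
  residual sum of squares wins; a least-squares objective (not MLE) is used,
  matching the regression-fit framing of the method;
* the fit is scale-equivariant: multiplying all counts by $k$ multiplies
  $\hat C$ by $k$ and leaves $(p, s)$ unchanged.

Before fitting, high-cardinality outliers are removed: clusters whose
log-cardinality exceeds median + 3.5 × MAD (with a MAD floor of
$\log(2)/2$ so that degenerate, near-uniform histograms flag nothing). A
single dominant outlier is typically undigested vector backbone; when the
backbone sequence is known the outlier is annotated by 20-mer containment
(≥ 50% of the consensus 20-mers occur in the backbone), a criterion chosen
because an scFv pseudo-read concatenates two non-contiguous blocks of its
source and therefore never matches the backbone as one ungapped interval.

## Protein-level diversity

For constructs short enough that the mates overlap (VH single domains), the
merged reads cover the whole CDS and are translated in silico. Frame class
is determined by length alone — the construct geometry fixes the first codon
at a constant offset from the 5' restriction-site anchor, so
$(\mathrm{length} - \mathrm{anchor}) \bmod 3$ classifies in-frame / +1 / +2.
Stop codons are scanned per codon under IUPAC expansion, only inside the CDS
(the terminal anchor is excluded):

* every expansion a stop → **definite** stop;
* some but not all expansions stops → **possible** stop (an
  ambiguity-flagged position could hide either reading);
* translation emits the unique non-stop residue when all non-stop
  expansions agree, `*` for definite stops, and `X` otherwise.

Synonymous clusters are aggregated by amino-acid identity with `X` matching
any single residue (never a stop); a strict-identity mode exists for
comparison. Because wildcard identity is not transitive, grouping is greedy
first-match in input order, exactly like the nucleotide stage. The
functional complexity is reported as a range: the upper bound excludes only
definite stops, the lower bound also excludes possible stops. If both chains
of a two-chain construct independently had per-chain functional fraction
$f$, the expected two-chain functional fraction is $f^2$; the package
reports this as an explicitly labelled independence assumption, not a
measurement.

## Primer classes and assortment

Sequences are assigned to forward/reverse primer classes by anchored
mismatch counting at the respective end (IUPAC-degenerate primer bases match
any expansion; the constant anchor outside the primer site is skipped via
the `offset` argument). The best class wins only if it is within the
mismatch tolerance (default 2) and untied — ties go to `UC` (unclassified)
rather than inflating an arbitrary class. The observed joint distribution of
(forward, reverse) classes is compared with the outer product of the
classified marginals; per-cell $\log_2(\mathrm{obs}/\mathrm{exp})$ values
and a descriptive chi-square summarize departures from independent
chain/VDJ assortment.

## The simulator and what it does (not) show

All validation runs on simulated data with full truth tables, because the
method's claims are about recovering known quantities. The generator
emulates:

* a repertoire of `n_unique` pairwise-distinct constructs with a fixed
  scaffold geometry — 5' anchor (10 nt), class-specific forward primer site
  (24 nt), constant framework, hypervariable CDR3 (length-varied to control
  frame class; stop codons sampled out or planted to control the stop
  fraction), class-specific reverse primer site (22 nt), 3' anchor (8 nt).
  scFv constructs (~750 nt, mates do not overlap; joined into 540-nt
  pseudo-reads) add a linker and a second (light-chain) CDR3 placed so both
  default seed windows fall on hypervariable sequence;
* abundance laws: zero-truncated negative binomial (the family the
  complexity fit assumes; default NB(p = 0.3, s = 1.5)), log-normal, or
  uniform — the true abundance law of a real library is unknown, so it is a
  configuration choice, not an assertion;
* an Illumina-like paired run: per-index shifter bases (R1 offsets 0/1/7/8,
  R2 offsets 13/12/11/10 for the four barcodes), 350/250 cycles,
  cycle-indexed substitution spikes over a baseline rate (default 0.34%,
  with 2% spikes in early cycles), and a Phred-reporting model in which the
  first 40 cycles report a quality drawn independently of the true error
  rate (the miscalibration regime that motivates the dual flagging);
* a Phi-X-like control: reads drawn from a fixed 5386-nt synthetic
  reference through the same error process. The bundled reference is a
  synthetic stand-in, not the Phi-X174 genome; the profiling machinery only
  requires a known constant reference.
* defaults for composition match the study conditions the package targets:
  13.4% frameshifted, 10% of in-frame sequences carrying a stop.

Deliberately not modeled: indels (negligible on this platform — all
alignment in the package is ungapped on that assumption), PCR chimeras,
per-tile spatial effects, cluster-density optics. Consequently, passing
tests demonstrate correct error *compensation logic* under substitution
noise with miscalibrated qualities — they do not certify behavior on data
with indels or amplification artifacts, and a real library's unknown
abundance law means the NB fit's 15%-level accuracy observed in simulation
is a property of NB-generated data, not a guarantee.

Problem sizes used by the test-suite and the acceptance script (5,000
unique sequences, 20–30k reads, 5,000 Phi-X reads per mate, NB fits at
$10^5$ true sequences over 10 seeds) were chosen as the smallest scales at
which the sampling noise of each claim is comfortably below its assertion
threshold.

## Degenerate inputs and tie-breaks

* Median Phred of an even-length read: lower middle value (conservative).
* Overlap-merge quality tie at a discordant position: the forward base is
  kept and the position gets the *minimum* of the two qualities, so it is
  likely flagged downstream — uncertainty is propagated, not hidden.
* Cycles with zero Phi-X observations are flagged (fail-unsafe), since the
  whole design premise is that Phred alone cannot be trusted.
* Phi-X reads whose best ungapped placement falls below 70% identity are
  excluded as non-control contamination (the exact cutoff is a logged
  default).
* Variable-length inputs (VH mode): reads of different lengths never merge;
  they can share a seed group but always mismatch.
* Empty input yields complexity 0 with a warning; an all-`UC` assortment is
  an error.

## A worked example

```{r example, eval = FALSE}
library(dealr)

cfg <- simulation_config(n_unique = 1000, n_reads = 8000, construct = "vh",
                         rng_seed = 7)
res <- run_pipeline("vh-demo", cfg)

glance(res$deal)            # reads, seed complexity, clusters, minimal
res$fit                     # truncated NB fit: p, s, C
res$protein$summary         # frame / stop / functional ranges
autoplot(res$histogram)     # cluster-cardinality distribution
autoplot(res$profile)       # per-cycle Phi-X error rate
autoplot(res$assortment)    # log2(obs/exp) heatmap
```

## Known limitations

* Greedy first-match clustering is order-dependent; reordering input can
  change cluster boundaries in edge cases (the report records input order).
* The seed ignores flags, so errors inside seed windows always cost a
  singleton; the published method shares this property.
* `C` from the NB fit inherits all caveats of the parametric family; the
  package reports the observed cluster count and the ratio alongside it.
* Protein wildcard grouping can chain X-containing sequences to the first
  compatible group rather than the globally best one.
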