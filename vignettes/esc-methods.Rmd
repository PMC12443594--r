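---
title: "Models and methods for excised signal circle analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for excised signal circle analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esctools)
```

# Background

Deletional V(D)J recombination excises the DNA between a V and a J gene
segment as a circle. The circle carries the **signal joint (SJ)** — the two
recombination signal sequence (RSS) heptamers fused head-to-head — while
the chromosome keeps the matching **coding (recombination) junction**.
Because one recombination event creates exactly one circle and one
footprint, the footprint's copy number records how many cell divisions have
elapsed since the event, and the SJ:footprint ratio measures whether the
circle has been diluted (the classical assumption) or replicated.

`esctools` provides the computational machinery for this analysis: junction
reference databases and LAM amplicon calling, divergent-read SJ detection
from paired-end WGS, replication/persistence inference, and cryptic-RSS
classification of structural variants (SVs) — all testable against a
synthetic-data generator whose ground truth is known exactly.

# The locus model

`locus_config()` / `build_locus()` create a toy immunoglobulin
light-chain-style locus: `n_v` V segments each flanked 3′ by a 12-RSS,
`n_j` J segments flanked 5′ by a 23-RSS, an intronic 12-RSS, a constant
exon, and a kappa-deleting element (KDE) carrying a 23-RSS that points
upstream. Coordinates are 0-based half-open (BED-compatible) throughout.
An RSS is heptamer + spacer + nonamer; the spacer class is 12 or 23 with
±1 bp tolerated, and recombination requires unlike classes (the 12/23
rule). The consensus motifs `CACAGTG` / `ACAAAAACC` are used for synthesis
and are overridable in the config.

**Topology.** A pair recombines *deletionally* when its heptamers face
each other (convergent): the join excises the intervening DNA as a circle.
Any other orientation is *inversional*: the junction forms by inversion and
the SJ stays chromosomal. `enumerate_junctions()` therefore creates coding
entries for every valid pair but signal entries only for deletional pairs;
V-to-V ("intra-KV") joins are never enumerated, matching the assays, which
prime from J regions and cannot see them. Signal references are written
J-side flank first, then the V-side signal end — the orientation in which
a J-RSS-primed amplicon reads across the joint — with the junction at
`junction_offset`. A structural identity ties everything together: for any
deletional pair, coding join + excised circle reconstruct the unrecombined
allele exactly (`reconstruct_allele()`), which the test suite asserts for
every entry.

The default flank length is 60 bp per side: long enough for the
seeded aligner's seeds and identity window, short enough that neighbouring
segments never overlap a reference. It is a free parameter of
`enumerate_junctions()`.

# The synthetic world

`sim_config()` fixes the stated world of all generators:

* WGS fragments average 500 bp (sd 60) with 35–50 bp sequenced per end
  (default 45) — the geometry under which a circle-spanning fragment maps
  divergently.
* LAM amplicons are 2 × 250 bp overlapping read pairs over a 320 bp
  amplicon whose junction sits mid-amplicon.
* Circles duplicate at most once per cell cycle with probability
  `esc_replication_prob` (r), then segregate **binomially** — the circles
  are acentric, so each copy picks a daughter independently. An `even`
  mode (deterministic near-equal split, remainder to daughter 1) exists
  for analytic tests: with one copy and r = 0 it realises the textbook
  `1/2^t` dilution exactly.
* Chromosomal junctions are inherited by every descendant, so a clone of
  age t has exactly `2^t` footprint copies — the bookkeeping the
  replication inference relies on.
* Per-junction LAM amplification efficiency is lognormal (sd 0.2). The
  source assays give no noise model; this is a synthetic-only choice that
  makes rank-based comparisons honest rather than trivially exact.
* Substitution sequencing errors only (no indels); base qualities are a
  constant Phred 30 since the pipeline uses quality only to break
  overlap-merge disagreements.

Founders acquire one primary deletional event (uniform over the deletional
pairs unless restricted) and, with probability `secondary_prob`, a
secondary event on the other allele biased to the KDE join — a nod to
receptor editing. Coding joins carry a random 0–8 bp junctional insert so
clonotypes are distinguishable.

**What a green test does not establish.** The generator has no PCR
chimeras, no indel errors, no selection (a fitness effect of high ESC copy
number is deliberately out of scope), no inter-locus events, and its
background genome is i.i.d. random sequence. Detector performance on real
data therefore cannot be inferred from these tests; what they do establish
is that each algorithm recovers the truth its own model generates, with
the failure modes (shared flanks, breakpoint uncertainty, chance RSS hits)
that the model does produce.

For structural variants, `simulate_sv_set()` plants consensus cRSS motifs
within ±50 bp of zero, one or both breakpoint sides at exactly the
configured proportions (largest-remainder allocation, so class counts are
deterministic). `none`-class breakpoints are drawn only at positions whose
windows are free of chance hits at the scanner threshold, making planted
labels exact ground truth. Insertion records are given two distinct clean
anchor coordinates: with a single coordinate both breakpoint "sides" would
share one window and a single-cRSS insertion could not exist.

# WGS signal-joint detection

A fragment that spans the circular junction maps to the linear reference
as an outward-facing (**divergent**) pair: the leftmost mate on the minus
strand at the circle start, the rightmost on the plus strand at the circle
end. `classify_pair()` distinguishes concordant (inward, insert within
mean ± 4 sd), divergent, inward-but-distal, same-strand and
interchromosomal pairs; the wording of field descriptions varies between
"reads point towards each other" and "divergent reads" in the literature,
and this implementation follows the divergent (outward) convention while
still counting inward distal pairs separately so both are auditable.

`detect_sj_candidates()` clusters divergent pairs whose mates both fall in
the configured antigen-receptor regions, greedily in two dimensions (both
boundary estimates within `merge_distance`, default 1 kb — distinct
junctions must be separated by more than this, which holds for real loci
and for the wide-gap test locus). Candidates below `min_support` (2) are
dropped. `refine_with_split_reads()` upgrades a candidate to exact
resolution by majority vote over split-read junctions, ties to the lower
coordinate. Database matching uses 10 bp tolerance for exact candidates
and a fragment-scale 200 bp for interval-only ones: a pair-only boundary
estimate is biased inward by up to a fragment length, and a circle can
draw zero split reads by chance (about three are expected per circle at
20× with 45 bp reads).

Detection is presence/absence by design: at realistic WGS depth an SJ is
seen only if a fragment happens to span it, so no quantification is
attempted from WGS.

# LAM junction calling

The pipeline mirrors the targeted assays: reads are demultiplexed by their
5′ nested J (or J-RSS) primer within `max_mismatch` (1) substitutions,
ties going to an unassigned bin; pairs are merged by the best-scoring
ungapped 3′/5′ overlap (minimum 20 bp, mismatch rate ≤ 0.1, disagreements
resolved by base quality, read 1 winning ties) with fall-back to read 1
alone; merged reads are assigned to junction database entries by a seeded,
banded Smith–Waterman (match 2, mismatch −2, linear gap 3; 12-mer seeds
sampled every 4 bp; band half-width 32 around the modal seed diagonal).
An assignment requires identity ≥ 0.9 over a reference span ≥ 50 bp that
crosses the junction point; equal best scores on different entries are
ambiguous and unassigned. Candidates with fewer than half the top
candidate's seed count are not aligned — entries sharing only one flank
with the read carry far fewer seeds than the true entry, and the
exhaustive-alignment equivalence is verified in the acceptance suite.

Quantification divides each junction's reads by the **total assay reads in
the experiment** (assigned + unassigned); an assigned-only denominator is
available behind `denominator = "assigned"`. The detection threshold is
the highest normalized junction level across healthy-control experiments,
and samples count as positive only strictly above it, so the controls
define zero positives by construction.

The identity/span cut-offs are not stated by the source assays; the
defaults above are exposed as parameters and reported in the run manifest.

# Replication and persistence inference

* `estimate_divisions()`: `n = log2(N2/N1)` from the doubling formula
  `N2 = N1·2^n`; divisions may be fractional and are never rounded.
* `predicted_sj()`: pure-dilution prediction `x_t = x_0/2^t`; after six
  divisions 1.5625% of the starting level remains —
  `r predicted_sj(100, 6)$xt` percent.
* `observed_over_predicted()`: ≈ 1 under pure dilution, > 1 with
  replication/persistence. `replication_ratios()` computes this per event
  from a simulated truth: observed per-cell SJ level over `1/2^t`, with
  `t` inferred from the footprint copies. A `max_divisions` filter (the
  "≤ 6 relative divisions" rule) restricts ratio aggregation to recent
  events; measurement is exact by default with an optional Poisson
  counting-noise mode.
* `select_recent_events()` keeps junctions at ≤ 0.2 normalized
  recombination reads (inclusive).
* `detect_major_events()` sorts junctions by normalized reads and puts the
  knee at the maximal discrete gradient `y_i − y_{i+1}` (ties to the
  smallest index; a single junction is major; a uniform distribution puts
  the knee at index 1). The gradient is taken on the linear scale by
  default — the source describes only "plots of the distribution of
  sequencing reads" — with a log-scale option.
* `extract_clonotypes()` takes two 5-bp anchor motifs, each starting 25 bp
  from the nominal V–J boundary (5 bp of reference, then 20 bp omitted to
  the boundary, on each side), and collapses identical intervening
  sequences into clonotypes by exact string identity; reads lacking an
  anchor, or with a non-unique anchor, are discarded and counted. No
  error-tolerant collapsing is applied by default since clonotype identity
  is defined by the exact insert.
* `clonotype_division_profile()` converts clonotype fractions to cells via
  absolute event copies (one recombination copy = one cell, single-allele
  assumption) and then to divisions.

# Cryptic RSS scanning and SV mechanism

`scan_rss()` is a log-odds position-weight-matrix scan seeded from the
canonical heptamer/nonamer consensus (consensus probability 0.79,
background uniform; `N` scores 0). Both strands are scanned; the nonamer
is scored at spacer offsets class−1, class, class+1 for both classes, and
the best variant per (position, strand, class) at or above the threshold
is reported. The original analysis delegated RSS detection to an external
web service whose scoring tables are not public, so the scorer is
pluggable: any `pwm_config`-shaped pair of matrices drops in. The default
threshold 15 was calibrated once: the consensus scores ~26.6 and stays
above threshold with three mismatches, while i.i.d. random sequence yields
well under one hit per 10 kb (an initial guess of 12 gave ~3/10 kb and was
revised before any acceptance measurement depended on it).

`annotate_breakpoint()` scans ±50 bp windows (closed; a heptamer counts
if it overlaps the window by one base) around both SV breakpoints and
assigns none/single/double cRSS categories; breakpoints inside the
antigen-receptor loci are flagged and excluded from cohort tallies.
`classify_sv_type()` types records as deletion / translocation / insertion
/ complex insertion (insert maps elsewhere in the genome).
`attribute_mechanism()` applies the rules in order: Ig-derived insert →
reintegration; double cRSS → two-cRSS off-target; single cRSS with insert
→ RAG-mediated insertion; single cRSS without → cut-and-run candidate;
otherwise other. Sidedness uses threshold-based absence (a side "lacks" a
cRSS when nothing scores above threshold), the natural reading when the
scorer is thresholded. `gene_set_enrichment()` maps SVs to genes by
breakpoint overlap and tests single-cRSS enrichment in a user-supplied
relapse gene set with an upper-tail hypergeometric (population = mapped
SVs, successes = SVs in the set, draws = single-cRSS SVs).

# Statistics

`fisher_2x2()` (two-tailed, summing tables with probability ≤ observed),
`mann_whitney_u()` and `wilcoxon_signed_rank()` (exact distributions for
small samples; under ties, exact by full enumeration of assignments or
sign vectors; normal approximation with tie and continuity corrections
above the `exact_limit` of 12) and `hypergeometric_upper()` (direct
summation) are implemented in-package so that every p value used in the
analyses has a brute-force oracle in the test suite. No multiple-testing
correction is applied by default; none of the in-scope analyses requires
one.

# Numerical and design notes

* All randomness flows from a mandatory integer seed; every stage derives
  a sub-seed from (seed, stage name), recorded in the pipeline manifest,
  and all outputs are byte-reproducible.
* Ties: knee detection and split-read voting break ties toward the
  smallest index / lowest coordinate; equal-best primers or database
  entries are deliberately unassigned rather than arbitrarily resolved.
* Degenerate inputs: zero total reads, empty control sets, empty
  databases, non-positive copy numbers and malformed records raise
  immediately with informative errors; all-zero paired differences give
  p = 1 with a warning.
* The acceptance suite (`tests/testthat/test-acceptance.R`) implements the
  five acceptance criteria one test per criterion; `scripts/acceptance.R`
  recomputes the two analytic targets (dilution to 1.5625% after six
  divisions; at most two KDE-derived circles per cell) from fresh
  simulations at the caller's seed.

# Known limitations

* The toy locus is not the human IGK/IGL geometry; ids are readable
  (`SJ_KDE_V2`-style) but coordinates are synthetic.
* The WGS simulator emits alignment records by exact projection rather
  than running an external aligner; mapping artefacts (multi-mapping,
  clipped misalignments) are out of its vocabulary.
* LAM amplification noise is a single lognormal factor per junction; real
  amplification bias is sequence-dependent.
* The RSS scorer is consensus-seeded, not trained on curated RSS
  collections; its absolute scores are not comparable to published RIC
  scores, only its decisions are (and those are pluggable).
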