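---
title: "Mining and comparing microsatellites across EST fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and comparing microsatellites across EST fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estssr)
```

## The analysis

`estssr` quantifies how simple sequence repeats (SSRs) are distributed
across the three functional fractions of transcribed sequence — 5'UTR, ORF
and 3'UTR — in collections of ESTs grouped by genus. The pipeline is:
optional redundancy removal, ORF calling and fraction partitioning, perfect
SSR scanning within each fraction, compound-event merging, and per-genus
aggregation into density and composition tables with accompanying tests.
Each stage is an exported function; `run_pipeline()` binds them.

## Repeat model and scanner

A perfect SSR is a maximal uninterrupted tandem array of a *primitive* unit
(one that is not itself a repetition of a shorter unit) of length 2–10 bp.
Three modelling decisions matter:

* **Complete units only.** The repeat count of a locus is the number of
  complete copies in the maximal exact extension; a trailing partial unit
  extends neither the span nor the count. This matches the `[TA]n` notation
  used for repeat loci and makes `length = unit × count` an identity.
* **Primitivity as the mononucleotide filter.** Mononucleotide repeats are
  notoriously platform-sensitive and are excluded; requiring primitive
  units does this at the unit level, so a poly-A tract can never resurface
  as a degenerate "AA" dimer or "AAAA" tetramer.
* **Containment-only overlap resolution.** A locus whose span lies fully
  inside another reported locus is suppressed (longer span wins; ties go to
  the smaller unit, then leftmost). Partially overlapping loci of different
  unit lengths are both reported by the scanner, because either choice of a
  single winner would be arbitrary at scan time. Event merging, however,
  needs disjoint loci, so the pipeline applies `resolve_partial_overlaps()`
  (same tie-break as containment) between scanning and merging. Partial
  overlaps are rare — two independent threshold-passing arrays must collide
  — and the run log plus locus tables always show what was scanned.

The scanner works on the self-match vector `s[i] == s[i+k]`: a maximal run
of `L` matches is a period-`k` array of length `L + k`. This is exact,
vectorised, and `N` (or any non-ACGT byte) simply breaks runs. Characters
outside `{A,C,G,T,N}` reject the record into the run log. A brute-force
oracle (`brute_force_oracle_scan()`) re-derives the same semantics by
direct substring comparison and is tested to agree exactly on thousands of
randomised and adversarial inputs.

The default minimum repeat counts (dimer-10, trimer-7, tetramer-5,
pentamer-4, hexamer-4, heptamer-3, octamer-3, nonamer-3, decamer-2) all
imply loci of at least 20 bp, the usual "class I" criterion for efficient
markers; the bound is attained by four classes (2×10, 4×5, 5×4, 10×2).
All thresholds are configurable through `ssr_scan_config()`.

**Compound events.** Consecutive loci separated by strictly fewer than
100 bp (configurable) merge transitively into one compound event. The bound
is exclusive: a 99 bp gap merges, a 100 bp gap does not. Compound events
count **once** in event densities (`counts_per_mbp`), while every member locus
contributes to the unit-length and canonical-class composition tables; both
event and member tallies are reported so either convention can be
reconstructed.

## Canonical motif classes

Units that are cyclic rotations and/or reverse complements of each other
describe the same repeat read from either strand or any phase, so counts
are pooled into canonical classes; the representative is the
lexicographically smallest member. Exhaustive enumeration gives 4 dimer
classes (AC, AG, AT, CG) and 10 trimer classes — these are exactly the rows
of the composition table. Under this algebra ACG and AGC are *distinct*
classes (each with six members); published example chains that string all
twelve of those trimers together conflate the two.

## ORF calling and fraction partitioning

Coding-potential gene prediction is out of scope; a deterministic
longest-ORF rule stands in. All six frames (three forward, three on the
reverse complement) are scanned for ATG-to-stop spans; the longest span of
at least `min_orf_bp` (default 90 bp — short enough to keep most genuine
EST fragments, long enough to avoid spurious 30-codon calls) is taken as
the coding region, ties preferring the forward strand and then the leftmost
start. The stop codon belongs to the ORF span, so it is never attributed to
the 3'UTR. Reverse-strand calls reverse-complement the sequence first, so
"5'UTR" is always the upstream fraction in coding orientation.
Externally produced annotations (GFF3, 1-based inclusive; BED, half-open —
both via `rtracklayer`) can replace the heuristic per sequence.

Sequences with no qualifying ORF are labelled unpartitioned, excluded from
fraction tables and counted in the run log: transcripts that a real
annotation pipeline would call non-coding have no defensible UTR/ORF split
under this heuristic. Scanning operates on the three fraction subsequences
independently, so a repeat straddling a boundary is truncated at the
boundary by construction — the price of making the three fractions sum
exactly to the sequence.

## Redundancy filter

EST collections are highly redundant. The optional pre-stage approximates
the standard greedy-incremental clustering scheme: sequences sorted longest
first, each assigned to the first representative it matches at ≥ 90%
identity (identity = exact matches over alignment columns of a global
alignment of the shorter against the longer; match 1, mismatch 0, unit gap
cost), preceded by a shared 8-mer prescreen that short-circuits unrelated
pairs. It is deliberately a simple, deterministic stand-in — it does not
reproduce any particular tool's short-word statistics — and it is off by
default; enable with `cluster_identity = 0.9`.

## Summaries and tests

Densities are `events × 10⁶ / fraction_bp`. Length dispersion uses the
sample SD (n − 1). The heterogeneity test builds a 2 × 3 table per genus —
rows: base pairs inside SSR member loci vs the remaining base pairs; columns:
the three fractions — and applies Pearson's chi-squared with df = 2 and no
continuity correction. Rates per Mbp are not counts, so this bp-level table
is the construction that makes the margins well-defined; spacer bases inside
compound events are counted as background, since they are not repeat
sequence.

Repeat-length comparisons between categories use Tukey's HSD. Because
repeat-length distributions are strongly right-skewed, the default is a
rank-based variant: observations are replaced by global midranks before the
one-way layout, and the classical procedure (available via
`use_ranks = FALSE`) runs on the ranks. Pairwise adjusted p-values come
from the studentized-range distribution and are cross-checked in the tests
against an independent hand computation via `ptukey()`.

Genome-size association is the Pearson correlation between haploid genome
size (pg) and a per-genus metric (mean repeat length or density) within one
fraction, p from the t transform on n − 2 df; it requires at least three
genera. A small genome-size table for 15 tree genera ships with the package
for demonstration runs (`default_genome_sizes()`).

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the analysis assumes so that recovery can be verified *exactly*:

* **Backgrounds are repeat-free by rejection.** UTR backgrounds draw i.i.d.
  bases at the target GC and re-sample any window where the scanner finds a
  threshold-passing SSR. Coding regions are built from non-stop codons
  (ATG ... stop, frame 0) and scrubbed the same way. Precision/recall
  against the manifest is therefore exact, not probabilistic.
* **Planted events cannot blur.** Flanking bases are adjusted so a planted
  array can neither extend by a full unit nor shift phase; compound members
  use distinct canonical classes and spacers of 1–99 bp; all events are
  mutually separated by more than 100 bp. Events planted inside the ORF are
  phase-checked so they never introduce an in-frame stop. Every planted
  fragment is re-scanned and re-drawn until the scanner reproduces the
  manifest exactly, and every assembled EST is re-drawn until the planted
  ORF is the unique longest-ORF call.
* **Densities are pooled Poisson.** Per fraction, the event total is drawn
  once as Poisson(density × total bp) and allocated to sequences
  proportionally to fragment length, moving events whose fragment cannot
  hold them at the required separation. This keeps genus-level densities
  unbiased even when single fragments saturate.
* **Presets.** The "angiosperm" preset (densities 1500/600/700 events per
  Mbp for 5'UTR/ORF/3'UTR, AG-rich dimers, GC 0.45) and the "gymnosperm"
  preset (250/200/300, AT-rich dimers, GC 0.40, larger genome size) loosely
  mirror the two regimes the pipeline is designed to contrast — high
  density with a 5'UTR peak versus low density with a 3'UTR peak — without
  claiming any published numeric values. Repeat counts are class minimum
  plus a geometric excess (p = 0.4, capped at +20), giving mean lengths in
  the mid-20s bp; 5% of events are compound. EST lengths are uniform
  600–1200 bp with the ORF occupying half, an ordinary size for assembled
  EST contigs.

What the simulator does **not** model: sequencing error, chimeric reads,
imperfect/interrupted repeats, expression-level redundancy, UTR coding
potential. Passing recovery tests therefore demonstrates the correctness of
the mining/partitioning machinery, not robustness to those artefacts in
real data.

## Numerical and reproducibility choices

* Coordinates are 0-based half-open everywhere internally; report files are
  the only place 1-based conventions appear (annotation import converts).
* All randomness flows from explicit seeds (`synthetic_spec(seed=)`);
  generation restores the caller's RNG state. The analysis pipeline draws
  no random numbers at all, so identical inputs and configuration produce
  byte-identical report bundles (numeric columns are written with fixed
  formatting for that reason).
* Benchmark problem sizes: the oracle-equivalence suite uses ~1,300
  randomised sequences of 20–500 bp; density recovery is checked on a
  simulated genus with ≥10 Mbp per fraction (5,000 ESTs of ~6 kb with the
  ORF occupying a third), where the observed relative error is within the
  ~2% Poisson noise floor and is asserted below 5%.
* Degenerate inputs have defined behaviour: empty FASTA files produce
  zero-filled report rows plus a warning; zero-length fractions yield
  placeholder summaries and skip the chi-squared test with a log entry;
  empty event sets report zero densities and `NA` length moments; zero
  detections score precision 1 with an explicit flag.

## Known limitations

The longest-ORF rule mis-partitions transcripts whose true CDS is not the
longest ORF (use external annotations where available). Only perfect
repeats are mined — interrupted single-motif repeats appear as separate
loci, possibly merged as compound events. The identity stand-in for
clustering is approximate by design. Tables analogous to published
EST-SSR surveys depend on the underlying sequence collections; this package
reproduces the *method*, and its acceptance checks assert internal,
verifiable quantities only.
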