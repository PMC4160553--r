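# estssr

Fraction-wise microsatellite mining and density analysis for EST
collections.

## The problem

Expressed sequence tags (ESTs) sample the transcribed portion of a genome,
and the simple sequence repeats (SSRs, microsatellites) they contain are
both widely used molecular markers and a window on how repeat content is
shaped by selection in coding versus untranslated sequence. Comparing repeat
landscapes across taxa requires a consistent operational pipeline: ESTs must
be oriented and split into 5'UTR, ORF and 3'UTR fractions; repeats must be
mined under explicit thresholds; equivalent repeat units must be pooled; and
counts must be normalised to the amount of sequence scanned in each
fraction. `estssr` implements that pipeline end to end for R, plus a
synthetic-data generator with planted ground truth so every stage can be
validated exactly.

## What it computes

* **Perfect SSRs** — maximal uninterrupted tandem arrays of a primitive unit
  of 2–10 bp, counted in complete units only. The default per-unit minimum
  repeat counts are dimer-10, trimer-7, tetramer-5, pentamer-4, hexamer-4,
  heptamer-3, octamer-3, nonamer-3, decamer-2, so every reported locus is at
  least 20 bp long (the "class I" marker criterion). Mononucleotide repeats
  are excluded by requiring primitive units.
* **Compound SSRs** — adjacent loci separated by strictly fewer than 100 bp
  are merged into one compound event, e.g. `[TA]n-[GT]n`.
* **Canonical motif classes** — repeat units that are cyclic rotations
  and/or reverse complements of one another (AC = CA = GT = TG) are pooled;
  the class representative is the lexicographically smallest member. There
  are exactly 4 dimer classes (AC, AG, AT, CG) and 10 trimer classes.
* **Fractions** — each EST is oriented and partitioned by a six-frame
  longest-ORF rule (ATG to stop, stop codon included; 90 bp minimum by
  default), or by external GFF3/BED annotations. SSRs are scanned within
  each fraction independently.
* **Densities and tests** — per genus and fraction: events per Mbp, mean ±
  SD repeat length, percent compound, composition by unit length and by
  canonical class; a 2 × 3 Pearson chi-squared test of SSR-content
  heterogeneity across fractions; a rank-based (midrank) Tukey HSD
  comparison of repeat lengths between fractions; and Pearson correlation
  between genome size (pg) and repeat metrics across genera.
* **Synthetic genera** — `generate_genus_dataset()` builds EST-like
  sequences (SSR-free backgrounds by rejection sampling, a stop-free planted
  ORF, repeats planted at target per-fraction densities with >100 bp
  separation) together with an exact truth manifest, so scanner precision
  and recall are 1.0 by construction and density estimation can be
  benchmarked at scale.
* An optional greedy redundancy filter (`greedy_cluster()`) collapses
  near-duplicate sequences at a 90% identity cutoff before analysis.

## Worked example

```r
library(estssr)

spec <- synthetic_spec("angiosperm", n_sequences = 120, seed = 42)
ds <- generate_genus_dataset(spec)
ds
#> <genus_dataset> SynAngiosperm: 120 sequences (0.109 Mbp), 87 planted events

write_genus_dataset(ds, "demo")
res <- run_pipeline(list(SynAngiosperm = "demo/SynAngiosperm.fasta"),
                    pipeline_config(log_level = "quiet"), "demo/reports")
res$summaries$SynAngiosperm
#> <genus_summary> SynAngiosperm (genome size NA pg)
#> <fraction_summary> 5UTR: 0.027 Mbp, 34 events (1250.0/Mbp, 2.9% compound), mean length 24.4 (SD 4.53) bp
#> <fraction_summary> ORF: 0.054 Mbp, 26 events (479.5/Mbp, 11.5% compound), mean length 24.4 (SD 5.47) bp
#> <fraction_summary> 3UTR: 0.027 Mbp, 27 events (990.1/Mbp, 0.0% compound), mean length 24.3 (SD 4.98) bp

res$tests$chi2_heterogeneity_SynAngiosperm
#> <estssr_test> Pearson chi-squared heterogeneity (SSR bp vs background bp):
#>   statistic = 328.9591, df = 2, p = < 2.22e-16
```

The numbers read as follows: the simulated "angiosperm-like" genus plants
repeats most densely in the 5'UTR (target 1500/Mbp) and least densely in the
ORF (target 600/Mbp); at 0.1 Mbp the pipeline recovers 1250, 480 and
990 events/Mbp for 5'UTR, ORF and 3'UTR, each within the Poisson noise of
the small dataset, with mean repeat lengths around 24 bp. The chi-squared
test rejects homogeneity of SSR content across the three fractions, as
expected when the planted densities differ. `demo/reports/` then contains
`table1.tsv` (densities and length moments per fraction), `table2.tsv`
(composition by unit length), `table3.tsv` (composition by canonical dimer
and trimer class), per-genus locus/fraction tables, `tests.json` and a run
log accounting for every rejected or unpartitioned record.

A thin command-line wrapper is installed as `exec/estssr`
(subcommands `simulate`, `cluster`, `partition`, `scan`, `summarize`,
`stats`, `run`).

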