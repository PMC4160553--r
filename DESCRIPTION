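Package: estssr
Title: Fraction-Wise Microsatellite Mining and Density Analysis for EST
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines perfect and compound simple sequence repeats (SSRs,
    microsatellites) from expressed sequence tag (EST) collections, partitions
    each transcript into 5'UTR, ORF and 3'UTR fractions via a six-frame
    longest-ORF rule or external GFF3/BED annotations, clusters repeat units
    into canonical motif classes under cyclic rotation and reverse
    complementation, and aggregates per-genus, per-fraction repeat densities
    (counts per Mbp), length statistics and motif composition tables. Includes
    chi-squared heterogeneity tests of repeat content across fractions,
    rank-based Tukey HSD comparisons of repeat lengths, genome-size
    association tests, an optional greedy redundancy filter at a configurable
    identity cutoff, and a synthetic EST generator that plants repeats of
    known class, count and density on repeat-free backgrounds for exact
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
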