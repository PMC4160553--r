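sense_codons <- function(n) paste(rep("GCT", n), collapse = "")

test_that("find_longest_orf locates ATG-to-stop spans across six frames", {
  s <- paste0("CCC", "ATG", sense_codons(29), "TAA", "GG")
  oc <- find_longest_orf(s)
  expect_equal(oc$start0, 3L)
  expect_equal(oc$end0, 96L)
  expect_identical(oc$strand, "forward")
  expect_equal(oc$length_bp %% 3L, 0L)

  # the longest of two forward ORFs wins (120 bp vs 90 bp)
  s2 <- paste0("ATG", sense_codons(38), "TAG",
               "CC",
               "ATG", sense_codons(28), "TGA")
  oc2 <- find_longest_orf(s2)
  expect_equal(oc2$start0, 0L)
  expect_equal(oc2$end0, 120L)

  expect_null(find_longest_orf("TTTTTTTTTT"))
  expect_null(find_longest_orf(paste0("ATG", sense_codons(5), "TAA"),
                               min_orf_bp = 90L))
  expect_error(find_longest_orf("AC"), class = "estssr_invalid_sequence")
})

test_that("reverse-strand ORFs are found and reported on the oriented sequence", {
  fwd <- paste0("CCCCC", "ATG", sense_codons(30), "TAA", "GG")
  rev <- revcomp(fwd)
  oc_f <- find_longest_orf(fwd)
  oc_r <- find_longest_orf(rev)
  expect_identical(oc_r$strand, "reverse")
  expect_equal(oc_r$start0, oc_f$start0)
  expect_equal(oc_r$end0, oc_f$end0)
  # forward strand wins ties: a palindrome-free sequence with equal-length
  # ORFs on both strands
  both <- paste0("ATG", sense_codons(10), "TAA",
                 revcomp(paste0("ATG", sense_codons(10), "TAA")))
  oc_b <- find_longest_orf(both, min_orf_bp = 30L)
  expect_identical(oc_b$strand, "forward")
})

test_that("partition_by_orf splits the sequence conservatively", {
  set.seed(5)
  s <- paste0(random_dna(100), "ATG", sense_codons(98), "TAA", random_dna(100))
  oc <- find_longest_orf(s)
  fs <- partition_by_orf(s, oc)
  sp <- fs$spans
  expect_identical(sp$fraction, c("5UTR", "ORF", "3UTR"))
  expect_equal(sum(sp$length_bp), nchar(s))
  expect_true(all(sp$start0 <= sp$end0))
  expect_equal(sp$end0[1], sp$start0[2])
  expect_equal(sp$end0[2], sp$start0[3])
  # the stop codon belongs to the ORF, not the 3'UTR
  expect_identical(substr(fs$oriented_residues, sp$end0[2] - 2, sp$end0[2]),
                   "TAA")
  subs <- fraction_subsequences(fs)
  expect_identical(paste(subs, collapse = ""), fs$oriented_residues)

  # boundary: ORF at the very start leaves an empty 5'UTR
  s2 <- paste0("ATG", sense_codons(97), "TGA", random_dna(50))
  fs2 <- partition_by_orf(s2, find_longest_orf(s2))
  expect_equal(fs2$spans$length_bp[1], 0L)
  expect_equal(fs2$spans$length_bp[3], 50L)

  bad <- find_longest_orf(s)
  bad$end0 <- nchar(s) + 3L
  expect_error(partition_by_orf(s, bad), class = "estssr_invalid_orf")
})

test_that("reverse-strand partitioning equals partitioning the reverse complement", {
  set.seed(6)
  core <- paste0(random_dna(40), "ATG", sense_codons(60), "TAG", random_dna(70))
  rev <- revcomp(core)
  oc_rev <- find_longest_orf(rev)
  expect_identical(oc_rev$strand, "reverse")
  fs_a <- partition_by_orf(rev, oc_rev)
  fs_b <- partition_by_orf(core, find_longest_orf(core))
  expect_identical(fs_a$oriented_residues, fs_b$oriented_residues)
  expect_identical(fs_a$spans, fs_b$spans)
})

test_that("GFF3 and BED annotations load with correct coordinate conversion", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "seqA\ttest\tCDS\t101\t400\t.\t+\t0\tID=orf1",
               "seqB\ttest\tCDS\t11\t310\t.\t+\t0\tID=orf2",
               "seqB\ttest\tCDS\t401\t550\t.\t+\t0\tID=orf3"), gff)
  calls <- load_orf_annotations(gff)
  expect_equal(calls$seqA$start0, 100L)
  expect_equal(calls$seqA$end0, 400L)
  expect_identical(calls$seqA$strand, "forward")
  # longest CDS wins for seqB (300 bp vs 150 bp)
  expect_equal(calls$seqB$end0 - calls$seqB$start0, 300L)

  bed <- tempfile(fileext = ".bed")
  writeLines("seqC\t100\t400\torf\t0\t+", bed)
  calls_bed <- load_orf_annotations(bed)
  expect_equal(calls_bed$seqC$start0, 100L)
  expect_equal(calls_bed$seqC$end0, 400L)

  # minus strand requires a sequence length and is flipped onto the
  # oriented sequence
  gff2 <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "seqD\ttest\tCDS\t11\t100\t.\t-\t0\tID=orf4"), gff2)
  expect_warning(calls_na <- load_orf_annotations(gff2))
  expect_null(calls_na$seqD)
  calls_rev <- load_orf_annotations(gff2, seq_lengths = c(seqD = 120L))
  expect_equal(calls_rev$seqD$start0, 20L)
  expect_equal(calls_rev$seqD$end0, 110L)
  expect_identical(calls_rev$seqD$strand, "reverse")
})
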