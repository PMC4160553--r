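test_that("default scan thresholds realize the >= 20 bp class I bound", {
  cfg <- ssr_scan_config()
  ks <- as.integer(names(cfg$min_repeats))
  expect_setequal(ks, 2:10)
  expect_true(all(ks * cfg$min_repeats >= 20L))
  # the bound is attained (20 bp is the minimum possible SSR length)
  expect_identical(min(ks * cfg$min_repeats), 20L)
})

test_that("scan_unit_runs finds maximal complete-copy tandem arrays", {
  runs <- scan_unit_runs(strrep("TA", 10), 2L)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$start0, 0L)
  expect_equal(runs$end0, 20L)
  expect_identical(runs$unit, "TA")
  expect_equal(runs$repeats, 10L)

  runs <- scan_unit_runs("ACGACGACGACGACGACGACG", 3L)
  expect_equal(runs$repeats, 7L)
  expect_equal(runs$end0, 21L)

  # non-primitive unit at this length: nothing reported
  expect_equal(nrow(scan_unit_runs(strrep("A", 12), 2L)), 0L)
  # trailing partial unit extends neither span nor count
  runs <- scan_unit_runs(paste0(strrep("CAG", 5), "CA"), 3L)
  expect_equal(runs$repeats, 5L)
  expect_equal(runs$end0, 15L)
  # N terminates runs
  runs <- scan_unit_runs(paste0(strrep("TA", 4), "N", strrep("TA", 4)), 2L)
  expect_equal(nrow(runs), 2L)
  expect_true(all(runs$repeats == 4L))
  expect_equal(nrow(scan_unit_runs("", 2L)), 0L)
})

test_that("scan_perfect_ssrs applies class minima and labels canonically", {
  s <- paste0("GGC", strrep("TA", 10), "CCG")
  loci <- scan_perfect_ssrs(s)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start0, 3L)
  expect_equal(loci$length_bp, 20L)
  expect_equal(loci$repeats, 10L)
  expect_identical(loci$canonical, "AT")

  # 8 dimer copies are below the dimer-10 threshold
  expect_equal(nrow(scan_perfect_ssrs(strrep("TA", 8))), 0L)
  # mononucleotide tracts can never surface at any unit size
  expect_equal(nrow(scan_perfect_ssrs(strrep("A", 40))), 0L)
  # invalid characters reject the record
  expect_error(scan_perfect_ssrs("ACGTRYACGT"),
               class = "estssr_invalid_sequence")
})

test_that("reported loci are never contained in another locus", {
  set.seed(101)
  for (i in 1:40) {
    s <- random_dna(300, gc = runif(1, 0.25, 0.75))
    units <- sample(c("AT", "AG", "ACG", "AAG", "ACGT", "AATC"), 2)
    s <- paste0(substr(s, 1, 100), strrep(units[1], 12),
                substr(s, 101, 200), strrep(units[2], 11),
                substr(s, 201, 300))
    loci <- scan_perfect_ssrs(s)
    expect_gte(nrow(loci), 2L)
    for (a in seq_len(nrow(loci))) {
      contained <- loci$start0[-a] <= loci$start0[a] &
        loci$end0[-a] >= loci$end0[a]
      expect_false(any(contained))
    }
    expect_true(all(loci$length_bp >= 20L))
    expect_true(all(diff(loci$start0) >= 0))
  }
})

test_that("scanner output is identical to the brute-force oracle", {
  set.seed(2024)
  n_checked <- 0L
  for (i in 1:300) {
    n <- sample(20:500, 1)
    gc <- runif(1, 0.2, 0.8)
    s <- random_dna(n, gc)
    if (i %% 3 == 0) {
      # adversarial: plant a repeat (sometimes sub-threshold, sometimes not)
      u <- sample(c("TA", "GT", "CT", "ACG", "CCG", "AATC", "AACGT",
                    "ACGTAC"), 1)
      reps <- sample(2:14, 1)
      p <- sample(n, 1)
      s <- paste0(substr(s, 1, p), strrep(u, reps), substr(s, p + 1, n))
    }
    if (i %% 7 == 0) {
      # sprinkle Ns
      ch <- strsplit(s, "")[[1]]
      ch[sample(length(ch), 3)] <- "N"
      s <- paste(ch, collapse = "")
    }
    expect_identical(scan_perfect_ssrs(s), brute_force_oracle_scan(s))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 300L)
  # determinism of the oracle itself
  s <- random_dna(500)
  expect_identical(brute_force_oracle_scan(s), brute_force_oracle_scan(s))
  expect_equal(nrow(brute_force_oracle_scan("")), 0L)
})

test_that("phase-shifted and nested arrays resolve to a single locus", {
  # trailing partial unit: the shifted phase must not produce a second locus
  s <- paste0(strrep("TA", 10), "T")
  expect_identical(scan_perfect_ssrs(s), brute_force_oracle_scan(s))
  expect_equal(nrow(scan_perfect_ssrs(s)), 1L)
  # a (ACGT) x 6 array is also a sub-threshold dimer/8-mer pattern
  s2 <- paste0("GG", strrep("ACGT", 6), "CC")
  loci <- scan_perfect_ssrs(s2)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$unit_length, 4L)
  expect_identical(scan_perfect_ssrs(s2), brute_force_oracle_scan(s2))
})

test_that("custom thresholds are honoured", {
  cfg <- ssr_scan_config(min_repeats = c("2" = 5L, "3" = 4L))
  loci <- scan_perfect_ssrs(strrep("TG", 6), cfg)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$repeats, 6L)
  expect_error(ssr_scan_config(min_repeats = c("2" = 1L)),
               class = "estssr_invalid_config")
  expect_error(ssr_scan_config(min_repeats = c("11" = 3L)),
               class = "estssr_invalid_config")
})
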