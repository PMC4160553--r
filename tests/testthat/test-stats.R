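events_from_loci <- function(loci) merge_compound(loci, ssr_scan_config())

test_that("counts_per_mbp scales event counts to Mbp", {
  expect_equal(counts_per_mbp(5, 10000), 500)
  expect_equal(counts_per_mbp(0, 1e6), 0)
  expect_equal(counts_per_mbp(247, 1e6), 247)
  expect_error(counts_per_mbp(1, 0), class = "estssr_undefined_density")
})

test_that("summarize_fraction computes density, length moments and composition", {
  # 4 perfect loci of lengths 20, 20, 24, 28 in 0.1 Mbp
  loci <- rbind(make_loci(0, 20), make_loci(200, 220),
                make_loci(400, 424), make_loci(700, 728))
  fs <- summarize_fraction(events_from_loci(loci), 1e5)
  expect_equal(fs$event_count, 4L)
  expect_equal(fs$counts_per_mbp, 40)
  expect_equal(fs$mean_length_bp, 23)
  expect_equal(fs$sd_length_bp, sd(c(20, 20, 24, 28)))
  expect_equal(round(fs$sd_length_bp, 2), 3.83)
  expect_equal(fs$percent_compound, 0)
  # composition: all four loci are AT dimers
  expect_equal(sum(fs$counts_per_mbp_by_unit_length), fs$members_per_mbp)
  expect_equal(unname(fs$counts_per_mbp_by_unit_length[["2"]]), 40)
  expect_equal(unname(fs$counts_per_mbp_by_canonical[["AT"]]), 40)

  # 1 compound (2 members) + 3 perfect -> 25% compound
  loci2 <- rbind(make_loci(0, 20, unit = "TA"),
                 make_loci(40, 60, unit = "GT"),     # gap 20 -> compound
                 make_loci(300, 320), make_loci(600, 620),
                 make_loci(900, 920))
  fs2 <- summarize_fraction(events_from_loci(loci2), 1e5)
  expect_equal(fs2$event_count, 4L)
  expect_equal(fs2$member_count, 5L)
  expect_equal(fs2$percent_compound, 25)

  # empty fraction: zero counts, moments not available
  fs3 <- summarize_fraction(events_from_loci(empty_frame <- make_loci(integer(0), integer(0))),
                            1e6, fraction = "ORF")
  expect_equal(fs3$event_count, 0L)
  expect_equal(fs3$counts_per_mbp, 0)
  expect_true(is.na(fs3$mean_length_bp))
  expect_error(summarize_fraction(events_from_loci(make_loci(0, 20)), 0),
               class = "estssr_undefined_density")
})

test_that("density is invariant under dataset duplication", {
  loci <- rbind(make_loci(0, 20), make_loci(300, 324, unit = "ACG"))
  fs1 <- summarize_fraction(events_from_loci(loci), 5e4)
  dup <- loci
  dup$seq_id <- "s_copy"
  fs2 <- summarize_fraction(events_from_loci(rbind(loci, dup)), 1e5)
  expect_equal(fs2$counts_per_mbp, fs1$counts_per_mbp)
  expect_equal(fs2$counts_per_mbp_by_unit_length,
               fs1$counts_per_mbp_by_unit_length)
  expect_equal(fs2$counts_per_mbp_by_canonical,
               fs1$counts_per_mbp_by_canonical)
})

test_that("chi-squared heterogeneity equals the hand-computed Pearson statistic", {
  mk <- function(ssr_bp, total_bp, fraction) {
    # single locus of the requested total SSR length
    loci <- make_loci(0, ssr_bp, fraction = fraction)
    summarize_fraction(events_from_loci(loci), total_bp, fraction = fraction)
  }
  sums <- list("5UTR" = mk(30, 1000, "5UTR"), ORF = mk(20, 1000, "ORF"),
               "3UTR" = mk(10, 1000, "3UTR"))
  res <- chi2_fraction_heterogeneity(sums)
  tb <- rbind(c(30, 20, 10), c(970, 980, 990))
  E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
  expect_equal(res$statistic, sum((tb - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, pchisq(res$statistic, 2, lower.tail = FALSE))

  # identical SSR proportions -> statistic 0, p = 1
  sums_eq <- list("5UTR" = mk(20, 1000, "5UTR"), ORF = mk(40, 2000, "ORF"),
                  "3UTR" = mk(60, 3000, "3UTR"))
  res_eq <- chi2_fraction_heterogeneity(sums_eq)
  expect_equal(res_eq$statistic, 0, tolerance = 1e-12)
  expect_equal(res_eq$p_value, 1)

  # column order invariance
  res_perm <- chi2_fraction_heterogeneity(sums[c(3, 1, 2)])
  expect_equal(res_perm$statistic, res$statistic)

  # zero-bp fraction is an error
  sums_bad <- sums
  sums_bad[["ORF"]]$total_bp <- 0
  expect_error(chi2_fraction_heterogeneity(sums_bad),
               class = "estssr_undefined_density")
})


test_that("rank-based Tukey HSD matches the studentized-range oracle", {
  groups <- list("5UTR" = c(20, 22, 24, 26, 30, 24),
                 ORF = c(20, 20, 22, 24, 21),
                 "3UTR" = c(24, 28, 30, 33, 27, 40, 22))
  for (ranks in c(TRUE, FALSE)) {
    res <- tukey_hsd_lengths(groups, use_ranks = ranks)
    oracle <- manual_tukey_p(groups, use_ranks = ranks)
    got <- setNames(res$pairwise$p_adj, res$pairwise$comparison)
    expect_equal(round(got[names(oracle)], 4), round(oracle, 4))
  }
  # three identical groups: no differences, all adjusted p = 1
  same <- list(a = c(20, 24, 28), b = c(20, 24, 28), c = c(20, 24, 28))
  res_same <- tukey_hsd_lengths(same)
  expect_true(all(abs(res_same$pairwise$diff) < 1e-12))
  expect_true(all(res_same$pairwise$p_adj > 0.999))
  expect_error(tukey_hsd_lengths(list(a = c(1, 2))),
               class = "estssr_insufficient_data")
  expect_error(tukey_hsd_lengths(list(a = c(1, 2), b = 3)),
               class = "estssr_insufficient_data")
})

make_genus <- function(name, pg, locus_len) {
  loci <- lapply(c("5UTR", "ORF", "3UTR"), function(fr) {
    make_loci(0, locus_len, fraction = fr)
  })
  fs <- lapply(loci, function(l) {
    summarize_fraction(events_from_loci(l), 1e5, fraction = l$fraction[1])
  })
  names(fs) <- c("5UTR", "ORF", "3UTR")
  genus_summary(name, fs, genome_size_pg = pg)
}

test_that("genome-size association recovers exact and null relationships", {
  # mean length exactly linear in pg -> r = 1
  genera <- lapply(1:5, function(i) make_genus(paste0("g", i), i, 20 + 2 * i))
  res <- genome_size_association(genera, "mean_length", "3UTR")
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)

  # metric independent of pg: |r| small and p large on average
  set.seed(77)
  rs <- replicate(25, {
    lens <- 2 * sample(10:15)
    g <- lapply(1:6, function(i) make_genus(paste0("h", i), i, 20 + lens[i]))
    res0 <- genome_size_association(g, "mean_length", "5UTR")
    c(r = abs(res0$statistic), p = res0$p_value)
  })
  expect_lt(mean(rs["r", ]), 0.5)
  expect_gt(mean(rs["p", ]), 0.25)

  expect_error(genome_size_association(genera[1:2], "mean_length", "3UTR"),
               class = "estssr_insufficient_data")
  const <- lapply(1:4, function(i) make_genus(paste0("c", i), i, 24))
  expect_error(genome_size_association(const, "mean_length", "3UTR"),
               class = "estssr_undefined_correlation")
})
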