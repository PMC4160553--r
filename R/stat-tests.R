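test_result <- function(method, statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, pairwise = NULL) {
  structure(list(method = method, statistic = as.numeric(statistic),
                 df = as.numeric(df), p_value = as.numeric(p_value),
                 pairwise = pairwise),
            class = "estssr_test")
}

#' @export
print.estssr_test <- function(x, ...) {
  cat(sprintf("<estssr_test> %s: statistic = %s, df = %s, p = %s\n",
              x$method, format(x$statistic), format(x$df),
              format.pval(x$p_value)))
  if (!is.null(x$pairwise)) {
    cat("pairwise comparisons:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' Chi-squared heterogeneity of SSR content across fractions
#'
#' Tests whether the proportion of sequence occupied by microsatellites
#' differs among the 5'UTR, ORF and 3'UTR fractions. The 2 x 3 contingency
#' table has one column per fraction and two rows: base pairs inside SSR
#' member loci, and the remaining base pairs of the fraction. Pearson's
#' chi-squared statistic (no continuity correction) with 2 degrees of
#' freedom.
#'
#' @param summaries Named list of three `fraction_summary` objects.
#' @return An `estssr_test` with the statistic, df = 2 and the upper-tail
#'   p-value; the table used is attached as attribute `"table"`.
#' @export
chi2_fraction_heterogeneity <- function(summaries) {
  stopifnot(length(summaries) == 3L,
            all(vapply(summaries, inherits, logical(1), "fraction_summary")))
  tb <- vapply(summaries, function(fs) {
    if (fs$total_bp <= 0) {
      stop_estssr("estssr_undefined_density",
                  "all three fractions need total_bp > 0")
    }
    c(ssr = fs$ssr_bp, background = fs$total_bp - fs$ssr_bp)
  }, numeric(2))
  if (any(colSums(tb) == 0) || any(rowSums(tb) == 0)) {
    stop_estssr("estssr_degenerate_table",
                "contingency table has a zero margin")
  }
  ht <- suppressWarnings(chisq.test(tb, correct = FALSE))
  res <- test_result("Pearson chi-squared heterogeneity (SSR bp vs background bp)",
                     statistic = unname(ht$statistic), df = unname(ht$parameter),
                     p_value = ht$p.value)
  attr(res, "table") <- tb
  res
}

#' Tukey HSD comparison of repeat lengths between categories
#'
#' Compares mean SSR lengths across categories (typically the three EST
#' fractions) by Tukey's honestly-significant-difference procedure. By
#' default the test is rank-based: observations are replaced by their global
#' midranks before the one-way layout is fitted, giving a non-parametric
#' analogue that is robust to the strong right skew of repeat-length
#' distributions. Set `use_ranks = FALSE` for the classical test on raw
#' lengths.
#'
#' @param groups Named list mapping category label to a numeric vector of
#'   SSR lengths (>= 2 groups of >= 2 observations).
#' @param use_ranks Replace observations by global midranks first
#'   (default `TRUE`).
#' @return An `estssr_test`; `statistic`/`df`/`p_value` describe the one-way
#'   ANOVA F on the (possibly ranked) layout and `pairwise` holds the Tukey
#'   HSD table (`diff`, `lwr`, `upr`, `p_adj` per category pair).
#' @export
tukey_hsd_lengths <- function(groups, use_ranks = TRUE) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(vapply(groups, length, integer(1)) < 2L)) {
    stop_estssr("estssr_insufficient_data",
                "need >= 2 groups with >= 2 observations each")
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups))
  if (use_ranks) values <- rank(values)   # midranks for ties
  fit <- aov(values ~ labels)
  an <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit)$labels
  pairwise <- data.frame(comparison = rownames(hsd),
                         diff = hsd[, "diff"], lwr = hsd[, "lwr"],
                         upr = hsd[, "upr"], p_adj = hsd[, "p adj"],
                         stringsAsFactors = FALSE, row.names = NULL)
  test_result(if (use_ranks) "Tukey HSD on midranks" else "Tukey HSD",
              statistic = an[["F value"]][1], df = an[["Df"]][1],
              p_value = an[["Pr(>F)"]][1], pairwise = pairwise)
}

#' Association between genome size and an SSR metric
#'
#' Pearson correlation between haploid genome size (pg) and a per-genus SSR
#' metric within one fraction, with the two-sided p-value from the t
#' transform on n - 2 degrees of freedom.
#'
#' @param genera List of `genus_summary` objects (>= 3 with known genome
#'   size).
#' @param metric `"mean_length"` or `"counts_per_mbp"`.
#' @param fraction Fraction label ("5UTR", "ORF" or "3UTR").
#' @return An `estssr_test` with `statistic` = r.
#' @export
genome_size_association <- function(genera,
                                    metric = c("mean_length", "counts_per_mbp"),
                                    fraction = "3UTR") {
  metric <- match.arg(metric)
  stopifnot(fraction %in% FRACTIONS)
  gs <- vapply(genera, function(g) g$genome_size_pg, numeric(1))
  val <- vapply(genera, function(g) {
    fs <- g$fractions[[fraction]]
    if (metric == "mean_length") fs$mean_length_bp else fs$counts_per_mbp
  }, numeric(1))
  keep <- !is.na(gs) & !is.na(val)
  gs <- gs[keep]; val <- val[keep]
  if (length(gs) < 3L) {
    stop_estssr("estssr_insufficient_data",
                "need >= 3 genera with genome size and metric")
  }
  if (sd(gs) == 0 || sd(val) == 0) {
    stop_estssr("estssr_undefined_correlation",
                "correlation undefined for a constant variable")
  }
  ct <- cor.test(gs, val, method = "pearson")
  test_result(sprintf("Pearson correlation: genome size (pg) vs %s [%s]",
                      metric, fraction),
              statistic = unname(ct$estimate), df = unname(ct$parameter),
              p_value = ct$p.value)
}
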