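# Shared fixtures, all built in code.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Full detection path on a synthetic dataset: partition every sequence by
# the longest-ORF rule, scan each fraction, merge into events.
detect_dataset_events <- function(ds, config = ssr_scan_config(),
                                  min_orf_bp = 90L) {
  loci <- list()
  for (sid in names(ds$sequences)) {
    oc <- find_longest_orf(ds$sequences[[sid]], min_orf_bp, seq_id = sid)
    if (is.null(oc)) next
    fs <- partition_by_orf(ds$sequences[[sid]], oc, seq_id = sid)
    subs <- fraction_subsequences(fs)
    for (fr in names(subs)) {
      if (nchar(subs[[fr]]) == 0L) next
      loci[[paste(sid, fr)]] <- scan_perfect_ssrs(subs[[fr]], config,
                                                  seq_id = sid, fraction = fr)
    }
  }
  merge_compound(do.call(rbind, loci), config)
}

# Hand-built loci data.frame for merge tests.
make_loci <- function(starts, ends, seq_id = "s", fraction = "3UTR",
                      unit = "TA") {
  k <- nchar(unit)
  n <- length(starts)
  data.frame(seq_id = rep(seq_id, n), fraction = rep(fraction, n),
             start0 = as.integer(starts), end0 = as.integer(ends),
             unit_length = rep(k, n), motif = rep(unit, n),
             canonical = rep(canonical_class(unit), n),
             repeats = as.integer((ends - starts) / k),
             length_bp = as.integer(ends - starts),
             stringsAsFactors = FALSE)
}

# independent Tukey HSD oracle from the studentized-range distribution
manual_tukey_p <- function(groups, use_ranks = TRUE) {
  vals <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (use_ranks) vals <- rank(vals)
  ni <- tapply(vals, g, length)
  mi <- tapply(vals, g, mean)
  k <- nlevels(g)
  dfe <- length(vals) - k
  mse <- sum((vals - ave(vals, g))^2) / dfe
  out <- c()
  lv <- levels(g)
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
      q <- abs(mi[b] - mi[a]) / se
      out[paste0(lv[b], "-", lv[a])] <-
        ptukey(q, k, dfe, lower.tail = FALSE)
    }
  }
  out
}
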