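#' Brute-force reference scanner
#'
#' Reference semantics for [scan_perfect_ssrs()], implemented by direct
#' substring comparison: for every start position and unit length it counts
#' the number of complete tandem copies of the unit beginning there, keeps the
#' triples that pass the unit filters and the minimum repeat counts, drops
#' candidates that are left-extendable (a copy of the same array starting one
#' unit earlier), and applies the same containment resolution as the scanner.
#' Intended for test-scale sequences.
#'
#' @param sequence A DNA string (length <= 10000 enforced).
#' @param config An [ssr_scan_config()].
#' @param seq_id,fraction Labels attached to the reported loci.
#' @return A loci data.frame with the same columns as [scan_perfect_ssrs()].
#' @export
brute_force_oracle_scan <- function(sequence, config = ssr_scan_config(),
                                    seq_id = NA_character_,
                                    fraction = NA_character_) {
  s <- validate_dna(sequence)
  n <- nchar(s)
  if (n > 10000L) {
    stop_estssr("estssr_invalid_sequence",
                "oracle scan is restricted to sequences of at most 10000 bp")
  }
  ch <- strsplit(s, "")[[1]]
  valid <- ch %in% c("A", "C", "G", "T")
  rows <- list()
  for (k in sort(as.integer(names(config$min_repeats)))) {
    min_rep <- config$min_repeats[[as.character(k)]]
    if (n < k * min_rep) next
    for (st in seq_len(n - k * min_rep + 1L)) {
      unit <- substr(s, st, st + k - 1L)
      if (!all(valid[st:(st + k - 1L)])) next
      # count complete copies of `unit` starting at st
      copies <- 1L
      while (st + (copies + 1L) * k - 1L <= n &&
             substr(s, st + copies * k, st + (copies + 1L) * k - 1L) == unit) {
        copies <- copies + 1L
      }
      if (copies < min_rep) next
      if (!unit_passes(unit, config)) next
      # left-maximality: reject if the periodic region extends even one
      # character to the left (this start is then not the leftmost phase of
      # the maximal tandem array)
      if (st > 1L && valid[st - 1L] && valid[st + k - 1L] &&
          ch[st - 1L] == ch[st + k - 1L]) next
      rows[[length(rows) + 1L]] <-
        data.frame(seq_id = seq_id, fraction = fraction,
                   start0 = st - 1L, end0 = st - 1L + copies * k,
                   unit_length = k, motif = unit,
                   canonical = canonical_class(unit),
                   repeats = copies, length_bp = copies * k,
                   stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(rows)) do.call(rbind, rows) else empty_loci()
  loci <- resolve_containment(loci)
  rownames(loci) <- NULL
  loci
}
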