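#' Scanner configuration
#'
#' Holds the per-unit-length minimum repeat counts, the compound spacer bound
#' and the unit filters. The defaults implement the class I marker criterion:
#' every default class yields a minimum total repeat length of at least 20 bp
#' (dimer 2x10, trimer 3x7, tetramer 4x5, pentamer/hexamer x4,
#' heptamer/octamer/nonamer x3, decamer 2x2... i.e. 10x2 = 20 bp).
#'
#' @param min_repeats Named integer vector mapping unit length ("2".."10") to
#'   the minimum number of complete repeat units.
#' @param max_compound_spacer Integer; adjacent repeats separated by strictly
#'   fewer than this many base pairs are merged into one compound event
#'   (default 100, exclusive bound).
#' @param exclude_mononucleotide Drop runs whose unit is a homopolymer.
#' @param exclude_nonprimitive Drop runs whose unit is itself a tandem repeat
#'   of a shorter unit (implies mononucleotide exclusion).
#' @return An object of class `ssr_scan_config`.
#' @examples
#' cfg <- ssr_scan_config()
#' cfg$min_repeats
#' @export
ssr_scan_config <- function(min_repeats = c("2" = 10L, "3" = 7L, "4" = 5L,
                                            "5" = 4L, "6" = 4L, "7" = 3L,
                                            "8" = 3L, "9" = 3L, "10" = 2L),
                            max_compound_spacer = 100L,
                            exclude_mononucleotide = TRUE,
                            exclude_nonprimitive = TRUE) {
  if (is.null(names(min_repeats)) || anyNA(suppressWarnings(as.integer(names(min_repeats))))) {
    stop_estssr("estssr_invalid_config", "min_repeats must be named by unit length")
  }
  ks <- as.integer(names(min_repeats))
  if (any(ks < 2L) || any(ks > 10L) || anyDuplicated(ks)) {
    stop_estssr("estssr_invalid_config", "min_repeats unit lengths must be unique and in [2, 10]")
  }
  mr <- as.integer(min_repeats)
  if (anyNA(mr) || any(mr < 2L)) {
    stop_estssr("estssr_invalid_config", "all min_repeats must be integers >= 2")
  }
  spacer <- as.integer(max_compound_spacer)
  if (is.na(spacer) || spacer < 0L) {
    stop_estssr("estssr_invalid_config", "max_compound_spacer must be a non-negative integer")
  }
  structure(list(min_repeats = setNames(mr, ks),
                 max_compound_spacer = spacer,
                 exclude_mononucleotide = isTRUE(exclude_mononucleotide),
                 exclude_nonprimitive = isTRUE(exclude_nonprimitive)),
            class = "ssr_scan_config")
}

.empty_runs <- data.frame(start0 = integer(0), end0 = integer(0),
                          unit = character(0), unit_length = integer(0),
                          repeats = integer(0), stringsAsFactors = FALSE)
empty_runs <- function() .empty_runs

.empty_loci <- data.frame(seq_id = character(0), fraction = character(0),
                          start0 = integer(0), end0 = integer(0),
                          unit_length = integer(0), motif = character(0),
                          canonical = character(0), repeats = integer(0),
                          length_bp = integer(0), stringsAsFactors = FALSE)
empty_loci <- function() .empty_loci

# Unit filter shared by the scanner and the oracle.
unit_passes <- function(unit, config) {
  if (config$exclude_nonprimitive) return(is_primitive(unit))
  if (config$exclude_mononucleotide &&
      length(unique(strsplit(unit, "")[[1]])) == 1L) return(FALSE)
  TRUE
}

#' Maximal exact tandem runs of one unit length
#'
#' Finds every maximal run of complete, exact copies of a primitive unit of
#' the given length. The detection works on the self-match vector
#' `s[i] == s[i + k]`: a maximal stretch of L consecutive matches corresponds
#' to a period-k array of total length L + k, of which `floor((L + k) / k)`
#' copies are complete. Trailing partial units extend neither the span nor the
#' count. `N` (or any non-ACGT position) never matches, so runs cannot cross
#' ambiguous bases.
#'
#' @param sequence A DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @param unit_length Integer in 2..10.
#' @param config An [ssr_scan_config()]; only the unit filters are used here.
#' @return A data.frame with columns `start0`, `end0` (0-based half-open),
#'   `unit`, `unit_length`, `repeats` (complete copies, >= 2), sorted by
#'   `start0`.
#' @export
scan_unit_runs <- function(sequence, unit_length, config = ssr_scan_config()) {
  k <- as.integer(unit_length)
  if (is.na(k) || k < 2L || k > 10L) {
    stop_estssr("estssr_invalid_config", "unit_length must be in [2, 10]")
  }
  s <- validate_dna(sequence)
  scan_unit_runs_raw(s, charToRaw(s), valid_base_mask(charToRaw(s)), k, config)
}

# lookup-table validity mask over raw bytes (A, C, G, T only)
valid_base_mask <- local({
  tab <- logical(256)
  tab[as.integer(charToRaw("ACGT")) + 1L] <- TRUE
  function(r) tab[as.integer(r) + 1L]
})

# core run finder on precomputed byte/validity vectors; `min_copies` lets the
# perfect-SSR scan discard sub-threshold runs before unit filtering
scan_unit_runs_raw <- function(s, r, ok, k, config, min_copies = 2L) {
  n <- length(r)
  if (n < k * min_copies) return(empty_runs())
  idx <- seq_len(n - k)
  eq <- (r[idx] == r[idx + k]) & ok[idx] & ok[idx + k]
  rl <- rle(eq)
  run_end <- cumsum(rl$lengths)
  sel <- which(rl$values & rl$lengths >= k * (min_copies - 1L))
  if (length(sel) == 0L) return(empty_runs())
  st <- run_end[sel] - rl$lengths[sel] + 1L
  copies <- rl$lengths[sel] %/% k + 1L
  units <- substring(s, st, st + k - 1L)
  keep <- units_pass_cached(units, config)
  if (!any(keep)) return(empty_runs())
  st <- st[keep]; copies <- copies[keep]; units <- units[keep]
  data.frame(start0 = st - 1L, end0 = st - 1L + copies * k,
             unit = units, unit_length = k, repeats = copies,
             stringsAsFactors = FALSE)
}

# memoised unit filter: the unit universe is tiny (<= 4^10 but in practice a
# few hundred distinct strings per dataset), so cache pass/fail per filter
# setting
.unit_cache <- new.env(parent = emptyenv())
units_pass_cached <- function(units, config) {
  key_pfx <- paste0(config$exclude_nonprimitive, config$exclude_mononucleotide)
  vapply(units, function(u) {
    key <- paste0(key_pfx, u)
    hit <- .unit_cache[[key]]
    if (is.null(hit)) {
      hit <- unit_passes(u, config)
      assign(key, hit, envir = .unit_cache)
    }
    hit
  }, logical(1), USE.NAMES = FALSE)
}

# Containment resolution shared by scanner and oracle: a locus whose span is
# fully contained in (or equal to) the span of another reported locus is
# suppressed. Longer spans win; ties go to the smaller unit length, then to
# the leftmost locus.
resolve_containment <- function(loci) {
  if (nrow(loci) <= 1L) return(loci)
  span <- loci$end0 - loci$start0
  ord <- order(-span, loci$unit_length, loci$start0)
  loci <- loci[ord, , drop = FALSE]
  keep <- logical(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    contained <- any(keep &
                       loci$start0 <= loci$start0[i] &
                       loci$end0 >= loci$end0[i])
    keep[i] <- !contained
  }
  loci <- loci[keep, , drop = FALSE]
  loci[order(loci$start0, loci$unit_length), , drop = FALSE]
}

#' Scan a sequence for perfect SSRs
#'
#' Detects all perfect microsatellites with unit lengths 2-10 whose complete
#' repeat count meets the class minimum in `config` (defaults: dimer-10,
#' trimer-7, tetramer-5, pentamer-4, hexamer-4, heptamer-3, octamer-3,
#' nonamer-3, decamer-2). Mononucleotide and degenerate (non-primitive) units
#' are excluded, so every reported locus under the defaults is at least 20 bp
#' long. Loci fully contained in the span of another reported locus are
#' suppressed.
#'
#' @param sequence A DNA string over `{A,C,G,T,N}`.
#' @param config An [ssr_scan_config()].
#' @param seq_id Identifier attached to the reported loci.
#' @param fraction Fraction label attached to the reported loci.
#' @return A data.frame of loci (columns `seq_id`, `fraction`, `start0`,
#'   `end0`, `unit_length`, `motif`, `canonical`, `repeats`, `length_bp`),
#'   sorted by start.
#' @examples
#' scan_perfect_ssrs(paste0("GGC", strrep("TA", 10), "CCG"))
#' @export
scan_perfect_ssrs <- function(sequence, config = ssr_scan_config(),
                              seq_id = NA_character_,
                              fraction = NA_character_) {
  s <- validate_dna(sequence)
  r <- charToRaw(s)
  ok <- valid_base_mask(r)
  ks <- as.integer(names(config$min_repeats))
  loci <- empty_loci()
  for (k in sort(ks)) {
    min_rep <- config$min_repeats[[as.character(k)]]
    runs <- scan_unit_runs_raw(s, r, ok, k, config, min_copies = min_rep)
    runs <- runs[runs$repeats >= min_rep, , drop = FALSE]
    if (nrow(runs) == 0L) next
    loci <- rbind(loci, data.frame(
      seq_id = seq_id, fraction = fraction,
      start0 = runs$start0, end0 = runs$end0,
      unit_length = runs$unit_length, motif = runs$unit,
      canonical = canonical_class_cached(runs$unit),
      repeats = runs$repeats,
      length_bp = runs$end0 - runs$start0,
      stringsAsFactors = FALSE))
  }
  loci <- resolve_containment(loci)
  rownames(loci) <- NULL
  loci
}

#' Reduce partially overlapping loci to a disjoint set
#'
#' The scanner suppresses only fully contained loci, so two threshold-passing
#' arrays of different unit lengths can still partially overlap. Event
#' merging requires disjoint loci, so this reduction keeps, within any
#' overlapping pair, the longer locus (ties: smaller unit length, then
#' leftmost) and drops the other. Applied by the pipeline between scanning
#' and compound merging.
#'
#' @param loci A loci data.frame.
#' @return The reduced loci data.frame, sorted by sequence/fraction/start.
#' @export
resolve_partial_overlaps <- function(loci) {
  if (nrow(loci) <= 1L) return(loci)
  out <- lapply(split(loci, paste(loci$seq_id, loci$fraction, sep = "\r")),
                function(g) {
    ord <- order(-(g$end0 - g$start0), g$unit_length, g$start0)
    g <- g[ord, , drop = FALSE]
    keep <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
      keep[i] <- !any(keep & g$start0 < g$end0[i] & g$end0 > g$start0[i])
    }
    g[keep, , drop = FALSE]
  })
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$seq_id, loci$fraction, loci$start0), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

#' Merge adjacent loci into perfect and compound events
#'
#' Consecutive loci on the same sequence and fraction whose gap is strictly
#' smaller than `config$max_compound_spacer` (default 100 bp) are grouped into
#' one compound event; grouping is transitive along the chain. Isolated loci
#' become perfect events. A gap of exactly 100 bp therefore separates two
#' perfect events; a gap of 99 bp makes a compound one.
#'
#' @param loci A loci data.frame as returned by [scan_perfect_ssrs()]; may
#'   span several sequences/fractions (grouping never crosses those
#'   boundaries).
#' @param config An [ssr_scan_config()].
#' @return An object of class `ssr_events`: a list with `events` (one row per
#'   event: `event_id`, `seq_id`, `fraction`, `kind`, `start0`, `end0`,
#'   `n_members`) and `members` (the input loci with `event_id` and
#'   `member_index` columns; compound members also record the `spacer_bp` gap
#'   to the previous member).
#' @export
merge_compound <- function(loci, config = ssr_scan_config()) {
  cols <- c("seq_id", "fraction", "start0", "end0")
  stopifnot(all(cols %in% names(loci)))
  loci <- loci[order(loci$seq_id, loci$fraction, loci$start0), , drop = FALSE]
  key <- paste(loci$seq_id, loci$fraction, sep = "\r")
  event_id <- integer(nrow(loci))
  spacer <- rep(NA_integer_, nrow(loci))
  eid <- 0L
  for (g in split(seq_len(nrow(loci)), factor(key, levels = unique(key)))) {
    prev_end <- NULL
    for (i in g) {
      gap <- if (is.null(prev_end)) NA_integer_ else loci$start0[i] - prev_end
      if (!is.na(gap) && gap < 0L) {
        stop_estssr("estssr_overlapping_loci",
                    "merge_compound requires non-overlapping loci")
      }
      if (is.na(gap) || gap >= config$max_compound_spacer) {
        eid <- eid + 1L
      } else {
        spacer[i] <- gap
      }
      event_id[i] <- eid
      prev_end <- loci$end0[i]
    }
  }
  members <- loci
  members$event_id <- event_id
  members$spacer_bp <- spacer
  members$member_index <- stats::ave(event_id, event_id, FUN = seq_along)
  ev <- lapply(split(seq_len(nrow(members)), event_id), function(ix) {
    data.frame(event_id = members$event_id[ix[1]],
               seq_id = members$seq_id[ix[1]],
               fraction = members$fraction[ix[1]],
               kind = if (length(ix) > 1L) "compound" else "perfect",
               start0 = min(members$start0[ix]),
               end0 = max(members$end0[ix]),
               n_members = length(ix),
               stringsAsFactors = FALSE)
  })
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(event_id = integer(0), seq_id = character(0),
               fraction = character(0), kind = character(0),
               start0 = integer(0), end0 = integer(0),
               n_members = integer(0), stringsAsFactors = FALSE)
  rownames(events) <- rownames(members) <- NULL
  structure(list(events = events, members = members), class = "ssr_events")
}

#' @export
print.ssr_events <- function(x, ...) {
  cat(sprintf("<ssr_events> %d events (%d compound), %d member loci\n",
              nrow(x$events), sum(x$events$kind == "compound"),
              nrow(x$members)))
  invisible(x)
}
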