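BASES <- c("A", "C", "G", "T")

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

gc_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

sample_bases <- function(n, gc) {
  if (n <= 0L) return(character(0))
  sample(BASES, n, replace = TRUE, prob = gc_probs(gc))
}

#' Synthetic EST dataset specification
#'
#' Parameters of the EST simulator. The two presets loosely emulate the two
#' regimes the pipeline is designed to contrast: an "angiosperm"-like genus
#' (high repeat density, highest in the 5'UTR, lowest in the ORF, AG-rich
#' dimers) and a "gymnosperm"-like genus (lower overall density, 3'UTR
#' dominant, AT-rich dimers, larger genome size). Densities are SSR events
#' per Mbp of fraction sequence; planted repeat counts always meet the
#' scanner's class minima, and planted events are separated by more than 100
#' bp so they can never merge with one another.
#'
#' @param preset "angiosperm" or "gymnosperm"; individual arguments override
#'   preset values.
#' @param n_sequences Number of ESTs to simulate.
#' @param length_range Min/max EST length (uniform), bp.
#' @param gc_content Background GC fraction in (0, 1).
#' @param orf_fraction Fraction of each EST occupied by the ORF.
#' @param density Named vector of target event densities (events/Mbp) for
#'   "5UTR", "ORF", "3UTR".
#' @param motif_weights Named probability vector over canonical motif
#'   classes (must sum to 1); unit lengths are implied by the class names.
#' @param extra_repeat_prob Geometric success probability for repeat counts:
#'   `count = class_minimum + rgeom(extra_repeat_prob)` (capped at +20).
#' @param compound_proportion Probability that a planted event is compound
#'   (two members of distinct classes).
#' @param spacer_range Min/max spacer between compound members, bp (strictly
#'   below 100 so compound members always merge).
#' @param genome_size_pg Genome size attached to the simulated genus.
#' @param genus Genus label.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("angiosperm", "gymnosperm"),
                           n_sequences = NULL, length_range = NULL,
                           gc_content = NULL, orf_fraction = NULL,
                           density = NULL, motif_weights = NULL,
                           extra_repeat_prob = 0.4,
                           compound_proportion = 0.05,
                           spacer_range = c(1L, 99L),
                           genome_size_pg = NULL, genus = NULL, seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "angiosperm") {
    list(n_sequences = 300L, length_range = c(600L, 1200L),
         gc_content = 0.45, orf_fraction = 0.5,
         density = c("5UTR" = 1500, "ORF" = 600, "3UTR" = 700),
         motif_weights = c(AG = 0.30, AT = 0.15, AC = 0.10, CG = 0.02,
                           AAG = 0.13, ACC = 0.08, AGG = 0.07, AGC = 0.05,
                           ACG = 0.02, AAT = 0.08),
         genome_size_pg = 0.6, genus = "SynAngiosperm")
  } else {
    list(n_sequences = 300L, length_range = c(600L, 1200L),
         gc_content = 0.40, orf_fraction = 0.5,
         density = c("5UTR" = 250, "ORF" = 200, "3UTR" = 300),
         motif_weights = c(AT = 0.35, AG = 0.15, AC = 0.10, CG = 0.02,
                           AAT = 0.12, AAG = 0.10, ACC = 0.06, ATC = 0.06,
                           AGG = 0.04),
         genome_size_pg = 15, genus = "SynGymnosperm")
  }
  spec <- list(
    preset = preset,
    n_sequences = as.integer(n_sequences %||% def$n_sequences),
    length_range = as.integer(length_range %||% def$length_range),
    gc_content = gc_content %||% def$gc_content,
    orf_fraction = orf_fraction %||% def$orf_fraction,
    density = density %||% def$density,
    motif_weights = motif_weights %||% def$motif_weights,
    extra_repeat_prob = extra_repeat_prob,
    compound_proportion = compound_proportion,
    spacer_range = as.integer(spacer_range),
    genome_size_pg = genome_size_pg %||% def$genome_size_pg,
    genus = genus %||% def$genus,
    seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_synthetic_spec <- function(spec) {
  if (abs(sum(spec$motif_weights) - 1) > 1e-8) {
    stop_estssr("estssr_invalid_config", "motif_weights must sum to 1")
  }
  if (is.null(names(spec$motif_weights)) ||
      !all(vapply(names(spec$motif_weights),
                  function(m) canonical_class(m) == m, logical(1)))) {
    stop_estssr("estssr_invalid_config",
                "motif_weights must be named by canonical class representatives")
  }
  if (!all(FRACTIONS %in% names(spec$density))) {
    stop_estssr("estssr_invalid_config",
                "density must name all of 5UTR, ORF, 3UTR")
  }
  if (spec$gc_content <= 0 || spec$gc_content >= 1) {
    stop_estssr("estssr_invalid_config", "gc_content must be in (0, 1)")
  }
  if (spec$spacer_range[1] < 0L || spec$spacer_range[2] >= 100L ||
      spec$spacer_range[1] > spec$spacer_range[2]) {
    stop_estssr("estssr_invalid_config", "spacer_range must lie within [0, 100)")
  }
  invisible(spec)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %s (%s preset): %d ESTs of %d-%d bp, GC %.2f, densities %s /Mbp, seed %d\n",
              x$genus, x$preset, x$n_sequences, x$length_range[1],
              x$length_range[2], x$gc_content,
              paste(sprintf("%s=%g", names(x$density[FRACTIONS]),
                            x$density[FRACTIONS]), collapse = " "),
              x$seed))
  invisible(x)
}

#' Generate SSR-free background sequence
#'
#' Draws i.i.d. bases at the requested GC content, then rejection-resamples
#' any window in which the scanner finds a threshold-passing SSR until the
#' sequence is certified repeat-free. This makes downstream precision/recall
#' on planted repeats exact rather than probabilistic.
#'
#' @param length Sequence length (> 0).
#' @param gc GC fraction in (0, 1).
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used.
#' @param config Scanner configuration defining "repeat-free".
#' @return A DNA string.
#' @export
generate_background <- function(length, gc, seed = NULL,
                                config = ssr_scan_config()) {
  stopifnot(length > 0, gc > 0, gc < 1)
  gen <- function() {
    s <- sample_bases(length, gc)
    for (iter in 1:100) {
      loci <- scan_perfect_ssrs(paste(s, collapse = ""), config)
      if (nrow(loci) == 0L) return(paste(s, collapse = ""))
      for (i in seq_len(nrow(loci))) {
        span <- (loci$start0[i] + 1L):loci$end0[i]
        s[span] <- sample_bases(base::length(span), gc)
      }
    }
    stop_estssr("estssr_infeasible_spec",
                "could not generate an SSR-free background")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Members of a canonical class (rotations of the representative and of its
# reverse complement).
class_members <- function(canonical) {
  unique(c(rotations(canonical), rotations(revcomp(canonical))))
}

# Draw one planted event description: 1 (perfect) or 2 (compound) member
# units with repeat counts meeting the scanner minima.
draw_event <- function(spec, config) {
  n_members <- if (runif(1) < spec$compound_proportion) 2L else 1L
  canon <- sample(names(spec$motif_weights), 1, prob = spec$motif_weights)
  if (n_members == 2L) {
    others <- setdiff(names(spec$motif_weights), canon)
    canon <- c(canon, if (length(others))
      sample(others, 1, prob = spec$motif_weights[others]) else canon)
  }
  units <- vapply(canon, function(cc) sample(class_members(cc), 1), character(1))
  reps <- vapply(units, function(u) {
    k <- as.character(nchar(u))
    config$min_repeats[[k]] + min(rgeom(1, spec$extra_repeat_prob), 20L)
  }, numeric(1))
  spacer <- if (n_members == 2L)
    sample(spec$spacer_range[1]:spec$spacer_range[2], 1) else integer(0)
  list(canon = unname(canon), units = unname(units),
       reps = as.integer(unname(reps)), spacer = as.integer(spacer))
}

# In-frame stop check for a fragment region: TRUE when codons of fragment
# chars (1-based index range) contain no stop, assuming the fragment is a
# frame-0 coding region.
region_stop_free <- function(chars, from, to) {
  c0 <- (from - 1L) %/% 3L          # first codon index (0-based) touched
  c1 <- (to - 1L) %/% 3L
  idx <- (c0 * 3L + 1L):min(c1 * 3L + 3L, base::length(chars))
  codons <- frame_codons(paste(chars[idx], collapse = ""), 0L)
  !any(codons %in% STOP_CODONS)
}

# Plant `n` events into a background fragment. Returns NULL when placement
# fails (caller retries with a fresh fragment), otherwise
# list(chars, truth rows). `coding` activates in-frame stop avoidance.
plant_into_fragment <- function(chars, fraction, n, spec, config, coding) {
  len <- base::length(chars)
  margin <- if (coding) 4L else 2L
  placed <- matrix(numeric(0), ncol = 2)   # occupied [start, end) 0-based
  truth <- list()
  for (e in seq_len(n)) {
    ev <- draw_event(spec, config)
    member_len <- nchar(ev$units) * ev$reps
    ev_len <- sum(member_len) + sum(ev$spacer)
    ok <- FALSE
    for (attempt in 1:400) {
      if (len - ev_len - 2L * margin < 1L) break
      p <- sample.int(len - ev_len - 2L * margin, 1) + margin  # 0-based start
      if (nrow(placed) &&
          any(p < placed[, 2] + 101 & p + ev_len > placed[, 1] - 101)) next
      cand <- build_event_chars(chars, p, ev, member_len, spec, coding)
      if (is.null(cand)) next
      chars <- cand
      placed <- rbind(placed, c(p, p + ev_len))
      truth[[base::length(truth) + 1L]] <- data.frame(
        fraction = fraction, start0 = p, end0 = p + ev_len,
        kind = if (base::length(ev$units) > 1L) "compound" else "perfect",
        n_members = base::length(ev$units),
        units = paste(ev$units, collapse = ","),
        canonicals = paste(ev$canon, collapse = ","),
        repeat_counts = paste(ev$reps, collapse = ","),
        spacers = paste(ev$spacer, collapse = ","),
        stringsAsFactors = FALSE)
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  truth <- if (base::length(truth)) do.call(rbind, truth) else NULL
  if (!is.null(truth)) {
    truth <- truth[order(truth$start0), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(chars = chars, truth = truth)
}

# Write one event (members + spacers + flank breaks) into `chars` starting at
# 0-based position p; NULL when no stop-free arrangement is found for coding
# fragments.
build_event_chars <- function(chars, p, ev, member_len, spec, coding) {
  pos <- p   # 0-based cursor
  new <- chars
  for (m in seq_along(ev$units)) {
    unit_chars <- strsplit(ev$units[m], "")[[1]]
    k <- base::length(unit_chars)
    seg <- rep(unit_chars, ev$reps[m])
    new[(pos + 1L):(pos + member_len[m])] <- seg
    # break left-phase extension: char before member must differ from the
    # char one unit-length into the member
    left <- pos       # 1-based index of flank char is `pos`
    need_ne <- new[pos + k]
    if (left >= 1L && new[left] == need_ne) {
      new[left] <- sample(setdiff(BASES, need_ne), 1)
    }
    pos <- pos + member_len[m]
    if (m < base::length(ev$units)) {
      sp <- ev$spacer[m]
      spacer_chars <- sample_bases(sp, spec$gc_content)
      # spacer must not extend the previous member by a partial copy, and its
      # last char must not phase-extend the next member leftwards
      if (spacer_chars[1] == new[pos + 1L - k]) {
        spacer_chars[1] <- sample(setdiff(BASES, new[pos + 1L - k]), 1)
      }
      next_k <- nchar(ev$units[m + 1L])
      new[(pos + 1L):(pos + sp)] <- spacer_chars
      pos <- pos + sp
      nk_char <- strsplit(ev$units[m + 1L], "")[[1]][next_k]
      if (new[pos] == nk_char) {
        new[pos] <- sample(setdiff(BASES, nk_char), 1)
      }
    }
  }
  # break rightward completion of the final member
  k_last <- nchar(ev$units[base::length(ev$units)])
  if (pos + 1L <= base::length(new) && new[pos + 1L] == new[pos + 1L - k_last]) {
    new[pos + 1L] <- sample(setdiff(BASES, new[pos + 1L - k_last]), 1)
  }
  if (coding) {
    # affected 1-based range: left flank char (index p) through right flank
    # (index pos + 1)
    if (!region_stop_free(new, max(p, 1L), min(pos + 1L, base::length(new)))) {
      return(NULL)
    }
  }
  new
}

#' Plant SSR events into a fractioned sequence
#'
#' Inserts perfect and compound SSR events into the 5'UTR/ORF/3'UTR spans of
#' a sequence at Poisson-drawn counts matching each fraction's target density
#' (events/Mbp). Planted events are mutually separated by more than 100 bp,
#' their flanks are adjusted so the tandem array can neither extend nor shift
#' phase, and events planted inside the ORF are phase-checked so they never
#' introduce an in-frame stop codon. Each planted fraction is re-scanned and
#' re-planted until the scanner recovers exactly the planted events, so
#' recovery is guaranteed by construction.
#'
#' @param sequence A DNA string whose spans are SSR-free background (see
#'   [generate_background()]).
#' @param spans Fraction span data.frame (`fraction`, `start0`, `end0`) as in
#'   a `fractioned_sequence`.
#' @param spec A [synthetic_spec()].
#' @param config Scanner configuration used for verification.
#' @param seq_id Identifier recorded in the manifest.
#' @return List with `sequence` (modified string) and `truth` (manifest
#'   data.frame with fraction-local 0-based coordinates; `NULL` columns when
#'   no event was planted).
#' @export
plant_ssrs <- function(sequence, spans, spec, config = ssr_scan_config(),
                       seq_id = NA_character_) {
  s <- validate_dna(sequence)
  frags <- setNames(substring(s, spans$start0 + 1L, spans$end0),
                    spans$fraction)
  out_truth <- list()
  for (fr in spans$fraction) {
    len <- nchar(frags[[fr]])
    if (len == 0L) next
    n <- rpois(1, spec$density[[fr]] * len / 1e6)
    if (n == 0L) next
    res <- plant_fragment_verified(frags[[fr]], fr, n, spec, config)
    frags[[fr]] <- res$fragment
    if (!is.null(res$truth)) {
      res$truth$seq_id <- seq_id
      out_truth[[base::length(out_truth) + 1L]] <- res$truth
    }
  }
  truth <- if (base::length(out_truth)) do.call(rbind, out_truth) else NULL
  list(sequence = paste(frags[spans$fraction], collapse = ""), truth = truth)
}

# Plant n events into a fragment and verify by re-scanning; re-draws the
# placement until the scan reproduces the planted truth exactly. With
# `strict = FALSE`, capacity failures (no placement with >100 bp separation)
# return NULL instead of raising, so the caller can move events to another
# fragment.
plant_fragment_verified <- function(fragment, fraction, n, spec, config,
                                    max_tries = 50L, strict = TRUE) {
  coding <- fraction == "ORF"
  n_capacity_fail <- 0L
  for (try in seq_len(max_tries)) {
    chars <- strsplit(fragment, "")[[1]]
    res <- plant_into_fragment(chars, fraction, n, spec, config, coding)
    if (is.null(res)) {
      n_capacity_fail <- n_capacity_fail + 1L
      if (n_capacity_fail >= 5L) {
        if (!strict) return(NULL)
        stop_estssr("estssr_infeasible_spec", sprintf(
          "cannot place %d events with >100 bp separation in a %d bp %s fragment",
          n, nchar(fragment), fraction))
      }
      next
    }
    planted <- paste(res$chars, collapse = "")
    if (planting_verified(planted, res$truth, fraction, config, coding)) {
      return(list(fragment = planted, truth = res$truth))
    }
  }
  stop_estssr("estssr_infeasible_spec",
              "planted events could not be verified after repeated redraws")
}

planting_verified <- function(fragment, truth, fraction, config, coding) {
  # a scan yielding partially overlapping loci cannot match the planted
  # layout; treat it as a failed draw
  ev <- tryCatch(
    merge_compound(scan_perfect_ssrs(fragment, config, seq_id = "x",
                                     fraction = fraction), config),
    estssr_overlapping_loci = function(e) NULL)
  if (is.null(ev)) return(FALSE)
  found <- ev$events
  tr <- truth[order(truth$start0), , drop = FALSE]
  if (nrow(found) != nrow(tr)) return(FALSE)
  if (!all(found$start0 == tr$start0 & found$end0 == tr$end0 &
           found$kind == tr$kind & found$n_members == tr$n_members)) {
    return(FALSE)
  }
  by_ev <- split(ev$members, ev$members$event_id)
  for (i in seq_len(nrow(tr))) {
    mem <- by_ev[[i]]
    if (paste(mem$motif, collapse = ",") != tr$units[i]) return(FALSE)
    if (paste(mem$repeats, collapse = ",") != tr$repeat_counts[i]) return(FALSE)
  }
  if (coding && !region_stop_free(strsplit(fragment, "")[[1]],
                                  4L, nchar(fragment) - 3L)) {
    return(FALSE)
  }
  TRUE
}

# Non-stop codon string of n codons at the background GC.
coding_interior <- function(n_codons, gc) {
  if (n_codons <= 0L) return(character(0))
  codons <- paste0(sample_bases(n_codons, gc),
                   sample_bases(n_codons, gc),
                   sample_bases(n_codons, gc))
  bad <- which(codons %in% STOP_CODONS)
  while (base::length(bad)) {
    codons[bad] <- paste0(sample_bases(base::length(bad), gc),
                          sample_bases(base::length(bad), gc),
                          sample_bases(base::length(bad), gc))
    bad <- which(codons %in% STOP_CODONS)
  }
  codons
}

# SSR-free, stop-free frame-0 coding fragment: ATG + interior + stop.
generate_coding_fragment <- function(orf_len, gc, config) {
  n_int <- orf_len %/% 3L - 2L
  codons <- c("ATG", coding_interior(n_int, gc),
              sample(STOP_CODONS, 1, prob = c(0.5, 0.2, 0.3)))
  for (iter in 1:100) {
    s <- paste(codons, collapse = "")
    loci <- scan_perfect_ssrs(s, config)
    if (nrow(loci) == 0L) return(s)
    # resample interior codons overlapping any detected repeat
    for (i in seq_len(nrow(loci))) {
      c0 <- max(loci$start0[i] %/% 3L, 1L)
      c1 <- min(loci$end0[i] %/% 3L, n_int)
      if (c1 >= c0) codons[(c0:c1) + 1L] <- coding_interior(c1 - c0 + 1L, gc)
    }
  }
  stop_estssr("estssr_infeasible_spec", "could not build an SSR-free ORF")
}

#' Generate a synthetic genus dataset with ground truth
#'
#' Builds `n_sequences` EST-like sequences, each as 5'UTR + ORF + 3'UTR: the
#' UTRs are SSR-free random background, the ORF is an ATG-to-stop frame-0
#' coding region free of internal in-frame stops and of repeats, and SSR
#' events are planted into each fraction at the spec's target densities.
#' Each sequence is verified end to end -- the six-frame longest-ORF caller
#' must recover the planted ORF exactly and the scanner must recover exactly
#' the planted events -- and re-drawn otherwise, so recovery on the emitted
#' dataset is exact. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param config Scanner configuration.
#' @param min_orf_bp Minimum ORF length passed to the verification caller.
#' @return An object of class `genus_dataset`: list with `sequences` (named
#'   character), `truth` (manifest data.frame, fraction-local coordinates),
#'   `fractions` (per-sequence fraction lengths), `genus`, `genome_size_pg`
#'   and `spec`.
#' @export
generate_genus_dataset <- function(spec, config = ssr_scan_config(),
                                   min_orf_bp = 90L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_sequences
  with_seed(spec$seed, {
    ids <- if (n) sprintf("%s_est%05d", spec$genus, seq_len(n)) else character(0)
    # --- skeletons: repeat-free UTR backgrounds + stop-free coding regions
    frag <- list()      # frag[[i]] = named character(3)
    spans_list <- list()
    for (i in seq_len(n)) {
      L <- sample(spec$length_range[1]:spec$length_range[2], 1)
      orf_len <- 3L * max((round(L * spec$orf_fraction)) %/% 3L,
                          ceiling(max(min_orf_bp, 90L) / 3))
      orf_len <- min(orf_len, 3L * (L %/% 3L))
      utr5 <- (L - orf_len) %/% 2L
      utr3 <- L - orf_len - utr5
      frag[[i]] <- build_skeleton(utr5, orf_len, utr3, spec, config,
                                  min_orf_bp)
      spans_list[[i]] <- data.frame(
        seq_id = ids[i], fraction = FRACTIONS,
        start0 = c(0L, utr5, utr5 + orf_len),
        end0 = c(utr5, utr5 + orf_len, utr5 + orf_len + utr3),
        length_bp = c(utr5, orf_len, utr3), stringsAsFactors = FALSE)
    }
    # --- pooled planting: Poisson event totals per fraction, allocated to
    # fragments proportionally to length, redistributed when a fragment
    # cannot hold its share with >100 bp separation
    alloc <- matrix(0L, nrow = max(n, 1L), ncol = 3,
                    dimnames = list(NULL, FRACTIONS))
    truth <- list()
    if (n) {
      for (fr in FRACTIONS) {
        lens <- vapply(spans_list, function(sp)
          sp$length_bp[sp$fraction == fr], numeric(1))
        total <- sum(lens)
        if (total == 0) next
        n_ev <- rpois(1, spec$density[[fr]] * total / 1e6)
        if (n_ev == 0L) next
        alloc[, fr] <- tabulate(sample.int(n, n_ev, replace = TRUE,
                                           prob = lens), nbins = n)
        pending <- which(alloc[, fr] > 0L)
        moves <- 0L
        while (length(pending)) {
          i <- pending[1]
          res <- plant_fragment_verified(frag[[i]][[fr]], fr, alloc[i, fr],
                                         spec, config, strict = FALSE)
          if (is.null(res)) {
            alloc[i, fr] <- alloc[i, fr] - 1L
            j <- sample.int(n, 1, prob = lens)
            alloc[j, fr] <- alloc[j, fr] + 1L
            pending <- union(pending, j)
            if (alloc[i, fr] == 0L) pending <- setdiff(pending, i)
            moves <- moves + 1L
            if (moves > 50L + 2L * n_ev) {
              stop_estssr("estssr_infeasible_spec", sprintf(
                "cannot place %d %s events at >100 bp separation", n_ev, fr))
            }
          } else {
            frag[[i]][[fr]] <- res$fragment
            res$truth$seq_id <- ids[i]
            truth[[paste(fr, i)]] <- res$truth
            pending <- setdiff(pending, i)
          }
        }
      }
    }
    # --- sequence-level verification: the planted ORF must be the unique
    # longest-ORF call on the assembled sequence; rebuild offenders
    seqs <- character(n)
    for (i in seq_len(n)) {
      sp <- spans_list[[i]]
      for (try in 1:25) {
        full <- paste(frag[[i]][FRACTIONS], collapse = "")
        oc <- find_longest_orf(full, min_orf_bp)
        if (!is.null(oc) && oc$strand == "forward" &&
            oc$start0 == sp$start0[2] && oc$end0 == sp$end0[2]) break
        # rebuild this sequence with the same fraction lengths and event
        # counts, under fresh randomness
        frag[[i]] <- build_skeleton(sp$length_bp[1], sp$length_bp[2],
                                    sp$length_bp[3], spec, config, min_orf_bp)
        for (fr in FRACTIONS) {
          if (alloc[i, fr] > 0L) {
            res <- plant_fragment_verified(frag[[i]][[fr]], fr, alloc[i, fr],
                                           spec, config)
            frag[[i]][[fr]] <- res$fragment
            res$truth$seq_id <- ids[i]
            truth[[paste(fr, i)]] <- res$truth
          }
        }
        if (try == 25L) {
          stop_estssr("estssr_infeasible_spec",
                      sprintf("failed to assemble sequence %d", i))
        }
      }
      seqs[i] <- paste(frag[[i]][FRACTIONS], collapse = "")
    }
    truth <- if (base::length(truth)) do.call(rbind, truth) else
      data.frame(fraction = character(0), start0 = integer(0),
                 end0 = integer(0), kind = character(0),
                 n_members = integer(0), units = character(0),
                 canonicals = character(0), repeat_counts = character(0),
                 spacers = character(0), seq_id = character(0),
                 stringsAsFactors = FALSE)
    truth <- truth[order(truth$seq_id, match(truth$fraction, FRACTIONS),
                         truth$start0), , drop = FALSE]
    rownames(truth) <- NULL
    fractions <- if (base::length(spans_list)) do.call(rbind, spans_list) else
      data.frame(seq_id = character(0), fraction = character(0),
                 start0 = integer(0), end0 = integer(0),
                 length_bp = integer(0), stringsAsFactors = FALSE)
    structure(list(sequences = setNames(seqs, ids),
                   truth = truth[, c("seq_id", "fraction", "start0", "end0",
                                     "kind", "n_members", "units",
                                     "canonicals", "repeat_counts",
                                     "spacers")],
                   fractions = fractions,
                   genus = spec$genus,
                   genome_size_pg = spec$genome_size_pg,
                   spec = spec),
              class = "genus_dataset")
  })
}

# UTR backgrounds plus coding fragment for one EST, re-drawn until the
# planted ORF is the unique longest-ORF call on the unplanted skeleton.
build_skeleton <- function(utr5, orf_len, utr3, spec, config, min_orf_bp) {
  for (try in 1:50) {
    u5 <- if (utr5 > 0L) generate_background(utr5, spec$gc_content,
                                             config = config) else ""
    u3 <- if (utr3 > 0L) generate_background(utr3, spec$gc_content,
                                             config = config) else ""
    orf <- generate_coding_fragment(orf_len, spec$gc_content, config)
    oc <- find_longest_orf(paste0(u5, orf, u3), min_orf_bp)
    if (!is.null(oc) && oc$strand == "forward" && oc$start0 == utr5 &&
        oc$end0 == utr5 + orf_len) {
      return(setNames(c(u5, orf, u3), FRACTIONS))
    }
  }
  stop_estssr("estssr_infeasible_spec",
              "could not build an EST skeleton with a dominant planted ORF")
}

#' @export
print.genus_dataset <- function(x, ...) {
  cat(sprintf("<genus_dataset> %s: %d sequences (%.3f Mbp), %d planted events\n",
              x$genus, base::length(x$sequences),
              sum(nchar(x$sequences)) / 1e6, nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic genus dataset to disk
#'
#' Writes the FASTA, the ground-truth manifest (JSON) and a one-row
#' genome-size metadata TSV.
#'
#' @param dataset A `genus_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the file paths written.
#' @export
write_genus_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(dataset$genus, ".fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(dataset$sequences), fa, width = 70L)
  manifest <- file.path(dir, paste0(dataset$genus, "_truth.json"))
  jsonlite::write_json(dataset$truth, manifest, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  meta <- file.path(dir, paste0(dataset$genus, "_metadata.tsv"))
  write_tsv_fixed(data.frame(genus = dataset$genus,
                             genome_size_pg = dataset$genome_size_pg,
                             n_sequences = base::length(dataset$sequences),
                             stringsAsFactors = FALSE), meta)
  invisible(c(fa, manifest, meta))
}

#' Score detected events against the planted ground truth
#'
#' Matches detected events to planted events within the same sequence and
#' fraction by at least 50 percent reciprocal span overlap, then reports
#' precision (matched / detected), recall (matched / planted) and, over
#' matched pairs, the agreement rates of the fraction label, the ordered
#' member canonical classes and the ordered member repeat counts. With zero
#' detections precision is reported as 1 and flagged.
#'
#' @param truth Manifest data.frame from the generator.
#' @param events An `ssr_events` object of detected events (loci coordinates
#'   fraction-local, as produced by scanning fraction subsequences).
#' @return An object of class `recovery_report`.
#' @export
evaluate_recovery <- function(truth, events) {
  stopifnot(inherits(events, "ssr_events"))
  det <- events$events
  mem <- split(events$members, events$members$event_id)
  det$canonicals <- vapply(as.character(det$event_id), function(id)
    paste(mem[[id]]$canonical, collapse = ","), character(1))
  det$repeat_counts <- vapply(as.character(det$event_id), function(id)
    paste(mem[[id]]$repeats, collapse = ","), character(1))
  n_planted <- nrow(truth)
  n_detected <- nrow(det)
  matched <- 0L
  agree <- c(fraction = 0L, canonical = 0L, repeat_count = 0L)
  if (n_planted && n_detected) {
    for (i in seq_len(n_planted)) {
      cand <- which(det$seq_id == truth$seq_id[i] &
                      det$fraction == truth$fraction[i])
      if (!base::length(cand)) next
      ov <- pmin(det$end0[cand], truth$end0[i]) -
        pmax(det$start0[cand], truth$start0[i])
      lt <- truth$end0[i] - truth$start0[i]
      ld <- det$end0[cand] - det$start0[cand]
      ok <- ov >= 0.5 * lt & ov >= 0.5 * ld
      if (!any(ok)) next
      j <- cand[ok][which.max(ov[ok])]
      matched <- matched + 1L
      agree["fraction"] <- agree["fraction"] +
        (det$fraction[j] == truth$fraction[i])
      agree["canonical"] <- agree["canonical"] +
        (det$canonicals[j] == truth$canonicals[i])
      agree["repeat_count"] <- agree["repeat_count"] +
        (det$repeat_counts[j] == truth$repeat_counts[i])
      det <- det[det$event_id != det$event_id[j], , drop = FALSE]
      if (!nrow(det)) break
    }
  }
  structure(list(
    n_planted = n_planted, n_detected = n_detected, n_matched = matched,
    precision = if (n_detected == 0L) 1 else matched / n_detected,
    recall = if (n_planted == 0L) 1 else matched / n_planted,
    zero_detections = n_detected == 0L && n_planted > 0L,
    field_agreement = if (matched) agree / matched
                      else setNames(rep(NA_real_, 3), names(agree))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> planted %d, detected %d, matched %d: precision %.3f, recall %.3f\n",
              x$n_planted, x$n_detected, x$n_matched, x$precision, x$recall))
  if (x$n_matched) {
    cat(sprintf("field agreement: fraction %.3f, canonical %.3f, repeat count %.3f\n",
                x$field_agreement["fraction"], x$field_agreement["canonical"],
                x$field_agreement["repeat_count"]))
  }
  invisible(x)
}
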