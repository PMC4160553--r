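# Fraction labels used throughout the package. `UNPARTITIONED` marks sequences
# for which no ORF call was possible; they are excluded from fraction tables.
FRACTIONS <- c("5UTR", "ORF", "3UTR")
FRACTION_LEVELS <- c(FRACTIONS, "unpartitioned")

#' Reverse complement of a DNA string
#'
#' Byte-level reverse complement over the alphabet `{A,C,G,T,N}` (case
#' preserved for the canonical uppercase alphabet; inputs are expected
#' uppercase).
#'
#' @param x A character vector of DNA strings.
#' @return A character vector of the same length.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Validate a repeat motif
#'
#' A motif is an uppercase DNA string over `{A,C,G,T}` of length 2 to 10.
#' Invalid motifs raise an error of class `estssr_invalid_motif`.
#'
#' @param motif A single character string.
#' @return The motif, invisibly, if valid.
#' @keywords internal
validate_motif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif)) {
    stop_estssr("estssr_invalid_motif", "motif must be a single DNA string")
  }
  k <- nchar(motif)
  if (k < 2L || k > 10L) {
    stop_estssr("estssr_invalid_motif",
                sprintf("motif length %d outside [2, 10]: %s", k, motif))
  }
  if (grepl("[^ACGT]", motif)) {
    stop_estssr("estssr_invalid_motif",
                sprintf("motif contains characters outside {A,C,G,T}: %s", motif))
  }
  invisible(motif)
}

#' All cyclic rotations of a motif
#'
#' @param motif A DNA string.
#' @return Character vector of `nchar(motif)` rotations (including the motif).
#' @export
rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1, i - 1L))
  }, character(1))
}

#' Is a motif primitive?
#'
#' A motif is primitive when it is not an exact concatenation of two or more
#' copies of a shorter unit. Homopolymer units ("AA", "AAA", ...) are
#' non-primitive, which is how mononucleotide repeats are excluded from
#' scanning: a poly-A tract can never surface as a degenerate dimer or trimer.
#'
#' @param motif A DNA string of length 2 to 10.
#' @return `TRUE` if primitive, `FALSE` otherwise.
#' @examples
#' is_primitive("ACG")  # TRUE
#' is_primitive("ATAT") # FALSE, (AT) x 2
#' is_primitive("AAA")  # FALSE, (A) x 3
#' @export
is_primitive <- function(motif) {
  validate_motif(motif)
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(motif, 1L, d), k %/% d) == motif) {
      return(FALSE)
    }
  }
  TRUE
}

#' Canonical motif class representative
#'
#' Repeat units that are cyclic rotations and/or reverse complements of each
#' other describe the same microsatellite (e.g. AC, CA, GT and TG), so counts
#' are pooled into one class. The class representative is the
#' lexicographically smallest string among all rotations of the motif and all
#' rotations of its reverse complement.
#'
#' @param motif A primitive DNA motif (length 2-10).
#' @return The canonical representative (same length as `motif`).
#' @examples
#' canonical_class("GT")   # "AC"
#' canonical_class("CGA")  # "ACG"
#' canonical_class("TTG")  # "AAC"
#' @export
canonical_class <- function(motif) {
  if (!is_primitive(motif)) {
    stop_estssr("estssr_invalid_motif",
                sprintf("motif is not primitive: %s", motif))
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' Enumerate canonical motif classes of a given unit length
#'
#' Exhaustively enumerates all primitive motifs of length `unit_length` and
#' returns the sorted unique canonical representatives. There are 4 dimer
#' classes (AC, AG, AT, CG) and 10 trimer classes.
#'
#' @param unit_length Integer unit length (2-10; exhaustive enumeration is
#'   practical up to 6 or 7).
#' @return Sorted character vector of canonical representatives.
#' @export
canonical_motif_classes <- function(unit_length) {
  stopifnot(unit_length >= 2L, unit_length <= 10L)
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), unit_length),
                    list(stringsAsFactors = FALSE)))
  motifs <- do.call(paste0, grid)
  prim <- motifs[vapply(motifs, is_primitive, logical(1))]
  sort(unique(vapply(prim, canonical_class, character(1))))
}

# memoised canonical_class over a character vector (scanner hot path)
.canon_cache <- new.env(parent = emptyenv())
canonical_class_cached <- function(motifs) {
  vapply(motifs, function(m) {
    hit <- .canon_cache[[m]]
    if (is.null(hit)) {
      hit <- canonical_class(m)
      assign(m, hit, envir = .canon_cache)
    }
    hit
  }, character(1), USE.NAMES = FALSE)
}

# Internal error helper: all user-facing failures carry a condition class so
# callers (and the pipeline log) can distinguish rejection kinds.
stop_estssr <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "estssr_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

# Uppercase and validate a sequence for scanning. Characters outside
# {A,C,G,T,N} reject the record.
validate_dna <- function(sequence, allow_n = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop_estssr("estssr_invalid_sequence", "sequence must be a single string")
  }
  s <- toupper(sequence)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (grepl(pat, s)) {
    bad <- regmatches(s, regexpr(pat, s))
    stop_estssr("estssr_invalid_sequence",
                sprintf("sequence contains invalid character '%s'", bad))
  }
  s
}
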