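STOP_CODONS <- c("TAA", "TAG", "TGA")

orf_call <- function(seq_id = NA_character_, start0, end0, strand, frame,
                     length_bp = end0 - start0) {
  structure(list(seq_id = seq_id, start0 = as.integer(start0),
                 end0 = as.integer(end0), strand = strand,
                 frame = as.integer(frame),
                 length_bp = as.integer(length_bp)),
            class = "orf_call")
}

#' @export
print.orf_call <- function(x, ...) {
  cat(sprintf("<orf_call> %s [%d, %d) %s frame %d (%d bp)\n",
              ifelse(is.na(x$seq_id), "<unnamed>", x$seq_id),
              x$start0, x$end0, x$strand, x$frame, x$length_bp))
  invisible(x)
}

# Codons of `s` in frame f (0-2); returns character vector, last partial
# codon dropped.
frame_codons <- function(s, f) {
  n <- nchar(s)
  starts <- seq.int(f + 1L, by = 3L, length.out = (n - f) %/% 3L)
  if (length(starts) == 0L) return(character(0))
  substring(s, starts, starts + 2L)
}

#' Find the longest open reading frame in six frames
#'
#' Scans the three forward frames and the three frames of the reverse
#' complement for ATG-to-stop spans (stop codon included) and returns the
#' longest one, as a call whose coordinates refer to the oriented
#' (forward-coding) sequence. On transcripts carrying several ORFs the
#' longest is taken as the true coding region; ties are broken in favour of
#' the forward strand, then the leftmost start on the oriented sequence.
#'
#' @param sequence A DNA string.
#' @param min_orf_bp Minimum ORF length in bp, ATG through stop inclusive
#'   (default 90).
#' @param seq_id Identifier attached to the call.
#' @return An `orf_call` (fields `seq_id`, `start0`, `end0`, `strand`
#'   ("forward"/"reverse"), `frame`, `length_bp`), or `NULL` when no ORF of at
#'   least `min_orf_bp` exists.
#' @export
find_longest_orf <- function(sequence, min_orf_bp = 90L,
                             seq_id = NA_character_) {
  s <- validate_dna(sequence)
  if (nchar(s) < 3L) {
    stop_estssr("estssr_invalid_sequence", "sequence shorter than one codon")
  }
  best <- NULL
  for (strand in c("forward", "reverse")) {
    oriented <- if (strand == "forward") s else revcomp(s)
    for (f in 0:2) {
      codons <- frame_codons(oriented, f)
      atg <- which(codons == "ATG")
      stp <- which(codons %in% STOP_CODONS)
      if (length(atg) == 0L || length(stp) == 0L) next
      # first stop at or after each ATG
      j <- stp[findInterval(atg - 0.5, stp) + 1L]
      ok <- !is.na(j)
      if (!any(ok)) next
      len <- (j[ok] - atg[ok] + 1L) * 3L
      start0 <- f + (atg[ok] - 1L) * 3L
      cand_ok <- len >= min_orf_bp
      if (!any(cand_ok)) next
      len <- len[cand_ok]; start0 <- start0[cand_ok]
      rank <- order(-len, start0)[1]
      cand <- orf_call(seq_id, start0[rank], start0[rank] + len[rank],
                       strand, f)
      if (is.null(best) ||
          cand$length_bp > best$length_bp ||
          (cand$length_bp == best$length_bp &&
           best$strand == "reverse" && cand$strand == "forward") ||
          (cand$length_bp == best$length_bp && cand$strand == best$strand &&
           cand$start0 < best$start0)) {
        best <- cand
      }
    }
  }
  best
}

#' Partition a sequence into 5'UTR, ORF and 3'UTR
#'
#' Orients the sequence so that the ORF reads forward (reverse-complementing
#' it for reverse-strand calls) and assigns the flanking spans: the 5'UTR is
#' everything upstream of the ATG, the 3'UTR everything downstream of the
#' stop codon (the stop codon belongs to the ORF span). UTR spans may be
#' empty; the three span lengths always sum to the sequence length.
#'
#' @param sequence A DNA string.
#' @param orf An `orf_call` with coordinates on the oriented sequence.
#' @param seq_id Identifier; defaults to the one in `orf`.
#' @return An object of class `fractioned_sequence`: list with `seq_id`,
#'   `oriented_residues` and `spans` (data.frame `fraction`, `start0`, `end0`,
#'   `length_bp`).
#' @export
partition_by_orf <- function(sequence, orf, seq_id = orf$seq_id) {
  s <- validate_dna(sequence)
  L <- nchar(s)
  oriented <- if (identical(orf$strand, "reverse")) revcomp(s) else s
  if (orf$start0 < 0L || orf$end0 > L || orf$end0 <= orf$start0 ||
      (orf$end0 - orf$start0) %% 3L != 0L) {
    stop_estssr("estssr_invalid_orf",
                sprintf("ORF span [%d, %d) invalid for sequence of length %d",
                        orf$start0, orf$end0, L))
  }
  spans <- data.frame(
    fraction = FRACTIONS,
    start0 = c(0L, orf$start0, orf$end0),
    end0 = c(orf$start0, orf$end0, L),
    stringsAsFactors = FALSE)
  spans$length_bp <- spans$end0 - spans$start0
  structure(list(seq_id = seq_id, oriented_residues = oriented, spans = spans),
            class = "fractioned_sequence")
}

#' @export
print.fractioned_sequence <- function(x, ...) {
  cat(sprintf("<fractioned_sequence> %s (%d bp): 5'UTR %d bp | ORF %d bp | 3'UTR %d bp\n",
              ifelse(is.na(x$seq_id), "<unnamed>", x$seq_id),
              nchar(x$oriented_residues),
              x$spans$length_bp[1], x$spans$length_bp[2], x$spans$length_bp[3]))
  invisible(x)
}

#' Extract the three fraction subsequences
#'
#' Returns the 5'UTR, ORF and 3'UTR subsequences of a `fractioned_sequence`
#' as a named character vector (empty fractions give `""`). Downstream SSR
#' scanning operates on these three subsequences independently, so a repeat
#' straddling a fraction boundary is truncated at the boundary.
#'
#' @param fs A `fractioned_sequence` from [partition_by_orf()].
#' @return Named character vector of length 3.
#' @export
fraction_subsequences <- function(fs) {
  setNames(substring(fs$oriented_residues, fs$spans$start0 + 1L,
                     fs$spans$end0),
           fs$spans$fraction)
}

#' Load ORF calls from a GFF3 or BED annotation file
#'
#' Reads CDS-like records and converts them to ORF calls in the package's
#' 0-based half-open convention (GFF3 coordinates are 1-based inclusive; BED
#' is already half-open -- both conversions are handled by the importer).
#' When a sequence has several records, the longest span is kept. Records on
#' the minus strand are flipped onto the oriented (reverse-complemented)
#' sequence, which requires `seq_lengths`; minus-strand records without a
#' known sequence length are rejected with a warning, as are records for
#' spans whose length is not a codon multiple.
#'
#' @param path Path to a `.gff3`/`.gff` or `.bed` file.
#' @param format "auto" (from extension), "gff3" or "bed".
#' @param seq_lengths Optional named integer vector of sequence lengths,
#'   needed to orient minus-strand records.
#' @return A named list of `orf_call` objects, one per annotated sequence.
#' @export
load_orf_annotations <- function(path, format = c("auto", "gff3", "bed"),
                                 seq_lengths = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else if (ext == "bed")
      "bed" else stop_estssr("estssr_invalid_annotation",
                             sprintf("cannot infer annotation format from '%s'", path))
  }
  gr <- if (format == "gff3") rtracklayer::import(path, format = "gff3")
        else rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) {
    cds <- df$type %in% c("CDS", "ORF", "open_reading_frame")
    if (any(cds)) df <- df[cds, , drop = FALSE]
  }
  out <- list()
  for (sid in unique(as.character(df$seqnames))) {
    rec <- df[df$seqnames == sid, , drop = FALSE]
    rec <- rec[which.max(rec$end - rec$start), , drop = FALSE]
    start0 <- rec$start - 1L   # rtracklayer yields 1-based inclusive
    end0 <- rec$end
    strand <- if (as.character(rec$strand) == "-") "reverse" else "forward"
    if ((end0 - start0) %% 3L != 0L) {
      warning(sprintf("rejecting annotation for '%s': span not a codon multiple", sid))
      next
    }
    if (strand == "reverse") {
      L <- if (!is.null(seq_lengths) && sid %in% names(seq_lengths))
        seq_lengths[[sid]] else NA_integer_
      if (is.na(L)) {
        warning(sprintf(
          "rejecting minus-strand annotation for '%s': sequence length unknown", sid))
        next
      }
      tmp <- start0
      start0 <- L - end0
      end0 <- L - tmp
    }
    out[[sid]] <- orf_call(sid, start0, end0, strand, start0 %% 3L)
  }
  out
}
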