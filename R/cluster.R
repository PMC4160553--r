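#' Pairwise identity estimate for redundancy clustering
#'
#' Global alignment of the shorter sequence against the longer one (pattern
#' aligned end-to-end inside the subject; match 1, mismatch 0, unit gap
#' cost), with identity defined as exact matches over alignment columns. A
#' shared 8-mer prescreen short-circuits clearly unrelated pairs to identity
#' 0 without aligning them.
#'
#' @param a,b Non-empty DNA strings.
#' @param prescreen_k Word size of the shared-k-mer prescreen (default 8;
#'   set to 0 to disable).
#' @return Identity fraction in `[0, 1]`.
#' @export
estimate_identity <- function(a, b, prescreen_k = 8L) {
  a <- validate_dna(a); b <- validate_dna(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop_estssr("estssr_invalid_sequence", "empty sequence in identity estimate")
  }
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  if (prescreen_k > 0L && nchar(a) >= prescreen_k) {
    ka <- substring(a, seq_len(nchar(a) - prescreen_k + 1L),
                    seq_len(nchar(a) - prescreen_k + 1L) + prescreen_k - 1L)
    kb <- substring(b, seq_len(nchar(b) - prescreen_k + 1L),
                    seq_len(nchar(b) - prescreen_k + 1L) + prescreen_k - 1L)
    if (!any(ka %in% kb)) return(0)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::alignedPattern(al)))
  Biostrings::nmatch(al) / cols
}

#' Greedy redundancy clustering at an identity cutoff
#'
#' CD-HIT-style greedy incremental clustering: sequences are sorted longest
#' first (ties keep input order) and each is assigned to the first existing
#' representative it matches at `cutoff` identity or better, otherwise it
#' founds a new cluster. Deterministic for a fixed input.
#'
#' @param sequences Named character vector of DNA sequences.
#' @param cutoff Identity cutoff in `(0, 1]` (default 0.90).
#' @return A data.frame (`seq_id`, `representative_id`,
#'   `identity_to_representative`), one row per input sequence, in the
#'   processing order. Representatives map to themselves at identity 1.
#' @export
greedy_cluster <- function(sequences, cutoff = 0.90) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop_estssr("estssr_invalid_config", "cutoff must be in (0, 1]")
  }
  if (length(sequences) == 0L) {
    return(data.frame(seq_id = character(0), representative_id = character(0),
                      identity_to_representative = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_estssr("estssr_invalid_sequence",
                "sequences must carry unique names")
  }
  ord <- order(-nchar(sequences))   # stable: ties keep input order
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  rep_ids <- character(0)
  rep_seqs <- character(0)
  out_rep <- character(length(ids))
  out_ident <- numeric(length(ids))
  for (i in seq_along(ids)) {
    assigned <- FALSE
    for (j in seq_along(rep_ids)) {
      ident <- estimate_identity(seqs[i], rep_seqs[j])
      if (ident >= cutoff) {
        out_rep[i] <- rep_ids[j]
        out_ident[i] <- ident
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_ids <- c(rep_ids, ids[i])
      rep_seqs <- c(rep_seqs, seqs[i])
      out_rep[i] <- ids[i]
      out_ident[i] <- 1
    }
  }
  data.frame(seq_id = ids, representative_id = out_rep,
             identity_to_representative = out_ident,
             stringsAsFactors = FALSE)
}
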