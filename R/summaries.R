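#' Event density per megabase pair
#'
#' @param event_count Number of SSR events.
#' @param total_bp Total sequence length of the fraction in bp (> 0).
#' @return `event_count * 1e6 / total_bp`.
#' @export
counts_per_mbp <- function(event_count, total_bp) {
  if (any(total_bp <= 0)) {
    stop_estssr("estssr_undefined_density",
                "density undefined for total_bp <= 0")
  }
  event_count * 1e6 / total_bp
}

#' Summarise SSR events of one fraction
#'
#' Computes the per-fraction quantities reported in the density tables:
#' event density (counts/Mbp, compound events counting once), mean and sample
#' standard deviation (n - 1) of member-locus lengths, percentage of compound
#' events, and member-locus densities broken down by unit length and by
#' canonical motif class. Dimer and trimer classes are always present
#' (zero-filled) in the by-class map; classes of longer units appear when
#' observed.
#'
#' @param events An `ssr_events` object from [merge_compound()], all on one
#'   fraction.
#' @param total_bp Total bp of the fraction across the dataset (> 0).
#' @param fraction Fraction label; defaults to the label carried by the
#'   events (or `NA` when empty).
#' @return An object of class `fraction_summary`.
#' @export
summarize_fraction <- function(events, total_bp, fraction = NULL) {
  stopifnot(inherits(events, "ssr_events"))
  ev <- events$events
  mem <- events$members
  if (is.null(fraction)) {
    fraction <- if (nrow(ev)) unique(ev$fraction) else NA_character_
  }
  if (nrow(ev) && length(unique(ev$fraction)) != 1L) {
    stop_estssr("estssr_invalid_events",
                "summarize_fraction requires events from a single fraction")
  }
  if (total_bp <= 0) {
    stop_estssr("estssr_undefined_density",
                "density undefined for total_bp <= 0")
  }
  n_ev <- nrow(ev)
  n_mem <- nrow(mem)
  lengths <- mem$length_bp
  by_unit <- setNames(numeric(9), as.character(2:10))
  if (n_mem) {
    tab <- table(factor(mem$unit_length, levels = 2:10))
    by_unit <- counts_per_mbp(as.numeric(tab), total_bp)
    names(by_unit) <- as.character(2:10)
  }
  class_levels <- unique(c(canonical_motif_classes(2L),
                           canonical_motif_classes(3L),
                           if (n_mem) sort(unique(mem$canonical))))
  by_canon <- setNames(numeric(length(class_levels)), class_levels)
  if (n_mem) {
    tab <- table(factor(mem$canonical, levels = class_levels))
    by_canon <- counts_per_mbp(as.numeric(tab), total_bp)
    names(by_canon) <- class_levels
  }
  structure(list(
    fraction = fraction,
    total_bp = as.numeric(total_bp),
    mbp = total_bp / 1e6,
    event_count = n_ev,
    member_count = n_mem,
    counts_per_mbp = counts_per_mbp(n_ev, total_bp),
    members_per_mbp = counts_per_mbp(n_mem, total_bp),
    mean_length_bp = if (n_mem) mean(lengths) else NA_real_,
    sd_length_bp = if (n_mem >= 2) sd(lengths) else NA_real_,
    percent_compound = if (n_ev) 100 * sum(ev$kind == "compound") / n_ev else 0,
    ssr_bp = if (n_mem) sum(lengths) else 0,
    member_lengths = as.integer(lengths),
    counts_per_mbp_by_unit_length = by_unit,
    counts_per_mbp_by_canonical = by_canon),
    class = "fraction_summary")
}

#' @export
print.fraction_summary <- function(x, ...) {
  cat(sprintf("<fraction_summary> %s: %.3f Mbp, %d events (%.1f/Mbp, %.1f%% compound), mean length %.1f (SD %.2f) bp\n",
              x$fraction, x$mbp, x$event_count, x$counts_per_mbp,
              x$percent_compound, x$mean_length_bp, x$sd_length_bp))
  invisible(x)
}

#' Assemble a per-genus summary
#'
#' Bundles the three fraction summaries of a genus with its genome size and
#' derives the dimer/trimer density ratio per fraction.
#'
#' @param genus Genus name.
#' @param fraction_summaries Named list of three `fraction_summary` objects
#'   (names "5UTR", "ORF", "3UTR").
#' @param genome_size_pg Haploid genome size in picograms (optional,
#'   `NA` if unknown).
#' @return An object of class `genus_summary`.
#' @export
genus_summary <- function(genus, fraction_summaries, genome_size_pg = NA_real_) {
  stopifnot(setequal(names(fraction_summaries), FRACTIONS))
  fraction_summaries <- fraction_summaries[FRACTIONS]
  ratio <- vapply(fraction_summaries, function(fs) {
    d <- sum(fs$counts_per_mbp_by_canonical[canonical_motif_classes(2L)])
    t <- sum(fs$counts_per_mbp_by_canonical[canonical_motif_classes(3L)])
    if (t == 0) NA_real_ else d / t
  }, numeric(1))
  structure(list(genus = genus, genome_size_pg = as.numeric(genome_size_pg),
                 fractions = fraction_summaries,
                 dimer_trimer_ratio = ratio),
            class = "genus_summary")
}

#' @export
print.genus_summary <- function(x, ...) {
  cat(sprintf("<genus_summary> %s (genome size %s pg)\n", x$genus,
              format(x$genome_size_pg)))
  for (fs in x$fractions) print(fs)
  invisible(x)
}

#' Bundled demonstration genome sizes
#'
#' Reads the genome-size metadata table shipped with the package (mean
#' haploid genome sizes in picograms for 8 angiosperm and 7 gymnosperm tree
#' genera), used as default covariates for demonstration runs of the
#' genome-size association test.
#'
#' @return A data.frame with columns `genus`, `taxon`, `genome_size_pg`.
#' @export
default_genome_sizes <- function() {
  read.delim(system.file("extdata", "genome_sizes.tsv", package = "estssr"),
             stringsAsFactors = FALSE)
}
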