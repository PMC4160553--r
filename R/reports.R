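fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

#' Render per-genus report tables
#'
#' Writes the three density tables and a machine-readable summary:
#' * `table1.tsv` -- per genus and fraction: Mbp scanned, event counts and
#'   counts/Mbp, mean SSR length with its standard deviation, percent
#'   compound events, and genome size;
#' * `table2.tsv` -- member-locus counts/Mbp by unit length (2-10) per genus
#'   and fraction;
#' * `table3.tsv` -- member-locus counts/Mbp for the 4 canonical dimer and 10
#'   canonical trimer classes per genus and fraction;
#' * `summary.json` -- the full summaries as JSON.
#'
#' Empty fractions produce zero-filled rows, never missing rows. Coordinates
#' and densities in the TSVs are written with fixed formatting so identical
#' runs give byte-identical files.
#'
#' @param genera List of `genus_summary` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @export
render_reports <- function(genera, dir) {
  stopifnot(length(genera) >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t1 <- do.call(rbind, lapply(genera, function(g) {
    do.call(rbind, lapply(g$fractions, function(fs) {
      data.frame(genus = g$genus, fraction = fs$fraction,
                 genome_size_pg = g$genome_size_pg,
                 mbp = fs$mbp, events = fs$event_count,
                 counts_per_mbp = fs$counts_per_mbp,
                 mean_length_bp = fs$mean_length_bp,
                 sd_length_bp = fs$sd_length_bp,
                 percent_compound = fs$percent_compound,
                 dimer_trimer_ratio = g$dimer_trimer_ratio[[fs$fraction]],
                 stringsAsFactors = FALSE)
    }))
  }))
  t2 <- do.call(rbind, lapply(genera, function(g) {
    do.call(rbind, lapply(g$fractions, function(fs) {
      cbind(data.frame(genus = g$genus, fraction = fs$fraction,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(
              fs$counts_per_mbp_by_unit_length,
              paste0("unit_", names(fs$counts_per_mbp_by_unit_length))))))
    }))
  }))
  classes <- c(canonical_motif_classes(2L), canonical_motif_classes(3L))
  t3 <- do.call(rbind, lapply(genera, function(g) {
    do.call(rbind, lapply(g$fractions, function(fs) {
      dens <- fs$counts_per_mbp_by_canonical[classes]
      dens[is.na(dens)] <- 0
      cbind(data.frame(genus = g$genus, fraction = fs$fraction,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(setNames(dens, classes))))
    }))
  }))
  paths <- file.path(dir, c("table1.tsv", "table2.tsv", "table3.tsv",
                            "summary.json"))
  write_tsv_fixed(t1, paths[1])
  write_tsv_fixed(t2, paths[2])
  write_tsv_fixed(t3, paths[3])
  json <- lapply(genera, function(g) {
    list(genus = g$genus, genome_size_pg = g$genome_size_pg,
         dimer_trimer_ratio = as.list(g$dimer_trimer_ratio),
         fractions = lapply(g$fractions, function(fs) {
           fs$member_lengths <- NULL
           unclass(fs)
         }))
  })
  jsonlite::write_json(json, paths[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(paths)
}

# Deterministic TSV writer: numeric columns rendered with 6 significant
# digits, fixed notation.
write_tsv_fixed <- function(df, path) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "NA",
                         formatC(df[[nm]], digits = 6, format = "g"))
    }
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
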