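#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end workflow. Defaults are the
#' standard search settings: per-class minimum repeat counts dimer-10 through
#' decamer-2, a 100 bp compound spacer bound, a 90 bp minimum ORF, and
#' redundancy clustering disabled (identity 0.90 when enabled).
#'
#' @param scan An [ssr_scan_config()].
#' @param min_orf_bp Minimum ORF length for the longest-ORF caller.
#' @param cluster_identity Redundancy-filter identity cutoff; 0 disables the
#'   filter.
#' @param genome_sizes `NULL` (use the bundled demonstration table), a path
#'   to a TSV with columns `genus` and `genome_size_pg`, or such a
#'   data.frame.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic).
#' @param log_level "info" or "quiet".
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scan = ssr_scan_config(), min_orf_bp = 90L,
                            cluster_identity = 0, genome_sizes = NULL,
                            seed = 1L, log_level = "info") {
  stopifnot(inherits(scan, "ssr_scan_config"))
  if (min_orf_bp <= 0) {
    stop_estssr("estssr_invalid_config", "min_orf_bp must be positive")
  }
  if (cluster_identity < 0 || cluster_identity > 1) {
    stop_estssr("estssr_invalid_config", "cluster_identity must be in [0, 1]")
  }
  structure(list(scan = scan, min_orf_bp = as.integer(min_orf_bp),
                 cluster_identity = cluster_identity,
                 genome_sizes = genome_sizes, seed = as.integer(seed),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Parse a key-value pipeline configuration file
#'
#' Reads `key = value` lines (`#` comments and blank lines ignored) into a
#' [pipeline_config()]. Recognised keys: `dimer_min` .. `decamer_min`,
#' `compound_spacer`, `min_orf_bp`, `cluster_identity`, `genome_sizes`,
#' `seed`, `log_level`. Unknown keys and unparseable values are rejected
#' with a diagnostic naming the key. An empty file yields all defaults.
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config`.
#' @export
parse_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  num_keys <- c(dimer_min = "2", trimer_min = "3", tetramer_min = "4",
                pentamer_min = "5", hexamer_min = "6", heptamer_min = "7",
                octamer_min = "8", nonamer_min = "9", decamer_min = "10")
  min_repeats <- ssr_scan_config()$min_repeats
  spacer <- 100L; min_orf <- 90L; ident <- 0; gsz <- NULL
  seed <- 1L; log_level <- "info"
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop_estssr("estssr_invalid_config",
                  sprintf("malformed config line (expected key = value): '%s'", ln))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    as_num <- function() {
      x <- suppressWarnings(as.numeric(val))
      if (is.na(x)) {
        stop_estssr("estssr_invalid_config",
                    sprintf("config key '%s': expected a number, got '%s'", key, val))
      }
      x
    }
    if (key %in% names(num_keys)) {
      min_repeats[[num_keys[[key]]]] <- as.integer(as_num())
    } else if (key == "compound_spacer") {
      spacer <- as.integer(as_num())
    } else if (key == "min_orf_bp") {
      min_orf <- as.integer(as_num())
    } else if (key == "cluster_identity") {
      ident <- as_num()
    } else if (key == "seed") {
      seed <- as.integer(as_num())
    } else if (key == "genome_sizes") {
      gsz <- val
    } else if (key == "log_level") {
      log_level <- val
    } else {
      stop_estssr("estssr_invalid_config",
                  sprintf("unknown config key '%s'", key))
    }
  }
  pipeline_config(scan = ssr_scan_config(min_repeats = min_repeats,
                                         max_compound_spacer = spacer),
                  min_orf_bp = min_orf, cluster_identity = ident,
                  genome_sizes = gsz, seed = seed, log_level = log_level)
}

resolve_genome_sizes <- function(genome_sizes) {
  if (is.null(genome_sizes)) return(default_genome_sizes())
  if (is.character(genome_sizes)) {
    return(read.delim(genome_sizes, stringsAsFactors = FALSE))
  }
  as.data.frame(genome_sizes)
}

# Placeholder summary for a fraction with no sequence at all.
empty_fraction_summary <- function(fraction) {
  structure(list(fraction = fraction, total_bp = 0, mbp = 0, event_count = 0L,
                 member_count = 0L, counts_per_mbp = NA_real_,
                 members_per_mbp = NA_real_, mean_length_bp = NA_real_,
                 sd_length_bp = NA_real_, percent_compound = 0, ssr_bp = 0,
                 member_lengths = integer(0),
                 counts_per_mbp_by_unit_length =
                   setNames(numeric(9), as.character(2:10)),
                 counts_per_mbp_by_canonical =
                   setNames(numeric(14), c(canonical_motif_classes(2L),
                                           canonical_motif_classes(3L)))),
            class = "fraction_summary")
}

read_genus_sequences <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- Biostrings::readDNAStringSet(x)
    seqs <- toupper(as.character(ss))
    names(seqs) <- sub("\\s.*$", "", names(ss))
    return(seqs)
  }
  if (is.character(x)) return(toupper(x))
  stop_estssr("estssr_invalid_sequence",
              "genus input must be a FASTA path or a named character vector")
}

#' Run the end-to-end EST-SSR workflow
#'
#' For each genus: reads the sequences, optionally removes redundancy by
#' greedy clustering, orients and partitions every EST into 5'UTR/ORF/3'UTR
#' by the six-frame longest-ORF rule (or external annotations), scans each
#' fraction for perfect SSRs, merges adjacent loci into compound events,
#' and aggregates per-fraction summaries. Across genera it then runs the
#' chi-squared heterogeneity test (per genus), the rank-based Tukey HSD on
#' SSR lengths between fractions, and -- given at least three genera with
#' genome sizes -- the genome-size association tests. Writes per-genus locus
#' and fraction tables, the three density report tables, a JSON bundle of
#' test results and a run log accounting for every rejected or unpartitioned
#' record. The pipeline draws no random numbers: identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param genera Named list: one element per genus, each either a FASTA path
#'   or a named character vector of sequences.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param annotations Optional named list (by genus) of GFF3/BED annotation
#'   paths used instead of the longest-ORF rule where a sequence is
#'   annotated.
#' @return Invisibly, a list with `summaries` (per-genus `genus_summary`),
#'   `tests`, `loci` (per-genus members data.frame) and `log`.
#' @export
run_pipeline <- function(genera, config = pipeline_config(), out_dir,
                         annotations = NULL) {
  if (length(genera) < 1L || is.null(names(genera))) {
    stop_estssr("estssr_invalid_config", "need >= 1 named genus input")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("estssr run: %d genera, seed %d", length(genera),
                         config$seed))
  gsz <- resolve_genome_sizes(config$genome_sizes)
  summaries <- list()
  all_loci <- list()
  tests <- list()
  pooled_lengths <- list("5UTR" = numeric(0), ORF = numeric(0),
                         "3UTR" = numeric(0))
  for (genus in names(genera)) {
    seqs <- read_genus_sequences(genera[[genus]])
    log_lines <- c(log_lines, sprintf("[%s] %d input sequences", genus,
                                      length(seqs)))
    if (length(seqs) == 0L) {
      warning(sprintf("genus '%s': empty input", genus))
    }
    if (config$cluster_identity > 0 && length(seqs) > 1L) {
      cl <- greedy_cluster(seqs, config$cluster_identity)
      reps <- cl$seq_id[cl$seq_id == cl$representative_id]
      write_tsv_fixed(cl, file.path(out_dir, paste0(genus, "_clusters.tsv")))
      log_lines <- c(log_lines,
                     sprintf("[%s] redundancy filter at %.2f: %d -> %d sequences",
                             genus, config$cluster_identity, length(seqs),
                             length(reps)))
      seqs <- seqs[reps]
    }
    ann <- if (!is.null(annotations) && genus %in% names(annotations)) {
      load_orf_annotations(annotations[[genus]],
                           seq_lengths = setNames(nchar(seqs), names(seqs)))
    }
    frac_rows <- list()
    loci_rows <- list()
    n_unpart <- 0L
    for (sid in names(seqs)) {
      res <- tryCatch({
        orf <- if (!is.null(ann) && sid %in% names(ann)) ann[[sid]] else
          find_longest_orf(seqs[[sid]], config$min_orf_bp, seq_id = sid)
        if (is.null(orf)) {
          n_unpart <- n_unpart + 1L
          log_lines <- c(log_lines,
                         sprintf("[%s] %s: no ORF >= %d bp, unpartitioned",
                                 genus, sid, config$min_orf_bp))
          NULL
        } else {
          fs <- partition_by_orf(seqs[[sid]], orf, seq_id = sid)
          subs <- fraction_subsequences(fs)
          loci <- do.call(rbind, lapply(FRACTIONS, function(fr) {
            if (nchar(subs[[fr]]) == 0L) return(empty_loci())
            scan_perfect_ssrs(subs[[fr]], config$scan, seq_id = sid,
                              fraction = fr)
          }))
          list(spans = cbind(seq_id = sid, fs$spans,
                             length_bp = fs$spans$end0 - fs$spans$start0),
               loci = loci)
        }
      }, estssr_error = function(e) {
        log_lines <<- c(log_lines, sprintf("[%s] %s: rejected (%s)",
                                           genus, sid, conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        frac_rows[[sid]] <- res$spans
        loci_rows[[sid]] <- res$loci
      }
    }
    if (n_unpart) {
      log_lines <- c(log_lines, sprintf("[%s] %d sequences unpartitioned",
                                        genus, n_unpart))
    }
    fractions <- if (length(frac_rows)) do.call(rbind, frac_rows) else
      data.frame(seq_id = character(0), fraction = character(0),
                 start0 = integer(0), end0 = integer(0),
                 length_bp = integer(0), stringsAsFactors = FALSE)
    loci <- if (length(loci_rows)) do.call(rbind, loci_rows) else empty_loci()
    loci <- resolve_partial_overlaps(loci)
    merged <- merge_compound(loci, config$scan)
    rownames(fractions) <- NULL
    write_tsv_fixed(fractions, file.path(out_dir,
                                         paste0(genus, "_fractions.tsv")))
    members_out <- merged$members
    members_out$event_kind <- merged$events$kind[
      match(members_out$event_id, merged$events$event_id)]
    write_tsv_fixed(members_out, file.path(out_dir, paste0(genus, "_loci.tsv")))
    fsum <- lapply(FRACTIONS, function(fr) {
      bp <- sum(fractions$length_bp[fractions$fraction == fr])
      if (bp == 0) return(empty_fraction_summary(fr))
      sub <- subset_events(merged, fr)
      summarize_fraction(sub, bp, fraction = fr)
    })
    names(fsum) <- FRACTIONS
    size <- gsz$genome_size_pg[match(genus, gsz$genus)]
    summaries[[genus]] <- genus_summary(genus, fsum, size)
    all_loci[[genus]] <- members_out
    for (fr in FRACTIONS) {
      pooled_lengths[[fr]] <- c(pooled_lengths[[fr]],
                                fsum[[fr]]$member_lengths)
    }
    tests[[paste0("chi2_heterogeneity_", genus)]] <- tryCatch(
      chi2_fraction_heterogeneity(fsum),
      estssr_error = function(e) {
        log_lines <<- c(log_lines, sprintf("[%s] chi2 skipped: %s", genus,
                                           conditionMessage(e)))
        NULL
      })
  }
  tests[["tukey_hsd_length_by_fraction"]] <- tryCatch(
    tukey_hsd_lengths(pooled_lengths),
    estssr_error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("tukey HSD skipped: %s", conditionMessage(e)))
      NULL
    })
  if (length(summaries) >= 3L) {
    for (metric in c("mean_length", "counts_per_mbp")) {
      for (fr in FRACTIONS) {
        nm <- sprintf("genome_size_vs_%s_%s", metric, fr)
        tests[[nm]] <- tryCatch(
          genome_size_association(summaries, metric, fr),
          estssr_error = function(e) NULL)
      }
    }
  }
  render_reports(summaries, out_dir)
  tests <- Filter(Negate(is.null), tests)
  jsonlite::write_json(
    lapply(tests, function(t) {
      list(method = t$method, statistic = t$statistic, df = t$df,
           p_value = t$p_value,
           pairwise = if (!is.null(t$pairwise)) t$pairwise)
    }),
    file.path(out_dir, "tests.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null", dataframe = "rows")
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  if (identical(config$log_level, "info")) {
    message(paste(log_lines, collapse = "\n"))
  }
  invisible(list(summaries = summaries, tests = tests, loci = all_loci,
                 log = log_lines))
}

# Restrict an ssr_events object to one fraction.
subset_events <- function(events, fraction) {
  keep <- events$events$fraction == fraction
  ids <- events$events$event_id[keep]
  structure(list(events = events$events[keep, , drop = FALSE],
                 members = events$members[
                   events$members$event_id %in% ids, , drop = FALSE]),
            class = "ssr_events")
}
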