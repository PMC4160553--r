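test_that("background generation is repeat-free, seeded and GC-faithful", {
  bg <- generate_background(10000, 0.5, seed = 1)
  expect_equal(nrow(brute_force_oracle_scan(bg)), 0L)
  expect_identical(generate_background(10000, 0.5, seed = 1), bg)
  expect_false(identical(generate_background(10000, 0.5, seed = 2), bg))
  # observed GC close to target at large length
  bg_gc <- generate_background(1e5, 0.9, seed = 3)
  gc_obs <- mean(strsplit(bg_gc, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.9), 0.02)
})

test_that("synthetic_spec validates its parameters", {
  spec <- synthetic_spec("angiosperm", seed = 1)
  expect_s3_class(spec, "synthetic_spec")
  expect_equal(sum(spec$motif_weights), 1)
  expect_error(synthetic_spec("angiosperm",
                              motif_weights = c(AG = 0.5, AT = 0.4)),
               class = "estssr_invalid_config")
  expect_error(synthetic_spec("angiosperm",
                              motif_weights = c(GT = 0.5, AT = 0.5)),
               class = "estssr_invalid_config")  # GT is not canonical
  expect_error(synthetic_spec("angiosperm", gc_content = 1.2),
               class = "estssr_invalid_config")
  expect_error(synthetic_spec("angiosperm", spacer_range = c(0, 120)),
               class = "estssr_invalid_config")
})

test_that("plant_ssrs inserts recoverable events and records exact truth", {
  set.seed(31)
  spans <- data.frame(fraction = c("5UTR", "ORF", "3UTR"),
                      start0 = c(0L, 2000L, 5000L),
                      end0 = c(2000L, 5000L, 8000L))
  # assemble an SSR-free skeleton with a stop-free coding middle
  u5 <- generate_background(2000, 0.45)
  orf <- estssr:::generate_coding_fragment(3000, 0.45, ssr_scan_config())
  u3 <- generate_background(3000, 0.45)
  spec <- synthetic_spec("angiosperm", density = c("5UTR" = 3000, ORF = 1500,
                                                   "3UTR" = 2000), seed = 1)
  res <- plant_ssrs(paste0(u5, orf, u3), spans, spec, seq_id = "estX")
  expect_gt(nrow(res$truth), 0L)
  # re-scan every fraction: detected events must equal the manifest
  for (fr in c("5UTR", "ORF", "3UTR")) {
    frag <- substring(res$sequence, spans$start0[spans$fraction == fr] + 1,
                      spans$end0[spans$fraction == fr])
    ev <- merge_compound(scan_perfect_ssrs(frag, seq_id = "estX",
                                           fraction = fr))
    tr <- res$truth[res$truth$fraction == fr, , drop = FALSE]
    expect_equal(nrow(ev$events), nrow(tr))
    if (nrow(tr)) {
      expect_equal(ev$events$start0, tr$start0)
      expect_equal(ev$events$end0, tr$end0)
      expect_identical(ev$events$kind, tr$kind)
    }
  }
  # density 0 plants nothing and leaves the sequence untouched
  spec0 <- synthetic_spec("angiosperm",
                          density = c("5UTR" = 0, ORF = 0, "3UTR" = 0))
  res0 <- plant_ssrs(paste0(u5, orf, u3), spans, spec0, seq_id = "estY")
  expect_null(res0$truth)
  expect_identical(res0$sequence, paste0(u5, orf, u3))
  # impossible density raises the infeasibility signal
  spec_hi <- synthetic_spec("angiosperm",
                            density = c("5UTR" = 2e5, ORF = 0, "3UTR" = 0))
  expect_error(
    plant_ssrs(paste0(u5, orf, u3), spans, spec_hi, seq_id = "estZ"),
    class = "estssr_infeasible_spec")
})

test_that("generated datasets are byte-reproducible from the seed", {
  spec <- synthetic_spec("gymnosperm", n_sequences = 15, seed = 41)
  ds1 <- generate_genus_dataset(spec)
  ds2 <- generate_genus_dataset(spec)
  expect_identical(ds1$sequences, ds2$sequences)
  expect_identical(ds1$truth, ds2$truth)
  ds3 <- generate_genus_dataset(synthetic_spec("gymnosperm",
                                               n_sequences = 15, seed = 42))
  expect_false(identical(ds1$sequences, ds3$sequences))
  # empty spec gives valid empty outputs
  ds0 <- generate_genus_dataset(synthetic_spec("gymnosperm",
                                               n_sequences = 0, seed = 1))
  expect_length(ds0$sequences, 0L)
  expect_equal(nrow(ds0$truth), 0L)
})

test_that("end-to-end recovery on simulated genera is exact", {
  for (seed in c(7, 8)) {
    spec <- synthetic_spec("angiosperm", n_sequences = 40, seed = seed)
    ds <- generate_genus_dataset(spec)
    rep <- evaluate_recovery(ds$truth, detect_dataset_events(ds))
    expect_equal(rep$precision, 1.0)
    expect_equal(rep$recall, 1.0)
    expect_equal(unname(rep$field_agreement["fraction"]), 1.0)
    expect_equal(unname(rep$field_agreement["canonical"]), 1.0)
    expect_equal(unname(rep$field_agreement["repeat_count"]), 1.0)
  }
})

test_that("evaluate_recovery scores partial detection correctly", {
  spec <- synthetic_spec("angiosperm", n_sequences = 25, seed = 9)
  ds <- generate_genus_dataset(spec)
  ev <- detect_dataset_events(ds)
  # drop one detected event -> recall < 1, precision stays 1
  drop_id <- ev$events$event_id[1]
  ev_miss <- structure(list(
    events = ev$events[ev$events$event_id != drop_id, , drop = FALSE],
    members = ev$members[ev$members$event_id != drop_id, , drop = FALSE]),
    class = "ssr_events")
  rep <- evaluate_recovery(ds$truth, ev_miss)
  expect_equal(rep$precision, 1.0)
  expect_equal(rep$recall, (nrow(ds$truth) - 1) / nrow(ds$truth))
  # empty detection: recall 0, precision reported 1 with a flag
  ev_none <- structure(list(events = ev$events[0, ], members = ev$members[0, ]),
                       class = "ssr_events")
  rep0 <- evaluate_recovery(ds$truth, ev_none)
  expect_equal(rep0$recall, 0)
  expect_equal(rep0$precision, 1)
  expect_true(rep0$zero_detections)
})

test_that("planted fraction densities are ordered as specified at scale", {
  spec <- synthetic_spec("angiosperm", n_sequences = 150,
                         length_range = c(1500, 2100),
                         density = c("5UTR" = 4000, ORF = 1000,
                                     "3UTR" = 2000),
                         seed = 51)
  ds <- generate_genus_dataset(spec)
  bp <- tapply(ds$fractions$length_bp, ds$fractions$fraction, sum)
  n_ev <- table(factor(ds$truth$fraction, levels = c("5UTR", "ORF", "3UTR")))
  dens <- as.numeric(n_ev) * 1e6 / as.numeric(bp[c("5UTR", "ORF", "3UTR")])
  expect_true(dens[1] > dens[3] && dens[3] > dens[2])
})
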