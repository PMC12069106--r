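test_that("an all-zero spec yields a registry and empty source tables", {
  spec <- universe_spec(seed = 1, n_universe = 10)
  b <- generate_universe(spec)
  expect_equal(nrow(b$registry), 10)
  expect_equal(nrow(b$biomonitoring), 0)
  expect_equal(nrow(b$metabolome), 0)
  expect_equal(nrow(b$evidence_map), 0)
  expect_equal(nrow(b$hazard), 0)
})

test_that("infeasible specs error before anything is generated", {
  # partition does not sum to the detected total
  expect_error(
    universe_spec(seed = 1, n_universe = 100, n_biomon_detected = 5,
                  n_metabolome_listed = 10, n_overlap_biomon_metabolome = 2,
                  n_fccdb_only = 1, n_migex_only = 1, n_both = 1),
    "partition"
  )
  # overlap larger than a marginal
  expect_error(
    universe_spec(seed = 1, n_universe = 100, n_biomon_detected = 2,
                  n_metabolome_listed = 10, n_overlap_biomon_metabolome = 5,
                  n_fccdb_only = 7, n_migex_only = 0, n_both = 0),
    "overlap"
  )
  # nested step-2 counts
  expect_error(
    universe_spec(seed = 1, n_universe = 100, n_prioritized = 3,
                  n_step2_with_studies = 5),
    "nest"
  )
  # universe too small
  expect_error(
    universe_spec(seed = 1, n_universe = 4, n_biomon_detected = 3,
                  n_metabolome_listed = 3, n_overlap_biomon_metabolome = 1,
                  n_fccdb_only = 5, n_migex_only = 0, n_both = 0,
                  n_prioritized = 2),
    "universe too small"
  )
})

test_that("identical spec and seed give byte-identical bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_universe(random_spec(17), dir = d1)
  generate_universe(random_spec(17), dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("generated CAS numbers are checksum-valid and collision-free", {
  b <- generate_universe(random_spec(23))
  expect_true(all(cas_is_valid(b$registry$cas)))
  expect_equal(anyDuplicated(b$registry$cas), 0)
  analyte_cas <- b$biomonitoring$analyte_cas
  expect_true(all(cas_is_valid(analyte_cas)))
  # metabolite analytes live in a separate reserved range from registry chemicals
  mets <- b$biomonitoring[b$biomonitoring$parent_cas != "", ]
  expect_false(any(mets$analyte_cas %in% b$registry$cas))
  expect_true(all(mets$parent_cas %in% b$registry$cas))
})

test_that("the pipeline recovers every quota of random feasible specs", {
  for (seed in c(1, 8, 21, 34, 55)) {
    spec <- random_spec(seed)
    res <- run_fcc_pipeline(generate_universe(spec),
                            threshold = spec$prioritization_threshold)
    lbl <- paste("seed", seed)
    n_det <- spec$n_biomon_detected + spec$n_metabolome_listed -
      spec$n_overlap_biomon_metabolome
    p <- res$partition
    expect_equal(p$detected_total, n_det, label = lbl)
    expect_equal(p$fccdb_only, spec$n_fccdb_only, label = lbl)
    expect_equal(p$fccmigex_only, spec$n_migex_only, label = lbl)
    expect_equal(p$both, spec$n_both, label = lbl)
    expect_equal(sum(res$step1$biomon_monitored_in != ""),
                 spec$n_biomon_detected + spec$n_biomon_monitored_only,
                 label = lbl)
    expect_equal(p$monitored_not_detected,
                 spec$n_biomon_monitored_only - spec$n_notdetected_in_metabolome,
                 label = lbl)
    expect_equal(sum(set_has(res$step1$metabolome_listed_in, "HMDB")),
                 sum(spec$hmdb_status_counts), label = lbl)
    expect_equal(res$overlap$all_five_monitored, spec$all_five_monitored,
                 label = lbl)
    expect_equal(res$overlap$all_five_detected, spec$all_five_detected,
                 label = lbl)
    expect_equal(nrow(res$prioritized), spec$n_prioritized, label = lbl)
    expect_equal(sum(res$step2$category == "detected"),
                 spec$n_step2_with_studies - spec$n_step2_all_negative,
                 label = lbl)
    expect_equal(sum(res$step2$category == "monitored_not_detected"),
                 spec$n_step2_all_negative, label = lbl)
    q <- spec$hazard_tier_quota$biomonitored
    cnt <- res$tiers_biomonitored$counts
    expect_equal(unname(cnt[["high"]]), unname(q[["high"]]), label = lbl)
    expect_equal(unname(cnt[["medium"]]), unname(q[["medium"]]), label = lbl)
    expect_equal(unname(cnt[["other_concern"]] + cnt[["not_classified"]]),
                 unname(q[["other_or_not_classified"]]), label = lbl)
    expect_equal(unname(cnt[["no_hazard_data"]]), unname(q[["no_hazard_data"]]),
                 label = lbl)
    stq <- spec$sample_type_quota
    if (length(stq) > 0) {
      got <- res$aggregates$sample_types
      for (ty in names(stq)) {
        expect_equal(got$n_fccs[got$sample_type == ty], unname(stq[[ty]]),
                     label = paste(lbl, ty))
      }
    }
  }
})

test_that("the reference preset satisfies its own set-algebra identities", {
  spec <- fcchumon_marginals()
  # inclusion-exclusion: biomonitoring + metabolome - overlap
  expect_equal(spec$n_biomon_detected + spec$n_metabolome_listed -
                 spec$n_overlap_biomon_metabolome, 3538)
  expect_equal(spec$n_fccdb_only + spec$n_migex_only + spec$n_both, 3538)
  # monitored-only chemicals not rescued by a metabolome listing
  expect_equal(spec$n_biomon_monitored_only -
                 spec$n_notdetected_in_metabolome, 10)
  expect_equal(sum(spec$hazard_tier_quota$prioritized), spec$n_prioritized)
})

test_that("metabolite routing leaves quota recovery intact at high fractions", {
  spec <- random_spec(12)
  spec$metabolite_fraction <- 0.5
  b <- generate_universe(spec)
  res <- run_fcc_pipeline(b, threshold = spec$prioritization_threshold)
  expect_equal(sum(res$step1$biomon_monitored_in != ""),
               spec$n_biomon_detected + spec$n_biomon_monitored_only)
  expect_true(any(b$biomonitoring$parent_cas != ""))
})
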