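small_world <- function() {
  cas <- fccmap:::synth_cas(1:6)
  reg <- tiny_registry(cas, in_fccmigex = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  st1 <- tibble::tibble(
    chem_id = reg$chem_id,
    category = c("detected", "detected", "monitored_not_detected",
                 "no_evidence", "no_evidence", "no_evidence"),
    biomon_monitored_in = c("CHMS|NHANES", "", "KoNEHS", "", "", ""),
    biomon_detected_in = c("NHANES", "", "", "", "", ""),
    metabolome_listed_in = c("BloodExposome", "HMDB", "", "", "", "")
  )
  st2 <- tibble::tibble(
    chem_id = reg$chem_id[4], cas = cas[4], n_studies = 2L,
    category = "detected", sample_types_detected = "urine",
    methods_used = "targeted", analyte_forms = "parent",
    unspecific_only = FALSE
  )
  list(reg = reg, st1 = st1, st2 = st2, cas = cas)
}

test_that("consolidation merges step-1 and step-2 into one status per chemical", {
  w <- small_world()
  out <- consolidate(w$reg, w$st1, w$st2)
  expect_equal(nrow(out), 6)
  expect_equal(out$overall_status,
               c("detected", "detected", "monitored_not_detected",
                 "detected", "no_evidence", "no_evidence"))
  expect_equal(out$step,
               c("step1", "step1", "step1", "step2", "none", "none"))
  expect_equal(out$evidence_sources[1], "biomonitoring|metabolome")
  expect_equal(out$evidence_sources[4], "literature")
  # detected implies nonempty evidence sources
  expect_true(all(out$evidence_sources[out$overall_status == "detected"] != ""))
})

test_that("a step-2 status for a step-1 chemical is a consistency error", {
  w <- small_world()
  bad <- w$st2
  bad$chem_id <- w$reg$chem_id[1]
  bad$cas <- w$cas[1]
  expect_error(consolidate(w$reg, w$st1, bad), "step-1")
})

test_that("evidence summary reproduces totals, overlap, and percentage", {
  w <- small_world()
  out <- consolidate(w$reg, w$st1, w$st2)
  s <- evidence_summary(out)
  expect_equal(s$n_universe, 6)
  expect_equal(s$n_evidence, 3)
  expect_equal(s$pct_evidence, 50)
  expect_equal(s$n_biomon_detected, 1)
  expect_equal(s$n_metabolome_listed, 2)
  expect_equal(s$n_overlap, 1)
  expect_equal(s$n_step2_detected, 1)
  expect_equal(s$n_evidence + s$n_monitored_not_detected + s$n_no_evidence,
               s$n_universe)
  # 2 of 8 detected is exactly 25%
  eight <- out[rep(5, 8), ]
  eight$overall_status <- rep(c("detected", "no_evidence"), c(2, 6))
  expect_equal(evidence_summary(eight)$pct_evidence, 25)
})

test_that("group summaries apply the program-sum and study-count weights", {
  w <- small_world()
  out <- consolidate(w$reg, w$st1, w$st2)
  out$group_label <- c("plasticizers", "plasticizers", "", "oligomers", "", "")
  out$migex_detect_entries <- c(99L, 1L, 0L, 5L, 0L, 0L)
  g1 <- group_summaries(out[1:3, ], step1_statuses = w$st1)
  plast <- g1[g1$group_label == "plasticizers", ]
  # members monitored in 2 and 0 programs -> weight 2; entry sum 100
  expect_equal(plast$human_evidence_weight, 2L)
  expect_equal(plast$migex_detect_entry_sum, 100L)
  expect_equal(plast$n_detected + plast$n_monitored_not_detected +
                 plast$n_no_evidence, plast$n_fccs)
  expect_true("(ungrouped)" %in% g1$group_label)

  records <- dplyr::bind_rows(
    ev_row("S1", w$cas[4]), ev_row("S2", w$cas[4], "serum"),
    ev_row("S3", w$cas[4], "blood", detected = FALSE)
  )
  g2 <- group_summaries(out[4, ], step2_records = records)
  # three distinct studies monitor the only member
  expect_equal(g2$human_evidence_weight, 3L)
  expect_error(group_summaries(out), "exactly one")
})

test_that("per-program monitoring weights sum across group members", {
  w <- small_world()
  out <- consolidate(w$reg, w$st1, w$st2)
  out$group_label <- "g"
  st1 <- w$st1
  st1$biomon_monitored_in[1] <- set_join(fcc_programs[1:3])
  st1$biomon_monitored_in[2] <- set_join(fcc_programs[1:2])
  g <- group_summaries(out[1:2, ], step1_statuses = st1)
  expect_equal(g$human_evidence_weight, 5L)
})

test_that("sankey flows merge the middle tiers and conserve the subset", {
  recs <- tibble::tibble(
    chem_id = sprintf("C%d", 1:5), cas = fccmap:::synth_cas(1:5),
    overall_status = c("detected", "detected", "no_evidence",
                       "monitored_not_detected", "detected"),
    evidence_sources = "", step = "step1",
    tier = c("high", "high", "no_hazard_data", "not_classified", "other_concern"),
    group_label = "", migex_detect_entries = 0L
  )
  fl <- sankey_export(recs)
  expect_equal(sum(fl$n), nrow(recs))
  expect_equal(fl$n[fl$status == "detected" & fl$tier_band == "high"], 2L)
  merged <- fl[fl$tier_band == "other_or_not_classified", ]
  expect_equal(sum(merged$n), 2L)
  bad <- recs
  bad$tier[1] <- ""
  expect_error(sankey_export(bad), "tier")
})

test_that("the biomonitored-and-found-in-FCM subset intersects both criteria", {
  w <- small_world()
  migex <- tibble::tibble(
    entry_id = c("E1", "E2", "E3"),
    cas = c(w$cas[1], w$cas[3], w$cas[2]),
    inchikey = "", smiles = "", name = "", fca_type = "packaging",
    fcm_material = "plastic", detected = c(TRUE, TRUE, TRUE),
    reference_id = "R"
  )
  sub <- biomonitored_fcm_subset(w$reg, w$st1, migex)
  # chem 1 (monitored + entry) and chem 3 (monitored + entry) qualify;
  # chem 2 has an entry but was never monitored
  expect_setequal(sub, w$cas[c(1, 3)])
})

test_that("global conservation holds on randomized full pipeline runs", {
  for (seed in c(6, 13)) {
    bundle <- generate_universe(random_spec(seed))
    res <- run_fcc_pipeline(bundle)
    s <- res$summary
    expect_equal(s$n_evidence + s$n_monitored_not_detected + s$n_no_evidence,
                 s$n_universe)
    tab <- table(factor(res$fcchumon$overall_status,
                        levels = fcc_evidence_statuses))
    expect_equal(unname(tab[["detected"]]), s$n_evidence)
    expect_equal(unname(tab[["monitored_not_detected"]]),
                 s$n_monitored_not_detected)
  }
})
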