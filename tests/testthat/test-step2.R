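make_step2_world <- function() {
  cas <- fccmap:::synth_cas(1:4)
  reg <- tiny_registry(cas, in_fccmigex = TRUE)
  st <- tibble::tibble(
    chem_id = reg$chem_id,
    category = c("no_evidence", "no_evidence", "detected", "no_evidence"),
    biomon_monitored_in = "",
    biomon_detected_in = c("", "", "NHANES", ""),
    metabolome_listed_in = ""
  )
  migex <- tibble::tibble(
    entry_id = sprintf("E%03d", 1:31),
    cas = c(rep(cas[1], 5), rep(cas[2], 4), rep(cas[3], 20), rep(cas[4], 2)),
    inchikey = "", smiles = "", name = "", fca_type = "packaging",
    fcm_material = "plastic",
    detected = c(rep(TRUE, 29), TRUE, FALSE),
    reference_id = "REF1"
  )
  list(reg = reg, st = st, migex = migex, cas = cas)
}

test_that("prioritization needs step-1 absence and enough detection entries", {
  w <- make_step2_world()
  pri <- prioritize(w$reg, w$st, w$migex, threshold = 5)
  # chem 1: absent + 5 entries -> in; chem 2: absent + 4 -> out;
  # chem 3: 20 entries but step-1 detected -> out; chem 4: 1 detected entry -> out
  expect_equal(pri$chem_id, w$reg$chem_id[1])
  expect_equal(pri$migex_detect_entries, 5L)
})

test_that("raising the threshold never grows the prioritized set", {
  for (seed in c(4, 9)) {
    bundle <- generate_universe(random_spec(seed))
    reg <- chem_registry(bundle$registry)
    st <- resolve_step1(reg, expand_metabolite_links(bundle$biomonitoring),
                        bundle$metabolome)
    prev <- NULL
    for (thr in 1:7) {
      cur <- prioritize(reg, st, bundle$fccmigex, thr)$chem_id
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("prioritized ordering is count-descending with id tie-break", {
  cas <- fccmap:::synth_cas(1:3)
  reg <- tiny_registry(cas, in_fccmigex = TRUE)
  st <- tibble::tibble(chem_id = reg$chem_id, category = "no_evidence",
                       biomon_monitored_in = "", biomon_detected_in = "",
                       metabolome_listed_in = "")
  migex <- tibble::tibble(
    entry_id = sprintf("E%03d", 1:17),
    cas = c(rep(cas[1], 5), rep(cas[2], 7), rep(cas[3], 5)),
    inchikey = "", smiles = "", name = "", fca_type = "packaging",
    fcm_material = "plastic", detected = TRUE, reference_id = "R"
  )
  pri <- prioritize(reg, st, migex, 5)
  expect_equal(pri$chem_id, reg$chem_id[c(2, 1, 3)])
})

test_that("step-2 classification follows any-detection dominance", {
  w <- make_step2_world()
  pri <- tibble::tibble(chem_id = w$reg$chem_id[1:2], cas = w$cas[1:2],
                        migex_detect_entries = c(6L, 5L))
  records <- dplyr::bind_rows(
    ev_row("S1", w$cas[1], "urine", detected = TRUE),
    ev_row("S2", w$cas[1], "serum", detected = FALSE),
    ev_row("S3", w$cas[2], "urine", detected = FALSE),
    ev_row("S4", w$cas[2], "blood", detected = FALSE),
    ev_row("S5", w$cas[2], "plasma", detected = FALSE)
  )
  st2 <- classify_step2(records, pri)
  expect_equal(st2$category, c("detected", "monitored_not_detected"))
  expect_equal(st2$sample_types_detected, c("urine", ""))
  expect_equal(st2$n_studies, c(2L, 3L))
})

test_that("chemicals without records are no_evidence and partition conserves", {
  w <- make_step2_world()
  pri <- tibble::tibble(chem_id = w$reg$chem_id[1:2], cas = w$cas[1:2],
                        migex_detect_entries = c(6L, 5L))
  st2 <- classify_step2(ev_row("S1", w$cas[1]), pri)
  expect_equal(st2$category, c("detected", "no_evidence"))
  expect_equal(st2$n_studies, c(1L, 0L))
  expect_equal(sum(st2$category == "detected") +
                 sum(st2$category == "monitored_not_detected") +
                 sum(st2$category == "no_evidence"), nrow(pri))
})

test_that("classification ignores record order and duplication", {
  w <- make_step2_world()
  pri <- tibble::tibble(chem_id = w$reg$chem_id[1], cas = w$cas[1],
                        migex_detect_entries = 6L)
  records <- dplyr::bind_rows(
    ev_row("S1", w$cas[1], "urine", detected = TRUE),
    ev_row("S2", w$cas[1], "serum", detected = FALSE)
  )
  base <- classify_step2(records, pri)
  flipped <- classify_step2(records[2:1, ], pri)
  doubled <- classify_step2(records[c(1, 2, 1, 2), ], pri)
  for (other in list(flipped, doubled)) {
    expect_equal(base$category, other$category)
    expect_equal(base$n_studies, other$n_studies)
    expect_equal(base$sample_types_detected, other$sample_types_detected)
  }
})

test_that("records for unknown chemicals are rejected with a report", {
  w <- make_step2_world()
  pri <- tibble::tibble(chem_id = w$reg$chem_id[1], cas = w$cas[1],
                        migex_detect_entries = 6L)
  stray <- ev_row("S9", "84-66-2")
  st2 <- classify_step2(dplyr::bind_rows(ev_row("S1", w$cas[1]), stray), pri)
  expect_equal(nrow(attr(st2, "rejected")), 1)
  expect_equal(attr(st2, "rejected")$fcc_cas, "84-66-2")
})

test_that("unspecific-metabolite-only detections are flagged but count", {
  w <- make_step2_world()
  pri <- tibble::tibble(chem_id = w$reg$chem_id[1], cas = w$cas[1],
                        migex_detect_entries = 6L)
  st2 <- classify_step2(
    ev_row("S1", w$cas[1], form = "unspecific_metabolite"), pri
  )
  expect_equal(st2$category, "detected")
  expect_true(st2$unspecific_only)
})

test_that("aggregation counts sample types per chemical and methods per study", {
  cas <- fccmap:::synth_cas(1:2)
  pri <- tibble::tibble(chem_id = c("C001", "C002"), cas = cas,
                        migex_detect_entries = c(5L, 5L))
  records <- dplyr::bind_rows(
    ev_row("S1", cas[1], "urine"), ev_row("S1", cas[1], "blood"),
    ev_row("S2", cas[2], "urine"), ev_row("S2", cas[2], "blood"),
    ev_row("S3", cas[2], "urine", method = "both")
  )
  st2 <- classify_step2(records, pri)
  agg <- aggregate_step2(st2, records)
  stc <- agg$sample_types
  expect_equal(stc$n_fccs[stc$sample_type == "urine"], 2L)
  expect_equal(stc$n_fccs[stc$sample_type == "blood"], 2L)
  m <- agg$methods
  expect_equal(m$n_studies[m$method == "both"], 1L) # never double-counted
  expect_equal(m$n_studies[m$method == "targeted"], 2L)
  f <- agg$analyte_forms
  expect_equal(f$n_fccs[f$analyte_form == "parent"], 2L)
})
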