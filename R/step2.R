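#' Prioritize chemicals for systematic literature evidence mapping
#'
#' Step 2 targets chemicals invisible to all step-1 sources: never monitored
#' in any biomonitoring program (detected or not) and never listed in any
#' metabolome/exposome database. Among those candidates, chemicals with at
#' least `threshold` FCCmigex entries reporting their *detection* in food
#' contact material migrates or extracts are prioritized: frequent detection
#' in the materials implies likely human exposure worth a literature search.
#'
#' Only entries with `detected = true` count toward the threshold; entries
#' for chemicals targeted but never detected in materials do not.
#'
#' @param registry a [chem_registry()] tibble.
#' @param step1_statuses output of [resolve_step1()].
#' @param migex_entries validated fccmigex tibble.
#' @param threshold minimum number of detection entries (default 5).
#' @return tibble `chem_id`, `cas`, `migex_detect_entries`, ordered by
#'   count descending then `chem_id`.
#' @export
prioritize <- function(registry, step1_statuses, migex_entries, threshold = 5) {
  if (threshold < 1) abort_fcc("prioritize(): threshold must be >= 1")
  absent <- step1_statuses$chem_id[
    step1_statuses$category == "no_evidence" &
      step1_statuses$biomon_monitored_in == ""
  ]
  counts <- count_migex_detections(registry, migex_entries)
  out <- counts[counts$chem_id %in% absent &
                  counts$migex_detect_entries >= threshold, ]
  out <- dplyr::left_join(out, dplyr::select(registry, "chem_id", "cas"),
                          by = "chem_id")
  out <- out[order(-out$migex_detect_entries, out$chem_id), ]
  tibble::as_tibble(out[, c("chem_id", "cas", "migex_detect_entries")])
}

#' Count FCCmigex detection entries per registry chemical
#'
#' @inheritParams prioritize
#' @return tibble `chem_id`, `migex_detect_entries` (one row per registry
#'   chemical, zero where none).
#' @export
count_migex_detections <- function(registry, migex_entries) {
  migex_entries <- tibble::as_tibble(migex_entries)
  det <- migex_entries[migex_entries$detected, ]
  det$row_id <- as.character(seq_len(max(nrow(det), 0)))
  m <- match_chemicals(registry, det)
  counts <- m |>
    dplyr::count(chem_id = .data$left_id, name = "migex_detect_entries")
  tibble::tibble(chem_id = registry$chem_id) |>
    dplyr::left_join(counts, by = "chem_id") |>
    dplyr::mutate(migex_detect_entries =
                    dplyr::coalesce(.data$migex_detect_entries, 0L))
}

#' Classify step-2 evidence status from literature extraction records
#'
#' One status per prioritized chemical, from the post-screening extraction
#' records (study x chemical x sample type x method x analyte form x
#' detected):
#'
#' * `detected` - at least one record with `detected = true` (any-detection
#'   dominance).
#' * `monitored_not_detected` - at least one study, all records negative.
#' * `no_evidence` - no eligible study records at all.
#'
#' `n_studies` counts distinct `study_id` per chemical, regardless of how
#' many sample types a study reports. Detections identified only through an
#' unspecific metabolite count as evidence but are flagged via
#' `unspecific_only`. Records referencing a CAS outside the prioritized set
#' are rejected and reported in the `rejected` attribute.
#'
#' @param records validated evidence_map tibble.
#' @param prioritized output of [prioritize()].
#' @return tibble with one row per prioritized chemical: `chem_id`, `cas`,
#'   `n_studies`, `category`, `sample_types_detected`, `methods_used`,
#'   `analyte_forms`, `unspecific_only`; attribute `rejected` holds the
#'   dropped records.
#' @export
classify_step2 <- function(records, prioritized) {
  records <- tibble::as_tibble(records)
  known <- records$fcc_cas %in% prioritized$cas
  rejected <- records[!known, ]
  records <- records[known, ]
  records <- dplyr::distinct(records)  # duplicated extraction rows are harmless

  per <- records |>
    dplyr::group_by(cas = .data$fcc_cas) |>
    dplyr::summarise(
      n_studies = dplyr::n_distinct(.data$study_id),
      any_detected = any(.data$detected),
      sample_types_detected = set_join(.data$sample_type[.data$detected]),
      methods_used = set_join(.data$method),
      analyte_forms = set_join(.data$analyte_form),
      unspecific_only = any(.data$detected) &&
        all(.data$analyte_form[.data$detected] == "unspecific_metabolite"),
      .groups = "drop"
    )
  out <- dplyr::left_join(
    prioritized[, c("chem_id", "cas")], per, by = "cas"
  ) |>
    dplyr::mutate(
      n_studies = dplyr::coalesce(.data$n_studies, 0L),
      any_detected = dplyr::coalesce(.data$any_detected, FALSE),
      dplyr::across(c("sample_types_detected", "methods_used", "analyte_forms"),
                    ~ dplyr::coalesce(.x, "")),
      unspecific_only = dplyr::coalesce(.data$unspecific_only, FALSE),
      category = dplyr::case_when(
        any_detected ~ "detected",
        n_studies >= 1 ~ "monitored_not_detected",
        TRUE ~ "no_evidence"
      )
    ) |>
    dplyr::select("chem_id", "cas", "n_studies", "category",
                  "sample_types_detected", "methods_used", "analyte_forms",
                  "unspecific_only")
  attr(out, "rejected") <- rejected
  out
}

#' Aggregate step-2 evidence by sample type, method, and analyte form
#'
#' Produces the three summary tables of the evidence map:
#'
#' * `sample_types`: per sample type, the number of distinct chemicals with
#'   at least one detection in that sample type (multiple sample types per
#'   chemical possible, so columns need not sum to the number of detected
#'   chemicals).
#' * `methods`: per analytical method, the number of studies using it (a
#'   study using both targeted and non-targeted approaches is counted once
#'   under `both`) and the number of distinct detected chemicals.
#' * `analyte_forms`: per analyte form, the number of distinct chemicals
#'   measured in that form.
#'
#' @param statuses output of [classify_step2()].
#' @param records the evidence_map records used to build them.
#' @return named list of three tibbles.
#' @export
aggregate_step2 <- function(statuses, records) {
  records <- dplyr::distinct(tibble::as_tibble(records))
  det <- records[records$detected, ]
  sample_types <- det |>
    dplyr::distinct(.data$fcc_cas, .data$sample_type) |>
    dplyr::count(.data$sample_type, name = "n_fccs") |>
    dplyr::right_join(tibble::tibble(sample_type = fcc_sample_types),
                      by = "sample_type") |>
    dplyr::mutate(n_fccs = dplyr::coalesce(.data$n_fccs, 0L))

  study_method <- records |>
    dplyr::group_by(study_id = .data$study_id) |>
    dplyr::summarise(method = if (dplyr::n_distinct(.data$method) > 1 ||
                                    any(.data$method == "both")) "both"
                     else .data$method[1],
                     .groups = "drop")
  study_method$method <- as.character(study_method$method)
  methods <- study_method |>
    dplyr::count(.data$method, name = "n_studies") |>
    dplyr::full_join(
      det |>
        dplyr::distinct(.data$fcc_cas, .data$method) |>
        dplyr::count(.data$method, name = "n_fccs_detected"),
      by = "method"
    ) |>
    dplyr::right_join(tibble::tibble(method = fcc_methods), by = "method") |>
    dplyr::mutate(dplyr::across(c("n_studies", "n_fccs_detected"),
                                ~ dplyr::coalesce(.x, 0L)))

  analyte_forms <- records |>
    dplyr::distinct(.data$fcc_cas, .data$analyte_form) |>
    dplyr::count(.data$analyte_form, name = "n_fccs") |>
    dplyr::right_join(tibble::tibble(analyte_form = fcc_analyte_forms),
                      by = "analyte_form") |>
    dplyr::mutate(n_fccs = dplyr::coalesce(.data$n_fccs, 0L))

  list(sample_types = sample_types, methods = methods,
       analyte_forms = analyte_forms)
}
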