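#' Expand metabolite-parent links in biomonitoring analyte lists
#'
#' Biomonitoring programs often measure a metabolite as a proxy for its
#' parent compound (e.g. mono-ethyl phthalate, CAS 863029-89-4, as a proxy
#' for di-ethyl phthalate, CAS 84-66-2). For each analyte row carrying a
#' `parent_cas`, an additional row is emitted with the parent's CAS as the
#' analyte CAS, same program and status, so that a chemical is credited with
#' monitoring/detection regardless of whether the measurement targeted the
#' parent or a metabolite. Original rows are preserved, so expansion can
#' only grow the matched set, never shrink it.
#'
#' Expansion applies to biomonitoring sources only: metabolome/exposome
#' databases do not systematically report metabolite-parent links, so their
#' listings are used as-is.
#'
#' @param analytes validated biomonitoring tibble (see [read_source()]).
#' @return expanded tibble with an extra logical column `from_parent_link`
#'   marking the emitted parent rows.
#' @export
expand_metabolite_links <- function(analytes) {
  analytes <- tibble::as_tibble(analytes)
  analytes$from_parent_link <- FALSE
  with_parent <- analytes[analytes$parent_cas != "", ]
  if (nrow(with_parent) == 0) return(analytes)
  parent_rows <- with_parent
  parent_rows$analyte_cas <- parent_rows$parent_cas
  parent_rows$analyte_name <- paste0(parent_rows$analyte_name, " [parent]")
  parent_rows$parent_cas <- ""
  parent_rows$from_parent_link <- TRUE
  dplyr::bind_rows(analytes, parent_rows)
}

#' Resolve per-chemical step-1 evidence status
#'
#' Matches every registry chemical against the (expanded) biomonitoring
#' analyte set and the metabolome/exposome listings, and assigns one of
#' three categories:
#'
#' * `detected` - detected in at least one biomonitoring program *or* listed
#'   in at least one metabolome/exposome database. A listing alone counts as
#'   evidence of presence; per-database provenance is retained so stricter
#'   users can filter.
#' * `monitored_not_detected` - monitored in at least one program, never
#'   detected, and not listed anywhere.
#' * `no_evidence` - absent from all step-1 sources.
#'
#' Detection in any program dominates non-detection elsewhere. Biomonitoring
#' analytes are matched by CAS; metabolome listings by CAS, InChIKey, or
#' SMILES with the registry's union-match semantics ([match_chemicals()]).
#'
#' @param registry a [chem_registry()] tibble.
#' @param analytes expanded biomonitoring tibble
#'   (see [expand_metabolite_links()]).
#' @param listings validated metabolome tibble.
#' @return tibble with one row per registry chemical: `chem_id`, `category`,
#'   and `|`-serialized set columns `biomon_monitored_in`,
#'   `biomon_detected_in`, `metabolome_listed_in`.
#' @export
resolve_step1 <- function(registry, analytes, listings) {
  analytes <- tibble::as_tibble(analytes)
  listings <- tibble::as_tibble(listings)
  analytes$row_id <- as.character(seq_len(max(nrow(analytes), 0)))
  listings$row_id <- as.character(seq_len(max(nrow(listings), 0)))

  bm <- match_chemicals(
    registry,
    dplyr::rename(analytes, cas = "analyte_cas"),
    precedence = "cas"
  )
  bm <- dplyr::left_join(
    bm,
    dplyr::select(analytes, "row_id", "program", "status"),
    by = c(right_id = "row_id")
  )
  met <- match_chemicals(registry, listings)
  met <- dplyr::left_join(
    met,
    dplyr::select(listings, "row_id", "database"),
    by = c(right_id = "row_id")
  )

  bm_sets <- bm |>
    dplyr::group_by(chem_id = .data$left_id) |>
    dplyr::summarise(
      biomon_monitored_in = set_join(.data$program),
      biomon_detected_in = set_join(.data$program[.data$status == "detected"]),
      .groups = "drop"
    )
  met_sets <- met |>
    dplyr::group_by(chem_id = .data$left_id) |>
    dplyr::summarise(metabolome_listed_in = set_join(.data$database), .groups = "drop")

  out <- tibble::tibble(chem_id = registry$chem_id) |>
    dplyr::left_join(bm_sets, by = "chem_id") |>
    dplyr::left_join(met_sets, by = "chem_id") |>
    dplyr::mutate(dplyr::across(
      c("biomon_monitored_in", "biomon_detected_in", "metabolome_listed_in"),
      ~ dplyr::coalesce(.x, "")
    ))
  out$category <- dplyr::case_when(
    out$biomon_detected_in != "" | out$metabolome_listed_in != "" ~ "detected",
    out$biomon_monitored_in != "" ~ "monitored_not_detected",
    TRUE ~ "no_evidence"
  )
  out[, c("chem_id", "category", "biomon_monitored_in",
          "biomon_detected_in", "metabolome_listed_in")]
}

#' Partition step-1 detected chemicals by inventory membership
#'
#' Splits the step-1 `detected` set by the registry's `in_fccdb` /
#' `in_fccmigex` flags and tallies the other two categories.
#'
#' @param statuses output of [resolve_step1()].
#' @param registry the matching [chem_registry()].
#' @return named list: `fccdb_only`, `fccmigex_only`, `both`,
#'   `detected_total`, `monitored_not_detected`, `no_evidence`.
#' @export
count_step1_partition <- function(statuses, registry) {
  joined <- dplyr::inner_join(
    statuses, dplyr::select(registry, "chem_id", "in_fccdb", "in_fccmigex"),
    by = "chem_id"
  )
  det <- joined[joined$category == "detected", ]
  list(
    fccdb_only = sum(det$in_fccdb & !det$in_fccmigex),
    fccmigex_only = sum(!det$in_fccdb & det$in_fccmigex),
    both = sum(det$in_fccdb & det$in_fccmigex),
    detected_total = nrow(det),
    monitored_not_detected = sum(joined$category == "monitored_not_detected"),
    no_evidence = sum(joined$category == "no_evidence")
  )
}

#' Cross-program monitoring and detection overlap
#'
#' How widely are chemicals shared across the five biomonitoring programs?
#' Reports, for k = 1..5, the number of chemicals monitored in exactly and
#' in at least k programs, plus the number monitored in all five and the
#' number detected in all five (strict: a detection missing in even one
#' program disqualifies).
#'
#' @param statuses output of [resolve_step1()].
#' @return list with `per_k` (tibble: `k`, `monitored_exactly`,
#'   `monitored_at_least`), `all_five_monitored`, `all_five_detected`.
#' @export
cross_program_overlap <- function(statuses) {
  n_prog <- length(fcc_programs)
  n_mon <- set_size(statuses$biomon_monitored_in)
  n_det <- set_size(statuses$biomon_detected_in)
  per_k <- tibble::tibble(
    k = seq_len(n_prog),
    monitored_exactly = vapply(seq_len(n_prog), function(k) sum(n_mon == k), integer(1)),
    monitored_at_least = vapply(seq_len(n_prog), function(k) sum(n_mon >= k), integer(1))
  )
  list(
    per_k = per_k,
    all_five_monitored = sum(n_mon == n_prog),
    all_five_detected = sum(n_det == n_prog)
  )
}
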