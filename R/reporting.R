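#' Consolidate step-1, step-2, hazard, and group results per chemical
#'
#' Builds the final per-chemical table (the FCChumon-style export): exactly
#' one row per registry chemical with
#'
#' * `overall_status`: `detected` if detected in step 1 or step 2;
#'   `monitored_not_detected` if monitored anywhere but never detected and
#'   never listed; `no_evidence` otherwise.
#' * `evidence_sources`: `|`-set over `biomonitoring`, `metabolome`,
#'   `literature`.
#' * `step`: `step1` if the chemical has any step-1 evidence or monitoring,
#'   `step2` if it was prioritized and has step-2 records, else `none`.
#' * `tier`, `group_label`: carried through where supplied, `""` otherwise.
#' * `migex_detect_entries`: FCCmigex detection-entry count.
#'
#' A chemical carrying step-2 statuses while also monitored or listed in
#' step 1 violates the prioritization contract and raises an error.
#'
#' @param registry a [chem_registry()] tibble.
#' @param step1_statuses output of [resolve_step1()].
#' @param step2_statuses output of [classify_step2()], or `NULL`.
#' @param tiers tibble `cas`, `tier` (e.g. `tier_table()$assignments`), or
#'   `NULL`.
#' @param groups validated groups tibble, or `NULL`.
#' @param migex_entries validated fccmigex tibble, or `NULL`.
#' @return consolidated tibble matching the `fcchumon` schema.
#' @export
consolidate <- function(registry, step1_statuses, step2_statuses = NULL,
                        tiers = NULL, groups = NULL, migex_entries = NULL) {
  out <- dplyr::left_join(
    dplyr::select(registry, "chem_id", "cas"),
    step1_statuses, by = "chem_id"
  )
  if (anyNA(out$category)) {
    abort_fcc("consolidate(): step-1 statuses must cover every registry chemical")
  }

  s2_cat <- rep("no_evidence", nrow(out))
  s2_present <- rep(FALSE, nrow(out))
  if (!is.null(step2_statuses) && nrow(step2_statuses) > 0) {
    idx <- match(out$chem_id, step2_statuses$chem_id)
    hit <- !is.na(idx)
    in_step1 <- hit & (out$category == "detected" | out$biomon_monitored_in != "")
    if (any(in_step1)) {
      abort_fcc("consolidate(): step-2 status supplied for chemical(s) ",
                "already present in step-1 sources: ",
                paste(utils::head(out$chem_id[in_step1], 5), collapse = ", "))
    }
    s2_cat[hit] <- step2_statuses$category[idx[hit]]
    s2_present[hit] <- step2_statuses$n_studies[idx[hit]] > 0
  }

  out$overall_status <- dplyr::case_when(
    out$category == "detected" | s2_cat == "detected" ~ "detected",
    out$category == "monitored_not_detected" |
      s2_cat == "monitored_not_detected" ~ "monitored_not_detected",
    TRUE ~ "no_evidence"
  )
  out$evidence_sources <- mapply(function(bd, ml, s2c) {
    set_join(c(
      if (bd != "") "biomonitoring",
      if (ml != "") "metabolome",
      if (s2c == "detected") "literature"
    ))
  }, out$biomon_detected_in, out$metabolome_listed_in, s2_cat, USE.NAMES = FALSE)
  out$step <- dplyr::case_when(
    out$category != "no_evidence" ~ "step1",
    s2_present ~ "step2",
    TRUE ~ "none"
  )

  out$tier <- ""
  if (!is.null(tiers)) {
    idx <- match(out$cas, tiers$cas)
    out$tier[!is.na(idx)] <- tiers$tier[idx[!is.na(idx)]]
  }
  out$group_label <- ""
  if (!is.null(groups)) {
    idx <- match(out$cas, groups$cas)
    out$group_label[!is.na(idx)] <- groups$group_label[idx[!is.na(idx)]]
  }
  out$migex_detect_entries <- 0L
  if (!is.null(migex_entries)) {
    counts <- count_migex_detections(registry, migex_entries)
    out$migex_detect_entries <-
      counts$migex_detect_entries[match(out$chem_id, counts$chem_id)]
  }
  out[, fcc_schemas$fcchumon]
}

#' Headline evidence counts from the consolidated table
#'
#' @param records consolidated tibble from [consolidate()].
#' @return named list: `n_universe`, `n_evidence`, `pct_evidence` (nearest
#'   integer percent), `n_biomon_detected`, `n_metabolome_listed`,
#'   `n_overlap` (chemicals in both source types), `n_step2_detected`,
#'   `n_monitored_not_detected`, `n_no_evidence`, `tier_counts` (named,
#'   over assigned tiers).
#' @export
evidence_summary <- function(records) {
  has_bio <- set_has(records$evidence_sources, "biomonitoring")
  has_met <- set_has(records$evidence_sources, "metabolome")
  has_lit <- set_has(records$evidence_sources, "literature")
  n_evidence <- sum(records$overall_status == "detected")
  tiered <- records$tier[records$tier != ""]
  list(
    n_universe = nrow(records),
    n_evidence = n_evidence,
    pct_evidence = as.integer(round(100 * n_evidence / max(nrow(records), 1))),
    n_biomon_detected = sum(has_bio),
    n_metabolome_listed = sum(has_met),
    n_overlap = sum(has_bio & has_met),
    n_step2_detected = sum(has_lit),
    n_monitored_not_detected = sum(records$overall_status == "monitored_not_detected"),
    n_no_evidence = sum(records$overall_status == "no_evidence"),
    tier_counts = as.list(vapply(fcc_tiers, function(t) sum(tiered == t), integer(1)))
  )
}

#' Per-group evidence summaries
#'
#' Aggregates a consolidated subset by curated group label (assigned
#' upstream by expert judgment; ungrouped chemicals are pooled under
#' `"(ungrouped)"`). For each group:
#'
#' * `migex_detect_entry_sum`: summed FCCmigex detection entries of its
#'   members - evidence of group presence in food contact materials.
#' * `human_evidence_weight`: in step-1 mode, the summed number of
#'   biomonitoring programs monitoring each member; in step-2 mode, the
#'   number of distinct studies monitoring at least one member.
#' * the `detected` / `monitored_not_detected` / `no_evidence` split, which
#'   always sums to `n_fccs`.
#'
#' @param records consolidated subset (rows of a [consolidate()] table).
#' @param step1_statuses output of [resolve_step1()] (step-1 mode), or
#'   `NULL`.
#' @param step2_records evidence_map records (step-2 mode), or `NULL`.
#'   Exactly one of the two must be supplied.
#' @return tibble of group summaries, one row per group label.
#' @export
group_summaries <- function(records, step1_statuses = NULL, step2_records = NULL) {
  if (is.null(step1_statuses) == is.null(step2_records)) {
    abort_fcc("group_summaries(): supply exactly one of step1_statuses, step2_records")
  }
  records <- tibble::as_tibble(records)
  records$group_label[records$group_label == ""] <- "(ungrouped)"

  if (!is.null(step1_statuses)) {
    idx <- match(records$chem_id, step1_statuses$chem_id)
    records$weight <- set_size(step1_statuses$biomon_monitored_in[idx])
    weight_fn <- function(sub) sum(sub$weight)
  } else {
    step2_records <- tibble::as_tibble(step2_records)
    weight_fn <- function(sub) {
      length(unique(step2_records$study_id[step2_records$fcc_cas %in% sub$cas]))
    }
  }
  records |>
    dplyr::group_by(group_label = .data$group_label) |>
    dplyr::group_modify(function(sub, key) {
      tibble::tibble(
        n_fccs = nrow(sub),
        migex_detect_entry_sum = sum(sub$migex_detect_entries),
        human_evidence_weight = weight_fn(sub),
        n_detected = sum(sub$overall_status == "detected"),
        n_monitored_not_detected =
          sum(sub$overall_status == "monitored_not_detected"),
        n_no_evidence = sum(sub$overall_status == "no_evidence")
      )
    }) |>
    dplyr::ungroup()
}

#' Flow table for an evidence-status x concern-tier Sankey diagram
#'
#' Cross-tabulates a consolidated subset by overall evidence status and
#' concern tier, merging `other_concern` and `not_classified` into one band
#' as conventionally displayed. Flows conserve: their weights sum to the
#' subset size. Every record must carry an assigned tier.
#'
#' @param records consolidated subset with non-empty `tier` for every row.
#' @return tibble `status`, `tier_band`, `n` (only nonzero flows, in fixed
#'   band order).
#' @export
sankey_export <- function(records) {
  records <- tibble::as_tibble(records)
  if (any(records$tier == "")) {
    abort_fcc("sankey_export(): every record needs an assigned tier")
  }
  bands <- c("high", "medium", "other_or_not_classified", "no_hazard_data")
  records$tier_band <- ifelse(
    records$tier %in% c("other_concern", "not_classified"),
    "other_or_not_classified", records$tier
  )
  records |>
    dplyr::count(
      status = factor(.data$overall_status, levels = fcc_evidence_statuses),
      tier_band = factor(.data$tier_band, levels = bands),
      name = "n"
    ) |>
    dplyr::mutate(status = as.character(.data$status),
                  tier_band = as.character(.data$tier_band))
}

#' Chemicals both found in food contact materials and biomonitored
#'
#' The step-1A hazard-mapping subset: chemicals monitored in at least one
#' biomonitoring program *and* carrying at least one FCCmigex entry
#' reporting detection in a migrate or extract. This operational definition
#' is a package design choice and can be overridden by passing an explicit
#' subset to [tier_table()].
#'
#' @param registry a [chem_registry()] tibble.
#' @param step1_statuses output of [resolve_step1()].
#' @param migex_entries validated fccmigex tibble.
#' @return character vector of CAS numbers.
#' @export
biomonitored_fcm_subset <- function(registry, step1_statuses, migex_entries) {
  monitored <- step1_statuses$chem_id[step1_statuses$biomon_monitored_in != ""]
  counts <- count_migex_detections(registry, migex_entries)
  with_migex <- counts$chem_id[counts$migex_detect_entries >= 1]
  ids <- intersect(monitored, with_migex)
  registry$cas[match(ids, registry$chem_id)]
}

#' Run the full two-step pipeline on an in-memory source bundle
#'
#' Convenience wrapper chaining metabolite expansion, step-1 resolution,
#' step-2 prioritization and classification, hazard tiering of the two
#' standard subsets, and consolidation. Input is a bundle as produced by
#' [generate_universe()] (or assembled from [read_source()] calls with the
#' same element names).
#'
#' @param bundle named list with elements `registry`, `biomonitoring`,
#'   `metabolome`, `fccmigex`, `evidence_map`, `hazard`, `groups`.
#' @param threshold step-2 prioritization threshold (default 5).
#' @return named list: `step1`, `partition`, `overlap`, `prioritized`,
#'   `step2`, `aggregates`, `tiers_biomonitored`, `tiers_prioritized`,
#'   `fcchumon`, `summary`.
#' @export
run_fcc_pipeline <- function(bundle, threshold = 5) {
  registry <- chem_registry(bundle$registry)
  expanded <- expand_metabolite_links(bundle$biomonitoring)
  step1 <- resolve_step1(registry, expanded, bundle$metabolome)
  partition <- count_step1_partition(step1, registry)
  overlap <- cross_program_overlap(step1)
  prioritized <- prioritize(registry, step1, bundle$fccmigex, threshold)
  step2 <- classify_step2(bundle$evidence_map, prioritized)
  aggregates <- aggregate_step2(step2, bundle$evidence_map)
  biomon_cas <- biomonitored_fcm_subset(registry, step1, bundle$fccmigex)
  tiers_bio <- tier_table(biomon_cas, bundle$hazard)
  tiers_pri <- tier_table(prioritized$cas, bundle$hazard)
  tiers <- dplyr::bind_rows(tiers_bio$assignments, tiers_pri$assignments) |>
    dplyr::distinct(.data$cas, .keep_all = TRUE)
  fcchumon <- consolidate(registry, step1, step2, tiers = tiers,
                          groups = bundle$groups,
                          migex_entries = bundle$fccmigex)
  list(
    step1 = step1, partition = partition, overlap = overlap,
    prioritized = prioritized, step2 = step2, aggregates = aggregates,
    tiers_biomonitored = tiers_bio, tiers_prioritized = tiers_pri,
    fcchumon = fcchumon, summary = evidence_summary(fcchumon)
  )
}

#' Write the headline summary as JSON
#'
#' Fixed, documented key set (see [evidence_summary()]); numbers are written
#' unboxed so downstream consumers read plain scalars.
#'
#' @param summary list from [evidence_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
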