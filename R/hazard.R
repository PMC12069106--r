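#' Assign a GHS-based concern tier to one chemical
#'
#' Pools the chemical's hazard classification records from both inventories
#' (ECHA C&L, Japanese GHS) with equal weight and applies, in order of
#' precedence:
#'
#' 1. `high`: any CMR (carcinogenicity, mutagenicity, reproductive
#'    toxicity) classification in category 1A or 1B, and/or STOT RE
#'    (specific target organ toxicity, repeated exposure) category 1.
#' 2. `medium`: any CMR or STOT RE classification in category 2 (suspected).
#' 3. `other_concern`: classified only for other hazards (e.g. aquatic
#'    toxicity, skin sensitization).
#' 4. `not_classified`: hazard data exist in at least one category but no
#'    classification was triggered.
#' 5. `no_hazard_data`: not present in either inventory, or no data in any
#'    hazard category.
#'
#' Endocrine disruption, persistence, bioaccumulation and mobility are not
#' tiered; records for them, if supplied under `hazard_class = "other"` with
#' `category = "none"`, still count as data for the
#' `not_classified`/`no_hazard_data` distinction. When the two inventories
#' disagree, the pooled maximum wins.
#'
#' @param records hazard records for one chemical (possibly zero rows), with
#'   columns `hazard_class`, `category`, `has_data`.
#' @return a single tier string, one of [fcc_tiers].
#' @export
#' @examples
#' assign_tier(tibble::tibble(hazard_class = "reproductive_toxicity",
#'                            category = "cat_1B", has_data = TRUE))
assign_tier <- function(records) {
  if (nrow(records) == 0) return("no_hazard_data")
  contradictory <- records$category != "none" & !records$has_data
  if (any(contradictory)) {
    abort_fcc("Contradictory hazard record: category set but has_data=false")
  }
  cmr <- c("carcinogenicity", "mutagenicity", "reproductive_toxicity")
  cls <- records$hazard_class
  cat <- records$category
  if (any(cls %in% cmr & cat %in% c("cat_1A", "cat_1B")) ||
        any(cls == "stot_re" & cat == "cat_1")) {
    return("high")
  }
  if (any(cls %in% c(cmr, "stot_re") & cat == "cat_2")) return("medium")
  if (any(cls == "other" & cat != "none")) return("other_concern")
  "not_classified"
}

#' Tier a set of chemicals and tabulate the result
#'
#' Applies [assign_tier()] to each chemical of a subset (typically either
#' the biomonitored-and-found-in-FCM set, or the step-2 prioritized set),
#' pooling each chemical's records across inventories. Chemicals without any
#' hazard record get `no_hazard_data`. When the two inventories would assign
#' different tiers on their own, the chemical is flagged
#' (`sources_disagree`) while receiving the pooled tier.
#'
#' @param subset_cas character vector of normalized CAS numbers defining the
#'   subset.
#' @param hazard validated hazard tibble.
#' @return list with `assignments` (tibble `cas`, `tier`,
#'   `sources_disagree`) and `counts` (named integer over [fcc_tiers];
#'   always sums to `length(subset_cas)`).
#' @export
tier_table <- function(subset_cas, hazard) {
  subset_cas <- unique(subset_cas)
  hazard <- tibble::as_tibble(hazard)
  hz <- hazard[hazard$cas %in% subset_cas, ]
  tiers <- vapply(subset_cas, function(ca) {
    assign_tier(hz[hz$cas == ca, ])
  }, character(1), USE.NAMES = FALSE)
  disagree <- vapply(subset_cas, function(ca) {
    rec <- hz[hz$cas == ca, ]
    if (length(unique(rec$source)) < 2) return(FALSE)
    per_source <- vapply(unique(rec$source), function(s) {
      assign_tier(rec[rec$source == s, ])
    }, character(1))
    length(unique(per_source)) > 1
  }, logical(1), USE.NAMES = FALSE)
  assignments <- tibble::tibble(cas = subset_cas, tier = tiers,
                                sources_disagree = disagree)
  counts <- vapply(fcc_tiers, function(t) sum(tiers == t), integer(1))
  list(assignments = assignments, counts = counts)
}
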