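#' Controlled vocabularies used across the pipeline
#'
#' Character vectors enumerating the closed value sets used by the source
#' tables and the pipeline outputs. All readers validate against these, and
#' all classifiers emit values drawn from them.
#'
#' * `fcc_programs`: the five human biomonitoring programs.
#' * `fcc_metabolome_dbs`: the three metabolome/exposome databases.
#' * `fcc_hmdb_statuses`: the HMDB metabolite-status labels that count as
#'   listing evidence.
#' * `fcc_sample_types`: human sample types recorded in literature
#'   extraction records.
#' * `fcc_methods`: analytical method labels (per study).
#' * `fcc_analyte_forms`: whether a chemical was measured directly or via a
#'   (specific or unspecific) metabolite.
#' * `fcc_hazard_classes`: GHS hazard classes relevant to concern tiering;
#'   everything outside CMR/STOT-RE is pooled under `"other"`.
#' * `fcc_hazard_categories`: GHS categories; `"none"` marks a record that
#'   asserts data availability without any classification.
#' * `fcc_tiers`: concern tiers in decreasing order of precedence.
#' * `fcc_evidence_statuses`: per-chemical evidence statuses.
#'
#' @name fcc_vocab
#' @keywords datasets
NULL

#' @rdname fcc_vocab
#' @export
fcc_programs <- c("NHANES", "CHMS", "HBM4EU", "KoNEHS", "BiomonitoringCalifornia")

#' @rdname fcc_vocab
#' @export
fcc_metabolome_dbs <- c("HMDB", "BloodExposome", "ExposomeExplorer")

#' @rdname fcc_vocab
#' @export
fcc_hmdb_statuses <- c(
  "detected_quantified", "detected_not_quantified", "expected_not_quantified"
)

#' @rdname fcc_vocab
#' @export
fcc_sample_types <- c(
  "urine", "serum", "blood", "plasma", "breast_milk",
  "umbilical_cord", "placenta", "other"
)

#' @rdname fcc_vocab
#' @export
fcc_methods <- c("targeted", "nontargeted", "both")

#' @rdname fcc_vocab
#' @export
fcc_analyte_forms <- c("parent", "specific_metabolite", "unspecific_metabolite")

#' @rdname fcc_vocab
#' @export
fcc_hazard_classes <- c(
  "carcinogenicity", "mutagenicity", "reproductive_toxicity", "stot_re", "other"
)

#' @rdname fcc_vocab
#' @export
fcc_hazard_categories <- c("cat_1A", "cat_1B", "cat_1", "cat_2", "other", "none")

#' @rdname fcc_vocab
#' @export
fcc_hazard_sources <- c("ECHA_CLP", "Japan_GHS")

#' @rdname fcc_vocab
#' @export
fcc_tiers <- c("high", "medium", "other_concern", "not_classified", "no_hazard_data")

#' @rdname fcc_vocab
#' @export
fcc_evidence_statuses <- c("detected", "monitored_not_detected", "no_evidence")
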