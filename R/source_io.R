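#' @noRd
fcc_schemas <- list(
  registry = c("chem_id", "cas", "inchikey", "smiles", "names",
               "is_mixture", "in_fccdb", "in_fccmigex"),
  biomonitoring = c("program", "analyte_cas", "analyte_name", "parent_cas", "status"),
  metabolome = c("database", "cas", "inchikey", "smiles", "name", "status"),
  fccmigex = c("entry_id", "cas", "inchikey", "smiles", "name",
               "fca_type", "fcm_material", "detected", "reference_id"),
  hazard = c("cas", "source", "hazard_class", "category", "has_data"),
  evidence_map = c("study_id", "fcc_cas", "sample_type", "method",
                   "analyte_form", "detected"),
  groups = c("cas", "group_label"),
  fcchumon = c("chem_id", "cas", "overall_status", "evidence_sources",
               "step", "tier", "group_label", "migex_detect_entries")
)

fcc_logical_cols <- list(
  registry = c("is_mixture", "in_fccdb", "in_fccmigex"),
  fccmigex = "detected",
  hazard = "has_data",
  evidence_map = "detected"
)

#' Source kinds understood by [read_source()] and [write_source()]
#' @return character vector of kind names.
#' @export
source_kinds <- function() names(fcc_schemas)

parse_bool <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "1")] <- TRUE
  out[v %in% c("false", "0")] <- FALSE
  out
}

# per-kind row validators: return character vector of row error messages ("" = ok)
validate_rows <- function(df, kind) {
  n <- nrow(df)
  err <- rep("", n)
  add <- function(bad, msg) {
    bad[is.na(bad)] <- TRUE
    err[bad] <<- ifelse(err[bad] == "", msg, paste(err[bad], msg, sep = "; "))
  }
  chk_cas <- function(col, required = FALSE) {
    v <- df[[col]]
    present <- !is.na(v) & v != ""
    if (required) add(!present, paste0(col, " missing"))
    if (any(present)) {
      parsed <- cas_normalize(v[present], strict = FALSE)
      bad <- rep(FALSE, n)
      bad[present] <- is.na(parsed$normalized)
      add(bad, paste0("unparseable ", col))
    }
  }
  chk_enum <- function(col, allowed) {
    add(!(df[[col]] %in% allowed), paste0("invalid ", col))
  }
  chk_bool <- function(col) add(is.na(df[[col]]), paste0(col, " must be true/false"))

  switch(kind,
    registry = {
      chk_cas("cas")
      for (col in fcc_logical_cols$registry) chk_bool(col)
    },
    biomonitoring = {
      chk_enum("program", fcc_programs)
      chk_enum("status", c("detected", "not_detected"))
      chk_cas("analyte_cas", required = TRUE)
      chk_cas("parent_cas")
    },
    metabolome = {
      chk_enum("database", fcc_metabolome_dbs)
      chk_cas("cas")
      hmdb <- df$database == "HMDB"
      add(hmdb & !(df$status %in% fcc_hmdb_statuses),
          "HMDB rows need an HMDB metabolite status")
      add(!hmdb & df$database %in% fcc_metabolome_dbs & df$status != "listed",
          "non-HMDB rows must carry status 'listed'")
    },
    fccmigex = {
      chk_cas("cas")
      chk_bool("detected")
      add(duplicated(df$entry_id), "duplicate entry_id")
    },
    hazard = {
      chk_cas("cas", required = TRUE)
      chk_enum("source", fcc_hazard_sources)
      chk_enum("hazard_class", fcc_hazard_classes)
      chk_enum("category", fcc_hazard_categories)
      chk_bool("has_data")
      # a classified row that claims to carry no data is contradictory
      add(df$category != "none" & !is.na(df$has_data) & !df$has_data,
          "category set but has_data=false")
    },
    evidence_map = {
      chk_cas("fcc_cas", required = TRUE)
      chk_enum("sample_type", fcc_sample_types)
      chk_enum("method", fcc_methods)
      chk_enum("analyte_form", fcc_analyte_forms)
      chk_bool("detected")
      key <- paste(df$study_id, df$fcc_cas, df$sample_type, df$analyte_form)
      add(duplicated(key), "duplicate (study_id, fcc_cas, sample_type, analyte_form)")
    },
    groups = {
      chk_cas("cas", required = TRUE)
      add(is.na(df$group_label) | df$group_label == "", "group_label missing")
    },
    fcchumon = {
      chk_enum("overall_status", fcc_evidence_statuses)
      chk_enum("step", c("step1", "step2", "none"))
      add(!(df$tier %in% c(fcc_tiers, "")), "invalid tier")
    }
  )
  err
}

#' Read and validate a source table
#'
#' Reads one of the pipeline's CSV source kinds (see [source_kinds()]) with
#' strict schema checking: the header must match the kind's schema exactly,
#' booleans must be `true`/`false`, enum columns must use their controlled
#' vocabulary, and CAS columns must parse. Empty string means missing.
#'
#' In `strict` mode (the default, used by the pipeline) any invalid row is an
#' error. In `lenient` mode invalid rows are dropped and collected in the
#' load report, which is attached as the `report` attribute:
#' `list(n_read, n_kept, n_rejected, errors)` with
#' `n_read == n_kept + n_rejected` always.
#'
#' @param path CSV file path.
#' @param kind one of [source_kinds()].
#' @param mode `"strict"` or `"lenient"`.
#' @return validated tibble with typed columns and a `report` attribute.
#' @export
read_source <- function(path, kind, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind, names(fcc_schemas))
  if (!file.exists(path)) abort_fcc("File not found: ", path)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE, na = character())
  validate_source(df, kind, mode)
}

#' Validate an in-memory source table
#'
#' Same checks as [read_source()] applied to a data frame already in memory
#' (all columns character, as read from CSV, or already typed).
#'
#' @inheritParams read_source
#' @param df data frame to validate.
#' @return validated tibble with typed columns and a `report` attribute.
#' @export
validate_source <- function(df, kind, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind, names(fcc_schemas))
  schema <- fcc_schemas[[kind]]
  if (!identical(names(df), schema)) {
    abort_fcc(
      "Schema mismatch for kind '", kind, "': expected columns [",
      paste(schema, collapse = ","), "], got [",
      paste(names(df), collapse = ","), "]"
    )
  }
  df <- tibble::as_tibble(df)
  for (col in schema) {
    if (!is.character(df[[col]]) && !is.logical(df[[col]]) && !is.numeric(df[[col]])) {
      df[[col]] <- as.character(df[[col]])
    }
  }
  for (col in fcc_logical_cols[[kind]] %||% character(0)) {
    if (!is.logical(df[[col]])) df[[col]] <- parse_bool(df[[col]])
  }
  if (kind == "fcchumon" && !is.numeric(df$migex_detect_entries)) {
    df$migex_detect_entries <- suppressWarnings(as.integer(df$migex_detect_entries))
  }
  char_cols <- setdiff(schema, c(unlist(fcc_logical_cols[[kind]]), "migex_detect_entries"))
  for (col in char_cols) df[[col]][is.na(df[[col]])] <- ""

  err <- validate_rows(df, kind)
  bad <- err != ""
  errors <- tibble::tibble(row = which(bad), message = err[bad])
  if (mode == "strict" && any(bad)) {
    abort_fcc(
      "Invalid ", kind, " row(s): ",
      paste(sprintf("row %d (%s)", utils::head(errors$row, 5),
                    utils::head(errors$message, 5)), collapse = "; "),
      if (nrow(errors) > 5) sprintf(" (and %d more)", nrow(errors) - 5) else ""
    )
  }
  kept <- df[!bad, ]
  # normalize CAS columns in place for downstream exact matching
  cas_cols <- intersect(c("cas", "analyte_cas", "parent_cas", "fcc_cas"), schema)
  for (col in cas_cols) {
    present <- kept[[col]] != ""
    if (any(present)) {
      kept[[col]][present] <- cas_normalize(kept[[col]][present], strict = FALSE)$normalized
    }
  }
  if ("inchikey" %in% schema) {
    kept$inchikey <- as.character(
      ifelse(kept$inchikey == "", "", inchikey_normalize(kept$inchikey))
    )
  }
  attr(kept, "report") <- list(
    n_read = nrow(df), n_kept = nrow(kept), n_rejected = sum(bad), errors = errors
  )
  kept
}

#' Write a source table to CSV
#'
#' Deterministic writer: RFC 4180 quoting, UTF-8, `true`/`false` booleans,
#' empty string for missing values. Re-reading with [read_source()] yields an
#' identical table, and writing the same table twice yields byte-identical
#' files.
#'
#' @param df table to write (must match the kind's schema).
#' @param path output path.
#' @param kind one of [source_kinds()].
#' @return `path`, invisibly.
#' @export
write_source <- function(df, path, kind) {
  kind <- match.arg(kind, names(fcc_schemas))
  schema <- fcc_schemas[[kind]]
  if (!identical(names(df), schema)) {
    abort_fcc("write_source(): columns must be exactly [",
              paste(schema, collapse = ","), "]")
  }
  out <- tibble::as_tibble(df)
  for (col in fcc_logical_cols[[kind]] %||% character(0)) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write the consolidated FCChumon table
#'
#' Rows are sorted by `chem_id` before writing, so output is a pure function
#' of the record set (round-trip and re-write are byte-identical).
#'
#' @param records consolidated records from [consolidate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fcchumon <- function(records, path) {
  records <- dplyr::arrange(tibble::as_tibble(records), .data$chem_id)
  write_source(records, path, "fcchumon")
}

#' Read a consolidated FCChumon table
#'
#' @param path CSV path written by [write_fcchumon()].
#' @param mode `"strict"` or `"lenient"`.
#' @return validated tibble.
#' @export
read_fcchumon <- function(path, mode = "strict") {
  read_source(path, "fcchumon", mode)
}

#' Fill in manually assigned CAS numbers for analytes missing them
#'
#' Biomonitoring lists occasionally omit CAS numbers; curators assign them by
#' hand. The patch table maps `analyte_name` to `cas`; rows whose
#' `analyte_cas` is empty and whose name appears in the patch get the patched
#' CAS.
#'
#' @param analytes biomonitoring tibble.
#' @param patch data frame with columns `analyte_name`, `cas`.
#' @return patched biomonitoring tibble.
#' @export
apply_cas_patch <- function(analytes, patch) {
  idx <- analytes$analyte_cas == "" &
    analytes$analyte_name %in% patch$analyte_name
  if (any(idx)) {
    m <- match(analytes$analyte_name[idx], patch$analyte_name)
    analytes$analyte_cas[idx] <- cas_normalize(patch$cas[m])$normalized
  }
  analytes
}
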