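#' Construct and validate a chemical registry
#'
#' The registry is the master table of known food contact chemicals, one row
#' per chemical, carrying the identifiers used for all cross-source matching.
#' Required columns:
#'
#' * `chem_id`: opaque unique key.
#' * `cas`, `inchikey`, `smiles`: identifiers, `""` where absent.
#' * `names`: `|`-separated synonym list.
#' * `is_mixture`: logical; mixtures (e.g. chlorinated paraffins) typically
#'   carry a CAS number only, so structural identifiers are never required.
#' * `in_fccdb`, `in_fccmigex`: logical membership flags in the two FCC
#'   inventories; every registry row must be in at least one.
#'
#' Identifiers are normalized in place ([cas_normalize()],
#' [inchikey_normalize()], [smiles_normalize()]); CAS numbers with a
#' non-verifying check digit are kept but reported via the
#' `invalid_checksum_cas` attribute so either auditing choice (keep or
#' filter) is available downstream.
#'
#' @param df data frame with the columns above.
#' @return validated registry tibble with an `invalid_checksum_cas`
#'   attribute (character vector of retained CAS with failing check digits).
#' @export
chem_registry <- function(df) {
  required <- c("chem_id", "cas", "inchikey", "smiles", "names",
                "is_mixture", "in_fccdb", "in_fccmigex")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_fcc("Registry is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  if (anyDuplicated(df$chem_id)) {
    abort_fcc("Registry chem_id values must be unique")
  }
  if (any(!df$in_fccdb & !df$in_fccmigex)) {
    abort_fcc("Every registry chemical must be flagged in_fccdb and/or in_fccmigex")
  }
  has_cas <- !is.na(df$cas) & df$cas != ""
  norm <- cas_normalize(df$cas[has_cas], strict = TRUE)
  df$cas[has_cas] <- norm$normalized
  df$inchikey <- ifelse(is.na(df$inchikey), "", inchikey_normalize(df$inchikey))
  df$smiles <- ifelse(is.na(df$smiles), "", smiles_normalize(df$smiles))
  bad_ik <- df$inchikey != "" & !inchikey_is_valid(df$inchikey)
  if (any(bad_ik)) {
    abort_fcc("Malformed InChIKey(s): ",
              paste(utils::head(unique(df$inchikey[bad_ik]), 5), collapse = ", "))
  }
  no_id <- !has_cas & df$inchikey == "" & df$smiles == "" &
    (is.na(df$names) | df$names == "")
  if (any(no_id)) {
    abort_fcc("Registry row(s) with no identifiers at all: ",
              paste(utils::head(df$chem_id[no_id], 5), collapse = ", "))
  }
  attr(df, "invalid_checksum_cas") <- norm$normalized[!norm$checksum_valid]
  df
}

#' Match two chemical tables on shared identifiers
#'
#' A pair matches if *any* shared identifier kind agrees exactly after
#' normalization (union semantics). `matched_on` records the first agreeing
#' kind in `precedence` order. The relation is many-to-many: each left record
#' may match many right rows and vice versa. Output order is deterministic
#' (sorted by left key, right key).
#'
#' Conflicting identifier kinds (e.g. CAS agrees while both sides carry
#' differing InChIKeys) still match; such pairs are listed in the
#' `conflicts` attribute for auditing. Rows with no usable identifier among
#' the requested kinds are skipped and tallied in the `skipped` attribute.
#'
#' @param left data frame with a `chem_id` column plus identifier columns.
#' @param right data frame with identifier columns; its key column is named
#'   by `right_key` (a `row_id` column is added from row numbers if absent).
#' @param precedence ordered character vector of identifier kinds to use,
#'   default `c("cas", "inchikey", "smiles")`.
#' @param right_key name of the key column on `right`.
#' @return tibble with columns `left_id`, `right_id`, `matched_on` and
#'   attributes `skipped` (named integer: left/right rows without usable
#'   identifiers) and `conflicts` (tibble of matched pairs whose other
#'   identifier kinds disagree).
#' @export
#' @examples
#' left <- tibble::tibble(chem_id = "X", cas = "84-66-2", inchikey = "")
#' right <- tibble::tibble(cas = "84-66-2", inchikey = "")
#' match_chemicals(left, right)
match_chemicals <- function(left, right,
                            precedence = c("cas", "inchikey", "smiles"),
                            right_key = "row_id") {
  if (!all(precedence %in% c("cas", "inchikey", "smiles"))) {
    abort_fcc("precedence must be drawn from cas, inchikey, smiles")
  }
  left <- tibble::as_tibble(left)
  right <- tibble::as_tibble(right)
  if (!"chem_id" %in% names(left)) abort_fcc("left table needs a chem_id column")
  if (!right_key %in% names(right)) {
    right[[right_key]] <- as.character(seq_len(nrow(right)))
  }

  norm_kind <- function(df, kind) {
    if (!kind %in% names(df)) return(rep("", nrow(df)))
    v <- as.character(df[[kind]])
    v[is.na(v)] <- ""
    as.character(switch(kind,
      cas = v, # assumed normalized upstream; trimming is harmless
      inchikey = ifelse(v == "", "", inchikey_normalize(v)),
      smiles = smiles_normalize(v)
    ))
  }
  lkeys <- lapply(precedence, function(k) norm_kind(left, k))
  rkeys <- lapply(precedence, function(k) norm_kind(right, k))
  names(lkeys) <- names(rkeys) <- precedence

  pieces <- vector("list", length(precedence))
  for (i in seq_along(precedence)) {
    kind <- precedence[i]
    l <- tibble::tibble(left_id = left$chem_id, key = lkeys[[kind]])
    r <- tibble::tibble(right_id = right[[right_key]], key = rkeys[[kind]])
    l <- l[l$key != "", ]
    r <- r[r$key != "", ]
    pieces[[i]] <- dplyr::inner_join(l, r, by = "key",
                                     relationship = "many-to-many") |>
      dplyr::transmute(.data$left_id, .data$right_id, matched_on = kind)
  }
  res <- dplyr::bind_rows(pieces) |>
    dplyr::distinct(.data$left_id, .data$right_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$left_id, .data$right_id)

  usable_l <- Reduce(`|`, lapply(lkeys, function(v) v != ""))
  usable_r <- Reduce(`|`, lapply(rkeys, function(v) v != ""))
  skipped <- c(left = sum(!usable_l), right = sum(!usable_r))

  # audit trail: matched pairs where some other identifier kind disagrees
  conflicts <- res[0, ]
  if (nrow(res) > 0 && length(precedence) > 1) {
    lid_idx <- match(res$left_id, left$chem_id)
    rid_idx <- match(res$right_id, right[[right_key]])
    disagrees <- rep(FALSE, nrow(res))
    for (kind in precedence) {
      lv <- lkeys[[kind]][lid_idx]
      rv <- rkeys[[kind]][rid_idx]
      disagrees <- disagrees | (lv != "" & rv != "" & lv != rv)
    }
    conflicts <- res[disagrees, ]
  }
  attr(res, "skipped") <- skipped
  attr(res, "conflicts") <- conflicts
  res
}

#' Look up registry chemicals by name
#'
#' Name matching is deliberately excluded from automated cross-source
#' matching (names are too inconsistent across sources); this helper supports
#' the manual checks practitioners perform instead. Matching is
#' case-insensitive against the `|`-separated `names` field.
#'
#' @param registry a [chem_registry()] tibble.
#' @param name single chemical name.
#' @return the matching registry rows (possibly zero).
#' @export
lookup_by_name <- function(registry, name) {
  hit <- vapply(
    registry$names,
    function(s) tolower(name) %in% tolower(set_split(s)),
    logical(1), USE.NAMES = FALSE
  )
  registry[hit, ]
}
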