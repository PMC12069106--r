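#' Normalize CAS Registry Numbers and compute their check digit validity
#'
#' A CAS Registry Number has the form `NNNNNNN-NN-R`: a first block of two to
#' seven digits, a two-digit second block, and a single check digit `R`. The
#' check digit equals the weighted sum of the other digits, taken right to
#' left with weights 1, 2, 3, ..., modulo 10.
#'
#' Normalization trims whitespace, strips leading zeros from the first block,
#' and accepts bare digit strings (no hyphens), splitting them from the right
#' as 1 check digit, 2 middle digits, and the remainder. Numbers whose check
#' digit does not verify are *retained* and flagged via `checksum_valid`;
#' sources in this domain carry occasional registry numbers with invalid
#' check digits that users must still be able to match verbatim.
#'
#' @param x character vector of raw CAS strings.
#' @param strict if `TRUE` (default), malformed values (wrong block lengths,
#'   non-digit characters) raise an error naming the offending values; if
#'   `FALSE` they yield `NA` in `normalized` and are counted in the
#'   `n_failed` attribute of the result.
#' @return A tibble with one row per input and columns `raw`, `normalized`
#'   (canonical hyphenated form, `NA` on failure in lenient mode), and
#'   `checksum_valid` (logical, `NA` on failure).
#' @export
#' @examples
#' cas_normalize(c("84-66-2", " 0100-42-5 ", "84663"))
cas_normalize <- function(x, strict = TRUE) {
  if (length(x) == 0) {
    return(tibble::tibble(
      raw = character(), normalized = character(), checksum_valid = logical()
    ))
  }
  raw <- as.character(x)
  trimmed <- gsub("[[:space:]]", "", raw)

  parse_one <- function(s) {
    if (is.na(s) || s == "") return(c(NA_character_, NA_character_, NA_character_))
    if (grepl("^\\d+-\\d{2}-\\d$", s)) {
      parts <- strsplit(s, "-", fixed = TRUE)[[1]]
    } else if (grepl("^\\d{5,10}$", s)) {
      n <- nchar(s)
      parts <- c(substr(s, 1, n - 3), substr(s, n - 2, n - 1), substr(s, n, n))
    } else {
      return(c(NA_character_, NA_character_, NA_character_))
    }
    b1 <- sub("^0+", "", parts[1])
    if (nchar(b1) < 2 || nchar(b1) > 7) {
      return(c(NA_character_, NA_character_, NA_character_))
    }
    c(b1, parts[2], parts[3])
  }

  parsed <- t(vapply(trimmed, parse_one, character(3), USE.NAMES = FALSE))
  failed <- is.na(parsed[, 1]) & !is.na(raw) & trimmed != ""
  failed[is.na(raw)] <- TRUE
  if (strict && any(failed)) {
    bad <- unique(raw[failed])
    abort_fcc(
      "Malformed CAS Registry Number(s): ",
      paste(utils::head(bad, 10), collapse = ", "),
      if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else ""
    )
  }

  normalized <- ifelse(
    is.na(parsed[, 1]), NA_character_,
    paste0(parsed[, 1], "-", parsed[, 2], "-", parsed[, 3])
  )
  checksum_valid <- rep(NA, length(raw))
  ok <- !is.na(parsed[, 1])
  if (any(ok)) {
    checksum_valid[ok] <- mapply(
      function(b1, b2, chk) cas_check_digit(b1, b2) == as.integer(chk),
      parsed[ok, 1], parsed[ok, 2], parsed[ok, 3], USE.NAMES = FALSE
    )
  }

  out <- tibble::tibble(raw = raw, normalized = normalized,
                        checksum_valid = checksum_valid)
  attr(out, "n_failed") <- sum(failed)
  out
}

#' Compute the CAS check digit for the two non-check blocks
#'
#' @param block1 first block (2-7 digits), character or integer.
#' @param block2 second block (2 digits), character or integer.
#' @return integer in 0-9.
#' @export
#' @examples
#' cas_check_digit("84", "66") # 2, so 84-66-2 verifies
cas_check_digit <- function(block1, block2) {
  digits <- as.integer(strsplit(paste0(block1, block2), "")[[1]])
  if (anyNA(digits)) abort_fcc("cas_check_digit(): non-digit input")
  sum(rev(digits) * seq_along(digits)) %% 10L
}

#' Is a CAS string well-formed with a verifying check digit?
#'
#' Vectorized convenience wrapper around [cas_normalize()] in lenient mode:
#' `TRUE` only for values that parse *and* pass the check digit test.
#'
#' @param x character vector of raw CAS strings.
#' @return logical vector (never `NA`).
#' @export
cas_is_valid <- function(x) {
  res <- cas_normalize(x, strict = FALSE)
  !is.na(res$checksum_valid) & res$checksum_valid
}

#' Validate InChIKey format
#'
#' An InChIKey is 27 characters: 14 uppercase letters, a hyphen, 10 uppercase
#' letters, a hyphen, and one final uppercase letter. Input is trimmed and
#' uppercased before testing; validation never throws.
#'
#' @param x character vector.
#' @return logical vector, `FALSE` for `NA`, empty, or malformed input.
#' @export
#' @examples
#' inchikey_is_valid("AAAAAAAAAAAAAA-BBBBBBBBBB-N")
inchikey_is_valid <- function(x) {
  x <- inchikey_normalize(x)
  !is.na(x) & grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", x)
}

#' Normalize an InChIKey (trim and uppercase)
#'
#' @param x character vector.
#' @return character vector; `NA` and `""` pass through as `NA`/`""`.
#' @export
inchikey_normalize <- function(x) toupper(trimws(as.character(x)))

#' Normalize a SMILES string for exact-string comparison
#'
#' SMILES are compared as exact trimmed strings: no canonicalization is
#' attempted, so two different valid encodings of the same structure do not
#' match. Structure-level matching is deliberately out of scope.
#'
#' @param x character vector.
#' @return character vector.
#' @export
smiles_normalize <- function(x) trimws(as.character(x))
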