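#' Serialize a character vector as a `|`-separated set field
#'
#' Set-valued columns (programs a chemical was monitored in, databases it is
#' listed in, ...) are stored in CSV-friendly form: unique elements, sorted,
#' joined with `|`. The empty set serializes to `""`.
#'
#' @param x character vector (elements of the set), possibly with duplicates.
#' @return length-1 character scalar.
#' @seealso [set_split()]
#' @export
#' @examples
#' set_join(c("NHANES", "CHMS", "NHANES"))
#' set_split("CHMS|NHANES")
set_join <- function(x) {
  x <- unique(x[!is.na(x) & x != ""])
  paste(sort(x), collapse = "|")
}

#' Split a `|`-separated set field back into a character vector
#'
#' @param s length-1 character scalar as produced by [set_join()].
#' @return character vector; `character(0)` for the empty set.
#' @export
set_split <- function(s) {
  if (length(s) != 1) stop("set_split() expects a single string", call. = FALSE)
  if (is.na(s) || s == "") return(character(0))
  strsplit(s, "|", fixed = TRUE)[[1]]
}

#' Number of elements in a serialized set field
#'
#' Vectorized over `s`.
#'
#' @param s character vector of `|`-separated set fields.
#' @return integer vector of set sizes.
#' @export
set_size <- function(s) {
  vapply(s, function(x) length(set_split(x)), integer(1), USE.NAMES = FALSE)
}

#' Test membership in a serialized set field
#'
#' Vectorized over `s`.
#'
#' @param s character vector of `|`-separated set fields.
#' @param element single element to look for.
#' @return logical vector.
#' @export
set_has <- function(s, element) {
  vapply(s, function(x) element %in% set_split(x), logical(1), USE.NAMES = FALSE)
}

# stop() with a consistent prefix-free message, no call
abort_fcc <- function(...) stop(paste0(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
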