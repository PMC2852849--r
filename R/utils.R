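#' Canonicalize a compound name
#'
#' Lower-cases, trims, and collapses internal whitespace; hyphens and
#' underscores count as whitespace, so `"biochanin A"` and `"Biochanin-A"`
#' map to the same key.
#'
#' @param x character vector of compound names.
#' @return character vector of canonical names.
#' @export
#' @examples
#' canonical_name(c("  Biochanin-A ", "GENISTEIN "))
canonical_name <- function(x) {
  stopifnot(is.character(x))
  x <- tolower(x)
  x <- gsub("[-_[:space:]]+", " ", x)
  trimws(x)
}

# Structured condition helper: all package errors carry class
# "terescore_error" plus a specific subclass, so callers (and the CLI)
# can distinguish user-input problems from bugs.
stop_terescore <- function(message, class, call. = FALSE, data = NULL) {
  cond <- errorCondition(message,
                         class = c(class, "terescore_error"),
                         data = data)
  stop(cond)
}

# scalar checks used across constructors
is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}
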