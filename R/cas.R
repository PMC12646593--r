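#' Validate CAS registry numbers
#'
#' A CAS registry number has the form `NNNNNNN-NN-R`: a body of 2-7 digits,
#' a 2-digit segment, and a single check digit `R`. The check digit equals
#' the sum of the body digits, each weighted by its 1-based position counted
#' from the right, modulo 10.
#'
#' @param cas Character vector of candidate CAS numbers.
#' @return Logical vector: `TRUE` where the checksum verifies, `FALSE` where
#'   the string is well-formed but the check digit is wrong.
#'
#'   Strings that do not match the `digits-digits-digit` pattern raise an
#'   error of class `chemtriage_malformed_cas`, so a malformed identifier is
#'   never silently conflated with a failed checksum.
#' @examples
#' validate_cas("76-74-4")     # TRUE  (pentobarbital)
#' validate_cas("2078-54-8")   # TRUE  (propofol)
#' validate_cas("76-74-5")     # FALSE (wrong check digit)
#' @export
validate_cas <- function(cas) {
  if (!is.character(cas)) {
    ct_abort("`cas` must be a character vector", class = "malformed_cas")
  }
  ok_pattern <- grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", cas)
  if (any(!ok_pattern)) {
    bad <- cas[!ok_pattern]
    ct_abort(
      sprintf("malformed CAS number(s): %s (expected digits-digits-digit)",
              paste(utils::head(bad, 5L), collapse = ", ")),
      class = "malformed_cas"
    )
  }
  vapply(cas, cas_checksum_ok, logical(1), USE.NAMES = FALSE)
}

cas_checksum_ok <- function(x) {
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  body <- as.integer(strsplit(paste0(parts[1], parts[2]), "")[[1]])
  check <- as.integer(parts[3])
  weights <- rev(seq_along(body))
  sum(body * weights) %% 10L == check
}

# append the correct check digit to a digit body such as "2078" + "54"
cas_with_checksum <- function(body1, body2) {
  body <- as.integer(strsplit(paste0(body1, body2), "")[[1]])
  check <- sum(body * rev(seq_along(body))) %% 10L
  paste0(body1, "-", body2, "-", check)
}
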