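#' Ionization profile of a chemical
#'
#' Describes the acid/base chemistry needed for Henderson-Hasselbalch
#' speciation: each ionizable group carries a pKa and a kind (`"acid"` loses
#' a proton to give a -1 charge, `"base"` gains one to give +1). At most two
#' groups of each kind are supported, so net charges stay within -2..+2.
#'
#' @param pka Numeric vector of acidity constants (one per group); may be
#'   empty for a non-ionizable chemical.
#' @param kind Character vector, same length as `pka`, each `"acid"` or
#'   `"base"`.
#' @param zwitterionic Flag: the molecule can hold compensating charges, so
#'   its net-neutral state is a zwitterion. Speciation pools all net-neutral
#'   microstates into the neutral fraction either way; the flag is carried
#'   for reporting.
#' @return An object of class `ionization_profile`.
#' @examples
#' ionization_profile()                          # non-ionizable
#' ionization_profile(4.8, "acid")               # carboxylic acid-like
#' ionization_profile(c(2.3, 9.7), c("acid", "base"), zwitterionic = TRUE)
#' @export
ionization_profile <- function(pka = numeric(), kind = character(),
                               zwitterionic = FALSE) {
  if (length(pka) != length(kind)) {
    ct_abort("`pka` and `kind` must have the same length", class = "bad_input")
  }
  if (length(pka) && (!is.numeric(pka) || any(!is.finite(pka)))) {
    ct_abort("all pKa values must be finite numbers", class = "bad_input")
  }
  if (!all(kind %in% c("acid", "base"))) {
    ct_abort("`kind` entries must be \"acid\" or \"base\"", class = "bad_input")
  }
  if (sum(kind == "acid") > 2L || sum(kind == "base") > 2L) {
    ct_abort(
      "at most 2 acid and 2 base groups are supported (species beyond +-2 charge unsupported)",
      class = "unsupported_charge"
    )
  }
  structure(
    list(pka = as.numeric(pka), kind = as.character(kind),
         zwitterionic = isTRUE(zwitterionic)),
    class = "ionization_profile"
  )
}

#' @export
print.ionization_profile <- function(x, ...) {
  if (!length(x$pka)) {
    cat("<ionization_profile: non-ionizable>\n")
  } else {
    cat(sprintf(
      "<ionization_profile: %s%s>\n",
      paste(sprintf("%s pKa=%.2f", x$kind, x$pka), collapse = ", "),
      if (x$zwitterionic) ", zwitterionic" else ""
    ))
  }
  invisible(x)
}

#' @export
format.ionization_profile <- function(x, ...) {
  if (!length(x$pka)) return("")
  paste(sprintf("%s:%.12g", x$kind, x$pka), collapse = ";")
}

# parse "acid:4.5;base:9.2" (optionally suffixed ";zwitterion") back into a
# profile; inverse of format.ionization_profile + the zwitterion column
parse_ionization <- function(text, zwitterionic = FALSE) {
  if (is.na(text) || !nzchar(text)) {
    return(ionization_profile(zwitterionic = zwitterionic))
  }
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    ct_abort(sprintf("cannot parse ionization spec %s", dQuote(text)),
             class = "parse")
  }
  kind <- vapply(kv, `[[`, character(1), 1L)
  pka <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2L)))
  if (any(is.na(pka))) {
    ct_abort(sprintf("non-numeric pKa in ionization spec %s", dQuote(text)),
             class = "parse")
  }
  ionization_profile(pka, kind, zwitterionic = zwitterionic)
}
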