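#' Classify intrinsic hepatic clearance
#'
#' Categorical bins for in vitro intrinsic hepatic clearance
#' (ul/min/10^6 cells): a value of 0 indicates little to no metabolism;
#' below 2.5 a very slow rate; above 10 fast; above 100 rapid; the gap
#' `[2.5, 10]` is labeled intermediate. The most specific applicable label
#' is returned (rapid implies fast but is reported as rapid).
#'
#' @param clint Numeric vector, non-negative, ul/min/10^6 cells.
#' @return Factor with levels `no_metabolism`, `very_slow`, `intermediate`,
#'   `fast`, `rapid`.
#' @examples
#' classify_clearance(c(0, 2.0, 5, 50, 195.1))
#' @export
classify_clearance <- function(clint) {
  if (!is.numeric(clint) || any(is.na(clint)) || any(clint < 0)) {
    ct_abort("`clint` must be non-negative and non-missing", class = "bad_input")
  }
  out <- character(length(clint))
  out[clint == 0] <- "no_metabolism"
  out[clint > 0 & clint < 2.5] <- "very_slow"
  out[clint >= 2.5 & clint <= 10] <- "intermediate"
  out[clint > 10] <- "fast"
  out[clint > 100] <- "rapid"
  factor(out, levels = c("no_metabolism", "very_slow", "intermediate",
                         "fast", "rapid"))
}

#' Classify the plasma unbound fraction
#'
#' An unbound fraction of at least 50% indicates high availability of the
#' free chemical in plasma (boundary inclusive).
#'
#' @param fu Numeric vector of unbound fractions in `[0, 1]`.
#' @return Factor with levels `lower_availability`, `high_availability`.
#' @examples
#' classify_fu(c(0.49, 0.5, 1))
#' @export
classify_fu <- function(fu) {
  if (!is.numeric(fu) || any(is.na(fu)) || any(fu < 0) || any(fu > 1)) {
    ct_abort("`fu` must lie in [0, 1] and be non-missing", class = "bad_input")
  }
  factor(ifelse(fu >= 0.5, "high_availability", "lower_availability"),
         levels = c("lower_availability", "high_availability"))
}

#' ADME record for a chemical
#'
#' Carries clearance and unbound-fraction values with their provenance
#' (`human` preferred over `rodent` over `predicted`; `absent` when no
#' value exists). Provenance is recorded for reporting but does not alter
#' classification. Metals and inorganics are outside the applicability
#' domain of the prediction models; flag them with `out_of_domain`.
#'
#' @param clint Clearance in ul/min/10^6 cells, or `NA`.
#' @param fu Unbound fraction in `[0, 1]`, or `NA`.
#' @param source One of `"human"`, `"rodent"`, `"predicted"`, `"absent"`.
#' @param out_of_domain Flag for chemicals outside the model domain.
#' @return A list of class `adme_record` including the categorical
#'   classifications (`NA` where the input is absent).
#' @export
adme_record <- function(clint = NA_real_, fu = NA_real_,
                        source = c("absent", "human", "rodent", "predicted"),
                        out_of_domain = FALSE) {
  source <- match.arg(source)
  assert_scalar_num(clint, "clint", lower = 0, allow_na = TRUE)
  assert_scalar_num(fu, "fu", 0, 1, allow_na = TRUE)
  structure(
    list(
      clint = clint, fu = fu, source = source,
      out_of_domain = isTRUE(out_of_domain),
      clearance_class = if (is.na(clint)) NA_character_
                        else as.character(classify_clearance(clint)),
      fu_class = if (is.na(fu)) NA_character_
                 else as.character(classify_fu(fu))
    ),
    class = "adme_record"
  )
}
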