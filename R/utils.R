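#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# classed abort so callers can distinguish failure modes programmatically
ct_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("chemtriage_", class), "chemtriage_error"), ...)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    ct_abort(
      sprintf("`%s` must be a single number in [%s, %s], got %s",
              name, format(lower), format(upper), deparse(x)),
      class = "bad_input"
    )
  }
  invisible(x)
}
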