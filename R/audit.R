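#' Write a machine-readable triage audit report
#'
#' Serializes a [run_triage()] result to JSON: totals, per-stage counts,
#' the retained identifiers, every excluded record with its stage and all
#' failed criteria, waived (exception-flagged) identifiers, and the
#' threshold configuration that produced the result. The report
#' round-trips losslessly through [read_audit_report()].
#'
#' @param result A `triage_result`.
#' @param path Output path for the JSON file.
#' @param models Optional partition model configuration to echo into the
#'   report for provenance.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(result, path, models = NULL) {
  stopifnot(inherits(result, "triage_result"))
  decisions <- lapply(seq_len(nrow(result$excluded)), function(i) {
    list(id = result$excluded$id[i],
         stage = result$excluded$stage[i],
         reasons = as.list(result$excluded$reasons[[i]]))
  })
  report <- list(
    n_input = result$stage_counts$n_in[1],
    n_retained = nrow(result$retained),
    n_excluded = nrow(result$excluded),
    stage_counts = result$stage_counts,
    retained_ids = as.list(chem_id(result$retained)),
    exception_flagged = as.list(attr(result$retained, "exception_flagged") %||% character()),
    excluded = decisions,
    config = unclass(result$config)
  )
  if (!is.null(models)) {
    report$models <- lapply(models, function(m) {
      if (inherits(m, "linear_map_model")) unclass(m) else m
    })
  }
  tryCatch(
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE),
    error = function(e) {
      ct_abort(sprintf("cannot write audit report to %s: %s", path,
                       conditionMessage(e)), class = "io")
    }
  )
  invisible(path)
}

#' Read a triage audit report back
#'
#' @param path Path to a JSON file written by [write_audit_report()].
#' @return A list mirroring the report structure, with `stage_counts` as a
#'   tibble and `excluded` as a tibble with a `reasons` list-column.
#' @export
read_audit_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  excluded <- tibble(
    id = vapply(raw$excluded, function(d) d$id, character(1)),
    stage = vapply(raw$excluded, function(d) d$stage, character(1)),
    reasons = lapply(raw$excluded, function(d) unlist(d$reasons) %||% character())
  )
  counts <- raw$stage_counts
  stage_counts <- tibble(
    stage = vapply(counts, function(r) r$stage, character(1)),
    n_in = vapply(counts, function(r) as.integer(r$n_in), integer(1)),
    n_excluded = vapply(counts, function(r) as.integer(r$n_excluded), integer(1)),
    n_retained = vapply(counts, function(r) as.integer(r$n_retained), integer(1))
  )
  list(
    n_input = as.integer(raw$n_input),
    n_retained = as.integer(raw$n_retained),
    n_excluded = as.integer(raw$n_excluded),
    stage_counts = stage_counts,
    retained_ids = unlist(raw$retained_ids) %||% character(),
    exception_flagged = unlist(raw$exception_flagged) %||% character(),
    excluded = excluded,
    config = raw$config,
    models = raw$models
  )
}
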