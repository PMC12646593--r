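#' Chemical-record tables
#'
#' A chemical-record table is a tibble with one row per nominee and a fixed
#' column contract:
#' \describe{
#'   \item{identifiers}{`name`, `cas`, `dtxsid`, `smiles`, `inchikey`
#'     (character; optional ones `NA`). At least one identifier must be
#'     present per row; a present `cas` must pass the checksum.}
#'   \item{physchem}{`log_kow` (neutral species), `log_kaw` (optional),
#'     `ionization` (list-column of [ionization_profile()]s).}
#'   \item{logistics}{`purity_pct` in `[0, 100]`, `cost_eur >= 0`,
#'     `available`, `restricted`, `hazard_excluded`, `stability_ok`
#'     (logical).}
#'   \item{annotation}{`toxicity_groups`, `moa_tags`, `use_categories`
#'     (list-columns of character vectors), `exposome`,
#'     `reference_compound`, `moa_exception` (logical).}
#' }
#' Missing optional numerics are `NA` -- an explicit absent state; models
#' that need them raise rather than impute.
#'
#' @param ... Columns passed to [tibble::tibble()]; missing optional
#'   columns are filled with their absent defaults.
#' @return A validated `chemical_records` tibble.
#' @export
chemical_records <- function(...) {
  df <- tibble(...)
  as_chemical_records(df)
}

record_column_defaults <- function(n) {
  list(
    name = rep(NA_character_, n), cas = rep(NA_character_, n),
    dtxsid = rep(NA_character_, n), smiles = rep(NA_character_, n),
    inchikey = rep(NA_character_, n),
    log_kow = rep(NA_real_, n), log_kaw = rep(NA_real_, n),
    ionization = replicate(n, ionization_profile(), simplify = FALSE),
    purity_pct = rep(NA_real_, n), cost_eur = rep(NA_real_, n),
    available = rep(NA, n), restricted = rep(NA, n),
    hazard_excluded = rep(NA, n), stability_ok = rep(NA, n),
    toxicity_groups = replicate(n, character(), simplify = FALSE),
    moa_tags = replicate(n, character(), simplify = FALSE),
    use_categories = replicate(n, character(), simplify = FALSE),
    exposome = rep(FALSE, n), reference_compound = rep(FALSE, n),
    moa_exception = rep(FALSE, n)
  )
}

#' Coerce and validate a data frame as a chemical-record table
#'
#' @param df A data frame with at least one identifier column.
#' @return A validated tibble with the full column contract.
#' @export
as_chemical_records <- function(df) {
  df <- as_tibble(df)
  n <- nrow(df)
  defaults <- record_column_defaults(n)
  for (col in names(defaults)) {
    if (!col %in% names(df)) df[[col]] <- defaults[[col]]
  }
  df <- df[names(defaults)]
  validate_records(df)
  df
}

validate_records <- function(df) {
  id_cols <- c("inchikey", "dtxsid", "cas", "name")
  has_id <- Reduce(`|`, lapply(df[id_cols], function(x) !is.na(x) & nzchar(x)))
  if (nrow(df) && any(!has_id)) {
    ct_abort(sprintf("row(s) %s carry no identifier",
                     paste(utils::head(which(!has_id), 5L), collapse = ", ")),
             class = "schema")
  }
  with_cas <- which(!is.na(df$cas) & nzchar(df$cas))
  if (length(with_cas)) {
    ok <- validate_cas(df$cas[with_cas])
    if (any(!ok)) {
      ct_abort(sprintf("CAS checksum failure in row(s) %s",
                       paste(utils::head(with_cas[!ok], 5L), collapse = ", ")),
               class = "schema")
    }
  }
  bad_purity <- !is.na(df$purity_pct) & (df$purity_pct < 0 | df$purity_pct > 100)
  if (any(bad_purity)) {
    ct_abort("purity_pct must lie in [0, 100]", class = "schema")
  }
  if (any(!is.na(df$cost_eur) & df$cost_eur < 0)) {
    ct_abort("cost_eur must be >= 0", class = "schema")
  }
  ok_profile <- vapply(df$ionization, inherits, logical(1), "ionization_profile")
  if (any(!ok_profile)) {
    ct_abort("`ionization` must hold ionization_profile objects", class = "schema")
  }
  invisible(df)
}

#' Canonical per-record identifier
#'
#' Identifier precedence for deduplication and joins:
#' InChIKey > DTXSID > CAS > name.
#'
#' @param records A chemical-record tibble.
#' @return Character vector of identifiers, one per row.
#' @export
chem_id <- function(records) {
  if (nrow(records) == 0L) return(character(0))
  pick <- function(inchikey, dtxsid, cas, name) {
    for (x in c(inchikey, dtxsid, cas, name)) {
      if (!is.na(x) && nzchar(x)) return(x)
    }
    NA_character_
  }
  mapply(pick, records$inchikey, records$dtxsid, records$cas, records$name,
         USE.NAMES = FALSE)
}

default_column_mapping <- function() {
  fields <- c("name", "cas", "dtxsid", "smiles", "inchikey", "log_kow",
              "log_kaw", "pka_groups", "zwitterionic", "purity_pct",
              "cost_eur", "available", "restricted", "hazard_excluded",
              "stability_ok", "toxicity_groups", "moa_tags",
              "use_categories", "exposome", "reference_compound",
              "moa_exception")
  stats::setNames(as.list(fields), fields)
}

#' Read a delimited chemical table
#'
#' Reads a UTF-8 delimited text file with a header row into a validated
#' chemical-record table. Multi-valued cells use `|` as the within-cell
#' separator (`toxicity_groups`, `moa_tags`, `use_categories`); ionizable
#' groups are written `"acid:4.5;base:9.2"` in the `pka_groups` column.
#'
#' @param source Path to the file.
#' @param mapping Named list mapping record fields to column names in the
#'   file (defaults to identity); alternatively the path of a JSON file
#'   holding that mapping. `name` and `log_kow` are mandatory fields.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return A `chemical_records` tibble; missing optional fields are `NA`.
#' @export
read_chemical_table <- function(source, mapping = default_column_mapping(),
                                delim = ",") {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- jsonlite::read_json(mapping, simplifyVector = TRUE)
  }
  mapping <- utils::modifyList(default_column_mapping(), as.list(mapping))
  raw <- readr::read_delim(source, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)

  mandatory <- c("name", "log_kow")
  missing_cols <- vapply(mandatory, function(f) {
    !mapping[[f]] %in% names(raw)
  }, logical(1))
  if (any(missing_cols)) {
    ct_abort(
      sprintf("mandatory column(s) missing from %s: %s", source,
              paste(unlist(mapping[mandatory[missing_cols]]), collapse = ", ")),
      class = "schema"
    )
  }

  col <- function(field) {
    nm <- mapping[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  }
  num <- function(field) parse_numeric_column(col(field), mapping[[field]], source)
  lgl <- function(field, default = NA) {
    x <- toupper(trimws(col(field)))
    out <- rep(default, nrow(raw))
    out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
    out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
    out
  }
  split_col <- function(field) {
    lapply(col(field), function(x) {
      if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
    })
  }

  zwit <- lgl("zwitterionic", default = FALSE)
  zwit[is.na(zwit)] <- FALSE
  ion <- mapply(function(spec, z) parse_ionization(spec, z),
                col("pka_groups"), zwit, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  chemical_records(
    name = col("name"), cas = col("cas"), dtxsid = col("dtxsid"),
    smiles = col("smiles"), inchikey = col("inchikey"),
    log_kow = num("log_kow"), log_kaw = num("log_kaw"),
    ionization = ion,
    purity_pct = num("purity_pct"), cost_eur = num("cost_eur"),
    available = lgl("available"), restricted = lgl("restricted"),
    hazard_excluded = lgl("hazard_excluded"), stability_ok = lgl("stability_ok"),
    toxicity_groups = split_col("toxicity_groups"),
    moa_tags = split_col("moa_tags"),
    use_categories = split_col("use_categories"),
    exposome = lgl("exposome", FALSE) %in% TRUE,
    reference_compound = lgl("reference_compound", FALSE) %in% TRUE,
    moa_exception = lgl("moa_exception", FALSE) %in% TRUE
  )
}

parse_numeric_column <- function(x, colname, source) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(out))
  if (length(bad)) {
    ct_abort(
      sprintf("non-numeric value %s in column %s, row %d of %s",
              dQuote(x[bad[1]]), dQuote(colname %||% "?"), bad[1], source),
      class = "parse"
    )
  }
  out
}

#' Write a chemical-record table to delimited text
#'
#' Inverse of [read_chemical_table()]: list-columns are flattened with `|`,
#' ionization profiles serialized to the `pka_groups` syntax, numerics
#' written to full precision.
#'
#' @param records A chemical-record tibble.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_chemical_table <- function(records, path, delim = ",") {
  records <- as_chemical_records(records)
  flat <- tibble(
    name = records$name, cas = records$cas, dtxsid = records$dtxsid,
    smiles = records$smiles, inchikey = records$inchikey,
    log_kow = records$log_kow, log_kaw = records$log_kaw,
    pka_groups = vapply(records$ionization, format, character(1)),
    zwitterionic = vapply(records$ionization, function(p) p$zwitterionic, logical(1)),
    purity_pct = records$purity_pct, cost_eur = records$cost_eur,
    available = records$available, restricted = records$restricted,
    hazard_excluded = records$hazard_excluded, stability_ok = records$stability_ok,
    toxicity_groups = vapply(records$toxicity_groups, paste, character(1), collapse = "|"),
    moa_tags = vapply(records$moa_tags, paste, character(1), collapse = "|"),
    use_categories = vapply(records$use_categories, paste, character(1), collapse = "|"),
    exposome = records$exposome, reference_compound = records$reference_compound,
    moa_exception = records$moa_exception
  )
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}
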