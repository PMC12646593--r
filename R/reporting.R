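#' Bipartite category-chemical network
#'
#' Builds the category network behind the collection's visualization
#' views: category nodes on one side, chemical nodes on the other, an edge
#' wherever a chemical carries the category label. A chemical may connect
#' to any number of categories.
#'
#' @param records A chemical-record tibble.
#' @param classification `"toxicity"` (uses `toxicity_groups`) or `"use"`
#'   (uses `use_categories`).
#' @return An object of class `category_network`: `nodes` tibble
#'   (`id`, `kind`, `label`), `edges` tibble (`from` category id, `to`
#'   chemical id), and the `classification` label.
#' @export
build_category_network <- function(records, classification = c("toxicity", "use")) {
  if (is.character(classification) && length(classification) == 1L &&
      !classification %in% c("toxicity", "use")) {
    ct_abort(sprintf("unknown classification %s; use \"toxicity\" or \"use\"",
                     dQuote(classification)), class = "bad_input")
  }
  classification <- match.arg(classification)
  records <- as_chemical_records(records)
  ids <- chem_id(records)
  labels <- if (classification == "toxicity") records$toxicity_groups else records$use_categories

  cats <- sort(unique(unlist(labels)))
  cat_ids <- paste0("cat:", cats)
  nodes <- dplyr::bind_rows(
    tibble(id = cat_ids, kind = rep("category", length(cats)), label = cats),
    tibble(id = ids, kind = rep("chemical", length(ids)),
           label = ifelse(is.na(records$name), ids, records$name))
  )
  edge_list <- purrr::map2(ids, labels, function(id, ls) {
    if (!length(ls)) return(NULL)
    tibble(from = paste0("cat:", ls), to = rep(id, length(ls)))
  })
  edges <- dplyr::bind_rows(edge_list)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble(from = character(), to = character())
  }
  structure(
    list(nodes = nodes, edges = edges, classification = classification),
    class = "category_network"
  )
}

#' Export a category network as JSON
#'
#' Schema: an object with `classification`, `nodes` (array of
#' `{id, kind, label}`), and `edges` (array of `{source, target}`).
#' [network_from_json()] reproduces the graph exactly.
#'
#' @param network A `category_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
network_to_json <- function(network, path) {
  stopifnot(inherits(network, "category_network"))
  payload <- list(
    classification = network$classification,
    nodes = network$nodes,
    edges = tibble(source = network$edges$from, target = network$edges$to)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a category network from JSON
#'
#' Schema-checks the file: every edge endpoint must exist among the nodes.
#'
#' @param path Path to a JSON file written by [network_to_json()].
#' @return A `category_network`.
#' @export
network_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as_tibble(raw$nodes)
  if (length(raw$edges)) {
    edges <- tibble(from = raw$edges$source, to = raw$edges$target)
  } else {
    edges <- tibble(from = character(), to = character())
  }
  missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing_ep)) {
    ct_abort(sprintf("edge endpoint(s) missing from nodes: %s",
                     paste(utils::head(missing_ep, 5L), collapse = ", ")),
             class = "schema")
  }
  structure(
    list(nodes = nodes, edges = edges, classification = raw$classification),
    class = "category_network"
  )
}

#' Summary statistics of a chemical collection
#'
#' Property and annotation summaries of the kind used to characterize a
#' screening collection: range and mean of `log K_ow` (and of
#' `log D_lip/w` when a partition table is supplied), counts per toxicity
#' group (multi-membership counted per group), and a histogram of the
#' neutral-species fraction at pH 7.4 with the conventional bins
#' (strongly charged `< 0.2`, intermediate, neutral-dominant `>= 0.75`).
#'
#' @param records A non-empty chemical-record tibble.
#' @param partitions Optional [compute_partitions()] table.
#' @return A list of class `collection_summary`: `property_stats`,
#'   `group_counts`, `neutral_bins` tibbles.
#' @export
summarize_collection <- function(records, partitions = NULL) {
  records <- as_chemical_records(records)
  if (nrow(records) == 0L) {
    ct_abort("cannot summarize an empty collection", class = "bad_input")
  }
  stats_row <- function(name, x) {
    x <- x[!is.na(x)]
    tibble(property = name, n = length(x), min = min(x), max = max(x),
           mean = mean(x))
  }
  property_stats <- stats_row("log_kow", records$log_kow)
  if (!is.null(partitions)) {
    property_stats <- dplyr::bind_rows(
      property_stats, stats_row("log_dlipw", partitions$log_dlipw)
    )
  }

  group_tbl <- table(unlist(records$toxicity_groups))
  group_counts <- tibble(group = names(group_tbl),
                         n = as.integer(group_tbl))

  f_neutral <- vapply(records$ionization,
                      function(p) species_fractions(p, 7.4)$f_neutral,
                      numeric(1))
  bins <- cut(f_neutral, breaks = c(-Inf, 0.2, 0.5, 0.75, Inf),
              labels = c("charged (f_neutral < 0.2)",
                         "mostly charged [0.2, 0.5)",
                         "mixed [0.5, 0.75)",
                         "neutral-dominant [0.75, 1]"),
              right = FALSE)
  neutral_bins <- tibble(bin = levels(bins),
                         n = as.integer(table(bins)))

  structure(
    list(property_stats = property_stats, group_counts = group_counts,
         neutral_bins = neutral_bins),
    class = "collection_summary"
  )
}

#' @export
print.collection_summary <- function(x, ...) {
  cat("Collection summary\n\nProperties:\n")
  print(x$property_stats)
  cat("\nToxicity groups:\n")
  print(x$group_counts)
  cat("\nNeutral-fraction bins (pH 7.4):\n")
  print(x$neutral_bins)
  invisible(x)
}
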