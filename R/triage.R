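#' Triage configuration
#'
#' Thresholds of the three-stage selection pipeline:
#' stage 1 removes volatile (`D_aw > daw_max`), too-hydrophobic
#' (`log D_lip/w(pH) > log_dlipw_max`), and unstable chemicals; stage 2
#' removes chemicals failing logistics (purity below `purity_min_pct`,
#' cost above `cost_max_eur`, unavailable, restricted, or too hazardous);
#' stage 3 caps mechanistic redundancy within each toxicity group.
#'
#' @param daw_max Volatility cutoff on the linear `D_aw` (default `1e-4`).
#' @param log_dlipw_max Hydrophobicity cutoff (default 4).
#' @param purity_min_pct Minimum purity in percent (default 98).
#' @param cost_max_eur Maximum cost per chemical in euros (default 1000).
#' @param group_target_min,group_target_max Target size range per toxicity
#'   group (defaults 20 and 30). A group ending below the minimum emits a
#'   warning, never an error.
#' @param moa_max_per_group Maximum chemicals sharing one mechanism tag
#'   within a group (default 2, i.e. "1 or 2 per mechanism").
#' @param ph pH at which stage-1 distribution ratios are evaluated
#'   (default 7.4).
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(daw_max = 1e-4, log_dlipw_max = 4,
                          purity_min_pct = 98, cost_max_eur = 1000,
                          group_target_min = 20, group_target_max = 30,
                          moa_max_per_group = 2, ph = 7.4) {
  assert_scalar_num(daw_max, "daw_max", lower = 0)
  assert_scalar_num(log_dlipw_max, "log_dlipw_max")
  assert_scalar_num(purity_min_pct, "purity_min_pct", 0, 100)
  assert_scalar_num(cost_max_eur, "cost_max_eur", lower = 0)
  assert_scalar_num(group_target_min, "group_target_min", lower = 0)
  assert_scalar_num(group_target_max, "group_target_max", lower = 0)
  assert_scalar_num(moa_max_per_group, "moa_max_per_group", lower = 1)
  assert_scalar_num(ph, "ph", 0, 14)
  if (group_target_min > group_target_max) {
    ct_abort("group_target_min must not exceed group_target_max",
             class = "bad_input")
  }
  structure(
    list(daw_max = daw_max, log_dlipw_max = log_dlipw_max,
         purity_min_pct = purity_min_pct, cost_max_eur = cost_max_eur,
         group_target_min = group_target_min,
         group_target_max = group_target_max,
         moa_max_per_group = moa_max_per_group, ph = ph),
    class = "triage_config"
  )
}

new_stage_outcome <- function(ids, keep, reasons, stage) {
  list(
    retained_ids = ids[keep],
    excluded = tibble(
      id = ids[!keep],
      stage = rep(stage, sum(!keep)),
      reasons = reasons[!keep]
    )
  )
}

#' Stage 1: physicochemical applicability filter
#'
#' Excludes chemicals whose properties put them outside the applicability
#' domain of the bioassays: volatile (`D_aw` above the cutoff), too
#' hydrophobic (`log D_lip/w` above the cutoff), or unstable/insoluble in
#' aqueous media or DMSO. Records flagged `moa_exception` are retained
#' despite physicochemical breaches (mechanistic coverage can outweigh
#' dosing difficulty) but the waived criteria are recorded. Records
#' without usable partition data are excluded with reason `missing_data`.
#'
#' @param records A chemical-record tibble.
#' @param partitions Partition table from [compute_partitions()], matched
#'   to `records` by `id`.
#' @param config A [triage_config()].
#' @return A stage outcome: list with `retained_ids` and an `excluded`
#'   tibble (`id`, `stage`, `reasons` list-column), plus an
#'   `exception_flagged` character vector of waived ids.
#' @export
stage1_physchem <- function(records, partitions, config = triage_config()) {
  records <- as_chemical_records(records)
  ids <- chem_id(records)
  part <- partitions[match(ids, partitions$id), , drop = FALSE]
  n <- nrow(records)
  keep <- logical(n)
  reasons <- vector("list", n)
  flagged <- character()
  for (i in seq_len(n)) {
    r <- character()
    if (is.na(part$d_aw[i]) || is.na(part$log_dlipw[i])) {
      r <- c(r, "missing_data")
    } else {
      if (part$d_aw[i] > config$daw_max) r <- c(r, "volatile")
      if (part$log_dlipw[i] > config$log_dlipw_max) r <- c(r, "hydrophobic")
    }
    if (!isTRUE(records$stability_ok[i])) r <- c(r, "unstable")
    if (length(r) && isTRUE(records$moa_exception[i])) {
      flagged <- c(flagged, ids[i])
      r <- character()
    }
    keep[i] <- length(r) == 0L
    reasons[[i]] <- r
  }
  out <- new_stage_outcome(ids, keep, reasons, "stage1_physchem")
  out$exception_flagged <- flagged
  out
}

#' Stage 2: logistics filter
#'
#' Excludes chemicals failing practical procurement criteria: purity below
#' the minimum, cost above the limit, not commercially available,
#' prohibited/restricted (e.g. misuse potential), or too hazardous for
#' normal laboratory handling. All failing criteria are recorded per
#' record, not just the first. Records with absent logistics fields are
#' excluded with reason `missing_data`.
#'
#' @inheritParams stage1_physchem
#' @return A stage outcome (see [stage1_physchem()]).
#' @export
stage2_logistics <- function(records, config = triage_config()) {
  records <- as_chemical_records(records)
  ids <- chem_id(records)
  n <- nrow(records)
  keep <- logical(n)
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character()
    if (is.na(records$purity_pct[i]) || is.na(records$cost_eur[i]) ||
        is.na(records$available[i]) || is.na(records$restricted[i]) ||
        is.na(records$hazard_excluded[i])) {
      r <- c(r, "missing_data")
    } else {
      if (records$purity_pct[i] < config$purity_min_pct) r <- c(r, "purity")
      if (records$cost_eur[i] > config$cost_max_eur) r <- c(r, "cost")
      if (!records$available[i]) r <- c(r, "unavailable")
      if (records$restricted[i]) r <- c(r, "restricted")
      if (records$hazard_excluded[i]) r <- c(r, "hazard")
    }
    keep[i] <- length(r) == 0L
    reasons[[i]] <- r
  }
  new_stage_outcome(ids, keep, reasons, "stage2_logistics")
}

# priority order used by stage 3: exposome first, then reference
# compounds, then cheaper, id as the deterministic final tie-break
stage3_priority_order <- function(records, ids) {
  cost <- records$cost_eur
  cost[is.na(cost)] <- Inf
  order(-as.integer(records$exposome %in% TRUE),
        -as.integer(records$reference_compound %in% TRUE),
        cost, ids)
}

#' Stage 3: mechanistic-diversity selection
#'
#' Within each toxicity group, candidates are ranked (human-exposome
#' chemicals first, then reference compounds, then by ascending cost, then
#' by identifier) and admitted greedily while (a) no mechanism tag exceeds
#' `moa_max_per_group` admissions within the group and (b) the group stays
#' at or below `group_target_max`. A chemical belonging to several groups
#' counts toward each group's size but appears once in the retained set
#' (deduplicated by identifier). Records without a toxicity group are
#' handled as one `"unassigned"` group. Groups ending below
#' `group_target_min` trigger a warning.
#'
#' The greedy admission matches the exhaustive-search optimum on small
#' instances but is not guaranteed optimal in general; see the package
#' vignette.
#'
#' @inheritParams stage1_physchem
#' @return A stage outcome (see [stage1_physchem()]); exclusion reasons
#'   are `moa_redundant` and/or `group_full`.
#' @export
stage3_diversity <- function(records, config = triage_config()) {
  records <- as_chemical_records(records)
  ids <- chem_id(records)
  n <- nrow(records)
  if (n == 0L) return(new_stage_outcome(ids, logical(0), list(), "stage3_diversity"))

  groups <- lapply(records$toxicity_groups, function(g) {
    if (length(g) == 0L) "unassigned" else g
  })
  all_groups <- sort(unique(unlist(groups)))
  ord <- stage3_priority_order(records, ids)

  admitted <- logical(n)
  reject_reasons <- vector("list", n)
  for (g in all_groups) {
    members <- ord[vapply(groups[ord], function(x) g %in% x, logical(1))]
    tag_counts <- new.env(parent = emptyenv())
    size <- 0L
    for (i in members) {
      if (size >= config$group_target_max) {
        reject_reasons[[i]] <- union(reject_reasons[[i]], "group_full")
        next
      }
      tags <- records$moa_tags[[i]]
      counts <- vapply(tags, function(t) get0(t, tag_counts, ifnotfound = 0L),
                       integer(1))
      if (length(tags) && any(counts >= config$moa_max_per_group)) {
        reject_reasons[[i]] <- union(reject_reasons[[i]], "moa_redundant")
        next
      }
      admitted[i] <- TRUE
      size <- size + 1L
      for (t in tags) assign(t, get0(t, tag_counts, ifnotfound = 0L) + 1L, tag_counts)
    }
    if (size < config$group_target_min) {
      warn(sprintf("toxicity group %s ended with %d chemical(s), below the target minimum %d",
                   dQuote(g), size, as.integer(config$group_target_min)))
    }
  }
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    reasons[[i]] <- if (admitted[i]) character() else reject_reasons[[i]]
  }
  new_stage_outcome(ids, admitted, reasons, "stage3_diversity")
}

#' Run the full three-stage triage
#'
#' Applies [stage1_physchem()], [stage2_logistics()], and
#' [stage3_diversity()] in order; each stage sees only the survivors of
#' the previous one. Deterministic for fixed inputs.
#'
#' @param records A chemical-record tibble.
#' @param partitions Partition table from [compute_partitions()]; computed
#'   from `records` with `models` at `config$ph` when `NULL`.
#' @param config A [triage_config()].
#' @param models Partition model configuration used when `partitions` is
#'   `NULL`.
#' @return An object of class `triage_result`: `retained` (record tibble,
#'   with an `exception_flagged` attribute), `excluded` (tibble `id`,
#'   `stage`, `reasons`), `stage_counts` (tibble `stage`, `n_in`,
#'   `n_excluded`, `n_retained`), and the `config` echoed.
#' @export
run_triage <- function(records, partitions = NULL, config = triage_config(),
                       models = default_partition_models()) {
  records <- as_chemical_records(records)
  records <- dedupe_records(records)
  if (is.null(partitions)) {
    partitions <- compute_partitions(records, models = models, ph = config$ph)
  }
  ids <- chem_id(records)

  s1 <- stage1_physchem(records, partitions, config)
  rec2 <- records[ids %in% s1$retained_ids, , drop = FALSE]
  s2 <- stage2_logistics(rec2, config)
  rec3 <- rec2[chem_id(rec2) %in% s2$retained_ids, , drop = FALSE]
  s3 <- stage3_diversity(rec3, config)
  retained <- rec3[chem_id(rec3) %in% s3$retained_ids, , drop = FALSE]

  excluded <- dplyr::bind_rows(s1$excluded, s2$excluded, s3$excluded)
  stage_counts <- tibble(
    stage = c("stage1_physchem", "stage2_logistics", "stage3_diversity"),
    n_in = c(nrow(records), nrow(rec2), nrow(rec3)),
    n_excluded = c(nrow(s1$excluded), nrow(s2$excluded), nrow(s3$excluded)),
    n_retained = c(nrow(rec2), nrow(rec3), nrow(retained))
  )
  attr(retained, "exception_flagged") <- s1$exception_flagged
  structure(
    list(retained = retained, excluded = excluded,
         stage_counts = stage_counts, config = config),
    class = "triage_result"
  )
}

# drop duplicate nominees; first occurrence by canonical identifier wins
dedupe_records <- function(records) {
  ids <- chem_id(records)
  records[!duplicated(ids), , drop = FALSE]
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result: %d in, %d retained, %d excluded>\n",
              x$stage_counts$n_in[1], nrow(x$retained), nrow(x$excluded)))
  print(x$stage_counts)
  invisible(x)
}
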