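#' Linear log-log partition prediction model
#'
#' The package predicts neutral-species partition constants from the
#' octanol-water partition constant through configurable one-slope linear
#' maps on the log10 scale (`log K = slope * log K_ow + intercept`). These
#' stand behind the pluggable prediction backends (LSER databases,
#' consensus K_ow predictors) a production deployment would call; the
#' shipped defaults in [default_partition_models()] are documented
#' literature-style calibrations and can be replaced wholesale from a
#' config file.
#'
#' @param slope Dimensionless slope.
#' @param intercept Intercept in log10 units.
#' @param name Identifier echoed into audit reports.
#' @return An object of class `linear_map_model`.
#' @export
linear_map_model <- function(slope, intercept, name = "linear_map") {
  assert_scalar_num(slope, "slope")
  assert_scalar_num(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept, name = as.character(name)),
            class = "linear_map_model")
}

#' @export
print.linear_map_model <- function(x, ...) {
  cat(sprintf("<linear_map_model %s: %.4g * log_kow + %.4g>\n",
              x$name, x$slope, x$intercept))
  invisible(x)
}

eval_linear_map <- function(model, log_kow) {
  stopifnot(inherits(model, "linear_map_model"))
  model$slope * log_kow + model$intercept
}

#' Default partition prediction configuration
#'
#' One place for every tunable of the partition layer:
#' \describe{
#'   \item{klipw}{liposome-water map, `1.01 * log K_ow + 0.12` (membrane
#'     lipid tracks octanol closely).}
#'   \item{kbsaw_neutral}{serum-albumin map for neutral species,
#'     `0.71 * log K_ow + 0.42`.}
#'   \item{kbsaw_anion}{nonspecific albumin sorption map for anions,
#'     `0.30 * log K_ow + 2.00` (anions bind albumin more strongly than
#'     their hydrophobicity alone suggests).}
#'   \item{kspw}{structural-protein (muscle-type) map for neutral species,
#'     `0.76 * log K_ow - 0.46`.}
#'   \item{ion_offset}{log10 reduction of membrane affinity for charged
#'     species relative to the neutral species (default 1).}
#'   \item{anion_attenuation}{log10 reduction of the structural-protein
#'     anion term relative to the albumin anion term (default 1).}
#'   \item{hydrophilic_floor}{fixed albumin constant, 1.31, applied to
#'     neutral/cationic species of hydrophilic chemicals
#'     (`log K_ow < 2`).}
#'   \item{floor_scale}{`"log10"` (default): 1.31 is read as
#'     `log10 K_BSA/w`; `"linear"`: 1.31 is the ratio in L/L. Both
#'     readings circulate; switchable here.}
#' }
#' @return Named list of models and scalars.
#' @export
default_partition_models <- function() {
  list(
    klipw         = linear_map_model(1.01, 0.12, "klipw_from_kow"),
    kbsaw_neutral = linear_map_model(0.71, 0.42, "kbsaw_neutral_from_kow"),
    kbsaw_anion   = linear_map_model(0.30, 2.00, "kbsaw_anion_nonspecific"),
    kspw          = linear_map_model(0.76, -0.46, "kspw_from_kow"),
    ion_offset = 1,
    anion_attenuation = 1,
    hydrophilic_floor = 1.31,
    floor_scale = "log10"
  )
}

#' Predict the neutral-species liposome-water partition constant
#'
#' @param log_kow log10 octanol-water partition constant of the neutral
#'   species.
#' @param model A [linear_map_model()]; no silent default so calibrations
#'   are always explicit at the call site.
#' @return log10 K_lip/w of the neutral species.
#' @export
predict_log_klipw_neutral <- function(log_kow, model) {
  if (is.null(log_kow) || is.na(log_kow)) {
    ct_abort("`log_kow` is absent; cannot predict K_lip/w", class = "missing_input")
  }
  assert_scalar_num(log_kow, "log_kow")
  eval_linear_map(model, log_kow)
}

#' Ionization-corrected liposome-water distribution ratio
#'
#' `D_lip/w(pH)` is the species-weighted sum of the per-species
#' liposome-water partition constants. Charged species partition into
#' membranes about one order of magnitude more weakly than the neutral
#' species, expressed by `ion_offset` log units. The log10 result is
#' clipped from below at -1, the empirical lowest membrane distribution
#' ratio, below which the narcosis QSAR is not valid anyway.
#'
#' @param log_klipw_neutral log10 K_lip/w of the neutral species.
#' @param fractions A [species_fractions()] object.
#' @param ion_offset log10 reduction for charged species (default 1).
#' @return log10 `D_lip/w(pH)`, floored at -1.
#' @examples
#' f <- species_fractions(ionization_profile(4.8, "acid"), 7.4)
#' dlipw_at_ph(3, f)
#' @export
dlipw_at_ph <- function(log_klipw_neutral, fractions, ion_offset = 1) {
  assert_scalar_num(log_klipw_neutral, "log_klipw_neutral")
  assert_scalar_num(ion_offset, "ion_offset")
  stopifnot(inherits(fractions, "species_fractions"))
  k_neutral <- 10^log_klipw_neutral
  k_ion <- k_neutral * 10^(-ion_offset)
  f_charged <- fractions$f_minus + fractions$f_minus2 +
    fractions$f_plus + fractions$f_plus2
  d <- fractions$f_neutral * k_neutral + f_charged * k_ion
  max(log10(d), -1)
}

#' Ionization-corrected albumin-water distribution ratio
#'
#' Species rules: cations are assumed to bind albumin like the neutral
#' species; anions follow a separate nonspecific-sorption map because they
#' bind albumin more strongly; for hydrophilic chemicals (`log K_ow < 2`)
#' the neutral/cation constant is fixed at 1.31 (interpreted per
#' `floor_scale`). The result is the log10 of the species-weighted sum.
#'
#' @param log_kow log10 K_ow of the neutral species.
#' @param fractions A [species_fractions()] object.
#' @param neutral_model,anion_model [linear_map_model()]s for the neutral
#'   and anionic species.
#' @param hydrophilic_floor Fixed constant for hydrophilic chemicals
#'   (default 1.31).
#' @param floor_scale `"log10"` or `"linear"` reading of the floor.
#' @return log10 `D_BSA/w(pH)`.
#' @export
dbsaw_at_ph <- function(log_kow, fractions, neutral_model, anion_model,
                        hydrophilic_floor = 1.31,
                        floor_scale = c("log10", "linear")) {
  if (is.null(log_kow) || is.na(log_kow)) {
    ct_abort("`log_kow` is absent; cannot predict D_BSA/w", class = "missing_input")
  }
  assert_scalar_num(log_kow, "log_kow")
  floor_scale <- match.arg(floor_scale)
  stopifnot(inherits(fractions, "species_fractions"))

  log_k_neutral <- if (log_kow < 2) {
    if (floor_scale == "log10") hydrophilic_floor else log10(hydrophilic_floor)
  } else {
    eval_linear_map(neutral_model, log_kow)
  }
  log_k_anion <- eval_linear_map(anion_model, log_kow)

  f_nc <- fractions$f_neutral + fractions$f_plus + fractions$f_plus2
  f_an <- fractions$f_minus + fractions$f_minus2
  log10(f_nc * 10^log_k_neutral + f_an * 10^log_k_anion)
}

#' Ionization-corrected structural-protein-water distribution ratio
#'
#' Analogous to [dbsaw_at_ph()] with muscle-type structural proteins as
#' the sorbent. Anion binding to structural proteins is weaker than to
#' albumin, so the albumin anion term is attenuated by
#' `anion_attenuation` log units.
#'
#' @inheritParams dbsaw_at_ph
#' @param sp_model [linear_map_model()] for the neutral species against
#'   structural protein.
#' @param anion_model Albumin anion map that the attenuation applies to.
#' @param anion_attenuation log10 reduction (>= 0) of the anion term.
#' @return log10 `D_SP/w(pH)`.
#' @export
dspw_at_ph <- function(log_kow, fractions, sp_model, anion_model,
                       anion_attenuation = 1) {
  if (is.null(log_kow) || is.na(log_kow)) {
    ct_abort("`log_kow` is absent; cannot predict D_SP/w", class = "missing_input")
  }
  assert_scalar_num(log_kow, "log_kow")
  assert_scalar_num(anion_attenuation, "anion_attenuation", lower = 0)
  stopifnot(inherits(fractions, "species_fractions"))

  log_k_neutral <- eval_linear_map(sp_model, log_kow)
  log_k_anion <- eval_linear_map(anion_model, log_kow) - anion_attenuation

  f_nc <- fractions$f_neutral + fractions$f_plus + fractions$f_plus2
  f_an <- fractions$f_minus + fractions$f_minus2
  log10(f_nc * 10^log_k_neutral + f_an * 10^log_k_anion)
}

#' Assemble ionization-corrected distribution ratios for chemical records
#'
#' Convenience layer: speciates every record at `ph`, then evaluates the
#' air-water, liposome-water, albumin-water, and structural-protein-water
#' distribution ratios with one model configuration. This is the input the
#' triage and in vitro layers expect.
#'
#' @param records A chemical-record tibble (see [chemical_records()]).
#' @param models Model configuration, see [default_partition_models()].
#' @param ph pH (default 7.4).
#' @return A tibble with one row per record: `id`, `ph`, `f_neutral`,
#'   `d_aw` (linear), `log_dlipw`, `log_dbsaw`, `log_dspw`. Records with an
#'   absent `log_kaw` get `d_aw = NA` (explicitly absent, never imputed).
#' @export
compute_partitions <- function(records, models = default_partition_models(),
                               ph = 7.4) {
  records <- as_chemical_records(records)
  ids <- chem_id(records)
  n <- nrow(records)
  out <- tibble(
    id = ids, ph = rep(ph, n), f_neutral = NA_real_, d_aw = NA_real_,
    log_dlipw = NA_real_, log_dbsaw = NA_real_, log_dspw = NA_real_
  )
  for (i in seq_len(n)) {
    fr <- species_fractions(records$ionization[[i]], ph)
    out$f_neutral[i] <- fr$f_neutral
    if (!is.na(records$log_kaw[i])) {
      out$d_aw[i] <- daw_at_ph(records$log_kaw[i], fr)
    }
    lkow <- records$log_kow[i]
    if (!is.na(lkow)) {
      out$log_dlipw[i] <- dlipw_at_ph(
        predict_log_klipw_neutral(lkow, models$klipw), fr,
        ion_offset = models$ion_offset
      )
      out$log_dbsaw[i] <- dbsaw_at_ph(
        lkow, fr, models$kbsaw_neutral, models$kbsaw_anion,
        hydrophilic_floor = models$hydrophilic_floor,
        floor_scale = models$floor_scale
      )
      out$log_dspw[i] <- dspw_at_ph(
        lkow, fr, models$kspw, models$kbsaw_anion,
        anion_attenuation = models$anion_attenuation
      )
    }
  }
  out
}
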