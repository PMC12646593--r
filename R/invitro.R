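#' Bioassay composition for the in vitro mass balance
#'
#' Volumetric description of a serum-supplemented cell assay. Defaults are
#' typical values for medium with 10% fetal bovine serum: protein volume
#' fraction 0.3% and lipid 0.007% of medium volume; cells contain 3%
#' protein, 0.5% lipid, and the balance water. The cell volume relative to
#' the bioassay volume defaults to 0: in 10% FBS the mass taken up into
#' cells is negligible unless a cell volume is supplied.
#'
#' @param vf_protein_medium,vf_lipid_medium Volume fractions of protein and
#'   lipid per medium volume.
#' @param v_cell_over_v_bioassay Cell volume / bioassay volume.
#' @param vf_protein_cell,vf_lipid_cell,vf_water_cell Composition of the
#'   cell volume; must sum to 1.
#' @return An object of class `bioassay_setup`.
#' @export
bioassay_setup <- function(vf_protein_medium = 0.003,
                           vf_lipid_medium = 0.00007,
                           v_cell_over_v_bioassay = 0,
                           vf_protein_cell = 0.03,
                           vf_lipid_cell = 0.005,
                           vf_water_cell = 0.965) {
  for (nm in c("vf_protein_medium", "vf_lipid_medium", "v_cell_over_v_bioassay",
               "vf_protein_cell", "vf_lipid_cell", "vf_water_cell")) {
    assert_scalar_num(get(nm), nm, 0, 1)
  }
  if (abs(vf_protein_cell + vf_lipid_cell + vf_water_cell - 1) > 1e-9) {
    ct_abort("cell composition fractions must sum to 1", class = "bad_input")
  }
  structure(
    list(vf_protein_medium = vf_protein_medium,
         vf_lipid_medium = vf_lipid_medium,
         v_cell_over_v_bioassay = v_cell_over_v_bioassay,
         vf_protein_cell = vf_protein_cell,
         vf_lipid_cell = vf_lipid_cell,
         vf_water_cell = vf_water_cell),
    class = "bioassay_setup"
  )
}

#' Critical membrane concentration for baseline cytotoxicity
#'
#' The membrane concentration producing a 10% reduction of cell
#' proliferation is nearly invariant across cell types and species;
#' the default is 26 mmol per liter of membrane lipid.
#'
#' @param ic10_membrane_mmol_per_l_lip Positive value in mmol/L_lip.
#' @return An object of class `baseline_constants`.
#' @export
baseline_constants <- function(ic10_membrane_mmol_per_l_lip = 26) {
  assert_scalar_num(ic10_membrane_mmol_per_l_lip, "ic10_membrane_mmol_per_l_lip",
                    lower = 1e-12)
  structure(list(ic10_membrane = ic10_membrane_mmol_per_l_lip),
            class = "baseline_constants")
}

# sorptive-phase-normalized volume fractions of the medium; zero total
# sorptive volume contributes nothing rather than dividing by zero
medium_phase_fractions <- function(setup) {
  tot <- setup$vf_protein_medium + setup$vf_lipid_medium
  if (tot == 0) return(list(protein = 0, lipid = 0, total = 0))
  list(protein = setup$vf_protein_medium / tot,
       lipid = setup$vf_lipid_medium / tot,
       total = tot)
}

#' Medium-water distribution ratio
#'
#' Proteins (albumin surrogate) and lipids are the dominant sorptive phases
#' of serum-supplemented medium:
#' `D_medium/w = D_BSA/w * VF_protein + D_lip/w * VF_lipid`, with the
#' volume fractions normalized to the sorptive-phase volume.
#'
#' @param log_dbsaw log10 albumin-water distribution ratio.
#' @param log_dlipw log10 liposome-water distribution ratio.
#' @param setup A [bioassay_setup()].
#' @return `D_medium/w` on the linear scale.
#' @export
d_medium_w <- function(log_dbsaw, log_dlipw, setup = bioassay_setup()) {
  assert_scalar_num(log_dbsaw, "log_dbsaw")
  assert_scalar_num(log_dlipw, "log_dlipw")
  vf <- medium_phase_fractions(setup)
  10^log_dbsaw * vf$protein + 10^log_dlipw * vf$lipid
}

#' Cell-water distribution ratio
#'
#' Cells are modeled as structural protein (muscle-type proteins are the
#' better surrogate for intracellular protein than albumin), membrane
#' lipid, and water:
#' `D_cell/w = D_SP/w * VF_protein_cell + D_lip/w * VF_lipid_cell +
#' VF_water_cell`.
#'
#' @param log_dspw log10 structural-protein-water distribution ratio.
#' @inheritParams d_medium_w
#' @return `D_cell/w` on the linear scale.
#' @export
d_cell_w <- function(log_dspw, log_dlipw, setup = bioassay_setup()) {
  assert_scalar_num(log_dspw, "log_dspw")
  assert_scalar_num(log_dlipw, "log_dlipw")
  10^log_dspw * setup$vf_protein_cell +
    10^log_dlipw * setup$vf_lipid_cell +
    setup$vf_water_cell
}

#' Freely dissolved fraction in the bioassay
#'
#' Fraction of total chemical mass present freely dissolved in the aqueous
#' phase of the assay:
#' `f_free = 1 / (1 + D_medium/w * V_sorptive/V_medium +
#' D_cell/w * V_cell/V_medium)`.
#'
#' @param d_medium_w,d_cell_w Linear distribution ratios (>= 0).
#' @param setup A [bioassay_setup()].
#' @return Fraction in `(0, 1]`.
#' @export
f_free <- function(d_medium_w, d_cell_w, setup = bioassay_setup()) {
  assert_scalar_num(d_medium_w, "d_medium_w", lower = 0)
  assert_scalar_num(d_cell_w, "d_cell_w", lower = 0)
  vf <- medium_phase_fractions(setup)
  1 / (1 + d_medium_w * vf$total + d_cell_w * setup$v_cell_over_v_bioassay)
}

#' Nominal baseline-cytotoxic concentration
#'
#' Scales the critical membrane concentration back to the nominal dose in
#' the assay through the mass balance:
#' `IC10_nominal = IC10_membrane / D_lip/w * (1 + D_BSA/w * VF_protein_medium
#' + D_lip/w * VF_lipid_medium + D_cell/w * V_cell/V_bioassay)`,
#' with the volume fractions per bioassay volume.
#'
#' @param log_dlipw log10 liposome-water distribution ratio (linear ratio
#'   must be positive).
#' @param log_dbsaw log10 albumin-water distribution ratio.
#' @param d_cell_w Cell-water distribution ratio, linear scale.
#' @param setup A [bioassay_setup()].
#' @param constants A [baseline_constants()].
#' @return Concentration in mol/L.
#' @export
ic10_nominal_baseline <- function(log_dlipw, log_dbsaw,
                                  d_cell_w = 0,
                                  setup = bioassay_setup(),
                                  constants = baseline_constants()) {
  assert_scalar_num(log_dlipw, "log_dlipw")
  assert_scalar_num(log_dbsaw, "log_dbsaw")
  assert_scalar_num(d_cell_w, "d_cell_w", lower = 0)
  dlipw <- 10^log_dlipw
  dbsaw <- 10^log_dbsaw
  sorption <- 1 +
    dbsaw * setup$vf_protein_medium +
    dlipw * setup$vf_lipid_medium +
    d_cell_w * setup$v_cell_over_v_bioassay
  constants$ic10_membrane / dlipw * sorption / 1000  # mmol/L -> mol/L
}

#' Freely dissolved baseline-cytotoxic concentration
#'
#' `IC10_free = IC10_membrane / D_lip/w`, the freely dissolved
#' concentration at which baseline cytotoxicity is expected; comparable to
#' in vivo lethal concentrations.
#'
#' @inheritParams ic10_nominal_baseline
#' @return Concentration in mol/L.
#' @export
ic10_free <- function(log_dlipw, constants = baseline_constants()) {
  assert_scalar_num(log_dlipw, "log_dlipw")
  constants$ic10_membrane / 10^log_dlipw / 1000
}

#' Per-chemical in vitro availability table
#'
#' Applies the full mass balance to a partition table: medium and cell
#' distribution ratios, freely dissolved fraction, and nominal/free
#' baseline IC10. Emits a warning when predominantly cationic chemicals
#' are run on tissue-culture-treated plates, whose anionic surfaces can
#' bind cations (binding constants for treated plastic are not available,
#' so that loss process is not modeled).
#'
#' @param partitions Output of [compute_partitions()].
#' @param setup A [bioassay_setup()].
#' @param constants A [baseline_constants()].
#' @param treated_plates Flag: assay uses tissue-culture-treated plates.
#' @param fractions Optional list of [species_fractions()] (parallel to
#'   `partitions`) used only for the cation warning.
#' @return Tibble: `id`, `f_free`, `ic10_nominal_mol_l`, `ic10_free_mol_l`.
#' @export
assay_availability <- function(partitions, setup = bioassay_setup(),
                               constants = baseline_constants(),
                               treated_plates = TRUE, fractions = NULL) {
  n <- nrow(partitions)
  out <- tibble(id = partitions$id, f_free = NA_real_,
                ic10_nominal_mol_l = NA_real_, ic10_free_mol_l = NA_real_)
  for (i in seq_len(n)) {
    if (is.na(partitions$log_dlipw[i])) next
    dmw <- d_medium_w(partitions$log_dbsaw[i], partitions$log_dlipw[i], setup)
    dcw <- d_cell_w(partitions$log_dspw[i], partitions$log_dlipw[i], setup)
    out$f_free[i] <- f_free(dmw, dcw, setup)
    out$ic10_nominal_mol_l[i] <- ic10_nominal_baseline(
      partitions$log_dlipw[i], partitions$log_dbsaw[i],
      d_cell_w = dcw, setup = setup, constants = constants
    )
    out$ic10_free_mol_l[i] <- ic10_free(partitions$log_dlipw[i], constants)
  }
  if (treated_plates && !is.null(fractions)) {
    cationic <- vapply(fractions, function(f) f$f_plus + f$f_plus2 > 0.5, logical(1))
    if (any(cationic)) {
      warn(sprintf(
        "%d predominantly cationic chemical(s): treated plates carry anionic surfaces that may bind cations; this loss is not modeled",
        sum(cationic)
      ))
    }
  }
  out
}
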