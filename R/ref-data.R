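# Reference characterization data for the tolcapone-analogue TTR stabilizer
# series. These tables are the worked-example inputs for the bookkeeping
# operations and the validation fixtures for the consistency checks.

#' MD binding-energy components for the tolcapone analogue series
#'
#' Ensemble-averaged gas-phase interaction energies (`dE_gp`, from
#' \eqn{\Delta E_{gp} = E_{TTR} + 2 E_L - E_{TTR\cdot 2L}}) and continuum
#' ligand solvation free energies (`dG_Lsolv`) for tolcapone and the five
#' analogues M-14, M-17, M-20, M-21 and M-23, together with the reported
#' predicted binding energy `dG_bind_reported`
#' (\eqn{\Delta G_{bind} = \Delta E_{gp} + 2\Delta G_{L\mathchar`-solv}};
#' positive = favorable in this convention). All values in kcal/mol.
#'
#' @return Data frame with columns `ligand`, `dE_gp`, `dG_Lsolv`,
#'   `dG_bind_reported`.
#' @seealso [binding_energy()], [rank_ligands()]
#' @export
md_energy_table <- function() {
  data.frame(
    ligand = c("tolcapone", "M-14", "M-17", "M-20", "M-21", "M-23"),
    dE_gp = c(81.5, 76.6, 90.2, 79.0, 95.2, 116.2),
    dG_Lsolv = c(-10.9, -10.6, -11.1, -11.0, -10.6, -15.9),
    dG_bind_reported = c(59.7, 55.4, 68.0, 57.0, 74.0, 84.4),
    stringsAsFactors = FALSE
  )
}

#' ITC thermodynamic parameters for the tolcapone analogue series
#'
#' Dissociation constants and Gibbs decompositions from isothermal titration
#' calorimetry at 25 C. Tolcapone and its analogues bind the two thyroxine
#' sites of the TTR tetramer without cooperativity (one row each); tafamidis
#' shows negative cooperativity and carries one row per site (`site` 1 and 2).
#'
#' @return Data frame with columns `ligand`, `site`, `kd_nM`, `dG_kcal`,
#'   `dH_kcal`, `minus_TdS_kcal`.
#' @seealso [validate_thermo_table()]
#' @export
itc_thermo_table <- function() {
  data.frame(
    ligand = c("tolcapone", "tafamidis", "tafamidis", "M-14", "M-17",
               "M-20", "M-21", "M-23"),
    site = c(NA, 1L, 2L, NA, NA, NA, NA, NA),
    kd_nM = c(34, 9.9, 260, 310, 31, 85, 26, 6.2),
    dG_kcal = c(-10.2, -10.9, -9.0, -8.9, -10.3, -9.7, -10.4, -11.2),
    dH_kcal = c(-12.8, -6.0, -6.5, -9.2, -14.0, -11.7, -11.3, -16.6),
    minus_TdS_kcal = c(2.6, -4.9, -2.5, 0.3, 3.7, 2.0, 0.9, 5.4),
    stringsAsFactors = FALSE
  )
}

#' Aqueous solubility assays for M-23 and tolcapone
#'
#' Triplicate gravimetric solubility determinations: solid weighed, distilled
#' water added until total dissolution.
#'
#' @return Data frame with columns `compound`, `assay`, `weight_mg`,
#'   `water_mL`.
#' @seealso [solubility()]
#' @export
solubility_table <- function() {
  data.frame(
    compound = rep(c("M-23", "tolcapone"), each = 3L),
    assay = rep(1:3, 2L),
    weight_mg = c(15.4, 14.7, 15.0, 15.0, 14.4, 15.3),
    water_mL = c(350, 326, 333, 267, 261, 273),
    stringsAsFactors = FALSE
  )
}
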