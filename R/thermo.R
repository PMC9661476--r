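# Thermodynamic bookkeeping shared by the ITC and ranking stages.

#' Free energy of binding from a dissociation constant
#'
#' Computes \eqn{\Delta G = R T \ln K_d} (1 M standard state), the standard
#' conversion used to fill the \eqn{\Delta G} column of an ITC results table.
#' Negative for sub-molar dissociation constants.
#'
#' @param kd Dissociation constant in molar. Must be > 0.
#' @param temperature Temperature in kelvin. Default 298.15 K (25 C).
#' @return Free energy of binding in kcal/mol.
#' @examples
#' free_energy_from_kd(6.2e-9)   # approx -11.2 kcal/mol
#' free_energy_from_kd(34e-9)    # approx -10.2 kcal/mol
#' @export
free_energy_from_kd <- function(kd, temperature = T_STANDARD) {
  stop_if_not_positive(kd, "kd")
  stop_if_not_positive(temperature, "temperature")
  R_KCAL * temperature * log(kd)
}

#' Gibbs free energy from its enthalpic and entropic components
#'
#' \eqn{\Delta G = \Delta H + (-T \Delta S)}. Takes the entropic term in the
#' \eqn{-T\Delta S} form in which ITC tables report it, so the decomposition
#' is a plain sum.
#'
#' @param dH Binding enthalpy, kcal/mol.
#' @param minus_TdS Entropic term \eqn{-T\Delta S}, kcal/mol.
#' @return \eqn{\Delta G} in kcal/mol.
#' @examples
#' gibbs_from_components(-12.8, 2.6)  # -10.2
#' @export
gibbs_from_components <- function(dH, minus_TdS) {
  dH + minus_TdS
}

#' Fold change in binding affinity between two ligands
#'
#' Ratio of dissociation constants, `kd_ref / kd_test`; values > 1 mean the
#' test ligand binds more tightly than the reference.
#'
#' @param kd_ref Reference dissociation constant (molar, > 0).
#' @param kd_test Test dissociation constant (molar, > 0).
#' @return Dimensionless affinity fold.
#' @examples
#' fold_affinity(34e-9, 6.2e-9)   # approx 5.5-fold tighter
#' @export
fold_affinity <- function(kd_ref, kd_test) {
  stop_if_not_positive(kd_ref, "kd_ref")
  stop_if_not_positive(kd_test, "kd_test")
  kd_ref / kd_test
}

#' Consistency checks for a table of binding thermodynamics
#'
#' For each row, verifies the Gibbs decomposition
#' \eqn{|\Delta G - (\Delta H + (-T\Delta S))| \le} `tol_sum` and, when a
#' dissociation constant is present, \eqn{|\Delta G - RT\ln K_d| \le}
#' `tol_kd`. The default tolerances absorb one-decimal rounding of the energy
#' columns and two-significant-figure rounding of Kd.
#'
#' @param rows Data frame with columns `dG_kcal`, `dH_kcal`, `minus_TdS_kcal`
#'   and optionally `kd_nM`, `ligand`, `temperature_K`.
#' @param tol_sum Tolerance (kcal/mol) on the \eqn{\Delta H + (-T\Delta S)}
#'   sum check. Default 0.05.
#' @param tol_kd Tolerance (kcal/mol) on the \eqn{RT\ln K_d} check.
#'   Default 0.08.
#' @return Data frame with one row per input row: the absolute deviations
#'   (`dev_sum`, `dev_kd`; the latter `NA` when Kd is absent) and logical
#'   `pass_sum`, `pass_kd`, `pass`.
#' @examples
#' validate_thermo_table(itc_thermo_table())
#' @export
validate_thermo_table <- function(rows, tol_sum = 0.05, tol_kd = 0.08) {
  if (is.null(rows) || nrow(rows) == 0L) {
    return(data.frame(ligand = character(), dev_sum = numeric(),
                      dev_kd = numeric(), pass_sum = logical(),
                      pass_kd = logical(), pass = logical()))
  }
  stopifnot(all(c("dG_kcal", "dH_kcal", "minus_TdS_kcal") %in% names(rows)))
  temp <- if ("temperature_K" %in% names(rows)) rows$temperature_K else T_STANDARD
  dev_sum <- abs(rows$dG_kcal -
                 gibbs_from_components(rows$dH_kcal, rows$minus_TdS_kcal))
  dev_kd <- rep(NA_real_, nrow(rows))
  if ("kd_nM" %in% names(rows)) {
    has_kd <- !is.na(rows$kd_nM)
    dev_kd[has_kd] <- abs(rows$dG_kcal[has_kd] -
      free_energy_from_kd(rows$kd_nM[has_kd] * 1e-9,
                          rep(temp, length.out = nrow(rows))[has_kd]))
  }
  pass_sum <- dev_sum <= tol_sum
  pass_kd <- is.na(dev_kd) | dev_kd <= tol_kd
  data.frame(
    ligand = if ("ligand" %in% names(rows)) rows$ligand else as.character(seq_len(nrow(rows))),
    dev_sum = dev_sum, dev_kd = dev_kd,
    pass_sum = pass_sum, pass_kd = pass_kd,
    pass = pass_sum & pass_kd,
    stringsAsFactors = FALSE
  )
}

#' Read or write a binding-thermodynamics table
#'
#' CSV layout: columns `ligand`, `kd_nM`, `dG_kcal`, `dH_kcal`,
#' `minus_TdS_kcal` and optionally `temperature_K`.
#'
#' @param path File path.
#' @param rows Data frame to write.
#' @return `read_thermo_csv` returns the data frame; `write_thermo_csv`
#'   returns `path` invisibly.
#' @export
read_thermo_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_thermo_csv
#' @export
write_thermo_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
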