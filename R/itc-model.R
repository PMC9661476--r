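# Two-site ligand-binding model for ITC: model/protocol constructors,
# binding polynomial, mass-balance equilibrium solver and thermogram
# forward simulation.
#
# The TTR tetramer carries two thyroxine-binding sites. Binding is described
# by macroscopic stepwise association constants K1, K2 (M^-1) with the
# binding polynomial Z = 1 + K1 L + K1 K2 L^2. For two identical independent
# sites with microscopic association constant k the statistical factors give
# K1 = 2k, K2 = k/2, and the stepwise enthalpies coincide (dH1 = dH2); the
# cooperativity index c = 4 K2 / K1 is then exactly 1, with c < 1 indicating
# negative cooperativity.

#' Construct a two-site binding model
#'
#' @param K1,K2 Macroscopic stepwise association constants, M^-1 (> 0).
#' @param dH1,dH2 Stepwise binding enthalpies, kcal/mol.
#' @param mode `"cooperative"` or `"noncooperative"`. In noncooperative mode
#'   the statistical-factor identity `K1 = 4*K2` and `dH1 = dH2` must hold
#'   (use [two_site_noncooperative()] to build such a model from a
#'   microscopic Kd).
#' @param n_active Active protein fraction (default 1).
#' @param q_dil Per-injection dilution heat offset, kcal per mol of
#'   injectant (default 0).
#' @return Object of class `two_site_model`.
#' @examples
#' m <- two_site_noncooperative(kd_micro = 34e-9, dH = -12.8)
#' cooperativity_index(m)  # 1
#' @export
two_site_model <- function(K1, K2, dH1, dH2,
                           mode = c("cooperative", "noncooperative"),
                           n_active = 1, q_dil = 0) {
  mode <- match.arg(mode)
  stop_if_not_positive(K1, "K1")
  stop_if_not_positive(K2, "K2")
  stop_if_not_positive(n_active, "n_active")
  if (mode == "noncooperative") {
    if (abs(K1 / (4 * K2) - 1) > 1e-8 || abs(dH1 - dH2) > 1e-10)
      stop("noncooperative mode requires K1 = 4*K2 and dH1 = dH2",
           call. = FALSE)
  }
  structure(list(K1 = K1, K2 = K2, dH1 = dH1, dH2 = dH2, mode = mode,
                 n_active = n_active, q_dil = q_dil),
            class = "two_site_model")
}

#' @rdname two_site_model
#' @param kd_micro Microscopic (per-site) dissociation constant, molar.
#' @param dH Per-site binding enthalpy, kcal/mol.
#' @export
two_site_noncooperative <- function(kd_micro, dH, n_active = 1, q_dil = 0) {
  stop_if_not_positive(kd_micro, "kd_micro")
  k <- 1 / kd_micro
  two_site_model(K1 = 2 * k, K2 = k / 2, dH1 = dH, dH2 = dH,
                 mode = "noncooperative", n_active = n_active, q_dil = q_dil)
}

#' @rdname two_site_model
#' @param kd1,kd2 Per-site stepwise dissociation constants (molar) for a
#'   cooperative model, in the convention ITC results tables report them:
#'   the statistical factors are applied on conversion, `K1 = 2/kd1`,
#'   `K2 = 1/(2 kd2)`, so the cooperativity index reduces to
#'   `c = kd1/kd2` and `kd1 = kd2` recovers the noncooperative identity.
#' @export
two_site_cooperative <- function(kd1, kd2, dH1, dH2, n_active = 1, q_dil = 0) {
  stop_if_not_positive(kd1, "kd1")
  stop_if_not_positive(kd2, "kd2")
  two_site_model(K1 = 2 / kd1, K2 = 1 / (2 * kd2), dH1 = dH1, dH2 = dH2,
                 mode = "cooperative", n_active = n_active, q_dil = q_dil)
}

#' @export
print.two_site_model <- function(x, ...) {
  cat("Two-site binding model (", x$mode, ")\n", sep = "")
  cat(sprintf("  K1 = %.4g M^-1 (per-site Kd1 = %.4g nM), dH1 = %.3g kcal/mol\n",
              x$K1, 2e9 / x$K1, x$dH1))
  cat(sprintf("  K2 = %.4g M^-1 (per-site Kd2 = %.4g nM), dH2 = %.3g kcal/mol\n",
              x$K2, 1e9 / (2 * x$K2), x$dH2))
  cat(sprintf("  cooperativity index c = %.4g\n", cooperativity_index(x)))
  if (x$n_active != 1) cat(sprintf("  n_active = %.3g\n", x$n_active))
  if (x$q_dil != 0) cat(sprintf("  q_dil = %.3g kcal/mol\n", x$q_dil))
  invisible(x)
}

#' Cooperativity index of a two-site model
#'
#' \eqn{c = 4 K_2 / K_1}: exactly 1 for two identical independent sites,
#' below 1 for negative cooperativity (second site binds more weakly once
#' the first is occupied), above 1 for positive cooperativity.
#'
#' @param model A [two_site_model()].
#' @return Dimensionless cooperativity index.
#' @export
cooperativity_index <- function(model) {
  stopifnot(inherits(model, "two_site_model"))
  4 * model$K2 / model$K1
}

#' Binding polynomial and ligation-state populations
#'
#' Evaluates the partition function over ligation states,
#' \eqn{Z = 1 + K_1 L + K_1 K_2 L^2}, at a free-ligand concentration, and the
#' fractions of protein with 0, 1 and 2 ligands bound.
#'
#' @param L_free Free ligand concentration, molar (>= 0). Vectorized.
#' @param model A [two_site_model()].
#' @return Data frame with columns `L_free`, `Z`, `F0`, `F1`, `F2` and the
#'   average ligation number `nu = F1 + 2 F2`.
#' @examples
#' m <- two_site_noncooperative(34e-9, -12.8)
#' binding_polynomial(34e-9, m)$nu  # 1: each site half-occupied at L = Kd
#' @export
binding_polynomial <- function(L_free, model) {
  stopifnot(inherits(model, "two_site_model"))
  if (any(!is.finite(L_free)) || any(L_free < 0))
    stop("`L_free` must be finite and >= 0", call. = FALSE)
  K1 <- model$K1; K2 <- model$K2
  Z <- 1 + K1 * L_free + K1 * K2 * L_free^2
  F1 <- K1 * L_free / Z
  F2 <- K1 * K2 * L_free^2 / Z
  data.frame(L_free = L_free, Z = Z, F0 = 1 / Z, F1 = F1, F2 = F2,
             nu = F1 + 2 * F2)
}

# Scalar core of the mass-balance solve: returns c(L_free, F0, F1, F2, nu)
# without any data-frame overhead (hot path for thermogram simulation and
# fitting).
solve_free_ligand_core <- function(L_total, P, K1, K2, tol = 1e-14) {
  if (L_total == 0 || P == 0) {
    L <- L_total
    Z <- 1 + K1 * L + K1 * K2 * L^2
    F1 <- K1 * L / Z; F2 <- K1 * K2 * L^2 / Z
    return(c(L, 1 / Z, F1, F2, F1 + 2 * F2))
  }
  # Convergence demands both a tight bracket relative to the root itself
  # (so tiny free-ligand concentrations are resolved) and a mass-balance
  # residual far below 1e-10 relative; all residual terms are bounded by
  # L_total, so the floating-point floor is ~1e-15 * L_total.
  lo <- 0; hi <- L_total
  x <- L_total / 2
  for (iter in 1:2000) {
    Z <- 1 + K1 * x + K1 * K2 * x^2
    bound <- (K1 * x + 2 * K1 * K2 * x^2) / Z
    gx <- x + P * bound - L_total
    if (gx > 0) hi <- x else lo <- x
    if (abs(gx) <= tol * 100 * L_total &&
        (hi - lo) <= tol * 100 * max(x, .Machine$double.xmin)) break
    dZ <- K1 + 2 * K1 * K2 * x
    dnu <- ((K1 + 4 * K1 * K2 * x) * Z -
            (K1 * x + 2 * K1 * K2 * x^2) * dZ) / Z^2
    xn <- x - gx / (1 + P * dnu)
    x <- if (is.finite(xn) && xn > lo && xn < hi) xn else (lo + hi) / 2
  }
  Z <- 1 + K1 * x + K1 * K2 * x^2
  F1 <- K1 * x / Z; F2 <- K1 * K2 * x^2 / Z
  c(x, 1 / Z, F1, F2, F1 + 2 * F2)
}

#' Solve the free-ligand mass balance
#'
#' Finds the unique free ligand concentration satisfying
#' \eqn{L_{tot} = L + P_{tot}\,\nu(L)} with
#' \eqn{\nu(L) = (K_1 L + 2 K_1 K_2 L^2)/Z}, by safeguarded bisection/Newton
#' on the (monotone) mass-balance residual over \eqn{[0, L_{tot}]}.
#'
#' @param L_total Total ligand concentration, molar (>= 0).
#' @param P_total Total binding-competent protein concentration, molar
#'   (>= 0).
#' @param model A [two_site_model()]. `n_active` scales `P_total`.
#' @param tol Relative convergence tolerance on the bracket width
#'   (default 1e-14; residual mass balance is then far below 1e-10 relative).
#' @return One-row data frame: `L_free`, `F0`, `F1`, `F2`, `nu`, `Z`.
#' @export
solve_free_ligand <- function(L_total, P_total, model, tol = 1e-14) {
  stopifnot(inherits(model, "two_site_model"))
  if (!is.finite(L_total) || L_total < 0) stop("`L_total` must be >= 0", call. = FALSE)
  if (!is.finite(P_total) || P_total < 0) stop("`P_total` must be >= 0", call. = FALSE)
  P <- P_total * model$n_active
  s <- solve_free_ligand_core(L_total, P, model$K1, model$K2, tol)
  occ <- binding_polynomial(s[1L], model)
  data.frame(L_total = L_total, P_total = P_total, L_free = s[1L],
             Z = occ$Z, F0 = occ$F0, F1 = occ$F1, F2 = occ$F2, nu = occ$nu)
}

#' Define an ITC titration protocol
#'
#' Defaults reproduce the experimental design used throughout: a 100 uM
#' ligand syringe titrated into a 200 uL cell containing 5 uM TTR at 25 C,
#' in 2 uL injections. Nineteen injections carry the molar ratio past
#' saturation of both sites.
#'
#' @param cell_volume_uL Calorimeter cell volume, microliters.
#' @param cell_conc_uM Protein concentration in the cell, micromolar.
#' @param syringe_conc_uM Ligand concentration in the syringe, micromolar.
#' @param injection_volumes_uL Vector of injection volumes, microliters.
#' @param temperature_C Temperature, Celsius.
#' @return Object of class `titration_protocol` (volumes in liters,
#'   concentrations molar, temperature kelvin).
#' @export
titration_protocol <- function(cell_volume_uL = 200,
                               cell_conc_uM = 5,
                               syringe_conc_uM = 100,
                               injection_volumes_uL = rep(2, 19),
                               temperature_C = 25) {
  stop_if_not_positive(cell_volume_uL, "cell_volume_uL")
  stop_if_not_positive(cell_conc_uM, "cell_conc_uM")
  stop_if_not_positive(syringe_conc_uM, "syringe_conc_uM")
  stop_if_not_positive(injection_volumes_uL, "injection_volumes_uL")
  structure(list(
    cell_volume = cell_volume_uL * 1e-6,
    cell_conc = cell_conc_uM * 1e-6,
    syringe_conc = syringe_conc_uM * 1e-6,
    injection_volumes = injection_volumes_uL * 1e-6,
    temperature = temperature_C + 273.15
  ), class = "titration_protocol")
}

# Per-injection total concentrations in the cell under the instantaneous
# displacement convention: injecting dV first dilutes the cell contents by
# (1 - dV/V0), then the injected ligand mixes in.
injection_concentrations <- function(protocol) {
  V0 <- protocol$cell_volume
  n <- length(protocol$injection_volumes)
  P <- numeric(n); L <- numeric(n)
  p <- protocol$cell_conc; l <- 0
  for (i in seq_len(n)) {
    f <- 1 - protocol$injection_volumes[i] / V0
    p <- p * f
    l <- l * f + protocol$syringe_conc * protocol$injection_volumes[i] / V0
    P[i] <- p; L[i] <- l
  }
  data.frame(injection = seq_len(n), P_total = P, L_total = L,
             molar_ratio = L / P)
}

#' Simulate an ITC thermogram under the two-site model
#'
#' Forward model for the integrated per-injection heats. After each
#' injection the cell totals are updated by the instantaneous-displacement
#' convention, the binding equilibrium is re-solved, and the cumulative
#' binding heat \eqn{Q_i = V_0 P_i (F_1 \Delta H_1 + F_2 (\Delta H_1 +
#' \Delta H_2))} is differenced with a displaced-volume correction
#' \eqn{q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2}, normalized per
#' mole of injected ligand, plus the dilution offset `q_dil`.
#'
#' @param model A [two_site_model()].
#' @param protocol A [titration_protocol()].
#' @return Data frame of class `thermogram`: `injection`,
#'   `injection_volume_uL`, `molar_ratio`, `heat_kcal_per_mol`, plus the
#'   equilibrium bookkeeping columns `L_free` and `nu`.
#' @examples
#' m <- two_site_noncooperative(6.2e-9, -16.6)
#' tg <- simulate_thermogram(m, titration_protocol())
#' head(tg)
#' @export
simulate_thermogram <- function(model, protocol) {
  stopifnot(inherits(model, "two_site_model"),
            inherits(protocol, "titration_protocol"))
  conc <- injection_concentrations(protocol)
  V0 <- protocol$cell_volume
  n <- nrow(conc)
  Q <- numeric(n); L_free <- numeric(n); nu <- numeric(n)
  K1 <- model$K1; K2 <- model$K2
  for (i in seq_len(n)) {
    eq <- solve_free_ligand_core(conc$L_total[i],
                                 conc$P_total[i] * model$n_active, K1, K2)
    L_free[i] <- eq[1L]; nu[i] <- eq[5L]
    Q[i] <- V0 * conc$P_total[i] * model$n_active *
      (eq[3L] * model$dH1 + eq[4L] * (model$dH1 + model$dH2))
  }
  Qprev <- c(0, Q[-n])
  dV <- protocol$injection_volumes
  moles_injected <- protocol$syringe_conc * dV
  q <- (Q - Qprev + (dV / V0) * (Q + Qprev) / 2) / moles_injected + model$q_dil
  out <- data.frame(
    injection = conc$injection,
    injection_volume_uL = dV * 1e6,
    molar_ratio = conc$molar_ratio,
    heat_kcal_per_mol = q,
    L_free = L_free,
    nu = nu
  )
  class(out) <- c("thermogram", "data.frame")
  out
}

#' Read or write a thermogram CSV
#'
#' Layout: `injection`, `injection_volume_uL`, `heat_kcal_per_mol` and
#' optionally `molar_ratio` (recomputed from the protocol when fitting).
#'
#' @param path File path.
#' @param thermogram Data frame as produced by [simulate_thermogram()].
#' @return `read_thermogram_csv` returns the data frame;
#'   `write_thermogram_csv` returns `path` invisibly.
#' @export
read_thermogram_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("injection", "injection_volume_uL",
                  "heat_kcal_per_mol") %in% names(out)))
  class(out) <- c("thermogram", "data.frame")
  out
}

#' @rdname read_thermogram_csv
#' @export
write_thermogram_csv <- function(thermogram, path) {
  utils::write.csv(as.data.frame(thermogram), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a titration protocol from YAML
#'
#' Keys: `cell_volume_uL`, `cell_conc_uM`, `syringe_conc_uM`,
#' `injection_volume_uL`, `n_injections`, `temperature_C`.
#'
#' @param path YAML file path.
#' @return A [titration_protocol()].
#' @export
read_protocol_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read protocol files", call. = FALSE)
  y <- yaml::read_yaml(path)
  titration_protocol(
    cell_volume_uL = y$cell_volume_uL %||% 200,
    cell_conc_uM = y$cell_conc_uM %||% 5,
    syringe_conc_uM = y$syringe_conc_uM %||% 100,
    injection_volumes_uL = rep(y$injection_volume_uL %||% 2,
                               y$n_injections %||% 19),
    temperature_C = y$temperature_C %||% 25
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
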