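# Post-processing of MD-derived energetics: gas-phase binding-energy
# bookkeeping, ligand ranking, contact-frequency statistics with
# element-dependent cutoffs, and trajectory frame sampling.

#' Gas-phase interaction energy of a 2:1 ligand-protein complex
#'
#' \eqn{\Delta E_{gp} = E_{TTR} + 2 E_L - E_{TTR\cdot 2L}}: the
#' ensemble-mean receptor and (doubled) ligand energies minus the complex
#' energy. Positive values mean the complex is lower in energy than its
#' separated parts.
#'
#' @param E_TTR Ensemble-mean receptor energy, kcal/mol.
#' @param E_L Ensemble-mean ligand energy, kcal/mol.
#' @param E_TTR2L Ensemble-mean energy of the complex with two ligands
#'   bound, kcal/mol.
#' @return \eqn{\Delta E_{gp}} in kcal/mol.
#' @export
gas_phase_energy <- function(E_TTR, E_L, E_TTR2L) {
  E_TTR + 2 * E_L - E_TTR2L
}

#' Predicted binding energy from gas-phase and solvation components
#'
#' \eqn{\Delta G_{bind} = \Delta E_{gp} + 2 \Delta G_{L\mathchar`-solv}}:
#' the gas-phase interaction energy corrected by the desolvation of the two
#' bound ligands (complex and free receptor are assumed to have equal
#' solvation energies). Note the sign convention: larger positive values
#' indicate stronger predicted binding, opposite to the negative
#' \eqn{\Delta G} convention of the ITC tables.
#'
#' @param dE_gp Gas-phase interaction energy, kcal/mol (see
#'   [gas_phase_energy()]).
#' @param dG_Lsolv Ligand solvation free energy, kcal/mol (typically
#'   negative; counted twice, once per bound ligand).
#' @return Predicted binding energy in kcal/mol.
#' @examples
#' binding_energy(81.5, -10.9)   # 59.7, tolcapone
#' binding_energy(116.2, -15.9)  # 84.4, M-23
#' @export
binding_energy <- function(dE_gp, dG_Lsolv) {
  dE_gp + 2 * dG_Lsolv
}

#' Rank ligands by predicted binding energy
#'
#' Computes \eqn{\Delta G_{bind}} for each ligand from its components and
#' orders descending (strongest predicted binder first); ties are broken
#' lexicographically by ligand name for a deterministic ordering.
#'
#' @param components Data frame with columns `ligand`, `dE_gp`, `dG_Lsolv`
#'   (or precomputed `dG_bind`).
#' @return The input with a `dG_bind` column added, ordered by decreasing
#'   `dG_bind`, with a `rank` column.
#' @examples
#' rank_ligands(md_energy_table())
#' @export
rank_ligands <- function(components) {
  stopifnot(is.data.frame(components), nrow(components) >= 1L,
            "ligand" %in% names(components))
  if (!"dG_bind" %in% names(components)) {
    stopifnot(all(c("dE_gp", "dG_Lsolv") %in% names(components)))
    components$dG_bind <- binding_energy(components$dE_gp,
                                         components$dG_Lsolv)
  }
  ord <- order(-components$dG_bind, components$ligand)
  out <- components[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Contact frequency and distances for a donor-acceptor series
#'
#' A frame is in contact when the heavy-atom donor-acceptor distance is at
#' or below the cutoff. The cutoff is element-dependent: 3.0 A by default
#' (hydrogen bonds, distance-only criterion) and 3.5 A when the contact
#' partner is chlorine (halogen bonds). Mean distance is taken over contact
#' frames by default.
#'
#' @param distances Per-frame donor-acceptor distances, Angstrom (> 0).
#' @param partner_element Element symbol of the (non-hydrogen) ligand
#'   contact partner, e.g. `"O"` or `"Cl"`. Scalar.
#' @param cutoff Hydrogen-bond cutoff in Angstrom (default 3.0).
#' @param cl_cutoff Cutoff applied when `partner_element == "Cl"`
#'   (default 3.5).
#' @param mean_over `"contact"` (default) averages the distance over frames
#'   in contact; `"all"` averages over every frame.
#' @return List: `frequency` (percent of frames in contact),
#'   `min_distance`, `mean_distance` (NA when no frame is in contact and
#'   `mean_over = "contact"`), `cutoff_used`, `n_frames`.
#' @examples
#' contact_frequency(c(2.5, 2.9, 3.1, 3.4, 4.0), "O")$frequency   # 40
#' contact_frequency(c(2.5, 2.9, 3.1, 3.4, 4.0), "Cl")$frequency  # 80
#' @export
contact_frequency <- function(distances, partner_element = "O",
                              cutoff = 3.0, cl_cutoff = 3.5,
                              mean_over = c("contact", "all")) {
  mean_over <- match.arg(mean_over)
  if (length(distances) == 0L)
    stop("empty distance series", call. = FALSE)
  stop_if_not_positive(distances, "distances")
  stopifnot(length(partner_element) == 1L)
  cut_used <- if (identical(partner_element, "Cl")) cl_cutoff else cutoff
  in_contact <- distances <= cut_used
  freq <- 100 * sum(in_contact) / length(distances)
  mean_d <- if (mean_over == "contact") {
    if (any(in_contact)) mean(distances[in_contact]) else NA_real_
  } else mean(distances)
  list(frequency = freq,
       min_distance = min(distances),
       mean_distance = mean_d,
       cutoff_used = cut_used,
       n_frames = length(distances))
}

#' Summarize a contact-series table
#'
#' Applies [contact_frequency()] to each donor/acceptor pair of a long-form
#' contact table.
#'
#' @param series Data frame with columns `time_ns`, `distance_A`, `donor`,
#'   `acceptor`, `partner_element`.
#' @inheritParams contact_frequency
#' @return Data frame with one row per (donor, acceptor) pair: `frequency`,
#'   `min_distance`, `mean_distance`, `cutoff_used`, `n_frames`.
#' @export
summarize_contacts <- function(series, cutoff = 3.0, cl_cutoff = 3.5,
                               mean_over = c("contact", "all")) {
  mean_over <- match.arg(mean_over)
  stopifnot(all(c("distance_A", "donor", "acceptor",
                  "partner_element") %in% names(series)))
  key <- interaction(series$donor, series$acceptor, drop = TRUE)
  parts <- split(series, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    s <- contact_frequency(p$distance_A, p$partner_element[1L],
                           cutoff = cutoff, cl_cutoff = cl_cutoff,
                           mean_over = mean_over)
    data.frame(donor = p$donor[1L], acceptor = p$acceptor[1L],
               partner_element = p$partner_element[1L],
               frequency = s$frequency, min_distance = s$min_distance,
               mean_distance = s$mean_distance,
               cutoff_used = s$cutoff_used, n_frames = s$n_frames,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Evenly sample frame times from the tail of a trajectory
#'
#' Returns `n_frames` times evenly spaced over the last `window_ns` of a
#' `total_ns` trajectory, sampling at the end of each stride interval so
#' the final frame is always included: \eqn{t_i = T - W + i\,W/n}.
#'
#' @param total_ns Total trajectory length, ns.
#' @param window_ns Sampling window at the end of the trajectory, ns
#'   (<= `total_ns`).
#' @param n_frames Number of frames to sample (>= 1).
#' @return Strictly increasing numeric vector of length `n_frames` ending
#'   at `total_ns`.
#' @examples
#' sample_frames(150, 140, 140)  # 11, 12, ..., 150 (1 ns stride)
#' @export
sample_frames <- function(total_ns, window_ns, n_frames) {
  stop_if_not_positive(total_ns, "total_ns")
  stop_if_not_positive(window_ns, "window_ns")
  stopifnot(n_frames >= 1L)
  if (window_ns > total_ns)
    stop("`window_ns` must not exceed `total_ns`", call. = FALSE)
  stride <- window_ns / n_frames
  total_ns - window_ns + seq_len(n_frames) * stride
}

#' Read or write a contact-series CSV
#'
#' Layout: `time_ns`, `distance_A`, `donor`, `acceptor`, `partner_element`.
#'
#' @param path File path.
#' @param series Data frame to write.
#' @return The data frame, or `path` invisibly for the writer.
#' @export
read_contact_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time_ns", "distance_A", "donor", "acceptor",
                  "partner_element") %in% names(out)))
  out
}

#' @rdname read_contact_csv
#' @export
write_contact_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Annotate an energy-components table with binding energies
#'
#' Adds `dE_gp` (when raw ensemble means are given) and `dG_bind` columns
#' to a per-ligand component table, the layout consumed by
#' [rank_ligands()].
#'
#' @param components Data frame with `ligand`, `dG_Lsolv` and either
#'   `dE_gp` or the raw columns `E_TTR`, `E_L`, `E_TTR2L`.
#' @return The table with `dE_gp` and `dG_bind` filled in.
#' @export
annotate_binding_energies <- function(components) {
  stopifnot(is.data.frame(components),
            all(c("ligand", "dG_Lsolv") %in% names(components)))
  if (!"dE_gp" %in% names(components)) {
    stopifnot(all(c("E_TTR", "E_L", "E_TTR2L") %in% names(components)))
    components$dE_gp <- gas_phase_energy(components$E_TTR, components$E_L,
                                         components$E_TTR2L)
  }
  components$dG_bind <- binding_energy(components$dE_gp,
                                       components$dG_Lsolv)
  components
}
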