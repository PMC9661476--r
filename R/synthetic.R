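# Seeded synthetic-data generators. Each generator emulates the statistical
# structure of one assay's input so the full analysis chain is testable
# without instrument data, and each is a bit-reproducible function of
# (parameters, seed) with no RNG state leaking to the caller.

#' Generate a noisy ITC thermogram
#'
#' Forward-simulates the two-site model under a titration protocol and adds
#' i.i.d. Gaussian noise to the per-injection heats.
#'
#' @param model A [two_site_model()].
#' @param protocol A [titration_protocol()].
#' @param noise_sd Noise standard deviation, kcal per mol of injectant
#'   (>= 0).
#' @param seed Integer seed.
#' @param path Optional CSV output path (see [write_thermogram_csv()]).
#' @return The thermogram data frame (invisibly written to `path` when
#'   given).
#' @export
gen_thermogram <- function(model, protocol, noise_sd = 0, seed = 1,
                           path = NULL) {
  stopifnot(noise_sd >= 0)
  tg <- simulate_thermogram(model, protocol)
  if (noise_sd > 0) {
    tg$heat_kcal_per_mol <- tg$heat_kcal_per_mol +
      with_seed(seed, stats::rnorm(nrow(tg), 0, noise_sd))
  }
  if (!is.null(path)) write_thermogram_csv(tg, path)
  tg
}

#' Generate a contact-distance time series with a target frequency
#'
#' Each frame is in contact with probability `target_freq/100`; contact
#' frames draw a distance uniformly from `(cutoff - 0.5, cutoff)` and
#' non-contact frames from `(cutoff, cutoff + 2)`, so the realized
#' frequency is binomial around the target.
#'
#' @param target_freq Target contact frequency, percent (0-100).
#' @param cutoff Contact cutoff in Angstrom used to place the two distance
#'   bands (default 3.0).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param donor,acceptor,partner_element Atom labels copied into the
#'   output.
#' @param dt_ns Frame spacing, ns (default 1).
#' @param path Optional CSV output path.
#' @return Contact-series data frame (`time_ns`, `distance_A`, `donor`,
#'   `acceptor`, `partner_element`).
#' @export
gen_contact_series <- function(target_freq, cutoff = 3.0, n_frames = 1000,
                               seed = 1, donor = "LIG@O1",
                               acceptor = "T119@OG1",
                               partner_element = "O", dt_ns = 1,
                               path = NULL) {
  stopifnot(target_freq >= 0, target_freq <= 100, n_frames >= 1)
  dists <- with_seed(seed, {
    contact <- stats::runif(n_frames) < target_freq / 100
    ifelse(contact,
           stats::runif(n_frames, cutoff - 0.5, cutoff),
           stats::runif(n_frames, cutoff, cutoff + 2))
  })
  out <- data.frame(
    time_ns = seq_len(n_frames) * dt_ns,
    distance_A = dists,
    donor = donor, acceptor = acceptor,
    partner_element = partner_element,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_contact_csv(out, path)
  out
}

#' Build a toy TTR tetramer frame with prescribed interface distances
#'
#' Deterministically places a Ser117 OG atom in each of chains A-D and two
#' ligand carbonyl carbons (HETATM, residue `LIG`, atom `C7`) so that the
#' (A, C) and (B, D) Ser117 O-O distances and the inter-ligand
#' carbonyl-carbon distance equal the requested values exactly. A backbone
#' CA atom per chain is included so the frame is a well-formed (if
#' minimal) PDB model.
#'
#' @param ser117_AC,ser117_BD Ser117 O-O distances for the two subunit
#'   pairs, Angstrom (> 0).
#' @param ligand_depth Inter-ligand carbonyl-carbon distance, Angstrom
#'   (> 0).
#' @param path Optional PDB output path (see [write_structure_pdb()]).
#' @return A [structure_frame()].
#' @examples
#' fr <- gen_toy_tetramer(5.5, 5.4, 15.8)
#' ser117_oo_distances(fr)     # 5.5, 5.4
#' interligand_depth(fr)       # 15.8
#' @export
gen_toy_tetramer <- function(ser117_AC, ser117_BD, ligand_depth,
                             path = NULL) {
  stop_if_not_positive(ser117_AC, "ser117_AC")
  stop_if_not_positive(ser117_BD, "ser117_BD")
  stop_if_not_positive(ligand_depth, "ligand_depth")
  og <- rbind(
    A = c(0, 0, 0),
    B = c(0, 10, 0),
    C = c(ser117_AC, 0, 0),
    D = c(ser117_BD, 10, 0)
  )
  lig <- rbind(c(0, -10, 0), c(ligand_depth, -10, 0))
  atoms <- data.frame(
    atom_name = c(rep(c("CA", "OG"), 4L), "C7", "C7"),
    residue_name = c(rep("SER", 8L), "LIG", "LIG"),
    residue_number = c(rep(117L, 8L), 201L, 202L),
    chain_id = c(rep(c("A", "B", "C", "D"), each = 2L), "E", "F"),
    x = c(as.vector(rbind(og[, 1] + 1, og[, 1])), lig[, 1]),
    y = c(as.vector(rbind(og[, 2], og[, 2])), lig[, 2]),
    z = c(as.vector(rbind(og[, 3] + 1, og[, 3])), lig[, 3]),
    record = c(rep("ATOM", 8L), "HETATM", "HETATM"),
    stringsAsFactors = FALSE
  )
  fr <- structure_frame(atoms)
  if (!is.null(path)) write_structure_pdb(fr, path)
  fr
}

#' Generate a mono-exponential unfolding time course
#'
#' \eqn{f(t) = plateau (1 - e^{-kt})} mapped back to a 355/335
#' fluorescence ratio through the declared folded/unfolded reference
#' ratios, plus Gaussian noise on the ratio.
#'
#' @param k Dissociation rate, 1/h (>= 0).
#' @param plateau Asymptotic unfolded fraction in \[0, 1\].
#' @param times Time points, hours.
#' @param noise_sd Ratio noise standard deviation (default 0).
#' @param seed Integer seed.
#' @param ref_folded,ref_unfolded Reference 355/335 ratios for fully
#'   folded/unfolded protein.
#' @param path Optional CSV output path (layout of
#'   [read_unfolding_csv()]).
#' @return List with `times`, `ratio`, `ref_folded`, `ref_unfolded` and
#'   the noiseless `fraction`.
#' @export
gen_unfolding <- function(k, plateau, times = seq(0, 96, by = 2),
                          noise_sd = 0, seed = 1,
                          ref_folded = 0.55, ref_unfolded = 1.45,
                          path = NULL) {
  stopifnot(k >= 0, plateau >= 0, plateau <= 1, noise_sd >= 0,
            ref_unfolded > ref_folded)
  f <- plateau * (1 - exp(-k * times))
  ratio <- ref_folded + f * (ref_unfolded - ref_folded)
  if (noise_sd > 0)
    ratio <- ratio + with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# ref_folded=%.10g", ref_folded),
                 sprintf("# ref_unfolded=%.10g", ref_unfolded)), con)
    utils::write.csv(data.frame(time_h = times, ratio_355_335 = ratio),
                     con, row.names = FALSE, quote = FALSE)
  }
  list(times = times, ratio = ratio, ref_folded = ref_folded,
       ref_unfolded = ref_unfolded, fraction = f)
}

#' Generate an occupancy-driven aggregation dose-response table
#'
#' Fixture logic linking ligand binding to aggregation: the
#' aggregation-competent species is taken to be the fully unliganded
#' tetramer, so the noiseless aggregation percentage at each total
#' compound concentration is `max_agg_pct` times the equilibrium fraction
#' F0 of TTR with zero ligands bound (from the two-site model). The
#' percentages are converted to turbidity readings with a dose-dependent
#' compound blank, matching the layout consumed by
#' [annotate_aggregation()].
#'
#' @param model A [two_site_model()] for the compound.
#' @param ttr_uM TTR tetramer concentration in the assay, micromolar.
#' @param conc_grid_uM Total compound concentrations, micromolar (>= 0).
#' @param max_agg_pct Aggregation of the compound-free control, percent.
#' @param noise_sd Turbidity noise standard deviation (default 0).
#' @param seed Integer seed.
#' @param compound Compound label.
#' @param path Optional CSV output path.
#' @return Data frame: `compound`, `conc_uM`, `a340_sample`,
#'   `a340_compound_blank`, `a340_control`, `a340_buffer_blank`,
#'   `true_aggregation_pct`.
#' @export
gen_aggregation_response <- function(model, ttr_uM = 3.6,
                                     conc_grid_uM = c(0, 1.25, 2.5, 5, 10, 20, 40),
                                     max_agg_pct = 100, noise_sd = 0,
                                     seed = 1, compound = "compound",
                                     path = NULL) {
  stopifnot(all(conc_grid_uM >= 0), noise_sd >= 0)
  F0 <- vapply(conc_grid_uM * 1e-6, function(L)
    solve_free_ligand(L, ttr_uM * 1e-6, model)$F0, numeric(1))
  agg <- max_agg_pct * F0
  a340_buffer <- 0.010
  a340_control <- 0.850
  a340_cblank <- a340_buffer + 0.002 * conc_grid_uM
  a340_sample <- a340_cblank + (agg / 100) * (a340_control - a340_buffer)
  if (noise_sd > 0)
    a340_sample <- pmax(a340_sample +
      with_seed(seed, stats::rnorm(length(agg), 0, noise_sd)), 0)
  out <- data.frame(
    compound = compound, conc_uM = conc_grid_uM,
    a340_sample = a340_sample, a340_compound_blank = a340_cblank,
    a340_control = a340_control, a340_buffer_blank = a340_buffer,
    true_aggregation_pct = agg,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE,
                                       quote = FALSE)
  out
}

#' Generate paired IEF densitometry lanes
#'
#' For each donor, a control lane with tetramer ratio `baseline_ratio` and
#' a treated lane with ratio `baseline_ratio * (1 + effect_pct/100)`, plus
#' Gaussian noise on the ratios, converted to band intensities on a
#' fixed total of 100. Ratios driven outside (0, 1] are clipped with a
#' warning.
#'
#' @param effect_pct True stabilization percentage.
#' @param baseline_ratio Control tetramer ratio in (0, 1).
#' @param n_donors Number of donors (paired lanes).
#' @param noise_sd Ratio noise standard deviation (default 0).
#' @param seed Integer seed.
#' @param compound Compound label copied into the output.
#' @param path Optional CSV output path.
#' @return Data frame: `donor`, `condition`, `compound`,
#'   `tetramer_intensity`, `monomer_intensity`.
#' @export
gen_densitometry <- function(effect_pct, baseline_ratio = 0.6,
                             n_donors = 6, noise_sd = 0, seed = 1,
                             compound = "compound", path = NULL) {
  stopifnot(baseline_ratio > 0, baseline_ratio < 1, n_donors >= 1,
            noise_sd >= 0)
  ratios <- with_seed(seed, {
    ctrl <- baseline_ratio + stats::rnorm(n_donors, 0, noise_sd)
    trt <- ctrl * (1 + effect_pct / 100) +
      stats::rnorm(n_donors, 0, noise_sd)
    list(ctrl = ctrl, trt = trt)
  })
  clip <- function(r) {
    if (any(r <= 0) || any(r > 1)) {
      warning("generated tetramer ratios clipped to (0, 1]")
      r <- pmin(pmax(r, 1e-6), 1)
    }
    r
  }
  ctrl <- clip(ratios$ctrl); trt <- clip(ratios$trt)
  total <- 100
  out <- data.frame(
    donor = rep(sprintf("donor%02d", seq_len(n_donors)), each = 2L),
    condition = rep(c("control", "treated"), n_donors),
    compound = compound,
    tetramer_intensity = as.vector(rbind(ctrl, trt)) * total,
    monomer_intensity = (1 - as.vector(rbind(ctrl, trt))) * total,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE,
                                       quote = FALSE)
  out
}
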