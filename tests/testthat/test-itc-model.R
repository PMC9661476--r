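test_that("binding polynomial limits and identical-site algebra", {
  m <- two_site_noncooperative(34e-9, -12.8)
  at0 <- binding_polynomial(0, m)
  expect_identical(at0$Z, 1)
  expect_identical(at0$F0, 1)
  expect_identical(at0$nu, 0)
  # saturation limit
  sat <- binding_polynomial(1, m)
  expect_gt(sat$F2, 1 - 1e-6)
  expect_equal(sat$nu, 2, tolerance = 1e-6)
  # at L = micro Kd each identical site is half occupied, nu = 1
  half <- binding_polynomial(34e-9, m)
  expect_equal(half$nu, 1, tolerance = 1e-12)
  expect_error(binding_polynomial(-1e-9, m), "L_free")
})

test_that("binding polynomial matches microstate enumeration oracle", {
  set.seed(11)
  for (i in 1:50) {
    kd <- 10^stats::runif(1, -10, -6)
    L <- 10^stats::runif(1, -10, -5)
    m <- two_site_noncooperative(kd, -10)
    got <- binding_polynomial(L, m)
    want <- oracle_identical_sites(L, 1 / kd)
    expect_equal(got$Z, want$Z, tolerance = 1e-12)
    expect_equal(got$F1, want$F1, tolerance = 1e-12)
    expect_equal(got$F2, want$F2, tolerance = 1e-12)
    expect_equal(got$nu / 2, want$per_site, tolerance = 1e-12)
  }
})

test_that("noncooperative constructor enforces the statistical-factor identity", {
  m <- two_site_noncooperative(1e-8, -10)
  expect_equal(m$K1, 2e8, tolerance = 1e-12)
  expect_equal(m$K2, 0.5e8, tolerance = 1e-12)
  expect_identical(cooperativity_index(m), 1)
  expect_error(two_site_model(1e8, 1e8, -10, -10, mode = "noncooperative"),
               "statistical|K1")
  expect_error(two_site_model(-1, 1, -10, -10), "K1")
})

test_that("cooperativity index uses the per-site convention", {
  mc <- two_site_cooperative(9.9e-9, 260e-9, -6.0, -6.5)
  expect_equal(cooperativity_index(mc), 9.9 / 260, tolerance = 1e-12)
  expect_lt(cooperativity_index(mc), 1)
  # invariant under joint rescaling of K1, K2
  m2 <- two_site_model(mc$K1 * 7, mc$K2 * 7, -6, -6.5)
  expect_equal(cooperativity_index(m2), cooperativity_index(mc),
               tolerance = 1e-12)
})

test_that("free-ligand solver handles degenerate inputs", {
  m <- two_site_noncooperative(1e-9, -10)
  expect_identical(solve_free_ligand(0, 5e-6, m)$L_free, 0)
  expect_identical(solve_free_ligand(5e-6, 0, m)$L_free, 5e-6)
  weak <- two_site_model(1e-6, 1e-7, -10, -10)  # negligible binding
  expect_equal(solve_free_ligand(5e-6, 5e-6, weak)$L_free, 5e-6,
               tolerance = 1e-6)
})

test_that("free-ligand solver agrees with the bisection oracle", {
  set.seed(42)
  n <- 1000
  for (i in seq_len(n)) {
    K1 <- 10^stats::runif(1, 4, 10)
    K2 <- 10^stats::runif(1, 3, 9)
    L_total <- 10^stats::runif(1, -8, -4)
    P_total <- 10^stats::runif(1, -8, -4)
    m <- two_site_model(K1, K2, -10, -10)
    got <- solve_free_ligand(L_total, P_total, m)
    want <- oracle_free_ligand(L_total, P_total, K1, K2)
    expect_equal(got$L_free, want, tolerance = 1e-10)
    # mass conservation
    expect_lt(abs(got$nu * P_total + got$L_free - L_total),
              1e-10 * L_total)
  }
})

test_that("solver equilibrium matches the spec example scale", {
  m <- two_site_noncooperative(1e-9, -10)
  eq <- solve_free_ligand(5e-6, 5e-6, m)
  want <- oracle_free_ligand(5e-6, 5e-6, m$K1, m$K2)
  expect_equal(eq$L_free, want, tolerance = 1e-10)
})

test_that("thermogram simulation: trivial limits", {
  prot <- titration_protocol()
  null_model <- two_site_model(2e8, 0.5e8, 0, 0, mode = "noncooperative")
  tg0 <- simulate_thermogram(null_model, prot)
  expect_equal(tg0$heat_kcal_per_mol, rep(0, 19), tolerance = 1e-15)
  # saturation: late heats approach q_dil to within the residual
  # displacement term, bounded by (dV/V0) * V0 * P * |2 dH| / moles injected
  m <- two_site_model(2e8, 0.5e8, -16.6, -16.6, mode = "noncooperative",
                      q_dil = -0.15)
  prot_long <- titration_protocol(injection_volumes_uL = rep(2, 40))
  tg <- simulate_thermogram(m, prot_long)
  expect_gt(utils::tail(tg$molar_ratio, 1), 2)
  dVr <- 2e-6 / prot_long$cell_volume
  disp_bound <- dVr * prot_long$cell_conc * 2 * 16.6 / prot_long$syringe_conc
  expect_lt(abs(utils::tail(tg$heat_kcal_per_mol, 1) - (-0.15)),
            disp_bound)
  # molar ratio strictly increasing
  expect_true(all(diff(tg$molar_ratio) > 0))
})

test_that("thermogram simulation matches the independent forward oracle", {
  prot <- titration_protocol()
  m <- two_site_noncooperative(34e-9, -12.8)
  got <- simulate_thermogram(m, prot)$heat_kcal_per_mol
  want <- oracle_thermogram(m$K1, m$K2, m$dH1, m$dH2,
                            prot$cell_volume, prot$cell_conc,
                            prot$syringe_conc, prot$injection_volumes)
  expect_equal(got, want, tolerance = 1e-9)
  mc <- two_site_cooperative(9.9e-9, 260e-9, -6.0, -6.5)
  got_c <- simulate_thermogram(mc, prot)$heat_kcal_per_mol
  want_c <- oracle_thermogram(mc$K1, mc$K2, mc$dH1, mc$dH2,
                              prot$cell_volume, prot$cell_conc,
                              prot$syringe_conc, prot$injection_volumes)
  expect_equal(got_c, want_c, tolerance = 1e-9)
})

test_that("total integrated heat approaches V0 * P * (dH1 + dH2) at saturation", {
  # saturating titration: cumulative heat (undoing the per-mole
  # normalization and displacement correction) reaches the two-site total
  prot <- titration_protocol(injection_volumes_uL = rep(2, 60))
  m <- two_site_noncooperative(1e-9, -12)
  tg <- simulate_thermogram(m, prot)
  V0 <- prot$cell_volume
  P_final <- prot$cell_conc * prod(1 - prot$injection_volumes / V0)
  expect_equal(utils::tail(tg$nu, 1), 2, tolerance = 1e-3)
  Q_final <- V0 * P_final * utils::tail(tg$nu, 1) * m$dH1
  expect_equal(Q_final, V0 * P_final * (m$dH1 + m$dH2), tolerance = 1e-3)
})

test_that("thermogram CSV and protocol YAML round-trip", {
  prot <- titration_protocol()
  tg <- simulate_thermogram(two_site_noncooperative(6.2e-9, -16.6), prot)
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermogram_csv(tg, path)
  back <- read_thermogram_csv(path)
  expect_equal(back$heat_kcal_per_mol, tg$heat_kcal_per_mol,
               tolerance = 1e-12)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cell_volume_uL: 200", "cell_conc_uM: 5",
               "syringe_conc_uM: 100", "injection_volume_uL: 2",
               "n_injections: 19", "temperature_C: 25"), ypath)
  prot2 <- read_protocol_yaml(ypath)
  expect_equal(prot2$cell_conc, prot$cell_conc)
  expect_equal(length(prot2$injection_volumes), 19)
})
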