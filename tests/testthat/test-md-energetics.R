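test_that("gas-phase energy bookkeeping is the stated linear combination", {
  expect_identical(gas_phase_energy(0, 0, 0), 0)
  expect_equal(gas_phase_energy(-1000, -50, -1181.5), 81.5,
               tolerance = 1e-12)
  # lowering the complex energy by delta raises dE_gp by delta
  base <- gas_phase_energy(-900, -40, -1000)
  expect_equal(gas_phase_energy(-900, -40, -1000 - 2.5) - base, 2.5)
})

test_that("binding energy reproduces every reported component row", {
  tab <- md_energy_table()
  expect_equal(binding_energy(tab$dE_gp, tab$dG_Lsolv),
               tab$dG_bind_reported, tolerance = 1e-12)
  expect_identical(binding_energy(0, 0), 0)
})

test_that("ligand ranking orders by binding energy with name tie-break", {
  ranked <- rank_ligands(md_energy_table())
  expect_equal(ranked$ligand,
               c("M-23", "M-21", "M-17", "tolcapone", "M-20", "M-14"))
  expect_equal(ranked$rank, 1:6)
  one <- rank_ligands(data.frame(ligand = "only", dE_gp = 1, dG_Lsolv = 0))
  expect_equal(one$ligand, "only")
  tie <- rank_ligands(data.frame(ligand = c("b", "a"),
                                 dE_gp = c(10, 10),
                                 dG_Lsolv = c(-1, -1)))
  expect_equal(tie$ligand, c("a", "b"))
})

test_that("annotate_binding_energies fills dE_gp from raw ensemble means", {
  raw <- data.frame(ligand = "x", E_TTR = -1000, E_L = -50,
                    E_TTR2L = -1181.5, dG_Lsolv = -10.9)
  out <- annotate_binding_energies(raw)
  expect_equal(out$dE_gp, 81.5, tolerance = 1e-12)
  expect_equal(out$dG_bind, 59.7, tolerance = 1e-12)
})

test_that("contact frequency applies element-dependent cutoffs", {
  d <- c(2.5, 2.9, 3.1, 3.4, 4.0)
  o <- contact_frequency(d, "O")
  expect_equal(o$frequency, 40)
  expect_equal(o$min_distance, 2.5)
  expect_equal(o$cutoff_used, 3.0)
  cl <- contact_frequency(d, "Cl")
  expect_equal(cl$frequency, 80)
  expect_equal(cl$cutoff_used, 3.5)
  # mean over contact frames only vs all frames
  expect_equal(o$mean_distance, mean(c(2.5, 2.9)))
  expect_equal(contact_frequency(d, "O", mean_over = "all")$mean_distance,
               mean(d))
  expect_error(contact_frequency(numeric(0), "O"), "empty")
})

test_that("contact frequency equals brute-force counting on random series", {
  set.seed(7)
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    d <- stats::runif(n, 1.5, 6)
    el <- sample(c("O", "N", "Cl"), 1)
    cut <- if (el == "Cl") 3.5 else 3.0
    got <- contact_frequency(d, el)
    expect_identical(got$frequency, 100 * sum(d <= cut) / n)
    expect_identical(got$min_distance, min(d))
  }
})

test_that("generated contact series recover target frequencies", {
  s <- gen_contact_series(50, n_frames = 10000, seed = 123)
  got <- contact_frequency(s$distance_A, s$partner_element[1])
  expect_lt(abs(got$frequency - 50), 2 * sqrt(0.25 / 10000) * 100)
  expect_equal(contact_frequency(
    gen_contact_series(0, n_frames = 500, seed = 1)$distance_A,
    "O")$frequency, 0)
  expect_equal(contact_frequency(
    gen_contact_series(100, n_frames = 500, seed = 1)$distance_A,
    "O")$frequency, 100)
})

test_that("frame sampling is even, increasing and ends at the final time", {
  t1 <- sample_frames(150, 140, 140)
  expect_length(t1, 140)
  expect_equal(t1[1], 11)
  expect_equal(utils::tail(t1, 1), 150)
  expect_equal(unique(round(diff(t1), 12)), 1)
  expect_equal(sample_frames(100, 100, 1), 100)
  expect_equal(sample_frames(10, 4, 4), c(7, 8, 9, 10))
  expect_error(sample_frames(100, 140, 10), "window")
  # property: strictly increasing, right length, last = total
  for (i in 1:20) {
    total <- stats::runif(1, 10, 500)
    window <- stats::runif(1, 1, total)
    n <- sample(1:200, 1)
    tt <- sample_frames(total, window, n)
    expect_length(tt, n)
    expect_true(all(diff(tt) > 0) || n == 1)
    expect_equal(utils::tail(tt, 1), total)
  }
})

test_that("contact summaries group by donor/acceptor pair", {
  s1 <- gen_contact_series(30, n_frames = 200, seed = 1,
                           donor = "LIG@O1", acceptor = "T119@OG1")
  s2 <- gen_contact_series(80, n_frames = 200, seed = 2,
                           donor = "LIG@CL1", acceptor = "S117@OG",
                           partner_element = "Cl", cutoff = 3.5)
  out <- summarize_contacts(rbind(s1, s2))
  expect_equal(nrow(out), 2)
  expect_setequal(out$cutoff_used, c(3.0, 3.5))
})
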