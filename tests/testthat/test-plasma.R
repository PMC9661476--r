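test_that("tetramer ratio arithmetic and domain", {
  expect_equal(tetramer_ratio(3, 1), 0.75)
  expect_equal(tetramer_ratio(5, 0), 1)
  expect_equal(tetramer_ratio(0, 5), 0)
  expect_error(tetramer_ratio(0, 0), "> 0")
  expect_error(tetramer_ratio(-1, 2), ">= 0")
  # complement identity
  expect_equal(tetramer_ratio(3, 7) + tetramer_ratio(7, 3), 1)
})

test_that("stabilization percent formula and sign", {
  expect_equal(stabilization_percent(0.9, 0.6), 50)
  expect_equal(stabilization_percent(0.6, 0.6), 0)
  expect_equal(stabilization_percent(0.3, 0.6), -50)
  expect_error(stabilization_percent(0.5, 0), "ratio_control")
})

test_that("stabilization is invariant under per-lane intensity rescaling", {
  for (i in 1:10) {
    t_c <- stats::runif(1, 10, 100); m_c <- stats::runif(1, 10, 100)
    t_t <- stats::runif(1, 10, 100); m_t <- stats::runif(1, 10, 100)
    a <- stats::runif(1, 0.1, 10); b <- stats::runif(1, 0.1, 10)
    s1 <- stabilization_percent(tetramer_ratio(t_t, m_t),
                                tetramer_ratio(t_c, m_c))
    s2 <- stabilization_percent(tetramer_ratio(a * t_t, a * m_t),
                                tetramer_ratio(b * t_c, b * m_c))
    expect_equal(s1, s2, tolerance = 1e-10)
  }
})

test_that("per-donor IEF pipeline recovers generated effects", {
  tab0 <- gen_densitometry(effect_pct = 0, noise_sd = 0, n_donors = 4)
  out0 <- ief_stabilization(tab0)
  expect_equal(out0$per_donor$stabilization_pct, rep(0, 4),
               tolerance = 1e-10)
  tab50 <- gen_densitometry(effect_pct = 50, noise_sd = 0, n_donors = 4)
  expect_equal(ief_stabilization(tab50)$mean_pct, 50, tolerance = 1e-10)
  # noisy: mean within 2 SEM
  tabn <- gen_densitometry(effect_pct = 30, baseline_ratio = 0.6,
                           n_donors = 6, noise_sd = 0.02, seed = 5)
  outn <- ief_stabilization(tabn)
  expect_lt(abs(outn$mean_pct - 30), 2 * outn$sem_pct + 1e-9)
  # unpaired donor errors
  expect_error(ief_stabilization(tab0[-1, ]), "exactly one")
})

test_that("T4 bound fraction normalization and displacement", {
  ctrl <- list(tbg = 40, alb = 25, ttr = 35)
  same <- t4_bound_fraction(ctrl, ctrl)
  expect_equal(same$fraction, 1)
  expect_equal(same$displacement_pct, 0)
  gone <- t4_bound_fraction(list(tbg = 50, alb = 50, ttr = 0), ctrl)
  expect_equal(gone$fraction, 0)
  expect_equal(gone$displacement_pct, 100)
  # sample fraction at 15.4% of control: 84.6% displacement
  f_ctrl <- 35 / 100
  sample <- list(tbg = 60, alb = 30, ttr = 0)
  sample$ttr <- 0.154 * f_ctrl * (sample$tbg + sample$alb) /
    (1 - 0.154 * f_ctrl)
  disp <- t4_bound_fraction(sample, ctrl)
  expect_equal(disp$displacement_pct, 84.6, tolerance = 1e-9)
  expect_error(t4_bound_fraction(list(tbg = 0, alb = 0, ttr = 0), ctrl),
               "total")
})

test_that("solubility per-assay values and reported means", {
  m23 <- solubility(c(15.4, 14.7, 15.0), c(350, 326, 333))
  expect_equal(m23$per_assay_reported, c(0.044, 0.045, 0.045))
  expect_equal(m23$mean_reported, 0.045)
  tol <- solubility(c(15.0, 14.4, 15.3), c(267, 261, 273))
  expect_equal(tol$per_assay_reported, c(0.056, 0.055, 0.056))
  expect_equal(tol$mean_reported, 0.056)
  expect_equal(solubility(10, 100)$mean_reported, 0.1)
  expect_error(solubility(0, 100), "weight_mg")
})

test_that("group comparison reports means, SEM and Tukey contrasts", {
  set.seed(2)
  vals <- c(stats::rnorm(6, 50, 5), stats::rnorm(6, 10, 5))
  grp <- rep(c("M-23", "tolcapone"), each = 6)
  out <- compare_stabilization(vals, grp)
  expect_equal(nrow(out$summary), 2)
  expect_true(all(c("mean", "sem") %in% names(out$summary)))
  expect_s3_class(out$tukey, "TukeyHSD")
  # the large separation is detected
  pvals <- out$tukey$groups[, "p adj"]
  expect_lt(pvals[1], 0.001)
})
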