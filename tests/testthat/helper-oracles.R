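# Independent oracles, deliberately kept separate from the package's
# implementation paths.

# Pure-bisection solver for the free-ligand mass balance
# L_total = L + P * nu(L). Knows nothing about the package's
# safeguarded-Newton solver.
oracle_free_ligand <- function(L_total, P_total, K1, K2, iters = 200) {
  if (L_total == 0 || P_total == 0) return(L_total)
  g <- function(L) {
    Z <- 1 + K1 * L + K1 * K2 * L^2
    L + P_total * (K1 * L + 2 * K1 * K2 * L^2) / Z - L_total
  }
  lo <- 0
  hi <- L_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Site-state enumeration for two sites with microscopic association
# constant k (identical, independent): statistical weights over the four
# microstates {00, 10, 01, 11}.
oracle_identical_sites <- function(L, k) {
  w <- c(1, k * L, k * L, (k * L)^2)
  Z <- sum(w)
  list(
    Z = Z,
    F0 = w[1] / Z,
    F1 = (w[2] + w[3]) / Z,
    F2 = w[4] / Z,
    nu = (w[2] + w[3] + 2 * w[4]) / Z,
    per_site = k * L / (1 + k * L)
  )
}

# Forward thermogram simulation written independently: same displacement
# convention, straight-line code with the bisection oracle for equilibria.
oracle_thermogram <- function(K1, K2, dH1, dH2, cell_volume, cell_conc,
                              syringe_conc, injection_volumes) {
  V0 <- cell_volume
  p <- cell_conc; l <- 0
  Qprev <- 0
  q <- numeric(length(injection_volumes))
  for (i in seq_along(injection_volumes)) {
    dV <- injection_volumes[i]
    f <- 1 - dV / V0
    p <- p * f
    l <- l * f + syringe_conc * dV / V0
    L <- oracle_free_ligand(l, p, K1, K2)
    Z <- 1 + K1 * L + K1 * K2 * L^2
    F1 <- K1 * L / Z
    F2 <- K1 * K2 * L^2 / Z
    Q <- V0 * p * (F1 * dH1 + F2 * (dH1 + dH2))
    q[i] <- (Q - Qprev + (dV / V0) * (Q + Qprev) / 2) / (syringe_conc * dV)
    Qprev <- Q
  }
  q
}

# Random rigid motion (proper rotation + translation) applied to a
# structure frame.
apply_rigid_motion <- function(frame, seed = 1) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_vec <- stats::rnorm(3, sd = 20)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  frame$x <- xyz[, 1] + t_vec[1]
  frame$y <- xyz[, 2] + t_vec[2]
  frame$z <- xyz[, 3] + t_vec[3]
  frame
}
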