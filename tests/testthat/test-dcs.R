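test_that("pair Coulomb expectation reduces correctly for uncorrelated
           isotropic clouds", {
  osc <- toy_dimer(8, alpha = 6, omega = 0.5)
  st0 <- ground_state(osc, correlated = FALSE)
  s2 <- 6 * 0.5 / 2
  R <- c(0, 0, 8)
  direct <- 1 / 8 - 2 * gaussian_coulomb_kernel(R, s2 * diag(3)) +
    gaussian_coulomb_kernel(R, 2 * s2 * diag(3))
  expect_equal(pair_coulomb_expectation(osc, st0, 1, 2), direct,
               tolerance = 1e-12)
  expect_error(pair_coulomb_expectation(osc, st0, 1, 1), "distinct")
})

test_that("pair dipole expectation vanishes for the uncorrelated state
           and is rotationally covariant", {
  osc <- toy_trimer()
  st <- both_states(osc)
  expect_identical(pair_dipole_expectation(osc, st$uc, 1, 2), 0)
  v <- pair_dipole_expectation(osc, st$dc, 1, 3)
  expect_true(v != 0)
  Q <- random_rotation(5)
  osc_r <- rotate_oscillators(osc, Q)
  st_r <- rotate_state(st$dc, Q)
  expect_equal(pair_dipole_expectation(osc_r, st_r, 1, 3), v,
               tolerance = 1e-12)
})

test_that("pair dipole expectation equals the Monte-Carlo mean of the
           dipolar coupling", {
  osc <- toy_dimer(8)
  st <- ground_state(osc, damping = "none")
  v <- pair_dipole_expectation(osc, st, 1, 2)
  n <- 4e5
  withr::with_seed(31, {
    d <- matrix(stats::rnorm(6 * n), n, 6) %*% chol(st$covariance)
  })
  Tdd <- -dipole_tensor(c(0, 0, 8))
  samp <- rowSums((d[, 1:3] %*% Tdd) * d[, 4:6])
  expect_lt(abs(v - mean(samp)), 3 * stats::sd(samp) / sqrt(n))
})

test_that("DCS energy vanishes when the coupling is off and at large
           separation", {
  osc <- toy_dimer(8, 6, 0.5)
  st0 <- ground_state(osc, correlated = FALSE)
  expect_equal(dcs_energy(osc, st0, st0, damping = "none"), 0)
  # |E_DCS| -> 0 with distance
  vals <- vapply(c(10, 20, 40), function(R) {
    o <- toy_dimer(R, 6, 0.5)
    st <- both_states(o)
    abs(dcs_energy(o, st$dc, st$uc, damping = "none"))
  }, 0)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 1e-10)
})

test_that("DCS energy is invariant under rotation, translation and
           relabeling", {
  osc <- toy_trimer()
  st <- both_states(osc)
  e0 <- dcs_energy(osc, st$dc, st$uc, damping = "none")
  Q <- random_rotation(17)
  osc_r <- rotate_oscillators(osc, Q, c(-4, 2, 1))
  st_r <- both_states(osc_r)
  expect_lt(abs(dcs_energy(osc_r, st_r$dc, st_r$uc, damping = "none") -
                  e0), 1e-10)
  perm <- c(2, 3, 1)
  osc_p <- oscillator_set(osc$positions[perm, ], osc$alpha[perm],
                          osc$omega[perm], osc$r_vdw[perm])
  st_p <- both_states(osc_p)
  expect_lt(abs(dcs_energy(osc_p, st_p$dc, st_p$uc, damping = "none") -
                  e0), 1e-10)
})

test_that("decomposition satisfies the sum rule and populates both
           channels", {
  for (osc in list(toy_dimer(8), toy_trimer())) {
    st <- both_states(osc)
    bd <- dcs_decomposition(osc, st$dc, st$uc, damping = "none")
    expect_lt(abs(bd$e_dcs - ((bd$j_dc - bd$j_0) +
                                (bd$e_corr - bd$e_dip))), 1e-10)
    expect_equal(bd$e_dcs, dcs_energy(osc, st$dc, st$uc, damping = "none"),
                 tolerance = 1e-10)
    expect_equal(sum(bd$pairs$e_dcs), bd$e_dcs, tolerance = 1e-12)
  }
  # three-atom fixture: polarization (J) and dipolar channels both live
  tri <- toy_trimer()
  st <- both_states(tri)
  bd <- dcs_decomposition(tri, st$dc, st$uc, damping = "none")
  expect_gt(abs(bd$j_dc - bd$j_0), 1e-12)
  expect_gt(abs(bd$e_dip), 1e-12)
  # uncoupled system: every channel is zero
  bd0 <- dcs_decomposition(tri, st$uc, st$uc, damping = "none")
  expect_equal(abs(c(bd0$e_dcs, bd0$j_dc - bd0$j_0, bd0$e_corr,
                     bd0$e_dip)), rep(0, 4), tolerance = 1e-14)
})

test_that("body-body DCS interaction takes both signs across the
           orientation fixture pair", {
  col <- embedded_body_curve(c(20, 25), orientation = "collinear")
  tra <- embedded_body_curve(c(20, 25), orientation = "transverse")
  expect_lt(col$de_dcs[1], 0)
  expect_gt(tra$de_dcs[1], 0)
})

test_that("Monte-Carlo oracle is reproducible and scales as CLT", {
  osc <- toy_dimer(8)
  st <- ground_state(osc, damping = "none")
  a <- mc_expectation(osc, st, n = 5e4, seed = 7, damping = "none")
  b <- mc_expectation(osc, st, n = 5e4, seed = 7, damping = "none")
  expect_identical(a$mean, b$mean)
  big <- mc_expectation(osc, st, n = 2e5, seed = 7, damping = "none")
  expect_equal(big$stderr, a$stderr / 2, tolerance = 0.2)
  expect_error(mc_expectation(osc, st, n = 100), "at least 1000")
})

test_that("quadrature DCS energy matches the Monte-Carlo oracle on the
           dimer at moderate sampling", {
  osc <- toy_dimer(8)
  st <- both_states(osc)
  e <- dcs_energy(osc, st$dc, st$uc, damping = "none")
  m1 <- mc_expectation(osc, st$dc, n = 2e6, seed = 20210108,
                       damping = "none")
  m0 <- mc_expectation(osc, st$uc, n = 2e6, seed = 20210109,
                       damping = "none")
  expect_lt(abs(e - (m1$mean - m0$mean)),
            3 * sqrt(m1$stderr^2 + m0$stderr^2))
})
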