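test_that("parametrize applies the volume and polarizability scalings", {
  tab <- load_free_atom_table()
  xe <- tab[tab$symbol == "Xe", ]
  osc <- parametrize(geometry("Xe", matrix(0, 1, 3)))
  expect_equal(osc$omega, 4 * xe$c6_free / (3 * xe$alpha_free^2))
  expect_equal(osc$alpha, xe$alpha_free)
  # alpha = q^2/(m omega^2) holds to machine precision
  expect_equal(osc$alpha, osc$charge^2 / (osc$mass * osc$omega^2))
  # C6 scales as (s v)^2, so omega = 4 C6/(3 alpha^2) is scale-invariant
  s <- 1.5
  osc_s <- parametrize(geometry("Xe", matrix(0, 1, 3)), alpha_scale = s)
  expect_equal(osc_s$alpha, s * osc$alpha)
  expect_equal(osc_s$omega, osc$omega)
  expect_equal(osc_s$alpha, osc_s$charge^2 / (osc_s$mass * osc_s$omega^2))
  v <- 0.8
  osc_v <- parametrize(geometry("Xe", matrix(0, 1, 3),
                                hirshfeld_ratios = v))
  expect_equal(osc_v$alpha, v * osc$alpha)
  expect_equal(osc_v$r_vdw, v^(1 / 3) * osc$r_vdw)
  expect_error(parametrize(geometry("Xe", matrix(0, 1, 3)),
                           alpha_scale = -1), "positive")
  expect_error(parametrize(geometry("Uuo", matrix(0, 1, 3))),
               "not in free-atom table")
})

test_that("dipole tensor is the Hessian of 1/r, symmetric and traceless", {
  R <- 3.7
  expect_equal(dipole_tensor(c(0, 0, R)), diag(c(-1, -1, 2)) / R^3)
  set.seed(42)
  for (k in 1:5) {
    r <- stats::rnorm(3, sd = 4)
    T <- dipole_tensor(r)
    expect_equal(sum(diag(T)), 0, tolerance = 1e-12)
    expect_equal(T, t(T))
    # central finite differences of 1/|r|
    h <- 1e-4
    H <- matrix(0, 3, 3)
    f <- function(x) 1 / sqrt(sum(x^2))
    for (a in 1:3) for (b in 1:3) {
      ea <- eb <- c(0, 0, 0); ea[a] <- h; eb[b] <- h
      H[a, b] <- (f(r + ea + eb) - f(r + ea - eb) -
                    f(r - ea + eb) + f(r - ea - eb)) / (4 * h^2)
    }
    expect_equal(T, H, tolerance = 1e-6)
  }
  expect_error(dipole_tensor(c(0, 0, 0)), "singular")
})

test_that("Fermi damping has the right midpoint, origin value and limits", {
  p <- damping_params("dcs")
  expect_equal(p$a, 10.12)
  expect_equal(p$beta, 1.4)
  rv <- c(3.1, 3.6)
  mid <- p$beta * sum(rv)
  expect_equal(fermi_damping(mid, rv[1], rv[2], p), 0.5)
  expect_equal(fermi_damping(0, rv[1], rv[2], p), 1 / (1 + exp(10.12)))
  expect_equal(fermi_damping(1e6, rv[1], rv[2], p), 1)
  R <- seq(0, 30, by = 0.5)
  expect_true(all(diff(fermi_damping(R, rv[1], rv[2], p)) > 0))
})

test_that("interaction matrix matches the two-oscillator closed form", {
  one <- oscillator_set(matrix(0, 1, 3), 2, 0.7, 3)
  expect_equal(interaction_matrix(one), 0.49 * diag(3))
  alpha <- 1; omega <- 1; R <- 10
  dim2 <- toy_dimer(R, alpha, omega)
  C <- interaction_matrix(dim2, damping = "none")
  expect_equal(C, t(C))
  lam <- solve_modes(C, dim2$omega)$eigenvalues
  closed <- sort(c(omega^2 * (1 + 2 * alpha / R^3),
                   omega^2 * (1 - 2 * alpha / R^3),
                   rep(omega^2 * (1 + alpha / R^3), 2),
                   rep(omega^2 * (1 - alpha / R^3), 2)))
  expect_equal(sort(lam), closed, tolerance = 1e-12)
  expect_error(
    oscillator_set(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1), c(1, 1),
                   c(3, 3)),
    NA)  # constructor itself rejects via geometry only when used there
  expect_error(interaction_matrix(
    oscillator_set(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1), c(1, 1),
                   c(3, 3))), "coincident")
})

test_that("mode solver conserves the trace and flags the catastrophe", {
  set.seed(7)
  pos <- matrix(stats::rnorm(15, sd = 6), 5, 3)
  osc <- oscillator_set(pos, runif(5, 3, 8), runif(5, 0.3, 0.8), rep(3, 5))
  spec <- solve_modes(interaction_matrix(osc), osc$omega)
  expect_equal(sum(spec$eigenvalues), 3 * sum(osc$omega^2),
               tolerance = 1e-12)
  V <- spec$mode_matrix
  expect_lt(max(abs(crossprod(V) - diag(15))), 1e-10)
  # overlapping strong coupling: 2 alpha / R^3 > 1
  bad <- toy_dimer(1, alpha = 1, omega = 1)
  expect_error(mbd_energy(bad, damping = "none"),
               "polarization catastrophe.*-?[0-9]")
})

test_that("MBD energy reproduces the leading C6 term and R^-6 decay", {
  expect_identical(mbd_energy(oscillator_set(matrix(0, 1, 3), 1, 1, 3)), 0)
  e <- mbd_energy(toy_dimer(10, 1, 1), damping = "none")
  expect_equal(e, -0.75 / 10^6, tolerance = 0.01)
  Rs <- seq(10, 40, by = 3)
  Es <- vapply(Rs, function(R) mbd_energy(toy_dimer(R, 1, 1),
                                          damping = "none"), 0)
  fit <- fit_decay_exponent(Rs, Es)
  expect_equal(fit$slope, -6, tolerance = 0.05 / 6)
})

test_that("MBD energy is invariant under rotation, translation and
           permutation, and is not pairwise additive", {
  osc <- toy_trimer()
  e0 <- mbd_energy(osc)
  Q <- random_rotation(11)
  expect_lt(abs(mbd_energy(rotate_oscillators(osc, Q, c(3, -2, 5))) - e0),
            1e-10)
  perm <- c(3, 1, 2)
  osc_p <- oscillator_set(osc$positions[perm, ], osc$alpha[perm],
                          osc$omega[perm], osc$r_vdw[perm])
  expect_lt(abs(mbd_energy(osc_p) - e0), 1e-12)
  # many-body character: trimer energy is not the sum of its pairs
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  e_pairs <- sum(vapply(pairs, function(p)
    mbd_energy(subset_oscillators(osc, p)), 0))
  expect_gt(abs(e0 - e_pairs), 1e-9)
})

test_that("undamped identical dimers bind throughout the stable region", {
  for (alpha in c(0.5, 1, 2)) for (R in c(4, 6, 10)) {
    if (2 * alpha / R^3 < 1) {
      e <- mbd_energy(toy_dimer(R, alpha, 1), damping = "none")
      expect_lte(e, 0)
    }
  }
})

test_that("ground states have the harmonic-oscillator covariance", {
  osc <- toy_dimer(8, alpha = 6, omega = 0.5)
  st0 <- ground_state(osc, correlated = FALSE)
  expect_equal(covariance_block(st0, 1), (6 * 0.5 / 2) * diag(3))
  expect_equal(covariance_block(st0, 1, 2), matrix(0, 3, 3))
  # with the coupling damped to ~0 the correlated state collapses to
  # the uncorrelated one
  off <- damping_params("mbd", a = 60, beta = 40)
  st_dc <- ground_state(osc, params = off, damping = "fermi")
  expect_lt(max(abs(st_dc$covariance - st0$covariance)), 1e-12)
})

test_that("sample covariance of Gaussian draws matches the state", {
  osc <- toy_dimer(8, alpha = 6, omega = 0.5)
  st <- ground_state(osc, damping = "none")
  n <- 2e5
  withr::with_seed(123, {
    d <- matrix(stats::rnorm(n * 6), n, 6) %*% chol(st$covariance)
  })
  S_hat <- crossprod(d) / n
  se <- sqrt((outer(diag(st$covariance), diag(st$covariance)) +
                st$covariance^2) / n)
  expect_true(all(abs(S_hat - st$covariance) < 5 * se))
})

test_that("cross-covariance blocks vanish monotonically with distance", {
  vals <- vapply(c(10, 15, 20, 25), function(R) {
    st <- ground_state(toy_dimer(R, 6, 0.5), damping = "none")
    max(abs(covariance_block(st, 1, 2)))
  }, 0)
  expect_true(all(diff(vals) < 0))
})
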