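test_that("fragment interaction energy reduces to the dimer formula in
           vacuum and vanishes for one fragment", {
  builder <- vacuum_dimer_builder("Xe")
  osc <- builder(6)
  e <- interaction_energy(osc)
  # direct three-term dimer evaluation
  e_ab <- mbd_energy(osc)
  e_a <- mbd_energy(subset_oscillators(osc, "guestA"))
  e_b <- mbd_energy(subset_oscillators(osc, "guestB"))
  expect_equal(e$mbd, e_ab - e_a - e_b, tolerance = 1e-14)
  expect_equal(e$`mbd+dcs`, e$mbd + e$dcs, tolerance = 1e-12)
  single <- subset_oscillators(osc, "guestA")
  expect_equal(interaction_energy(single)$mbd, 0)
  # distant guests do not interact
  far <- interaction_energy(builder(200))
  expect_lt(abs(far$`mbd+dcs`) * units_au$kjmol_per_hartree, 1e-8)
})

test_that("interaction energy validates labels and names failing
           subsystems", {
  osc <- vacuum_dimer_builder("Xe")(6)
  bad <- oscillator_set(osc$positions, osc$alpha, osc$omega, osc$r_vdw,
                        labels = c("guestA", "stray"))
  expect_error(interaction_energy(bad), "stray")
  # catastrophic subsystem is reported by name
  tight <- oscillator_set(rbind(c(0, 0, 0), c(0, 0, 0.8)), c(10, 10),
                          c(0.5, 0.5), c(3, 3),
                          labels = c("guestA", "guestB"))
  expect_error(interaction_energy(tight, damping = "none"),
               "subsystem 'full'")
})

test_that("binding scans have the vdW-tail shape and fail loudly", {
  seps <- seq(6, 16, by = 2)
  curve <- binding_scan(vacuum_dimer_builder("Xe"), seps)
  expect_true(all(diff(curve$e_mbd) > 0))   # monotone toward zero
  expect_true(all(curve$e_mbd < 0))
  expect_equal(curve$e_vdw, curve$e_mbd + curve$e_dcs)
  wide <- binding_scan(vacuum_dimer_builder("Xe"), c(10, 30, 60))
  expect_lt(wide$ratio[3], wide$ratio[1])   # ratio decays to zero
  expect_error(binding_scan(vacuum_dimer_builder("Xe"), c(4, 3)),
               "increasing")
  boom <- function(R) stop("no system at R")
  expect_error(binding_scan(boom, c(1, 2)), "failed at.*R = 1")
})

test_that("alpha scaling acts on the guests of a geometry builder", {
  b1 <- vacuum_dimer_builder("Xe", alpha_scale = 1)
  b2 <- vacuum_dimer_builder("Xe", alpha_scale = 1.5)
  expect_equal(b2(6)$alpha, 1.5 * b1(6)$alpha)
  host <- build_armchair_cnt(4, length = 6)
  bc <- cnt_guest_builder(host, alpha_scale_guest = 1.5)(2)
  expect_equal(unique(bc$alpha[bc$labels != "host"]),
               1.5 * load_free_atom_table()$alpha_free[12])
  expect_equal(unique(bc$alpha[bc$labels == "host" &
                                 bc$elements == "C"]), 12)
})

test_that("decay-exponent fitting recovers known power laws", {
  R <- seq(10, 100, by = 5)
  f6 <- fit_decay_exponent(R, 3 / R^6)
  expect_equal(f6$slope, -6, tolerance = 1e-6)
  expect_lt(f6$stderr, 1e-6)
  mix <- 2 / R^5 + 40 / R^7
  f5 <- fit_decay_exponent(R, mix, window = c(30, 100))
  expect_equal(f5$slope, -5, tolerance = 0.1 / 5)
  expect_error(fit_decay_exponent(R, 1 / R^5 - 2e-9, window = c(10, 100)),
               "sign")
  expect_error(fit_decay_exponent(c(1, 2, 3), c(1, 1, 1)), "5 points")
})

test_that("embedded-body curves expose the two decay channels", {
  curve <- embedded_body_curve(c(20, 25, 30), orientation = "transverse")
  expect_named(curve, c("distance", "de_mbd", "de_dcs"))
  expect_true(all(curve$de_mbd < 0))
  expect_true(all(abs(curve$de_dcs) > 0))
  expect_true(all(abs(diff(abs(curve$de_dcs))) > 0))
})

test_that("collinear bodies steepen the apparent MBD exponent by their
           odd finite-size corrections", {
  Rs <- seq(20, 60, by = 5)
  col <- embedded_body_curve(Rs, orientation = "collinear")
  f_col <- fit_decay_exponent(Rs, col$de_mbd)
  expect_lt(f_col$slope, -6.15)   # ~ -6.3 in this window
  expect_gt(f_col$slope, -6.45)
  # a bare pairwise C6 sum over the same atom distances shows the same
  # steepening, so it is geometric, not a coupling effect
  pair6 <- 1 / (Rs - 4)^6 + 1 / (Rs + 4)^6 + 2 / Rs^6
  f_pair <- fit_decay_exponent(Rs, pair6)
  expect_equal(f_col$slope, f_pair$slope, tolerance = 0.02)
})

test_that("energy reports are deterministic and carry provenance", {
  osc <- toy_dimer(8, 6, 0.5)
  rep1 <- energy_report(osc, damping = "none")
  expect_equal(rep1$totals$e_vdw$hartree,
               rep1$totals$e_mbd$hartree + rep1$totals$e_dcs$hartree)
  expect_equal(rep1$totals$e_mbd$kjmol,
               rep1$totals$e_mbd$hartree * units_au$kjmol_per_hartree)
  bd <- rep1$dcs_components
  expect_equal(rep1$totals$e_dcs$hartree,
               (bd$j_dc - bd$j_0) + (bd$e_corr - bd$e_dip),
               tolerance = 1e-10)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_energy_report(rep1, f1)
  write_energy_report(energy_report(osc, damping = "none"), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("YAML configuration maps onto damping parameters and seeds", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("parameters:", "  alpha_scale: 1.5",
               "damping_dcs:", "  a: 9.0", "  beta: 1.2",
               "seeds:", "  mc: 42"), f)
  cfg <- read_config(f)
  expect_equal(cfg$alpha_scale, 1.5)
  expect_equal(cfg$params_dcs$a, 9)
  expect_equal(cfg$params_dcs$beta, 1.2)
  expect_equal(cfg$params_mbd$a, 6)      # untouched default
  expect_equal(cfg$seed, 42)
  dflt <- read_config(NULL)
  expect_equal(dflt$params_dcs$a, 10.12)
})
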