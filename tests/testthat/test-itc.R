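# ITC forward models and fitting: direct single-site, competitive
# replacement, enthalpy bookkeeping.

test_that("simulated heats conserve total binding enthalpy", {
  # zero enthalpy -> zero heat everywhere
  ex <- titration_experiment(cell = c(E = 20e-6), syringe = c(L = 150e-6),
                             injection_volumes = rep(2e-6, 25))
  h0 <- simulate_titration(ex, list(kind = "single_site", enzyme = "E",
                                    ligand = "L", kd = 1e-7, dh = 0, n = 1))
  expect_true(all(h0 == 0))
  # exact conservation under the overflow convention: total heat equals
  # dH * (complex in the cell at the end + complex expelled in overflow)
  h <- simulate_titration(ex, list(kind = "single_site", enzyme = "E",
                                   ligand = "L", kd = 1e-7, dh = -40, n = 1))
  totals <- coopkin:::.injection_totals(ex)
  el <- coopkin:::.single_site_complex(totals[, "E"], totals[, "L"], 1e-7, 1)
  f <- ex$injection_volumes / ex$cell_volume
  conserved <- 170e-6 * -40e3 * (el[26] + sum(f * el[1:25]))
  expect_equal(sum(h), conserved, tolerance = 1e-12)
  # and approaches n * dH * (initial cell moles) once the titration
  # saturates (enzyme conservation bounds it from below)
  expect_gt(sum(h), -40e3 * 170e-6 * 20e-6)
  expect_lt(sum(h), -40e3 * 170e-6 * 20e-6 * 0.85)
  # high c-value: near-step isotherm with inflection at molar ratio ~ n
  hs <- simulate_titration(ex, list(kind = "single_site", enzyme = "E",
                                    ligand = "L", kd = 1e-10, dh = -40, n = 1))
  per_mole <- hs / (ex$injection_volumes * ex$syringe)
  expect_true(all(abs(per_mole[1:10] / per_mole[1] - 1) < 0.02))
  expect_lt(abs(per_mole[25] / per_mole[1]), 0.05)
})

test_that("direct fit is an exact round trip on noiseless data", {
  ex <- make_single_site_experiment(kd = 100e-9, dh = -40, n = 0.95)
  fit <- fit_direct(ex)
  expect_equal(fit$kd, 100e-9, tolerance = 1e-6)
  expect_equal(fit$dh, -40, tolerance = 1e-6)
  expect_equal(fit$n, 0.95, tolerance = 1e-6)
  expect_true(fit$kd_ci[1] <= fit$kd && fit$kd <= fit$kd_ci[2])
})

test_that("the first injection is discarded from the fit objective", {
  ex <- make_single_site_experiment()
  fit1 <- fit_direct(ex)
  ex$heats[1] <- ex$heats[1] * 0.25   # typical short first injection
  fit2 <- fit_direct(ex)
  expect_equal(fit1$kd, fit2$kd, tolerance = 1e-12)
  expect_equal(fit1$dh, fit2$dh, tolerance = 1e-12)
})

test_that("low c-value designs trigger the identifiability warning", {
  ex <- make_single_site_experiment(kd = 100e-6, cell = 10e-6,
                                    syringe = 2000e-6)
  fit <- fit_direct(ex)
  expect_true(any(grepl("c-value", fit$warnings)))
})

test_that("competitive equilibrium cubic matches the bisection oracle", {
  set.seed(606)
  for (i in 1:500) {
    e0 <- 10^runif(1, -6, -4)
    a0 <- 10^runif(1, -6, -2)
    b0 <- 10^runif(1, -7, -4)
    ka <- 10^runif(1, -7, -3)
    kb <- 10^runif(1, -10, -6)
    e_cubic <- coopkin:::.competitive_free_enzyme(e0, a0, b0, ka, kb)
    e_oracle <- oracle_competitive_free_enzyme(e0, a0, b0, ka, kb)
    expect_equal(e_cubic, e_oracle, tolerance = 1e-8)
  }
})

test_that("displacement reduces to the direct model without competitor and shifts Kd by the competition factor", {
  ex <- titration_experiment(cell = c(E = 20e-6, A = 1e-16),
                             syringe = c(B = 150e-6),
                             injection_volumes = rep(2e-6, 25))
  h_disp <- simulate_displacement(ex, "E", "A", "B", kd_weak = 1e-4,
                                  dh_weak = -20, kd_tight = 1e-7,
                                  dh_tight = -40)
  h_direct <- simulate_titration(ex, list(kind = "single_site", enzyme = "E",
                                          ligand = "B", kd = 1e-7, dh = -40,
                                          n = 1))
  expect_equal(h_disp, h_direct, tolerance = 1e-9)

  # apparent affinity in the competition regime: K_B,app = K_B (1 + A/K_A)
  # K_B = 1 nM, [A] = 2 mM, K_A = 100 uM -> 21 nM
  e0 <- 1e-12  # trace enzyme: free ligands equal their totals
  # half-saturation of B against the A-loaded enzyme happens at K_B,app
  kb_app <- 1e-9 * (1 + 2e-3 / 1e-4)
  expect_equal(kb_app, 21e-9)
  occ <- function(b0) {
    coopkin:::.competitive_complexes(e0, 2e-3, b0, 1e-4, 1e-9)[["EB"]] / e0
  }
  expect_equal(occ(kb_app), 0.5, tolerance = 1e-3)
})

test_that("displacement fit recovers the generating tight-ligand parameters", {
  # replacement design: competitor-loaded cell, tight binder in the syringe
  ex <- titration_experiment(cell = c(E = 20e-6, AMPCP = 2000e-6),
                             syringe = c(dan = 150e-6),
                             injection_volumes = rep(2e-6, 25))
  ex$heats <- simulate_displacement(ex, "E", "AMPCP", "dan",
                                    kd_weak = 20e-6, dh_weak = -20,
                                    kd_tight = 2.4e-9, dh_tight = -55)
  fit <- fit_displacement(ex, kd_weak = 20e-6, dh_weak = -20)
  expect_equal(fit$kd, 2.4e-9, tolerance = 1e-5)
  expect_equal(fit$dh, -55, tolerance = 1e-5)
  expect_equal(fit$n, 1)  # fixed by default

  # with 1% heat noise the recovery stays within 15%
  set.seed(707)
  errs <- replicate(20, {
    exn <- ex
    exn$heats <- ex$heats + rnorm(25, 0, 0.01 * max(abs(ex$heats)))
    f <- fit_displacement(exn, kd_weak = 20e-6, dh_weak = -20)
    abs(f$kd - 2.4e-9) / 2.4e-9
  })
  expect_lt(median(errs), 0.15)
})

test_that("enthalpy difference table propagates errors in quadrature", {
  mk_fit <- function(dh, se) {
    coopkin:::.binding_fit(kd = 1e-9, kd_ci = c(0.5e-9, 2e-9), dh = dh,
                           dh_se = se, n = 1, n_se = NA, residuals = NULL,
                           model = "direct single-site")
  }
  fits <- list(mb1 = mk_fit(-30, 1), mb2 = mk_fit(-52.8, 1))
  tab <- ddh_report(fits)
  expect_equal(tab$ddh_kJ_per_mol, -22.8)
  expect_equal(tab$se_kJ_per_mol, sqrt(2))
  # identical fits: zero difference
  tab0 <- ddh_report(list(a = mk_fit(-40, 0.5), b = mk_fit(-40, 0.5)))
  expect_equal(tab0$ddh_kJ_per_mol, 0)
  expect_error(ddh_report(list(a = mk_fit(-40, 1))), "at least 2")
})
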