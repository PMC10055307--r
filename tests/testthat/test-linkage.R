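# Conformational-selection linkage model: species lattice, apparent
# affinities, cooperativity and inverse problems.

test_that("species fractions form a probability vector with the expected symmetry", {
  sch <- double_drug_scheme(
    two_state_ensemble(1),
    ligand_profile("o", "orthosteric", c(active = 10e-9, inactive = Inf)),
    ligand_profile("a", "allosteric", c(active = 100e-9, inactive = 100e-9)),
    catalytic_weights = c(active = 1, inactive = 0))
  sp <- species_fractions(sch, 0, 0)
  expect_equal(sum(sp$fraction), 1, tolerance = 1e-12)
  expect_equal(sp$fraction[sp$state == "active" & sp$occupancy == "apo"], 0.5)
  expect_equal(sp$fraction[sp$state == "inactive" & sp$occupancy == "apo"], 0.5)
  expect_true(all(sp$fraction[sp$occupancy != "apo"] == 0))

  # apo populations at the measured equilibrium constant
  sch2 <- double_drug_scheme(
    two_state_ensemble(0.67), sch$ortho, sch$allo,
    catalytic_weights = c(active = 1, inactive = 0))
  sp2 <- species_fractions(sch2, 0, 0)
  expect_equal(sp2$fraction[sp2$state == "inactive" & sp2$occupancy == "apo"],
               0.67 / 1.67, tolerance = 1e-12)

  # three finite Boltzmann terms, enumerated by hand: K_eq = 1, exclusive
  # orthosteric binder at its active-state kd -> thirds
  sp3 <- species_fractions(sch, 10e-9, 0)
  expect_equal(sp3$fraction[sp3$state == "active" & sp3$occupancy == "apo"],
               1 / 3, tolerance = 1e-12)
  expect_equal(sp3$fraction[sp3$state == "active" & sp3$occupancy == "ortho"],
               1 / 3, tolerance = 1e-12)
  expect_equal(sp3$fraction[sp3$state == "inactive" & sp3$occupancy == "apo"],
               1 / 3, tolerance = 1e-12)
})

test_that("species fractions sum to one and respect mass balance on random schemes", {
  set.seed(101)
  for (i in 1:50) {
    sch <- random_scheme(n_states = sample(2:3, 1), allow_coupling = TRUE)
    sp <- species_fractions(sch, 10^runif(1, -9, -5), 10^runif(1, -9, -5))
    expect_true(all(sp$fraction >= 0))
    expect_lt(abs(sum(sp$fraction) - 1), 1e-10)
  }
})

test_that("apparent kd is the harmonic population average", {
  ens <- two_state_ensemble(1)
  nonsel <- ligand_profile("x", "orthosteric",
                           c(active = 10e-9, inactive = 10e-9))
  expect_equal(apparent_kd(ens, nonsel), 10e-9)
  expect_equal(apparent_kd(two_state_ensemble(7.3), nonsel), 10e-9)

  sel <- ligand_profile("y", "orthosteric",
                        c(active = 10e-9, inactive = 100e-9))
  expect_equal(apparent_kd(ens, sel), 1 / (0.5 / 10e-9 + 0.5 / 100e-9))

  # inactive-exclusive ligand: K_app = K * (1 + K_eq) / K_eq
  excl <- ligand_profile("z", "orthosteric", c(active = Inf, inactive = 50e-9))
  expect_equal(apparent_kd(two_state_ensemble(0.67), excl),
               50e-9 * 1.67 / 0.67, tolerance = 1e-12)
})

test_that("apparent kd lies within the per-state kd range and matches the lattice oracle", {
  set.seed(202)
  for (i in 1:60) {
    sch <- random_scheme(n_states = sample(2:3, 1), allow_inf = FALSE,
                         allow_coupling = FALSE)
    for (probe in c("ortho", "allo")) {
      lig <- if (probe == "ortho") sch$ortho else sch$allo
      kapp <- apparent_kd(sch$ensemble, lig)
      expect_gte(kapp, min(lig$kd) * (1 - 1e-12))
      expect_lte(kapp, max(lig$kd) * (1 + 1e-12))
      expect_equal(kapp, oracle_apparent_kd(sch, probe, 0),
                   tolerance = 1e-6)
    }
  }
})

test_that("background ligand reweights the ensemble before averaging", {
  ens <- two_state_ensemble(0.67)
  probe <- ligand_profile("p", "allosteric", c(active = 100e-9, inactive = Inf))
  partner <- ligand_profile("q", "orthosteric",
                            c(active = 38.4e-9, inactive = 1e-9))
  # saturating partner shifts K_eq to K_eq * s
  kapp_sat <- apparent_kd(ens, probe, background = partner,
                          background_free = Inf)
  keq_sat <- 0.67 * 38.4
  expect_equal(kapp_sat, 100e-9 * (1 + keq_sat), tolerance = 1e-12)
  # zero background = apo
  expect_equal(apparent_kd(ens, probe, background = partner,
                           background_free = 0),
               apparent_kd(ens, probe))
  # same-site background is rejected
  same <- ligand_profile("r", "allosteric", c(active = 1e-9, inactive = 1e-9))
  expect_error(apparent_kd(ens, probe, background = same), "other site")
})

test_that("shifted ensemble follows the binding polynomial and its saturation limit", {
  ens <- two_state_ensemble(0.67)
  lig <- ligand_profile("d", "orthosteric",
                        c(active = 38.4e-9, inactive = 1e-9))
  expect_equal(unclass(shifted_ensemble(ens, lig, 0)), unclass(ens))
  # saturation: K_eq' = K_eq * kd(active)/kd(inactive)
  sat <- shifted_ensemble(ens, lig, Inf)
  expect_equal(ensemble_keq(sat), 0.67 * 38.4, tolerance = 1e-12)
  # finite concentration agrees with the analytic polynomial
  sh <- shifted_ensemble(ens, lig, 5e-9)
  expect_equal(ensemble_keq(sh),
               0.67 * (1 + 5 / 1) / (1 + 5 / 38.4), tolerance = 1e-12)
  # non-selective ligand leaves the equilibrium untouched
  nonsel <- ligand_profile("n", "orthosteric",
                           c(active = 10e-9, inactive = 10e-9))
  expect_equal(ensemble_keq(shifted_ensemble(ens, nonsel, 1e-6)), 0.67)
})

test_that("cooperativity factor reproduces the measured folds and the null", {
  ens <- two_state_ensemble(0.67)
  dan <- ligand_profile("dan", "orthosteric",
                        kd = c(active = 38.38806e-9, inactive = 1e-9))
  cw <- c(active = 1, inactive = 0)
  # active-exclusive probe: 16-fold weakening
  mb1 <- ligand_profile("mb1", "allosteric", c(active = 200e-9, inactive = Inf))
  expect_equal(cooperativity_factor(
    double_drug_scheme(ens, dan, mb1, cw), "allo"), 1 / 16, tolerance = 1e-6)
  # inactive-exclusive probe with the same partner: 2.40-fold tightening
  mbi <- ligand_profile("mbi", "allosteric", c(active = Inf, inactive = 150e-9))
  expect_equal(cooperativity_factor(
    double_drug_scheme(ens, dan, mbi, cw), "allo"),
    2.492537 / 1.038878, tolerance = 1e-4)
  # non-selective probe: alpha = 1 whatever the partner does
  mb6 <- ligand_profile("mb6", "allosteric",
                        c(active = 300e-9, inactive = 300e-9))
  expect_equal(cooperativity_factor(
    double_drug_scheme(ens, dan, mb6, cw), "allo"), 1)
  # a partner that binds no state cannot saturate
  expect_error(cooperativity_factor(
    double_drug_scheme(ens, dan, mb1, cw), "ortho"), NA)
})

test_that("cycle closure: alpha is identical for both probe choices on random schemes", {
  set.seed(303)
  for (i in 1:300) {
    sch <- random_scheme(n_states = sample(2:3, 1), allow_coupling = TRUE)
    a_allo <- tryCatch(cooperativity_factor(sch, "allo"),
                       error = function(e) NA)
    a_ortho <- tryCatch(cooperativity_factor(sch, "ortho"),
                        error = function(e) NA)
    if (is.finite(a_allo) && is.finite(a_ortho)) {
      expect_equal(a_allo, a_ortho, tolerance = 1e-9)
    }
  }
})

test_that("ceiling on shift-only cooperativity behaves across its domain", {
  expect_equal(max_cooperativity_ceiling(1), 2)
  expect_equal(max_cooperativity_ceiling(0.67), 1.67 / 0.67)
  expect_equal(max_cooperativity_ceiling(Inf), 1)
  expect_error(max_cooperativity_ceiling(0), "k_eq")
  expect_error(max_cooperativity_ceiling(-1), "k_eq")
  # strictly decreasing in K_eq
  ks <- 10^seq(-3, 3, length.out = 50)
  expect_true(all(diff(max_cooperativity_ceiling(ks)) < 0))
})

test_that("solve_selectivity inverts the linkage model and flags infeasible folds", {
  expect_equal(solve_selectivity(1, 0.67, "active_exclusive"), 1)
  expect_equal(solve_selectivity(1, 0.67, "inactive_exclusive"), 1)
  # the printed 16-fold weakening: s = (16 * 1.67 - 1) / 0.67
  s <- solve_selectivity(1 / 16, 0.67, "active_exclusive")
  expect_equal(s, (16 * 1.67 - 1) / 0.67, tolerance = 1e-12)
  # 3-fold tightening exceeds the 2.49 ceiling at K_eq = 0.67
  expect_error(solve_selectivity(3, 0.67, "inactive_exclusive"),
               "ceiling")
  # round trip through the forward model
  set.seed(404)
  for (i in 1:25) {
    k_eq <- 10^runif(1, -1, 1)
    s_true <- 10^runif(1, 0, 3)
    ens <- two_state_ensemble(k_eq)
    partner <- ligand_profile("p", "orthosteric",
                              c(active = s_true * 1e-9, inactive = 1e-9))
    cw <- c(active = 1, inactive = 0)
    probe_a <- ligand_profile("pa", "allosteric",
                              c(active = 1e-7, inactive = Inf))
    alpha <- cooperativity_factor(
      double_drug_scheme(ens, partner, probe_a, cw), "allo")
    expect_equal(solve_selectivity(alpha, k_eq, "active_exclusive"), s_true,
                 tolerance = 1e-9)
    probe_i <- ligand_profile("pi", "allosteric",
                              c(active = Inf, inactive = 1e-7))
    alpha_i <- cooperativity_factor(
      double_drug_scheme(ens, partner, probe_i, cw), "allo")
    expect_equal(solve_selectivity(alpha_i, k_eq, "inactive_exclusive"),
                 s_true, tolerance = 1e-9)
  }
})

test_that("mass balance solver matches closed forms and the excess-ligand limit", {
  one_state_kd <- 1e-6
  sch <- double_drug_scheme(
    two_state_ensemble(1e-12),  # effectively single-state
    ligand_profile("o", "orthosteric",
                   c(active = one_state_kd, inactive = one_state_kd)),
    ligand_profile("a", "allosteric", c(active = 1e-7, inactive = 1e-7)),
    catalytic_weights = c(active = 1, inactive = 0))
  # E_t = L_t = 2 uM, kd = 1 uM: bound = free = 1 uM (quadratic by hand)
  eq <- solve_free_concentrations(sch, 2e-6, 2e-6, 0)
  expect_equal(eq$free_ortho, 1e-6, tolerance = 1e-6)
  expect_equal(eq$bound_ortho, 1e-6, tolerance = 1e-6)
  expect_equal(eq$free_allo, 0)
  # all-zero totals: apo populations
  eq0 <- solve_free_concentrations(sch, 1e-6, 0, 0)
  expect_equal(eq0$free_ortho, 0)
  expect_true(all(eq0$species$fraction[eq0$species$occupancy != "apo"] == 0))
  # excess ligand: depletion negligible
  eq2 <- solve_free_concentrations(sch, 1e-8, 1e-3, 1e-3)
  expect_equal(eq2$free_ortho, 1e-3, tolerance = 0.01)
  expect_equal(eq2$free_allo, 1e-3, tolerance = 0.01)
  # random schemes satisfy mass balance to 1e-8
  set.seed(505)
  for (i in 1:20) {
    sch_r <- random_scheme(n_states = 2, allow_coupling = TRUE)
    et <- 10^runif(1, -6, -4)
    eqr <- solve_free_concentrations(sch_r, et, 10^runif(1, -7, -4),
                                     10^runif(1, -7, -4))
    expect_true(all(eqr$residual <= 1e-8))
  }
})

test_that("three-state ensemble reduces to two-state when the third weight vanishes", {
  # nested full-length model: open / closing-competent / closed
  mk <- function(w3) {
    ens <- conformational_ensemble(c("open", "cc", "closed"), c(1, 0.4, w3))
    o <- ligand_profile("o", "orthosteric",
                        c(open = 15e-9, cc = Inf, closed = Inf))
    a <- ligand_profile("a", "allosteric",
                        c(open = 40e-9, cc = 2e-9, closed = 2e-9))
    double_drug_scheme(ens, o, a,
                       catalytic_weights = c(open = 1, cc = 0, closed = 0))
  }
  ens2 <- conformational_ensemble(c("open", "cc"), c(1, 0.4))
  sch2 <- double_drug_scheme(
    ens2,
    ligand_profile("o", "orthosteric", c(open = 15e-9, cc = Inf)),
    ligand_profile("a", "allosteric", c(open = 40e-9, cc = 2e-9)),
    catalytic_weights = c(open = 1, cc = 0))
  w3 <- 1e-14
  expect_equal(cooperativity_factor(mk(w3), "allo"),
               cooperativity_factor(sch2, "allo"), tolerance = 1e-9)
  expect_equal(coopkin:::.scheme_apparent_kd(mk(w3), "ortho", 0),
               coopkin:::.scheme_apparent_kd(sch2, "ortho", 0),
               tolerance = 1e-9)
})

test_that("constructors enforce their invariants", {
  expect_error(conformational_ensemble("only", 1), "at least 2")
  expect_error(conformational_ensemble(c("a", "b"), c(1, -1)), "> 0")
  expect_error(conformational_ensemble(c("a", "a"), c(1, 1)), "unique")
  expect_error(ligand_profile("x", "orthosteric", c(a = Inf, b = Inf)),
               "binds no state")
  expect_error(ligand_profile("x", "orthosteric", c(a = -1e-9, b = 1e-9)),
               "> 0")
  ens <- two_state_ensemble(1)
  o <- ligand_profile("o", "orthosteric", c(active = 1e-9, inactive = 1e-9))
  a <- ligand_profile("a", "allosteric", c(active = 1e-9, inactive = 1e-9))
  expect_error(double_drug_scheme(ens, a, a, c(active = 1, inactive = 0)),
               "orthosteric")
  expect_error(double_drug_scheme(ens, o, a, c(active = 2, inactive = 0)),
               "0, 1")
  # mismatched state labels are a configuration error
  bad <- ligand_profile("b", "allosteric", c(open = 1e-9, closed = 1e-9))
  expect_error(double_drug_scheme(ens, o, bad, c(active = 1, inactive = 0)),
               "state")
})
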