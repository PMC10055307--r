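# Activity readout, 4PL fitting, dose extraction, jackknife, synergy grids.

test_that("kobs follows the Beer-Lambert slope conversion", {
  t <- seq(0, 300, by = 10)
  a <- 1 - 6.22e-5 * t
  res <- kobs_from_absorbance(t, a, enzyme_total = 20e-9)
  expect_equal(res$kobs, 0.5, tolerance = 1e-9)
  expect_equal(res$r_squared, 1)
  # zero slope -> zero rate
  expect_equal(kobs_from_absorbance(t, rep(1, length(t)),
                                    enzyme_total = 20e-9)$kobs, 0)
  # doubling enzyme halves kobs at fixed slope
  expect_equal(kobs_from_absorbance(t, a, enzyme_total = 40e-9)$kobs, 0.25,
               tolerance = 1e-9)
  # curvature triggers the linearity warning
  set.seed(1)
  a_curved <- 1 - 6e-5 * t + 2e-7 * t^2
  expect_warning(kobs_from_absorbance(t, a_curved, enzyme_total = 20e-9),
                 "linear")
})

test_that("predicted activity is normalized, bounded and monotone for inhibitors", {
  sch <- make_preset("AurA-danusertib-Mb2")$scheme
  expect_equal(predicted_activity(sch, 0, 0), 1)
  doses <- 10^seq(-10, -5, length.out = 30)
  act_o <- vapply(doses, function(d) predicted_activity(sch, d, 0), numeric(1))
  act_a <- vapply(doses, function(d) predicted_activity(sch, 0, d), numeric(1))
  expect_true(all(act_o >= 0 & act_o <= 1))
  expect_true(all(diff(act_o) <= 1e-12))
  expect_true(all(diff(act_a) <= 1e-12))
  # degenerate model rejected
  ens <- two_state_ensemble(1)
  dead <- double_drug_scheme(
    ens, ligand_profile("o", "orthosteric", c(active = 1e-9, inactive = 1e-9)),
    ligand_profile("a", "allosteric", c(active = 1e-9, inactive = 1e-9)),
    catalytic_weights = c(active = 0, inactive = 0))
  expect_error(predicted_activity(dead, 0, 0), "degenerate")
})

test_that("preset activity plateaus match the calibrated inhibition levels", {
  kd <- make_preset("AblKD-imatinib-asciminib")$scheme
  expect_equal(predicted_activity(kd, 0, Inf), 0.70, tolerance = 1e-9)
  fl <- make_preset("AblFL-SKI-asciminib")$scheme
  expect_equal(predicted_activity(fl, 0, Inf), 0.07, tolerance = 1e-9)
})

test_that("ATP as a state-selective competitor shifts the dose-response", {
  # open-state-selective nucleotide antagonizes an open-exclusive inhibitor
  fl <- make_preset("AblFL-imatinib-asciminib")$scheme
  atp_prof <- ligand_profile("AMPPCP", "orthosteric",
                             c(open = 50e-6, closing_competent = 100e-6,
                               closed = 100e-6))
  atp <- list(profile = atp_prof, conc = 1e-3)
  a_no <- predicted_activity(fl, 100e-9, 0)
  a_atp <- predicted_activity(fl, 100e-9, 0, atp = atp)
  expect_gt(a_atp, a_no)  # competition protects activity
  # normalization still holds with ATP present
  expect_equal(predicted_activity(fl, 0, 0, atp = atp), 1)
})

test_that("4PL fit round-trips and inverts in closed form", {
  conc <- c(0, 10^seq(-9.5, -5.5, length.out = 9))
  y <- 0.05 + (0.5 - 0.05) / (1 + (conc / 1e-7)^1.2)
  fit <- fit_4pl(conc, y)
  expect_equal(fit$ic50, 1e-7, tolerance = 1e-6)
  expect_equal(fit$hill, 1.2, tolerance = 1e-6)
  expect_equal(fit$top, 0.5, tolerance = 1e-6)
  expect_equal(fit$bottom, 0.05, tolerance = 1e-6)
  # midpoint definition
  mid <- fit$bottom + (fit$top - fit$bottom) /
    (1 + (fit$ic50 / fit$ic50)^fit$hill)
  expect_equal(mid, (fit$top + fit$bottom) / 2)
  # partial inhibition floor is recovered (30%-inhibition shape)
  y2 <- 0.35 + (0.5 - 0.35) / (1 + conc / 1e-7)
  fit2 <- fit_4pl(conc, y2)
  expect_equal((fit2$top - fit2$bottom) / fit2$top, 0.30, tolerance = 1e-4)
})

test_that("4PL recovery from noisy rates stays within 10% over 100 seeds", {
  conc <- c(0, 10^seq(-9.5, -5.5, length.out = 9))
  truth <- 1 / (1 + conc / 1e-7)
  errs <- vapply(1:100, function(seed) {
    set.seed(seed)
    y <- truth * (1 + rnorm(length(conc), 0, 0.02))
    f <- fit_4pl(conc, y)
    (f$ic50 - 1e-7) / 1e-7
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)
  expect_lt(sqrt(mean(errs^2)), 0.10)
})

test_that("dose for residual activity inverts the 4PL and the mechanistic model consistently", {
  conc <- c(0, 10^seq(-9.5, -5.5, length.out = 9))
  y <- 1 / (1 + conc / 1e-7)
  fit <- fit_4pl(conc, y)
  expect_equal(dose_for_residual_activity(fit, 0.10), 9e-7, tolerance = 1e-6)
  expect_equal(dose_for_residual_activity(fit, 0.50), 1e-7, tolerance = 1e-6)
  expect_error(dose_for_residual_activity(fit, 1.2), "between 0 and 1")

  # mechanistic inversion against 4PL-fit-then-invert on a model curve
  sch <- make_preset("AurA-danusertib-Mb2")$scheme
  act <- vapply(conc, function(d) predicted_activity(sch, d, 0), numeric(1))
  fit_m <- fit_4pl(conc, act)
  d_4pl <- dose_for_residual_activity(fit_m, 0.10)
  d_mech <- dose_for_residual_activity(sch, 0.10, allo_conc = 0)
  expect_equal(d_mech, d_4pl, tolerance = 0.02)  # 4PL is an approximant
})

test_that("asciminib alone cannot reach 10% residual activity on the kinase domain", {
  kd <- make_preset("AblKD-imatinib-asciminib")$scheme
  # mechanistic route: the 0.70 floor blocks the 10% target
  expect_error(dose_for_residual_activity(kd, 0.10, drug = "allo"),
               "unreachable")
  # empirical route: 4PL on the asciminib titration has bottom 0.70 * top
  truth <- make_preset("AblKD-imatinib-asciminib")
  dat <- gen_dose(truth, "dose_allo",
                  noise_spec("multiplicative_gaussian", 0, 1))
  fit <- fit_4pl(dat$conc_nM * 1e-9, dat$kobs_per_s)
  expect_equal(fit$bottom / fit$top, 0.70, tolerance = 1e-3)
  expect_error(dose_for_residual_activity(fit, 0.10), "unreachable")
})

test_that("jackknife SE matches closed forms and vanishes without noise", {
  res <- jackknife_se(c(1, 2, 3), mean)
  expect_equal(res$se, stats::sd(c(1, 2, 3)) / sqrt(3), tolerance = 1e-12)
  expect_equal(res$estimate, 2)
  # jackknife of IC50 on noiseless 4PL data is (numerically) zero
  conc <- c(0, 10^seq(-9.5, -5.5, length.out = 9))
  df <- data.frame(conc = conc, y = 1 / (1 + conc / 1e-7))
  res2 <- jackknife_se(df, function(d) fit_4pl(d$conc, d$y)$ic50)
  expect_lt(res2$se / res2$estimate, 1e-6)
  # perturbing one point makes it strictly positive; failed leave-one-out
  # refits are dropped with a warning and an effective-n report
  df$y[5] <- df$y[5] * 1.05
  res3 <- withCallingHandlers(
    jackknife_se(df, function(d) fit_4pl(d$conc, d$y)$ic50),
    warning = function(w) {
      expect_match(conditionMessage(w), "leave-one-out|SE uses")
      invokeRestart("muffleWarning")
    })
  expect_gt(res3$se, 0)
  expect_lte(res3$n_effective, nrow(df))
})

test_that("synergy grids capture positive and negative cooperativity in dose reductions", {
  ortho_grid <- c(0, 10^seq(-8.5, -5.5, length.out = 6))
  allo_grid <- c(0, 50e-9, 200e-9, 1000e-9)
  pos <- synergy_grid(make_preset("AblFL-SKI-asciminib")$scheme,
                      ortho_grid, allo_grid)
  neg <- synergy_grid(make_preset("AblFL-imatinib-asciminib")$scheme,
                      ortho_grid, allo_grid)
  # positive cooperativity: orthosteric dose decreases with the co-drug
  expect_true(all(diff(pos$dose_reduction$dose_10pct) < 0))
  expect_true(all(pos$dose_reduction$fold_reduction[-1] > 1))
  # negative cooperativity: smaller fold-reduction at matched co-drug levels
  expect_true(all(neg$dose_reduction$fold_reduction[-1] <
                    pos$dose_reduction$fold_reduction[-1]))
  # zero-co-drug row reduces to the single-drug curve
  ski_scheme <- make_preset("AblFL-SKI-asciminib")$scheme
  single <- vapply(ortho_grid, function(d) {
    predicted_activity(ski_scheme, d, 0)
  }, numeric(1))
  expect_equal(unname(pos$activity[1, ]), single, tolerance = 1e-12)
  # activities are proper fractions
  expect_true(all(pos$activity >= 0 & pos$activity <= 1))
  # invalid grids are rejected
  expect_error(synergy_grid(make_preset("null")$scheme,
                            c(1e-9, 1e-8), allo_grid), "zero")
})

test_that("the AurA presets order the danusertib dose requirement: Mb3 < Mb2 < apo", {
  d_apo <- dose_for_residual_activity(
    make_preset("AurA-danusertib-Mb2")$scheme, 0.10, allo_conc = 0)
  d_mb2 <- dose_for_residual_activity(
    make_preset("AurA-danusertib-Mb2")$scheme, 0.10, allo_conc = Inf)
  d_mb3 <- dose_for_residual_activity(
    make_preset("AurA-danusertib-Mb3")$scheme, 0.10, allo_conc = Inf)
  expect_lt(d_mb3, d_mb2)
  expect_lt(d_mb2, d_apo)
})
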