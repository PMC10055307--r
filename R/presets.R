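#' Ground-truth preset schemes for the studied kinase systems
#'
#' Builds a fully specified [double_drug_scheme()] plus experiment designs
#' and analytically derived truth values for one of the studied
#' orthosteric/allosteric combinations. Printed constants (equilibrium
#' constant, cooperativity folds, dissociation constants, inhibition
#' plateaus) are encoded directly; quantities the experiments do not pin
#' down (absolute monobody affinities, enthalpy magnitudes) use documented
#' defaults flagged in `$assumptions`.
#'
#' Available presets:
#' \describe{
#'   \item{`AurA-danusertib-Mb1`}{Aurora A (`K_eq = 0.67` inactive/active)
#'     with the inactive-selective orthosteric inhibitor danusertib
#'     (selectivity inverted from the 16-fold weakening of the
#'     active-exclusive monobody Mb1) and Mb1 as the allosteric ligand.}
#'   \item{`AurA-danusertib-Mb2`}{Inhibiting monobody whose
#'     inactive-selectivity is calibrated so the shift-only model yields
#'     exactly its 2-fold positive cooperativity with danusertib.}
#'   \item{`AurA-danusertib-Mb3`}{Stronger inhibiting monobody; its 3-fold
#'     cooperativity exceeds the shift-only ceiling, so the preset carries a
#'     calibrated extra-affinity coupling on the doubly-bound inactive state.}
#'   \item{`AurA-danusertib-Mb6`}{Non-selective monobody, the cooperativity
#'     null (`alpha = 1`).}
#'   \item{`AblKD-imatinib-asciminib`}{Abl kinase domain: open /
#'     closing-competent two-state ensemble; imatinib open-exclusive with
#'     `Kd = 15 nM`; asciminib selectivity calibrated so saturation leaves
#'     30% of the domain closing-competent (30% inhibition plateau).}
#'   \item{`AblFL-SKI-asciminib`}{Full-length Abl: open / closing-competent
#'     / closed three-state ensemble with weights calibrated to the 5-fold
#'     imatinib preference (15 vs 72.4 nM) and the 93% asciminib inhibition
#'     plateau; SKI closed-selective with its 5-fold full-length preference.}
#'   \item{`AblFL-imatinib-asciminib`}{Same full-length ensemble with
#'     imatinib as the orthosteric drug (negative-cooperativity reference
#'     for the synergy grids).}
#'   \item{`null`}{Two-state ensemble with non-selective ligands at both
#'     sites: `alpha = 1` by construction.}
#' }
#'
#' @param name preset name (see Details).
#' @return An object of class `ground_truth`: list with `name`, `scheme`,
#'   `designs` (ITC/FRET/dose-response experiment designs), `truth`
#'   (analytic apparent Kds, cooperativity factor, activity floor),
#'   and `assumptions` (character).
#' @export
make_preset <- function(name) {
  builders <- list(
    "AurA-danusertib-Mb1" = function() .preset_aura("Mb1"),
    "AurA-danusertib-Mb2" = function() .preset_aura("Mb2"),
    "AurA-danusertib-Mb3" = function() .preset_aura("Mb3"),
    "AurA-danusertib-Mb6" = function() .preset_aura("Mb6"),
    "AblKD-imatinib-asciminib" = .preset_ablkd,
    "AblFL-SKI-asciminib" = function() .preset_ablfl("SKI"),
    "AblFL-imatinib-asciminib" = function() .preset_ablfl("imatinib"),
    "null" = .preset_null
  )
  if (!name %in% names(builders)) {
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(builders), collapse = ", ")), call. = FALSE)
  }
  builders[[name]]()
}

#' @rdname make_preset
#' @export
preset_names <- function() {
  c("AurA-danusertib-Mb1", "AurA-danusertib-Mb2", "AurA-danusertib-Mb3",
    "AurA-danusertib-Mb6", "AblKD-imatinib-asciminib", "AblFL-SKI-asciminib",
    "AblFL-imatinib-asciminib", "null")
}

# assemble the ground_truth object with analytic derived quantities
.finish_truth <- function(name, scheme, designs, assumptions) {
  truth <- list(
    alpha = cooperativity_factor(scheme, "allo"),
    kd_app_ortho_apo = .scheme_apparent_kd(scheme, "ortho", 0),
    kd_app_ortho_sat = .scheme_apparent_kd(scheme, "ortho", Inf),
    kd_app_allo_apo = .scheme_apparent_kd(scheme, "allo", 0),
    kd_app_allo_sat = .scheme_apparent_kd(scheme, "allo", Inf),
    activity_floor_allo = tryCatch(predicted_activity(scheme, 0, Inf),
                                   error = function(e) NA_real_)
  )
  structure(list(name = name, scheme = scheme, designs = designs,
                 truth = truth, assumptions = assumptions),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground-truth preset '%s'\n", x$name))
  print(x$scheme)
  cat(sprintf("  cooperativity alpha = %.4g (%s)\n", x$truth$alpha,
              if (x$truth$alpha > 1) "positive" else if (x$truth$alpha < 1)
                "negative" else "independent"))
  cat(sprintf("  apparent Kd (allo): apo %.4g nM -> partner-saturated %.4g nM\n",
              x$truth$kd_app_allo_apo * 1e9, x$truth$kd_app_allo_sat * 1e9))
  if (is.finite(x$truth$activity_floor_allo)) {
    cat(sprintf("  activity floor at saturating allosteric drug: %.3f\n",
                x$truth$activity_floor_allo))
  }
  cat(sprintf("  designs: %s\n", paste(names(x$designs), collapse = ", ")))
  invisible(x)
}

.preset_aura <- function(mb) {
  k_eq <- 0.67                       # inactive/active, apo Aurora A
  ens <- two_state_ensemble(k_eq)
  # danusertib selectivity from the 16-fold weakening of active-exclusive Mb1
  s_dan <- solve_selectivity(1 / 16, k_eq, "active_exclusive")
  kd_dan_inactive <- 1e-9            # assumed scale (low-nanomolar binder)
  dan <- ligand_profile("danusertib", "orthosteric",
                        kd = c(active = s_dan * kd_dan_inactive,
                               inactive = kd_dan_inactive),
                        dh = c(active = -37.2, inactive = -60.0))
  assumptions <- c(
    "danusertib kd(inactive) = 1 nM: absolute scale assumed (only folds are printed)",
    "danusertib dH(active) - dH(inactive) = 22.8 kJ/mol; magnitudes assumed",
    "monobody intrinsic Kds at the 10^2 nM scale: assumed")
  coupling <- NULL
  if (mb == "Mb1") {
    allo <- ligand_profile("Mb1", "allosteric",
                           kd = c(active = 200e-9, inactive = Inf),
                           dh = c(active = -35))
    syringe_um <- 150
  } else if (mb == "Mb2") {
    # selectivity calibrated so the shift-only model gives exactly 2-fold
    kd_inact <- 150e-9
    r <- .calibrate_mb_selectivity(ens, dan, kd_inact, target_alpha = 2)
    allo <- ligand_profile("Mb2", "allosteric",
                           kd = c(active = r * kd_inact, inactive = kd_inact),
                           dh = c(active = -45, inactive = -45))
    syringe_um <- 150
    assumptions <- c(assumptions,
                     "Mb2 selectivity solved from its 2-fold cooperativity under the shift-only model")
  } else if (mb == "Mb3") {
    # stronger conformational shift than Mb2, plus extra affinity to the
    # drug-bound inactive state (3-fold exceeds the shift-only ceiling)
    kd_inact <- 150e-9
    r3 <- 15
    allo <- ligand_profile("Mb3", "allosteric",
                           kd = c(active = r3 * kd_inact, inactive = kd_inact),
                           dh = c(active = -45, inactive = -45))
    g <- .calibrate_coupling(ens, dan, allo, target_alpha = 3,
                             state = "inactive")
    coupling <- c(inactive = g)
    syringe_um <- 90.9
    assumptions <- c(assumptions,
                     "Mb3 state selectivity 15 assumed (stronger inhibitor than Mb2); doubly-bound coupling solved from its 3-fold cooperativity")
  } else if (mb == "Mb6") {
    allo <- ligand_profile("Mb6", "allosteric",
                           kd = c(active = 300e-9, inactive = 300e-9),
                           dh = c(active = -30, inactive = -30))
    syringe_um <- 51.7
  } else stop("unknown monobody ", mb)
  scheme <- double_drug_scheme(ens, dan, allo,
                               catalytic_weights = c(active = 1, inactive = 0),
                               coupling = coupling)
  cell_um <- if (mb == "Mb6") 8 else 20
  designs <- list(
    itc_allo_apo = list(kind = "itc_direct", ligand = "allo",
                        cell_enzyme = cell_um * 1e-6,
                        syringe = syringe_um * 1e-6,
                        n_injections = 25, injection_volume = 2e-6),
    itc_allo_drugged = list(kind = "itc_scheme", syringe_ligand = "allo",
                            cell_enzyme = cell_um * 1e-6,
                            cell_partner = 150e-6,
                            syringe = (if (mb == "Mb1") 384 else syringe_um) * 1e-6,
                            n_injections = 25, injection_volume = 2e-6),
    itc_displacement = list(kind = "itc_displacement",
                            cell_enzyme = 20e-6, cell_weak = 2000e-6,
                            kd_weak = 20e-6, dh_weak = -20,
                            syringe = 150e-6,
                            n_injections = 25, injection_volume = 2e-6),
    dose_response = list(kind = "dose", ortho_concs =
                           c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                         allo_conc = 0, kobs0 = 0.5, replicates = 2),
    dose_response_mb = list(kind = "dose", ortho_concs =
                              c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                            allo_conc = Inf, kobs0 = 0.5, replicates = 2)
  )
  .finish_truth(paste0("AurA-danusertib-", mb), scheme, designs, assumptions)
}

# monobody selectivity r = kd(active)/kd(inactive) reproducing a target
# shift-only cooperativity with the given orthosteric partner
.calibrate_mb_selectivity <- function(ens, ortho, kd_inactive, target_alpha) {
  f <- function(log_r) {
    allo <- ligand_profile("probe", "allosteric",
                           kd = c(active = exp(log_r) * kd_inactive,
                                  inactive = kd_inactive))
    sch <- double_drug_scheme(ens, ortho, allo,
                              catalytic_weights = c(active = 1, inactive = 0))
    cooperativity_factor(sch, "allo") - target_alpha
  }
  exp(stats::uniroot(f, c(log(1.0001), log(1e8)), tol = 1e-12)$root)
}

# doubly-bound coupling factor on one state reproducing a target
# cooperativity that exceeds the shift-only value
.calibrate_coupling <- function(ens, ortho, allo, target_alpha, state) {
  f <- function(log_g) {
    cp <- stats::setNames(exp(log_g), state)
    sch <- double_drug_scheme(ens, ortho, allo,
                              catalytic_weights = c(active = 1, inactive = 0),
                              coupling = cp)
    cooperativity_factor(sch, "allo") - target_alpha
  }
  exp(stats::uniroot(f, c(log(1e-3), log(1e6)), tol = 1e-12)$root)
}

.preset_ablkd <- function() {
  k_eq0 <- 0.02  # closing-competent/open; the apo domain is essentially open
  ens <- conformational_ensemble(c("open", "closing_competent"), c(1, k_eq0))
  # asciminib selectivity solved so the saturated activity floor is 70% of
  # the uninhibited rate (the measured 30% inhibition plateau); the
  # closing-competent fraction at saturation is then ~0.31, the printed
  # ~0.30 up to the small apo closing-competent population
  s_asc <- ((1 + k_eq0) / 0.70 - 1) / k_eq0
  kd_asc_cc <- 2e-9
  ima <- ligand_profile("imatinib", "orthosteric",
                        kd = c(open = 15e-9, closing_competent = Inf),
                        dh = c(open = -45))
  asc <- ligand_profile("asciminib", "allosteric",
                        kd = c(open = s_asc * kd_asc_cc,
                               closing_competent = kd_asc_cc),
                        dh = c(open = -40, closing_competent = -50))
  scheme <- double_drug_scheme(ens, ima, asc,
                               catalytic_weights = c(open = 1,
                                                     closing_competent = 0))
  ski <- .ski_profile_kd()
  designs <- list(
    itc_ortho_apo = list(kind = "itc_direct", ligand = "ortho",
                         cell_enzyme = 15e-6, syringe = 100e-6,
                         n_injections = 30, injection_volume = 1.5e-6),
    itc_displacement = list(kind = "itc_displacement",
                            cell_enzyme = 25e-6, cell_weak = 300e-6,
                            kd_weak = 40e-6, dh_weak = -15,
                            syringe = 250e-6,
                            n_injections = 30, injection_volume = 1.5e-6),
    fret_apo = list(kind = "fret", ligand = ski, et = 10e-9,
                    background_free = 0,
                    concs = c(0, 10^seq(-8.7, -5.7, length.out = 11)),
                    f0 = 1, amplitude = 2, replicates = 3),
    fret_asc = list(kind = "fret", ligand = ski, et = 10e-9,
                    background_free = 200e-9,
                    concs = c(0, 10^seq(-8.7, -5.7, length.out = 11)),
                    f0 = 1, amplitude = 2, replicates = 3),
    dose_allo = list(kind = "dose_allo", allo_concs =
                       c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                     kobs0 = 0.5, replicates = 2),
    dose_response = list(kind = "dose", ortho_concs =
                           c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                         allo_conc = 0, kobs0 = 0.5, replicates = 2)
  )
  .finish_truth("AblKD-imatinib-asciminib", scheme, designs, c(
    "apo closing-competent/open weight 0.02: the isolated domain is essentially open (assumed)",
    "asciminib selectivity solved from the 30% inhibition plateau",
    "asciminib kd(closing-competent) = 2 nM: absolute scale assumed"))
}

# SKI profile on the kinase-domain ensemble (tied sub-state kds)
.ski_profile_kd <- function() {
  r_s <- .ablfl_constants()$r_ski
  k_s <- 40e-9
  ligand_profile("SKI", "orthosteric",
                 kd = c(open = r_s * k_s, closing_competent = k_s),
                 dh = c(open = 0, closing_competent = 0))
}

# shared full-length Abl calibration: ensemble weights from the printed
# 15 vs 72.4 nM imatinib Kds; asciminib open-state affinity from the 93%
# inhibition plateau; SKI selectivity from its 5-fold full-length preference
.ablfl_constants <- function() {
  w_cc <- 0.02                       # tied to the kinase-domain equilibrium
  total <- 72.4 / 15                 # 1/f_open(apo) of the full-length enzyme
  w_cl <- total - 1 - w_cc
  # asciminib open-state kd ratio solved so saturation leaves 7% of the
  # uninhibited rate (the 93% inhibition plateau, normalized to apo)
  t_open <- 0.07 / total             # absolute open fraction at saturation
  beta <- (1 - t_open) / (t_open * (w_cc + w_cl))
  # SKI selectivity r: apparent Kd on the domain = 5 x apparent on full-length
  f <- function(log_r) {
    r <- exp(log_r)
    inv_kd_app_kd <- (1 / r + w_cc) / (1 + w_cc)
    inv_kd_app_fl <- (1 / r + w_cc + w_cl) / (1 + w_cc + w_cl)
    inv_kd_app_fl / inv_kd_app_kd - 5
  }
  r_ski <- exp(stats::uniroot(f, c(log(1.001), log(1e6)), tol = 1e-12)$root)
  list(w_cc = w_cc, w_cl = w_cl, beta = beta, r_ski = r_ski)
}

.preset_ablfl <- function(ortho_drug) {
  cst <- .ablfl_constants()
  ens <- conformational_ensemble(c("open", "closing_competent", "closed"),
                                 c(1, cst$w_cc, cst$w_cl))
  kd_asc <- 2e-9
  asc <- ligand_profile("asciminib", "allosteric",
                        kd = c(open = cst$beta * kd_asc,
                               closing_competent = kd_asc, closed = kd_asc),
                        dh = c(open = -40, closing_competent = -50,
                               closed = -50))
  if (ortho_drug == "SKI") {
    k_s <- 40e-9
    ortho <- ligand_profile("SKI", "orthosteric",
                            kd = c(open = cst$r_ski * k_s,
                                   closing_competent = k_s, closed = k_s),
                            dh = c(open = 0, closing_competent = 0, closed = 0))
  } else {
    ortho <- ligand_profile("imatinib", "orthosteric",
                            kd = c(open = 15e-9, closing_competent = Inf,
                                   closed = Inf),
                            dh = c(open = -45))
  }
  scheme <- double_drug_scheme(
    ens, ortho, asc,
    catalytic_weights = c(open = 1, closing_competent = 0, closed = 0))
  designs <- list(
    itc_ortho_apo = list(kind = "itc_direct", ligand = "ortho",
                         cell_enzyme = 15e-6, syringe = 100e-6,
                         n_injections = 30, injection_volume = 1.5e-6),
    itc_displacement = list(kind = "itc_displacement",
                            cell_enzyme = 25.5e-6, cell_weak = 300e-6,
                            kd_weak = 40e-6, dh_weak = -15,
                            syringe = 250e-6,
                            n_injections = 30, injection_volume = 1.5e-6),
    fret_apo = list(kind = "fret", ligand = NULL, et = 10e-9,
                    background_free = 0,
                    concs = c(0, 10^seq(-8.7, -5.7, length.out = 11)),
                    f0 = 1, amplitude = 2, replicates = 3),
    dose_allo = list(kind = "dose_allo", allo_concs =
                       c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                     kobs0 = 0.5, replicates = 2),
    dose_response = list(kind = "dose", ortho_concs =
                           c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                         allo_conc = 0, kobs0 = 0.5, replicates = 2),
    synergy = list(kind = "grid",
                   ortho_grid = c(0, 10^seq(-8.5, -5.5, length.out = 6)),
                   allo_grid = c(0, 50e-9, 200e-9, 1000e-9),
                   kobs0 = 0.5)
  )
  name <- paste0("AblFL-", ortho_drug, "-asciminib")
  .finish_truth(name, scheme, designs, c(
    "full-length ensemble weights calibrated to the 15 vs 72.4 nM imatinib Kds with the closing-competent weight tied to the domain's 0.02",
    "asciminib open-state affinity solved from the 93% inhibition plateau",
    if (ortho_drug == "SKI")
      "SKI selectivity solved from its 5-fold full-length preference; SKI dH = 0 (no detectable titration heat)"))
}

.preset_null <- function() {
  ens <- two_state_ensemble(1)
  ortho <- ligand_profile("orthoX", "orthosteric",
                          kd = c(active = 10e-9, inactive = 10e-9),
                          dh = c(active = -40, inactive = -40))
  allo <- ligand_profile("alloX", "allosteric",
                         kd = c(active = 100e-9, inactive = 100e-9),
                         dh = c(active = -40, inactive = -40))
  scheme <- double_drug_scheme(ens, ortho, allo,
                               catalytic_weights = c(active = 1, inactive = 0))
  designs <- list(
    itc_allo_apo = list(kind = "itc_direct", ligand = "allo",
                        cell_enzyme = 20e-6, syringe = 150e-6,
                        n_injections = 25, injection_volume = 2e-6),
    dose_response = list(kind = "dose", ortho_concs =
                           c(0, 10^seq(-9.5, -5.5, length.out = 9)),
                         allo_conc = 0, kobs0 = 0.5, replicates = 2)
  )
  .finish_truth("null", scheme, designs,
                "synthetic null system: non-selective ligands, alpha = 1")
}
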