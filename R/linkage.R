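#' Equilibrium species fractions of the double-drugging lattice
#'
#' Evaluates the partition function of the `4 * n_states` species lattice
#' (each conformation crossed with apo / orthosteric-bound /
#' allosteric-bound / doubly-bound) at given free ligand concentrations.
#' The Boltzmann weight of species (state s, occupancy o) is the state's
#' statistical weight multiplied by `free/kd` for each occupied site (and by
#' the state's coupling factor when both sites are occupied).
#'
#' @param scheme a [double_drug_scheme()].
#' @param free_ortho,free_allo free ligand concentrations (molar, >= 0).
#' @return An object of class `species_population`: a data frame with
#'   columns `state`, `occupancy` (`apo`, `ortho`, `allo`, `both`) and
#'   `fraction`, plus attributes `free_ortho` and `free_allo`.
#' @examples
#' sch <- double_drug_scheme(
#'   two_state_ensemble(0.67),
#'   ligand_profile("dan", "orthosteric", c(active = 38.4e-9, inactive = 1e-9)),
#'   ligand_profile("mb", "allosteric", c(active = 2e-7, inactive = Inf)),
#'   catalytic_weights = c(active = 1, inactive = 0))
#' species_fractions(sch, 0, 0)
#' @export
species_fractions <- function(scheme, free_ortho, free_allo) {
  stopifnot(inherits(scheme, "double_drug_scheme"))
  if (free_ortho < 0 || free_allo < 0) {
    stop("free concentrations must be >= 0", call. = FALSE)
  }
  states <- names(scheme$ensemble)
  w <- unclass(scheme$ensemble)
  ao <- .assoc(scheme$ortho, states)
  aa <- .assoc(scheme$allo, states)
  g <- scheme$coupling
  terms <- cbind(apo  = w,
                 ortho = w * free_ortho * ao,
                 allo  = w * free_allo * aa,
                 both  = w * g * free_ortho * ao * free_allo * aa)
  z <- sum(terms)
  frac <- terms / z
  out <- data.frame(state = rep(states, times = 4L),
                    occupancy = rep(colnames(terms), each = length(states)),
                    fraction = as.vector(frac),
                    stringsAsFactors = FALSE)
  structure(out, class = c("species_population", "data.frame"),
            free_ortho = free_ortho, free_allo = free_allo)
}

# fraction of enzyme with a given site occupied, at free concentrations
.site_bound_fraction <- function(scheme, free_ortho, free_allo, site) {
  sp <- species_fractions(scheme, free_ortho, free_allo)
  occ <- if (site == "orthosteric") c("ortho", "both") else c("allo", "both")
  sum(sp$fraction[sp$occupancy %in% occ])
}

#' Apparent (ensemble-averaged) dissociation constant
#'
#' The observable dissociation constant of a state-selective ligand against
#' a conformational ensemble is the harmonic population average
#' `1/K_app = sum_s f_s / kd_s`, where `f_s` are the populations of the
#' ligand-free ensemble. A background ligand at the other site reweights
#' the ensemble by its own binding polynomial `(1 + free_bg/kd_bg,s)`
#' before averaging; `background_free = Inf` applies the analytic
#' saturation limit (weights proportional to `w_s / kd_bg,s`).
#'
#' @param ensemble a [conformational_ensemble()].
#' @param ligand a [ligand_profile()].
#' @param background optional [ligand_profile()] occupying the other site.
#' @param background_free free concentration (molar) of the background
#'   ligand; may be `Inf` for saturation.
#' @return Apparent dissociation constant (molar).
#' @examples
#' ens <- two_state_ensemble(1)
#' lig <- ligand_profile("x", "orthosteric", c(active = 1e-8, inactive = 1e-7))
#' apparent_kd(ens, lig)  # 18.18 nM
#' @export
apparent_kd <- function(ensemble, ligand, background = NULL,
                        background_free = Inf) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(ligand, "ligand_profile"))
  states <- names(ensemble)
  w <- unclass(ensemble)
  if (!is.null(background)) {
    stopifnot(inherits(background, "ligand_profile"))
    if (background$site == ligand$site) {
      stop("background ligand must occupy the other site", call. = FALSE)
    }
    ab <- .assoc(background, states)
    if (is.infinite(background_free)) {
      w <- w * ab                       # saturation limit
    } else {
      if (background_free < 0) stop("background_free must be >= 0", call. = FALSE)
      w <- w * (1 + background_free * ab)
    }
    if (all(w == 0)) {
      stop("background ligand binds no state: cannot saturate", call. = FALSE)
    }
  }
  a <- .assoc(ligand, states)
  inv_kapp <- sum(w * a) / sum(w)
  if (inv_kapp == 0) {
    stop(sprintf("ligand '%s' binds no populated state: affinity undefined",
                 ligand$name), call. = FALSE)
  }
  1 / inv_kapp
}

#' Ensemble reweighted by a bound ligand
#'
#' Exposure to a state-selective ligand at free concentration `free` shifts
#' the conformational equilibrium: each state's weight is multiplied by its
#' binding polynomial `(1 + free/kd_s)`. At saturation (`free = Inf`, all
#' relevant kds finite) the two-state equilibrium constant becomes
#' `K_eq' = K_eq * s` with `s = kd(state 1)/kd(state 2)`.
#'
#' @inheritParams apparent_kd
#' @param free free ligand concentration (molar), possibly `Inf`.
#' @return A new `conformational_ensemble` (weights renormalized to the
#'   first state when possible). States excluded by a saturating exclusive
#'   ligand get weight 0 in the returned raw weights.
#' @export
shifted_ensemble <- function(ensemble, ligand, free) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(ligand, "ligand_profile"))
  if (free < 0) stop("free concentration must be >= 0", call. = FALSE)
  states <- names(ensemble)
  a <- .assoc(ligand, states)
  w <- if (is.infinite(free)) unclass(ensemble) * a
       else unclass(ensemble) * (1 + free * a)
  if (all(w == 0)) stop("ligand binds no state: shifted ensemble empty", call. = FALSE)
  ref <- if (w[1L] > 0) w[1L] else max(w)
  w <- w / ref
  if (any(w == 0)) {
    # saturating exclusive binder empties some states: keep zero weights,
    # bypassing the constructor's strict-positivity check
    structure(w, class = "conformational_ensemble")
  } else {
    conformational_ensemble(states, w)
  }
}

# apparent kd of one ligand of a scheme with the partner at free conc c
# (supports c = Inf and the doubly-bound coupling factor)
.scheme_apparent_kd <- function(scheme, probe = c("ortho", "allo"),
                                partner_free = 0) {
  probe <- match.arg(probe)
  states <- names(scheme$ensemble)
  w <- unclass(scheme$ensemble)
  ap <- .assoc(if (probe == "ortho") scheme$ortho else scheme$allo, states)
  ab <- .assoc(if (probe == "ortho") scheme$allo else scheme$ortho, states)
  g <- scheme$coupling
  if (is.infinite(partner_free)) {
    if (all(ab == 0)) stop("partner binds no state: cannot saturate", call. = FALSE)
    num <- sum(w * ab)            # probe-free partition, saturated
    den <- sum(w * ab * g * ap)   # probe-bound partition, saturated
  } else {
    num <- sum(w * (1 + partner_free * ab))
    den <- sum(w * ap * (1 + partner_free * g * ab))
  }
  if (den == 0) stop("probe binds no populated state: affinity undefined", call. = FALSE)
  num / den
}

#' Cooperativity factor between the two ligands of a scheme
#'
#' The cooperativity factor is the fold-change in a probe ligand's apparent
#' dissociation constant caused by saturating the enzyme with the partner
#' ligand at the other site:
#' `alpha = K_app(probe | apo) / K_app(probe | partner saturating)`.
#' `alpha > 1` is positive cooperativity (tightening), `alpha < 1` negative.
#' Thermodynamic cycle closure guarantees the identical value whichever
#' ligand is taken as the probe; saturation is evaluated as the analytic
#' `free -> Inf` limit.
#'
#' @param scheme a [double_drug_scheme()].
#' @param probe which ligand's affinity change to report (the result is
#'   probe-independent; the argument exists to express the experiment).
#' @return Dimensionless fold-change `alpha`.
#' @export
cooperativity_factor <- function(scheme, probe = c("ortho", "allo")) {
  probe <- match.arg(probe)
  stopifnot(inherits(scheme, "double_drug_scheme"))
  kapp_apo <- .scheme_apparent_kd(scheme, probe, partner_free = 0)
  kapp_sat <- .scheme_apparent_kd(scheme, probe, partner_free = Inf)
  kapp_apo / kapp_sat
}

#' Ceiling on shift-only positive cooperativity
#'
#' Under the two-state model with `K_eq = [inactive]/[active]`, an
#' inactive-state-exclusive probe can be tightened at most
#' `(1 + K_eq)/K_eq`-fold by a partner that shifts the equilibrium, however
#' inactive-selective that partner is. Observed cooperativities above this
#' ceiling require extra state-specific affinity beyond equilibrium shift.
#'
#' @param k_eq two-state equilibrium constant, inactive/active (> 0).
#' @return The supremum fold-change (dimensionless).
#' @examples
#' max_cooperativity_ceiling(0.67)  # 2.4925
#' @export
max_cooperativity_ceiling <- function(k_eq) {
  if (any(is.na(k_eq)) || any(k_eq <= 0)) {
    stop("k_eq must be > 0", call. = FALSE)
  }
  ifelse(is.infinite(k_eq), 1, (1 + k_eq) / k_eq)
}

#' Solve the two-state linkage model for partner selectivity
#'
#' Inverts the cooperativity relation of the two-state model: given an
#' observed fold-change `alpha` for an exclusive probe and the equilibrium
#' constant `K_eq` (inactive/active), returns the partner's
#' inactive-selectivity ratio `s = kd(active)/kd(inactive)` that reproduces
#' it. For an active-exclusive probe a weakening (`alpha < 1`) solves
#' `(1 + K_eq*s)/(1 + K_eq) = 1/alpha`; for an inactive-exclusive probe a
#' tightening (`alpha > 1`) solves
#' `alpha = [(1+K_eq)/K_eq] * [K_eq*s/(1+K_eq*s)]`, which is only feasible
#' below [max_cooperativity_ceiling()].
#'
#' @param alpha_observed observed cooperativity factor (fold; > 0).
#' @param k_eq two-state equilibrium constant, inactive/active.
#' @param probe `"active_exclusive"` or `"inactive_exclusive"`.
#' @return Selectivity ratio `s` of the partner ligand.
#' @examples
#' solve_selectivity(1 / 16, 0.67, "active_exclusive")  # 38.4
#' @export
solve_selectivity <- function(alpha_observed, k_eq,
                              probe = c("active_exclusive",
                                        "inactive_exclusive")) {
  probe <- match.arg(probe)
  if (!is.finite(alpha_observed) || alpha_observed <= 0) {
    stop("alpha_observed must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(k_eq) || k_eq <= 0) stop("k_eq must be > 0", call. = FALSE)
  if (probe == "active_exclusive") {
    if (alpha_observed > 1) {
      stop("an active-exclusive probe can only be weakened (alpha <= 1) by ",
           "an inactive-selective partner", call. = FALSE)
    }
    weakening <- 1 / alpha_observed
    s <- (weakening * (1 + k_eq) - 1) / k_eq
  } else {
    ceiling_ <- max_cooperativity_ceiling(k_eq)
    if (alpha_observed >= ceiling_) {
      stop(sprintf(paste0(
        "requested %.3g-fold tightening exceeds the shift-only ceiling ",
        "%.4g at k_eq = %.3g: extra state-specific affinity is required"),
        alpha_observed, ceiling_, k_eq), call. = FALSE)
    }
    if (alpha_observed < 1) {
      stop("an inactive-exclusive probe is only tightened (alpha >= 1) by ",
           "an inactive-selective partner", call. = FALSE)
    }
    s <- alpha_observed / (1 + k_eq - alpha_observed * k_eq)
  }
  if (s < 0) stop("no feasible selectivity for these inputs", call. = FALSE)
  s
}

#' Free ligand concentrations from totals (mass balance)
#'
#' Solves the coupled mass-balance equations for a scheme when enzyme and
#' ligand concentrations are comparable (the regime of ITC and FRET), by
#' nested safeguarded root-finding on the box `[0, total]` for each ligand.
#'
#' @param scheme a [double_drug_scheme()].
#' @param total_enzyme,total_ortho,total_allo total concentrations (molar).
#' @param tol relative mass-balance tolerance.
#' @return A list with `free_ortho`, `free_allo`, the `species_population`
#'   at those frees, bound concentrations and the residual relative errors.
#' @export
solve_free_concentrations <- function(scheme, total_enzyme, total_ortho,
                                      total_allo, tol = 1e-10) {
  stopifnot(inherits(scheme, "double_drug_scheme"))
  if (total_enzyme < 0 || total_ortho < 0 || total_allo < 0) {
    stop("total concentrations must be >= 0", call. = FALSE)
  }
  bound <- function(fo, fa, site) {
    total_enzyme * .site_bound_fraction(scheme, fo, fa, site)
  }
  solve_inner <- function(fo) {
    if (total_allo == 0) return(0)
    h <- function(fa) total_allo - fa - bound(fo, fa, "allosteric")
    if (h(total_allo) >= 0) return(total_allo)
    stats::uniroot(h, c(0, total_allo), tol = tol * max(total_allo, 1e-12),
                   maxiter = 200)$root
  }
  if (total_ortho == 0) {
    fo <- 0
    fa <- solve_inner(0)
  } else {
    gfun <- function(fo) {
      fa <- solve_inner(fo)
      total_ortho - fo - bound(fo, fa, "orthosteric")
    }
    fo <- if (gfun(total_ortho) >= 0) total_ortho else {
      stats::uniroot(gfun, c(0, total_ortho),
                     tol = tol * max(total_ortho, 1e-12), maxiter = 200)$root
    }
    fa <- solve_inner(fo)
  }
  # damped 2-D Newton polish (finite-difference Jacobian): the bracketed
  # roots above can leave steep-slope residuals when the enzyme is in
  # large excess over a tight ligand
  resid <- function(fo, fa) {
    c(total_ortho - fo - bound(fo, fa, "orthosteric"),
      total_allo - fa - bound(fo, fa, "allosteric"))
  }
  rel_res <- function(r) {
    max(if (total_ortho > 0) abs(r[1]) / total_ortho else 0,
        if (total_allo > 0) abs(r[2]) / total_allo else 0)
  }
  r <- resid(fo, fa)
  for (it in 1:40) {
    if (rel_res(r) <= tol) break
    ho <- max(abs(fo), total_ortho * 1e-9, 1e-18) * 1e-6
    ha <- max(abs(fa), total_allo * 1e-9, 1e-18) * 1e-6
    j11 <- (resid(fo + ho, fa)[1] - r[1]) / ho
    j21 <- (resid(fo + ho, fa)[2] - r[2]) / ho
    j12 <- (resid(fo, fa + ha)[1] - r[1]) / ha
    j22 <- (resid(fo, fa + ha)[2] - r[2]) / ha
    det <- j11 * j22 - j12 * j21
    if (!is.finite(det) || det == 0) break
    dfo <- (r[1] * j22 - r[2] * j12) / det
    dfa <- (j11 * r[2] - j21 * r[1]) / det
    fo_new <- min(max(fo - dfo, 0), total_ortho)
    fa_new <- min(max(fa - dfa, 0), total_allo)
    r_new <- resid(fo_new, fa_new)
    if (rel_res(r_new) >= rel_res(r)) break  # no further improvement
    fo <- fo_new; fa <- fa_new; r <- r_new
  }
  sp <- species_fractions(scheme, fo, fa)
  bo <- bound(fo, fa, "orthosteric")
  ba <- bound(fo, fa, "allosteric")
  res_o <- if (total_ortho > 0) abs(total_ortho - fo - bo) / total_ortho else 0
  res_a <- if (total_allo > 0) abs(total_allo - fa - ba) / total_allo else 0
  if (max(res_o, res_a) > 1e-8) {
    stop(sprintf("mass balance did not converge (residuals %.2e / %.2e)",
                 res_o, res_a), call. = FALSE)
  }
  list(free_ortho = fo, free_allo = fa, species = sp,
       bound_ortho = bo, bound_allo = ba,
       residual = c(ortho = res_o, allo = res_a))
}
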