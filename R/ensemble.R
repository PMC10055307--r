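#' Conformational ensemble of a kinase
#'
#' A kinase in solution populates a small set of conformations (e.g. active
#' and inactive for Aurora A; open, closing-competent and closed for Abl) in
#' thermodynamic equilibrium. The ensemble is described by named states with
#' relative statistical weights; by convention the first state's weight is 1,
#' so for a two-state system the second weight equals the equilibrium
#' constant between the two states.
#'
#' @param states character vector of state labels (at least 2, unique).
#' @param weights numeric relative statistical weights, same length as
#'   `states`; all must be > 0. They are rescaled so the first equals 1.
#' @return An object of class `conformational_ensemble`: a named numeric
#'   vector of weights with the state labels as names.
#' @examples
#' conformational_ensemble(c("active", "inactive"), c(1, 0.67))
#' @export
conformational_ensemble <- function(states, weights) {
  states <- as.character(states)
  weights <- as.numeric(weights)
  if (length(states) < 2L) {
    stop("an ensemble needs at least 2 states", call. = FALSE)
  }
  if (anyDuplicated(states)) {
    stop("state labels must be unique", call. = FALSE)
  }
  if (length(weights) != length(states)) {
    stop("'states' and 'weights' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("all ensemble weights must be finite and > 0", call. = FALSE)
  }
  w <- weights / weights[1L]
  names(w) <- states
  structure(w, class = "conformational_ensemble")
}

#' Two-state ensemble from an equilibrium constant
#'
#' Convenience constructor for the two-state (active/inactive) model. The
#' package convention is `k_eq = [inactive]/[active]`; pass
#' `convention = "active_over_inactive"` if your constant is defined the
#' other way around.
#'
#' @param k_eq equilibrium constant (> 0).
#' @param states labels for the two states, first = reference (active) state.
#' @param convention which ratio `k_eq` denotes.
#' @return A [conformational_ensemble()].
#' @examples
#' two_state_ensemble(0.67)  # apo Aurora A: 40.1% inactive
#' @export
two_state_ensemble <- function(k_eq, states = c("active", "inactive"),
                               convention = c("inactive_over_active",
                                              "active_over_inactive")) {
  convention <- match.arg(convention)
  if (!is.finite(k_eq) || k_eq <= 0) stop("k_eq must be finite and > 0", call. = FALSE)
  if (convention == "active_over_inactive") k_eq <- 1 / k_eq
  conformational_ensemble(states, c(1, k_eq))
}

#' Equilibrium constant of a two-state ensemble
#'
#' @param ensemble a [conformational_ensemble()] with exactly two states.
#' @return `weight(state 2) / weight(state 1)`, i.e. inactive/active under
#'   the default labeling.
#' @export
ensemble_keq <- function(ensemble) {
  stopifnot(inherits(ensemble, "conformational_ensemble"))
  if (length(ensemble) != 2L) {
    stop("ensemble_keq is defined for two-state ensembles", call. = FALSE)
  }
  unname(ensemble[2L] / ensemble[1L])
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  f <- unclass(x) / sum(x)
  cat("Conformational ensemble (", length(x), " states)\n", sep = "")
  for (s in names(x)) {
    cat(sprintf("  %-20s weight %-10.4g population %.3f\n", s, x[[s]], f[[s]]))
  }
  invisible(x)
}

#' State-selective binding profile of one ligand at one site
#'
#' Describes how a single ligand binds each conformation of the ensemble:
#' one dissociation constant per state (molar), optionally one binding
#' enthalpy per state (kJ/mol). A state the ligand cannot bind carries
#' `kd = Inf`, which is handled symbolically (its Boltzmann factor is
#' exactly 1) rather than as a large float.
#'
#' @param name ligand name.
#' @param site `"orthosteric"` (ATP site) or `"allosteric"`.
#' @param kd named numeric vector of dissociation constants (molar), one per
#'   state; `Inf` means no binding to that state. At least one must be
#'   finite, and all finite values must be > 0.
#' @param dh optional named numeric vector of binding enthalpies (kJ/mol)
#'   for the finite-kd states.
#' @return An object of class `ligand_profile`.
#' @examples
#' # danusertib-like inactive-state-selective orthosteric binder
#' ligand_profile("danusertib", "orthosteric",
#'                kd = c(active = 38.4e-9, inactive = 1e-9))
#' @export
ligand_profile <- function(name, site = c("orthosteric", "allosteric"),
                           kd, dh = NULL) {
  site <- match.arg(site)
  if (is.null(names(kd)) || any(!nzchar(names(kd)))) {
    stop("'kd' must be a named vector with state labels as names", call. = FALSE)
  }
  kd <- vapply(kd, as.numeric, numeric(1))
  if (any(is.na(kd)) || any(kd <= 0)) {
    stop("every dissociation constant must be > 0 (Inf = no binding)", call. = FALSE)
  }
  if (!any(is.finite(kd))) {
    stop(sprintf("ligand '%s' binds no state (all kd infinite)", name), call. = FALSE)
  }
  if (!is.null(dh)) {
    if (is.null(names(dh))) stop("'dh' must be named by state", call. = FALSE)
    if (!all(names(dh) %in% names(kd))) {
      stop("'dh' names must be a subset of 'kd' names", call. = FALSE)
    }
    dh <- vapply(dh, as.numeric, numeric(1))
  }
  structure(list(name = as.character(name), site = site, kd = kd, dh = dh),
            class = "ligand_profile")
}

#' @export
print.ligand_profile <- function(x, ...) {
  cat(sprintf("Ligand '%s' (%s site)\n", x$name, x$site))
  for (s in names(x$kd)) {
    kd_txt <- if (is.finite(x$kd[[s]])) sprintf("%.4g nM", x$kd[[s]] * 1e9) else "no binding"
    dh_txt <- if (!is.null(x$dh) && s %in% names(x$dh)) {
      sprintf("  dH %.1f kJ/mol", x$dh[[s]])
    } else ""
    cat(sprintf("  %-20s Kd %s%s\n", s, kd_txt, dh_txt))
  }
  invisible(x)
}

# per-state association constants (1/M); 0 encodes "no binding" so that the
# binding polynomial factor (1 + c * a) is exactly 1 for excluded states
.assoc <- function(profile, states) {
  kd <- profile$kd
  missing <- setdiff(states, names(kd))
  if (length(missing)) {
    stop(sprintf("ligand '%s' has no kd for state(s): %s", profile$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  a <- ifelse(is.finite(kd[states]), 1 / kd[states], 0)
  names(a) <- states
  a
}

#' Double-drugging scheme: ensemble + two ligands + catalytic weights
#'
#' The full model for a kinase simultaneously exposed to an orthosteric and
#' an allosteric modulator: the conformational ensemble, the two
#' state-selective binding profiles, and the catalytic activity of each
#' conformation when the orthosteric site is free. The species lattice has
#' `4 * n_states` members (each conformation crossed with apo, ortho-bound,
#' allo-bound, doubly-bound).
#'
#' The optional `coupling` factor multiplies the statistical weight of the
#' doubly-bound species of a state, modeling extra state-specific affinity
#' of one ligand for the other-drug-bound enzyme beyond pure equilibrium
#' shift (the mechanism required when an observed cooperativity exceeds the
#' shift-only ceiling). Default 1 for every state (pure conformational
#' selection).
#'
#' @param ensemble a [conformational_ensemble()].
#' @param ortho [ligand_profile()] with `site = "orthosteric"`.
#' @param allo [ligand_profile()] with `site = "allosteric"`.
#' @param catalytic_weights named numeric in `[0, 1]` per state: fractional
#'   activity of that conformation with an empty orthosteric site.
#' @param coupling optional named numeric (> 0) per state; weight multiplier
#'   of the doubly-bound species. Defaults to 1 everywhere.
#' @return An object of class `double_drug_scheme`.
#' @export
double_drug_scheme <- function(ensemble, ortho, allo, catalytic_weights,
                               coupling = NULL) {
  stopifnot(inherits(ensemble, "conformational_ensemble"),
            inherits(ortho, "ligand_profile"),
            inherits(allo, "ligand_profile"))
  if (ortho$site != "orthosteric" || allo$site != "allosteric") {
    stop("'ortho' must be an orthosteric and 'allo' an allosteric profile",
         call. = FALSE)
  }
  states <- names(ensemble)
  .assoc(ortho, states)  # validates label match
  .assoc(allo, states)
  if (is.null(names(catalytic_weights)) ||
      !setequal(names(catalytic_weights), states)) {
    stop("'catalytic_weights' must be named by the ensemble states", call. = FALSE)
  }
  cw <- vapply(states, function(s) as.numeric(catalytic_weights[[s]]), numeric(1))
  if (any(cw < 0 | cw > 1)) stop("catalytic weights must lie in [0, 1]", call. = FALSE)
  names(cw) <- states
  if (is.null(coupling)) {
    coupling <- rep(1, length(states))
    names(coupling) <- states
  } else {
    if (is.null(names(coupling)) || !all(names(coupling) %in% states)) {
      stop("'coupling' must be named by ensemble states", call. = FALSE)
    }
    g <- rep(1, length(states)); names(g) <- states
    g[names(coupling)] <- as.numeric(coupling)
    if (any(g <= 0)) stop("coupling factors must be > 0", call. = FALSE)
    coupling <- g
  }
  structure(list(ensemble = ensemble, ortho = ortho, allo = allo,
                 catalytic_weights = cw, coupling = coupling),
            class = "double_drug_scheme")
}

#' @export
print.double_drug_scheme <- function(x, ...) {
  cat("Double-drugging scheme\n")
  print(x$ensemble)
  print(x$ortho)
  print(x$allo)
  cat("  catalytic weights:",
      paste(sprintf("%s=%.2f", names(x$catalytic_weights), x$catalytic_weights),
            collapse = ", "), "\n")
  if (any(x$coupling != 1)) {
    cat("  doubly-bound coupling:",
        paste(sprintf("%s=%.3f", names(x$coupling), x$coupling), collapse = ", "),
        "\n")
  }
  invisible(x)
}
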