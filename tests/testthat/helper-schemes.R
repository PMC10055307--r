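# Shared fixtures: random scheme generation and independent brute-force
# oracles used across the test files.

# random double-drug scheme with n_states conformations; kds log-uniform in
# [1e-10, 1e-5] M, occasional exclusive (Inf) entries, occasional coupling
random_scheme <- function(n_states = 2, allow_inf = TRUE,
                          allow_coupling = FALSE) {
  states <- paste0("s", seq_len(n_states))
  w <- c(1, exp(stats::runif(n_states - 1, log(0.05), log(20))))
  ens <- conformational_ensemble(states, w)
  rand_kd <- function() {
    kd <- 10^stats::runif(n_states, -10, -5)
    if (allow_inf && stats::runif(1) < 0.3) {
      drop <- sample(n_states, sample(n_states - 1, 1))
      kd[drop] <- Inf
    }
    stats::setNames(kd, states)
  }
  coupling <- NULL
  if (allow_coupling && stats::runif(1) < 0.5) {
    coupling <- stats::setNames(10^stats::runif(n_states, -1, 1), states)
  }
  cw <- stats::setNames(stats::runif(n_states), states)
  double_drug_scheme(ens,
                     ligand_profile("o", "orthosteric", rand_kd()),
                     ligand_profile("a", "allosteric", rand_kd()),
                     catalytic_weights = cw, coupling = coupling)
}

# brute-force apparent Kd: enumerate the full 4 x n_states Boltzmann
# lattice directly from weights/kds (no package internals) and bisect for
# the probe concentration giving half-occupancy of the probe site
oracle_apparent_kd <- function(scheme, probe = "ortho", partner_free = 0) {
  states <- names(scheme$ensemble)
  w <- unclass(scheme$ensemble)
  inv <- function(kd) ifelse(is.finite(kd), 1 / kd, 0)
  ko <- inv(scheme$ortho$kd[states])
  ka <- inv(scheme$allo$kd[states])
  g <- scheme$coupling[states]
  occupancy <- function(co, ca) {
    terms <- rbind(apo = w, o = w * co * ko, a = w * ca * ka,
                   both = w * g * co * ko * ca * ka)
    probe_rows <- if (probe == "ortho") c("o", "both") else c("a", "both")
    sum(terms[probe_rows, ]) / sum(terms)
  }
  f <- if (probe == "ortho") {
    function(lfree) occupancy(exp(lfree), partner_free) - 0.5
  } else {
    function(lfree) occupancy(partner_free, exp(lfree)) - 0.5
  }
  exp(stats::uniroot(f, c(log(1e-16), log(1e2)), tol = 1e-13)$root)
}

# brute-force competitive equilibrium: bisection on free enzyme
oracle_competitive_free_enzyme <- function(e0, a0, b0, ka, kb) {
  g <- function(e) e * (1 + a0 / (ka + e) + b0 / (kb + e)) - e0
  stats::uniroot(g, c(0, e0), tol = 1e-18)$root
}

# noiseless single-site titration experiment with heats filled in
make_single_site_experiment <- function(kd = 100e-9, dh = -40, n = 1,
                                        cell = 20e-6, syringe = 150e-6,
                                        n_inj = 25, inj_vol = 2e-6) {
  ex <- titration_experiment(cell = c(enzyme = cell),
                             syringe = c(ligand = syringe),
                             injection_volumes = rep(inj_vol, n_inj))
  ex$heats <- simulate_titration(ex, list(kind = "single_site",
                                          enzyme = "enzyme", ligand = "ligand",
                                          kd = kd, dh = dh, n = n))
  ex
}
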