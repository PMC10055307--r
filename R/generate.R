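#' Noise specification for synthetic experiments
#'
#' @param kind `"additive_gaussian"` (ITC heats, fluorescence) or
#'   `"multiplicative_gaussian"` (observed rates, CV-like).
#' @param sigma noise magnitude as a fraction of the signal scale (>= 0).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("additive_gaussian", "multiplicative_gaussian"),
                       sigma = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

# evaluate code under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  force(code)
}

.apply_noise <- function(values, noise, scale = NULL) {
  if (noise$sigma == 0) return(values)
  if (noise$kind == "additive_gaussian") {
    if (is.null(scale)) scale <- max(abs(values))
    values + stats::rnorm(length(values), 0, noise$sigma * scale)
  } else {
    values * (1 + stats::rnorm(length(values), 0, noise$sigma))
  }
}

# build the titration_experiment + forward model for a preset ITC design
.itc_design_experiment <- function(truth, design) {
  scheme <- truth$scheme
  enzyme <- "enzyme"
  if (design$kind == "itc_direct") {
    lig <- if (design$ligand == "allo") scheme$allo else scheme$ortho
    kd_app <- .scheme_apparent_kd(scheme,
                                  if (design$ligand == "allo") "allo" else "ortho",
                                  partner_free = 0)
    # population-weighted apparent enthalpy over the bound states
    states <- names(scheme$ensemble)
    a <- .assoc(lig, states)
    w <- unclass(scheme$ensemble)
    pop <- w * a / sum(w * a)
    dh <- vapply(states, function(s) {
      if (!is.null(lig$dh) && s %in% names(lig$dh)) lig$dh[[s]] else 0
    }, numeric(1))
    dh_app <- sum(pop * dh)
    exper <- titration_experiment(
      cell = stats::setNames(design$cell_enzyme, enzyme),
      syringe = stats::setNames(design$syringe, lig$name),
      injection_volumes = rep(design$injection_volume, design$n_injections))
    model <- list(kind = "single_site", enzyme = enzyme, ligand = lig$name,
                  kd = kd_app, dh = dh_app, n = 1)
    list(experiment = exper, model = model,
         true_kd = kd_app, true_dh = dh_app)
  } else if (design$kind == "itc_scheme") {
    lig <- scheme$allo
    exper <- titration_experiment(
      cell = stats::setNames(c(design$cell_enzyme, design$cell_partner),
                             c(enzyme, scheme$ortho$name)),
      syringe = stats::setNames(design$syringe, lig$name),
      injection_volumes = rep(design$injection_volume, design$n_injections))
    model <- list(kind = "scheme", scheme = scheme, enzyme = enzyme)
    list(experiment = exper, model = model,
         true_kd = .scheme_apparent_kd(scheme, "allo", partner_free = Inf),
         true_dh = NA_real_)
  } else if (design$kind == "itc_displacement") {
    # tight ligand = the scheme's orthosteric drug at its apparent affinity
    kd_tight <- .scheme_apparent_kd(scheme, "ortho", partner_free = 0)
    states <- names(scheme$ensemble)
    a <- .assoc(scheme$ortho, states)
    w <- unclass(scheme$ensemble)
    pop <- w * a / sum(w * a)
    dh <- vapply(states, function(s) {
      if (!is.null(scheme$ortho$dh) && s %in% names(scheme$ortho$dh)) {
        scheme$ortho$dh[[s]]
      } else 0
    }, numeric(1))
    dh_tight <- sum(pop * dh)
    exper <- titration_experiment(
      cell = stats::setNames(c(design$cell_enzyme, design$cell_weak),
                             c(enzyme, "weak_ligand")),
      syringe = stats::setNames(design$syringe, scheme$ortho$name),
      injection_volumes = rep(design$injection_volume, design$n_injections))
    model <- list(kind = "competitive", enzyme = enzyme, weak = "weak_ligand",
                  tight = scheme$ortho$name,
                  kd_weak = design$kd_weak, dh_weak = design$dh_weak,
                  kd_tight = kd_tight, dh_tight = dh_tight)
    list(experiment = exper, model = model,
         true_kd = kd_tight, true_dh = dh_tight)
  } else {
    stop("not an ITC design: ", design$kind, call. = FALSE)
  }
}

#' Generate a synthetic ITC dataset from a preset
#'
#' Runs the exact forward titration model for one of the preset's ITC
#' designs and adds per-injection noise (additive Gaussian, sigma scaled to
#' the largest absolute heat). Noiseless output (`sigma = 0`) equals the
#' forward model exactly; identical seeds give identical data.
#'
#' @param truth a `ground_truth` from [make_preset()].
#' @param design name of an ITC design in `truth$designs`.
#' @param noise a [noise_spec()].
#' @return A data frame with columns `injection_index`, `volume_uL`,
#'   `heat_uJ`, with the `titration_experiment` (heats filled in J) in
#'   attribute `experiment`, the forward model in `model`, and the design's
#'   true parameters in `true_kd` / `true_dh`.
#' @export
gen_itc <- function(truth, design = "itc_allo_apo",
                    noise = noise_spec(seed = 1L)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  if (!design %in% names(truth$designs)) {
    stop(sprintf("preset '%s' has no design '%s'", truth$name, design),
         call. = FALSE)
  }
  d <- .itc_design_experiment(truth, truth$designs[[design]])
  heats <- simulate_titration(d$experiment, d$model)
  heats <- .with_seed(noise$seed, .apply_noise(heats, noise))
  exper <- d$experiment
  exper$heats <- heats
  out <- data.frame(injection_index = seq_along(heats),
                    volume_uL = exper$injection_volumes * 1e6,
                    heat_uJ = heats * 1e6)
  structure(out, experiment = exper, model = d$model,
            true_kd = d$true_kd, true_dh = d$true_dh)
}

#' Generate a synthetic FRET titration from a preset
#'
#' Simulates Morrison tight-binding fluorescence curves at the design's
#' enzyme concentration, using the scheme's apparent dissociation constant
#' at the design's background co-drug concentration. Noise is additive
#' Gaussian scaled to the amplitude, independent per replicate.
#'
#' @inheritParams gen_itc
#' @param design name of a FRET design in `truth$designs`.
#' @return Data frame `conc_nM`, `fluorescence_au`, `replicate`, with
#'   attributes `true_kd`, `et`, `f0`, `amplitude`.
#' @export
gen_fret <- function(truth, design = "fret_apo",
                     noise = noise_spec(seed = 1L)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  d <- truth$designs[[design]]
  if (is.null(d) || d$kind != "fret") {
    stop(sprintf("preset '%s' has no FRET design '%s'", truth$name, design),
         call. = FALSE)
  }
  scheme <- truth$scheme
  # probe = orthosteric ligand unless the design overrides the profile
  probe <- if (!is.null(d$ligand)) d$ligand else scheme$ortho
  tmp <- double_drug_scheme(scheme$ensemble, probe, scheme$allo,
                            catalytic_weights = scheme$catalytic_weights)
  kd_app <- .scheme_apparent_kd(tmp, "ortho", partner_free = d$background_free)
  f_true <- morrison_model(d$concs, d$f0, d$amplitude, d$et, kd_app)
  reps <- d$replicates
  out <- .with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(reps), function(r) {
      data.frame(conc_nM = d$concs * 1e9,
                 fluorescence_au = .apply_noise(f_true, noise,
                                                scale = abs(d$amplitude)),
                 replicate = r)
    }))
  })
  structure(out, true_kd = kd_app, et = d$et, f0 = d$f0,
            amplitude = d$amplitude)
}

#' Generate a synthetic dose-response dataset from a preset
#'
#' Observed rates are `kobs0 * predicted_activity(...)` with multiplicative
#' Gaussian noise per replicate, emulating the CV-like replicate scatter of
#' coupled-assay rates.
#'
#' @inheritParams gen_itc
#' @param design a design of kind `"dose"` (orthosteric titration at fixed
#'   allosteric co-drug) or `"dose_allo"` (allosteric titration alone).
#' @return Data frame `conc_nM`, `kobs_per_s`, `replicate`,
#'   `co_inhibitor_nM`, with attribute `true_curve` (noiseless rates).
#' @export
gen_dose <- function(truth, design = "dose_response",
                     noise = noise_spec("multiplicative_gaussian", 0.02, 1L)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  d <- truth$designs[[design]]
  if (is.null(d) || !d$kind %in% c("dose", "dose_allo")) {
    stop(sprintf("preset '%s' has no dose design '%s'", truth$name, design),
         call. = FALSE)
  }
  scheme <- truth$scheme
  if (d$kind == "dose") {
    concs <- d$ortho_concs
    act <- vapply(concs, function(x) {
      predicted_activity(scheme, x, d$allo_conc)
    }, numeric(1))
    co <- if (is.infinite(d$allo_conc)) Inf else d$allo_conc * 1e9
  } else {
    concs <- d$allo_concs
    act <- vapply(concs, function(x) predicted_activity(scheme, 0, x),
                  numeric(1))
    co <- 0
  }
  k_true <- d$kobs0 * act
  out <- .with_seed(noise$seed, {
    do.call(rbind, lapply(seq_len(d$replicates), function(r) {
      data.frame(conc_nM = concs * 1e9,
                 kobs_per_s = .apply_noise(k_true, noise),
                 replicate = r, co_inhibitor_nM = co)
    }))
  })
  structure(out, true_curve = k_true)
}

#' Generate a synthetic synergy grid from a preset
#'
#' @inheritParams gen_itc
#' @param design name of a design of kind `"grid"`.
#' @return Long-format data frame `ortho_nM`, `allo_nM`, `kobs_per_s` with
#'   the noiseless [synergy_grid()] in attribute `true_grid`.
#' @export
gen_grid <- function(truth, design = "synergy",
                     noise = noise_spec("multiplicative_gaussian", 0.02, 1L)) {
  stopifnot(inherits(truth, "ground_truth"))
  d <- truth$designs[[design]]
  if (is.null(d) || d$kind != "grid") {
    stop(sprintf("preset '%s' has no grid design '%s'", truth$name, design),
         call. = FALSE)
  }
  sg <- synergy_grid(truth$scheme, d$ortho_grid, d$allo_grid)
  k <- d$kobs0 * sg$activity
  out <- expand.grid(ortho_nM = d$ortho_grid * 1e9,
                     allo_nM = d$allo_grid * 1e9)
  # activity matrix rows = allo, cols = ortho; expand.grid varies ortho first
  out$kobs_per_s <- .with_seed(noise$seed,
                               .apply_noise(as.vector(t(k)), noise))
  structure(out, true_grid = sg)
}

#' Parameter-recovery harness
#'
#' Repeats generate-then-fit over seeds and summarizes recovery of a scalar
#' parameter: relative bias, relative RMSE and (when the fitter returns an
#' interval) confidence-interval coverage.
#'
#' @param generate function(seed) returning a dataset.
#' @param fit function(dataset) returning either a numeric estimate or a
#'   list with `estimate` and optionally `lower`, `upper`.
#' @param true_value the generating parameter value.
#' @param n_seeds number of seeds (>= 10).
#' @param base_seed seeds used are `base_seed + 0:(n_seeds-1)`.
#' @param max_failure_rate error if more than this fraction of fits fail.
#' @return A list with `bias` (relative), `rmse` (relative), `coverage`
#'   (or `NA`), `n_ok`, and the vector of `estimates`.
#' @export
recovery_harness <- function(generate, fit, true_value, n_seeds = 100,
                             base_seed = 1L, max_failure_rate = 0.2) {
  if (n_seeds < 10) stop("n_seeds must be >= 10", call. = FALSE)
  est <- rep(NA_real_, n_seeds)
  lo <- rep(NA_real_, n_seeds)
  hi <- rep(NA_real_, n_seeds)
  for (i in seq_len(n_seeds)) {
    res <- tryCatch({
      f <- fit(generate(base_seed + i - 1L))
      if (is.list(f)) f else list(estimate = f)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      est[i] <- res$estimate
      if (!is.null(res$lower)) lo[i] <- res$lower
      if (!is.null(res$upper)) hi[i] <- res$upper
    }
  }
  ok <- is.finite(est)
  if (mean(!ok) > max_failure_rate) {
    stop(sprintf("fitter failed for %.0f%% of seeds (cap %.0f%%)",
                 100 * mean(!ok), 100 * max_failure_rate), call. = FALSE)
  }
  rel <- (est[ok] - true_value) / true_value
  coverage <- if (any(is.finite(lo[ok]))) {
    mean(lo[ok] <= true_value & true_value <= hi[ok], na.rm = TRUE)
  } else NA_real_
  list(bias = mean(rel), rmse = sqrt(mean(rel^2)), coverage = coverage,
       n_ok = sum(ok), estimates = est)
}

#' Apparent-Kd recovery for a preset ITC design
#'
#' Convenience wrapper around [recovery_harness()]: generates synthetic
#' titrations for one preset ITC design at a given noise level and refits
#' them with [fit_direct()] (or [fit_displacement()] for replacement
#' designs), comparing recovered to generating apparent Kd.
#'
#' @param truth a `ground_truth`.
#' @param design ITC design name.
#' @param sigma additive heat-noise fraction.
#' @param n_seeds number of repetitions.
#' @param base_seed first seed.
#' @return As [recovery_harness()], plus `true_kd`.
#' @export
itc_kd_recovery <- function(truth, design = "itc_allo_apo", sigma = 0.01,
                            n_seeds = 100, base_seed = 1L) {
  d0 <- gen_itc(truth, design, noise_spec(sigma = 0, seed = 1L))
  true_kd <- attr(d0, "true_kd")
  kind <- truth$designs[[design]]$kind
  generate <- function(seed) {
    gen_itc(truth, design, noise_spec(sigma = sigma, seed = seed))
  }
  fit <- function(dat) {
    exper <- attr(dat, "experiment")
    f <- if (kind == "itc_displacement") {
      m <- attr(dat, "model")
      fit_displacement(exper, enzyme = m$enzyme, weak = m$weak,
                       tight = m$tight, kd_weak = m$kd_weak,
                       dh_weak = m$dh_weak)
    } else {
      fit_direct(exper)
    }
    list(estimate = f$kd, lower = f$kd_ci[1], upper = f$kd_ci[2])
  }
  out <- recovery_harness(generate, fit, true_kd, n_seeds = n_seeds,
                          base_seed = base_seed)
  out$true_kd <- true_kd
  out
}
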