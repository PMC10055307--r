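#' End-to-end double-drugging analysis pipeline
#'
#' Chains the full workflow on a preset (or a scheme config file):
#' synthetic data generation at a fixed seed, affinity fitting (direct ITC
#' for the allosteric or orthosteric ligand, displacement ITC for the tight
#' orthosteric drug when the design exists), cooperativity factors in both
#' binding orders with the order-symmetry check, dose-response fitting with
#' the dose for 10% residual activity, a model synergy table, and apparent-
#' Kd recovery metrics against the generating truth. The report is written
#' as JSON (plus a human-readable summary) and is byte-identical for
#' identical configs and seeds.
#'
#' @param config a list with fields `preset` (name for [make_preset()]) or
#'   `scheme_file` (JSON path), `outdir` (output directory), `seed`
#'   (integer), optional `sigma_itc` (default 0.01), `sigma_kobs` (default
#'   0.02), `residual` (default 0.10).
#' @return Invisibly the report list. Side effects: `report.json` and
#'   `report.txt` in `outdir`.
#' @export
run_pipeline <- function(config) {
  for (f in c("outdir", "seed")) {
    if (is.null(config[[f]])) stop("config needs '", f, "'", call. = FALSE)
  }
  if (is.null(config$preset) && is.null(config$scheme_file)) {
    stop("config needs 'preset' or 'scheme_file'", call. = FALSE)
  }
  sigma_itc <- if (is.null(config$sigma_itc)) 0.01 else config$sigma_itc
  sigma_kobs <- if (is.null(config$sigma_kobs)) 0.02 else config$sigma_kobs
  residual <- if (is.null(config$residual)) 0.10 else config$residual
  seed <- as.integer(config$seed)

  truth <- if (!is.null(config$preset)) {
    make_preset(config$preset)
  } else {
    if (!file.exists(config$scheme_file)) {
      stop("no such scheme file: ", config$scheme_file, call. = FALSE)
    }
    scheme <- read_scheme_json(config$scheme_file)
    structure(list(name = basename(config$scheme_file), scheme = scheme,
                   designs = list(), truth = list(
                     alpha = cooperativity_factor(scheme, "allo")),
                   assumptions = character()),
              class = "ground_truth")
  }
  scheme <- truth$scheme

  report <- list(
    schema_version = "1.0",
    preset = truth$name,
    seed = seed,
    linkage = list(
      alpha_probe_allo = cooperativity_factor(scheme, "allo"),
      alpha_probe_ortho = cooperativity_factor(scheme, "ortho"),
      kd_app_ortho_apo_nM = .scheme_apparent_kd(scheme, "ortho", 0) * 1e9,
      kd_app_ortho_sat_nM = .scheme_apparent_kd(scheme, "ortho", Inf) * 1e9,
      kd_app_allo_apo_nM = .scheme_apparent_kd(scheme, "allo", 0) * 1e9,
      kd_app_allo_sat_nM = .scheme_apparent_kd(scheme, "allo", Inf) * 1e9
    )
  )
  report$linkage$order_symmetry_ok <-
    abs(report$linkage$alpha_probe_allo - report$linkage$alpha_probe_ortho) <
    1e-9 * max(1, abs(report$linkage$alpha_probe_allo))

  # ITC stage: direct fit of whichever direct design the preset defines
  direct_design <- intersect(c("itc_allo_apo", "itc_ortho_apo"),
                             names(truth$designs))
  if (length(direct_design)) {
    dat <- gen_itc(truth, direct_design[1L],
                   noise_spec(sigma = sigma_itc, seed = seed))
    fit <- fit_direct(attr(dat, "experiment"))
    report$itc_direct <- list(
      design = direct_design[1L],
      kd_nM = fit$kd * 1e9, kd_ci_nM = fit$kd_ci * 1e9,
      dh_kJ_per_mol = fit$dh, n = fit$n,
      true_kd_nM = attr(dat, "true_kd") * 1e9,
      recovery_rel_error = (fit$kd - attr(dat, "true_kd")) / attr(dat, "true_kd"))
  }
  if ("itc_displacement" %in% names(truth$designs)) {
    dat <- gen_itc(truth, "itc_displacement",
                   noise_spec(sigma = sigma_itc, seed = seed + 1L))
    m <- attr(dat, "model")
    fit <- fit_displacement(attr(dat, "experiment"), enzyme = m$enzyme,
                            weak = m$weak, tight = m$tight,
                            kd_weak = m$kd_weak, dh_weak = m$dh_weak)
    report$itc_displacement <- list(
      kd_nM = fit$kd * 1e9, kd_ci_nM = fit$kd_ci * 1e9,
      dh_kJ_per_mol = fit$dh,
      true_kd_nM = attr(dat, "true_kd") * 1e9,
      recovery_rel_error = (fit$kd - attr(dat, "true_kd")) / attr(dat, "true_kd"))
  }

  # dose-response stage
  if ("dose_response" %in% names(truth$designs)) {
    dat <- gen_dose(truth, "dose_response",
                    noise_spec("multiplicative_gaussian", sigma_kobs,
                               seed + 2L))
    fit <- fit_4pl(dat$conc_nM * 1e-9, dat$kobs_per_s)
    d10 <- tryCatch(dose_for_residual_activity(fit, residual),
                    error = function(e) NA_real_)
    report$dose_response <- list(
      ic50_nM = fit$ic50 * 1e9, hill = fit$hill,
      top = fit$top, bottom = fit$bottom,
      dose_10pct_nM = d10 * 1e9, reachable = is.finite(d10))
  }

  # model synergy table over a default grid
  ortho_grid <- c(0, 10^seq(-9, -6, length.out = 4))
  allo_grid <- c(0, 10^seq(-8, -6, length.out = 3))
  sg <- synergy_grid(scheme, ortho_grid, allo_grid, residual = residual)
  report$synergy <- list(
    allo_conc_nM = sg$dose_reduction$allo_conc * 1e9,
    dose_10pct_nM = sg$dose_reduction$dose_10pct * 1e9,
    fold_reduction = sg$dose_reduction$fold_reduction,
    reachable = sg$dose_reduction$reachable)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  txt_path <- file.path(config$outdir, "report.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Double-drugging pipeline report: %s (seed %d)", truth$name, seed)
  w("cooperativity alpha = %.4g (probe allo) / %.4g (probe ortho); order symmetry %s",
    report$linkage$alpha_probe_allo, report$linkage$alpha_probe_ortho,
    if (report$linkage$order_symmetry_ok) "OK" else "VIOLATED")
  if (!is.null(report$itc_direct)) {
    w("direct ITC [%s]: Kd = %.4g nM (true %.4g nM, rel err %+.2f%%)",
      report$itc_direct$design, report$itc_direct$kd_nM,
      report$itc_direct$true_kd_nM,
      100 * report$itc_direct$recovery_rel_error)
  }
  if (!is.null(report$itc_displacement)) {
    w("displacement ITC: Kd = %.4g nM (true %.4g nM, rel err %+.2f%%)",
      report$itc_displacement$kd_nM, report$itc_displacement$true_kd_nM,
      100 * report$itc_displacement$recovery_rel_error)
  }
  if (!is.null(report$dose_response)) {
    w("dose-response: IC50 = %.4g nM, hill = %.3g, dose(%.0f%% residual) = %s nM",
      report$dose_response$ic50_nM, report$dose_response$hill, 100 * residual,
      if (report$dose_response$reachable)
        sprintf("%.4g", report$dose_response$dose_10pct_nM) else "unreachable")
  }
  w("synergy (orthosteric dose for %.0f%% residual):", 100 * residual)
  for (i in seq_along(report$synergy$allo_conc_nM)) {
    w("  allo %8.4g nM -> %s nM (fold reduction %.3g)",
      report$synergy$allo_conc_nM[i],
      if (report$synergy$reachable[i])
        sprintf("%.4g", report$synergy$dose_10pct_nM[i]) else "unreachable",
      report$synergy$fold_reduction[i])
  }
  invisible(report)
}
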