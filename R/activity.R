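#' Observed rate from an NADH-coupled absorbance trace
#'
#' In the coupled kinase assay every phosphotransfer oxidizes one NADH, so
#' the observed per-enzyme rate is the negative slope of A340 over time
#' divided by `epsilon * path * [E]`. The slope comes from ordinary linear
#' regression; a low R-squared triggers a nonlinearity warning.
#'
#' @param time time points (s), >= 10 in the linear regime.
#' @param a340 absorbance at 340 nm (AU), same length as `time`.
#' @param enzyme_total total enzyme concentration (molar).
#' @param epsilon NADH extinction coefficient (1/M/cm), default 6220.
#' @param path optical path length (cm), default 1.
#' @param r2_warn warn if regression R-squared falls below this (0.98).
#' @return A list with `kobs` (1/s), `slope` (AU/s), `r_squared`.
#' @examples
#' t <- seq(0, 300, by = 10)
#' a <- 1 - 6.22e-5 * t
#' kobs_from_absorbance(t, a, enzyme_total = 20e-9)$kobs  # 0.5 /s
#' @export
kobs_from_absorbance <- function(time, a340, enzyme_total, epsilon = 6220,
                                 path = 1, r2_warn = 0.98) {
  if (length(time) < 10L) stop("need >= 10 time points", call. = FALSE)
  if (length(time) != length(a340)) stop("time and a340 lengths differ", call. = FALSE)
  if (enzyme_total <= 0) stop("enzyme_total must be > 0", call. = FALSE)
  fit <- stats::lm(a340 ~ time)
  slope <- unname(stats::coef(fit)[2L])
  ss_tot <- sum((a340 - mean(a340))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  if (ss_tot > 0 && r2 < r2_warn) {
    warning(sprintf("A340 trace deviates from linearity (R^2 = %.3f); ",
                    r2), "restrict to the initial linear regime")
  }
  kobs <- -slope / (epsilon * path * enzyme_total)
  list(kobs = kobs, slope = slope, r_squared = r2)
}

#' Mechanistic fractional activity under double-drugging
#'
#' Activity predicted by the linkage model: each conformation contributes
#' its catalytic weight times the fraction of enzyme in that state with an
#' empty orthosteric site, normalized to the same quantity with no
#' inhibitors. ATP may be supplied as a state-selective orthosteric
#' competitor (it then appears in both the numerator condition and the
#' normalization, so only its competition and equilibrium-shifting effects
#' remain).
#'
#' Inhibitor concentrations are taken as free concentrations (the assay
#' regime has enzyme in the low-nanomolar range, far below the dosed
#' inhibitors).
#'
#' @param scheme a [double_drug_scheme()] with catalytic weights set.
#' @param ortho_conc,allo_conc inhibitor concentrations (molar); either may
#'   be `Inf` for saturation.
#' @param atp optional list `list(profile = ligand_profile, conc = molar)`
#'   with an orthosteric-site profile for the nucleotide.
#' @return Fractional activity in `[0, 1]` (1 = uninhibited).
#' @export
predicted_activity <- function(scheme, ortho_conc, allo_conc, atp = NULL) {
  stopifnot(inherits(scheme, "double_drug_scheme"))
  if (all(scheme$catalytic_weights == 0)) {
    stop("all catalytic weights are zero: activity model is degenerate",
         call. = FALSE)
  }
  if (ortho_conc < 0 || allo_conc < 0) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  states <- names(scheme$ensemble)
  w <- unclass(scheme$ensemble)
  ao <- .assoc(scheme$ortho, states)
  aa <- .assoc(scheme$allo, states)
  g <- scheme$coupling
  a_atp <- if (is.null(atp)) rep(0, length(states)) else {
    if (atp$profile$site != "orthosteric") {
      stop("ATP competitor must be an orthosteric profile", call. = FALSE)
    }
    atp$conc * .assoc(atp$profile, states)
  }
  cw <- scheme$catalytic_weights
  # the orthosteric site holds nothing, the inhibitor, or ATP (mutually
  # exclusive); only empty-orthosteric-site species are catalytically active
  z_of <- function(co, ca) {
    if (is.infinite(co) && is.infinite(ca)) {
      return(list(z = sum(w * g * ao * aa), act = rep(0, length(states))))
    }
    if (is.infinite(co)) {
      return(list(z = sum(w * ao * (1 + ca * g * aa)), act = rep(0, length(states))))
    }
    if (is.infinite(ca)) {
      z <- sum(w * aa * (1 + co * g * ao) + w * aa * a_atp)
      act <- cw * w * aa
      return(list(z = z, act = act))
    }
    per_state <- w * ((1 + co * ao + a_atp) * (1 + ca * aa) +
                        (g - 1) * co * ao * ca * aa)
    act <- cw * w * (1 + ca * aa)  # ortho site strictly empty
    list(z = sum(per_state), act = act)
  }
  num <- z_of(ortho_conc, allo_conc)
  den <- z_of(0, 0)
  activity <- (sum(num$act) / num$z) / (sum(den$act) / den$z)
  min(max(activity, 0), 1)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`, fitted by
#' nonlinear least squares with `ic50` on the log scale. Zero-dose points
#' evaluate exactly to `top` and therefore anchor the upper plateau.
#'
#' @param conc inhibitor concentrations (molar), >= 6 values including 0
#'   recommended.
#' @param response observed rates (e.g. `k_obs`, 1/s), same length.
#' @param start optional named list (`top`, `bottom`, `ic50`, `hill`).
#' @return An object of class `four_pl_fit` with fields `top`, `bottom`,
#'   `ic50`, `hill`, standard errors, `covariance`, `residuals`, `warnings`.
#' @export
fit_4pl <- function(conc, response, start = NULL) {
  if (length(conc) != length(response)) stop("length mismatch", call. = FALSE)
  if (sum(conc > 0) < 4L) stop("need >= 4 nonzero doses", call. = FALSE)
  fourpl <- function(x, top, bottom, log_ic50, hill) {
    r <- numeric(length(x))
    pos <- x > 0
    r[!pos] <- top
    r[pos] <- bottom + (top - bottom) /
      (1 + exp(hill * (log(x[pos]) - log_ic50)))
    r
  }
  top0 <- if (!is.null(start$top)) start$top else max(response)
  bot0 <- if (!is.null(start$bottom)) start$bottom else min(response)
  ic0 <- if (!is.null(start$ic50)) start$ic50 else {
    half <- (top0 + bot0) / 2
    pos <- conc > 0
    i <- which.min(abs(response[pos] - half))
    conc[pos][i]
  }
  h0 <- if (!is.null(start$hill)) start$hill else 1
  dat <- data.frame(conc = conc, y = response)
  fit <- NULL
  # multi-start: a start landing exactly on a flat direction of the
  # objective (possible with idealized data) gives a singular Jacobian
  for (st in list(c(ic0, h0), c(ic0 * 3, h0 * 1.3), c(ic0 / 3, 0.8 * h0),
                  c(stats::median(conc[conc > 0]), 1))) {
    f <- tryCatch(minpack.lm::nlsLM(
      y ~ fourpl(conc, top, bottom, log_ic50, hill), data = dat,
      start = list(top = top0, bottom = bot0, log_ic50 = log(st[1]),
                   hill = st[2]),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || stats::deviance(f) < stats::deviance(fit))) {
      fit <- f
    }
  }
  if (is.null(fit)) stop("4PL fit did not converge", call. = FALSE)
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  ic50 <- exp(cf[["log_ic50"]])
  warnings <- character()
  pos <- conc > 0
  if (min(response[pos]) > cf[["bottom"]] +
      0.25 * (cf[["top"]] - cf[["bottom"]])) {
    warnings <- c(warnings,
                  "lower plateau not reached by the data; bottom and IC50 have wide confidence intervals")
  }
  se <- function(nm) if (!is.null(vc)) sqrt(vc[nm, nm]) else NA_real_
  structure(list(top = cf[["top"]], top_se = se("top"),
                 bottom = cf[["bottom"]], bottom_se = se("bottom"),
                 ic50 = ic50, ic50_se = if (!is.null(vc)) ic50 * sqrt(vc["log_ic50", "log_ic50"]) else NA_real_,
                 hill = cf[["hill"]], hill_se = se("hill"),
                 covariance = vc, residuals = stats::resid(fit),
                 warnings = warnings),
            class = "four_pl_fit")
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat("Four-parameter dose-response fit\n")
  cat(sprintf("  IC50   = %.4g nM (se %.2g nM)\n", x$ic50 * 1e9, x$ic50_se * 1e9))
  cat(sprintf("  top    = %.4g (se %.2g)\n", x$top, x$top_se))
  cat(sprintf("  bottom = %.4g (se %.2g)\n", x$bottom, x$bottom_se))
  cat(sprintf("  hill   = %.3g (se %.2g)\n", x$hill, x$hill_se))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Dose required to reach a residual-activity level
#'
#' Inverts either a fitted 4PL curve (closed form) or the mechanistic
#' linkage model (root finding) for the inhibitor concentration at which
#' the rate equals `residual` times the same curve's uninhibited
#' (zero-dose) rate. The clinically motivated default is 10% residual
#' activity.
#'
#' @param object a `four_pl_fit`, or a [double_drug_scheme()].
#' @param residual target residual activity fraction (strictly between the
#'   curve floor and 1), default 0.10.
#' @param allo_conc for a scheme: fixed allosteric co-drug concentration
#'   (molar, may be `Inf`) while the orthosteric drug is titrated.
#' @param drug for a scheme: which drug to titrate (`"ortho"` default, or
#'   `"allo"` with the orthosteric drug held at `ortho_conc`).
#' @param ortho_conc fixed orthosteric concentration when `drug = "allo"`.
#' @param atp for a scheme: optional ATP competitor, as in
#'   [predicted_activity()].
#' @param upper for a scheme: upper bracket of the dose search (molar).
#' @return Dose (molar).
#' @export
dose_for_residual_activity <- function(object, residual = 0.10,
                                       allo_conc = 0, drug = c("ortho", "allo"),
                                       ortho_conc = 0, atp = NULL,
                                       upper = 1e-2) {
  drug <- match.arg(drug)
  if (residual <= 0 || residual >= 1) {
    stop("residual must be strictly between 0 and 1", call. = FALSE)
  }
  if (inherits(object, "four_pl_fit")) {
    y0 <- object$top
    y <- residual * y0
    if (y <= object$bottom) {
      stop(sprintf(paste0(
        "unreachable inhibition: the curve floor (%.3g, %.0f%% of the ",
        "uninhibited rate) lies above the %.0f%% residual target"),
        object$bottom, 100 * object$bottom / y0, 100 * residual),
        call. = FALSE)
    }
    return(object$ic50 * ((object$top - y) / (y - object$bottom))^(1 / object$hill))
  }
  if (inherits(object, "double_drug_scheme")) {
    act <- if (drug == "ortho") {
      function(d) predicted_activity(object, d, allo_conc, atp = atp)
    } else {
      function(d) predicted_activity(object, ortho_conc, d, atp = atp)
    }
    baseline <- act(0)
    target <- residual * baseline
    floor_ <- act(Inf)
    if (floor_ >= target) {
      stop(sprintf(paste0(
        "unreachable inhibition: the saturating titrated drug leaves %.1f%% ",
        "activity, above the %.0f%% residual target"),
        100 * floor_ / baseline, 100 * residual), call. = FALSE)
    }
    f <- function(ld) act(exp(ld)) - target
    lo <- log(1e-15)
    root <- stats::uniroot(f, c(lo, log(upper)), tol = 1e-12, maxiter = 200)
    return(exp(root$root))
  }
  stop("object must be a four_pl_fit or a double_drug_scheme", call. = FALSE)
}

#' Jackknife standard error of a fitted statistic
#'
#' Leave-one-out resampling over the rows of the curve data:
#' `SE = sqrt((n-1)/n * sum((theta_i - theta_bar)^2))`. Failed leave-one-out
#' refits are dropped with a warning and the effective n is reported.
#'
#' @param data a data frame (or vector) of curve data, >= 4 rows.
#' @param statistic function taking the (subsetted) data and returning a
#'   scalar.
#' @return A list with `se`, `estimate` (full-data statistic), `n_effective`
#'   and the leave-one-out `values`.
#' @examples
#' jackknife_se(c(1, 2, 3), mean)$se  # 0.577 = sd/sqrt(n)
#' @export
jackknife_se <- function(data, statistic) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 4L && !is.numeric(data)) stop("need >= 4 data points", call. = FALSE)
  take <- function(idx) if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  full <- statistic(data)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vals[i] <- tryCatch(statistic(take(setdiff(seq_len(n), i))),
                        error = function(e) NA_real_)
  }
  ok <- is.finite(vals)
  if (!all(ok)) {
    warning(sprintf("%d of %d leave-one-out refits failed; SE uses n = %d",
                    sum(!ok), n, sum(ok)))
  }
  m <- sum(ok)
  if (m < 2L) stop("too few successful leave-one-out refits", call. = FALSE)
  v <- vals[ok]
  se <- sqrt((m - 1) / m * sum((v - mean(v))^2))
  list(se = se, estimate = full, n_effective = m, values = vals)
}

#' Dose-reduction synergy grid for an inhibitor pair
#'
#' Fills a matrix of predicted fractional activities over a grid of
#' orthosteric x allosteric concentrations and, for each allosteric level,
#' extracts the orthosteric dose needed for a target residual activity and
#' its fold-reduction relative to the no-co-drug row. Rows where the target
#' is unreachable are recorded as `NA` rather than raising an error.
#'
#' @param scheme a [double_drug_scheme()].
#' @param ortho_grid,allo_grid strictly increasing concentration grids
#'   (molar) including 0.
#' @param residual target residual activity (default 0.10).
#' @param atp optional ATP competitor passed to [predicted_activity()].
#' @return Object of class `synergy_grid`: list with the `activity` matrix
#'   (rows = allo levels, columns = ortho levels) and a data frame
#'   `dose_reduction` with columns `allo_conc`, `dose_10pct`,
#'   `fold_reduction`, `reachable`.
#' @export
synergy_grid <- function(scheme, ortho_grid, allo_grid, residual = 0.10,
                         atp = NULL) {
  stopifnot(inherits(scheme, "double_drug_scheme"))
  if (is.unsorted(ortho_grid, strictly = TRUE) ||
      is.unsorted(allo_grid, strictly = TRUE)) {
    stop("concentration grids must be strictly increasing", call. = FALSE)
  }
  if (ortho_grid[1] != 0 || allo_grid[1] != 0) {
    stop("grids must include a zero concentration", call. = FALSE)
  }
  act <- matrix(NA_real_, nrow = length(allo_grid), ncol = length(ortho_grid),
                dimnames = list(paste0("allo_", signif(allo_grid * 1e9, 4), "nM"),
                                paste0("ortho_", signif(ortho_grid * 1e9, 4), "nM")))
  for (i in seq_along(allo_grid)) {
    for (j in seq_along(ortho_grid)) {
      act[i, j] <- predicted_activity(scheme, ortho_grid[j], allo_grid[i],
                                      atp = atp)
    }
  }
  upper <- max(ortho_grid[length(ortho_grid)] * 1e3, 1e-2)
  dose <- vapply(allo_grid, function(a) {
    tryCatch(dose_for_residual_activity(scheme, residual = residual,
                                        allo_conc = a, atp = atp,
                                        upper = upper),
             error = function(e) NA_real_)
  }, numeric(1))
  dr <- data.frame(allo_conc = allo_grid, dose_10pct = dose,
                   fold_reduction = dose[1] / dose,
                   reachable = is.finite(dose))
  structure(list(activity = act, dose_reduction = dr, residual = residual,
                 ortho = scheme$ortho$name, allo = scheme$allo$name),
            class = "synergy_grid")
}

#' @export
print.synergy_grid <- function(x, ...) {
  cat(sprintf("Synergy grid: %s (orthosteric) x %s (allosteric)\n",
              x$ortho, x$allo))
  cat("Fractional activity:\n")
  print(round(x$activity, 3))
  cat(sprintf("\nOrthosteric dose for %.0f%% residual activity:\n",
              100 * x$residual))
  df <- x$dose_reduction
  df$dose_10pct_nM <- df$dose_10pct * 1e9
  df$allo_conc_nM <- df$allo_conc * 1e9
  print(df[, c("allo_conc_nM", "dose_10pct_nM", "fold_reduction", "reachable")],
        row.names = FALSE)
  invisible(x)
}
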