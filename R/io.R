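#' Validate a scheme configuration list
#'
#' Checks the structure of a scheme configuration (as decoded from JSON)
#' against the shipped schema: an `ensemble` block (`states`, `weights`),
#' a `ligands` block with `ortho` and `allo` entries (`name`, `site`,
#' `kd_nM` per state, optional `dh_kJ_per_mol`), a `catalytic_weights`
#' block, and an optional `coupling` block. `null` kd entries mean "no
#' binding" and become `Inf`.
#'
#' @param config a named list (decoded JSON).
#' @return Invisibly `TRUE`; otherwise stops with an informative message.
#' @export
validate_scheme_config <- function(config) {
  need <- c("ensemble", "ligands", "catalytic_weights")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("scheme config is missing block(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ens <- config$ensemble
  if (is.null(ens$states) || is.null(ens$weights) ||
      length(ens$states) != length(ens$weights)) {
    stop("ensemble block needs matching 'states' and 'weights'", call. = FALSE)
  }
  for (role in c("ortho", "allo")) {
    lig <- config$ligands[[role]]
    if (is.null(lig)) stop("ligands block needs '", role, "'", call. = FALSE)
    if (is.null(lig$name) || is.null(lig$site) || is.null(lig$kd_nM)) {
      stop("ligand '", role, "' needs name, site and kd_nM", call. = FALSE)
    }
    expected_site <- if (role == "ortho") "orthosteric" else "allosteric"
    if (!identical(lig$site, expected_site)) {
      stop(sprintf("ligand '%s' must have site '%s'", role, expected_site),
           call. = FALSE)
    }
    unknown <- setdiff(names(lig$kd_nM), ens$states)
    if (length(unknown)) {
      stop(sprintf("ligand '%s' kd_nM has unknown state(s): %s", role,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  unknown <- setdiff(names(config$catalytic_weights), ens$states)
  if (length(unknown)) {
    stop("catalytic_weights has unknown state(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# kd list from config: NULL -> Inf, nM -> molar
.kd_from_config <- function(kd_nM, states) {
  kd <- stats::setNames(rep(Inf, length(states)), states)
  for (s in names(kd_nM)) {
    if (!is.null(kd_nM[[s]])) kd[s] <- kd_nM[[s]] * 1e-9
  }
  kd
}

#' Read a double-drugging scheme from a JSON config file
#'
#' @param path path to a JSON scheme file (see [validate_scheme_config()]
#'   for the structure; concentrations in nM, enthalpies in kJ/mol).
#' @return A [double_drug_scheme()].
#' @export
read_scheme_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  config <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_scheme_config(config)
  states <- config$ensemble$states
  ens <- conformational_ensemble(states, unlist(config$ensemble$weights))
  mk_lig <- function(role) {
    lig <- config$ligands[[role]]
    dh <- if (!is.null(lig$dh_kJ_per_mol)) unlist(lig$dh_kJ_per_mol) else NULL
    ligand_profile(lig$name, lig$site,
                   kd = .kd_from_config(lig$kd_nM, states), dh = dh)
  }
  cw <- unlist(config$catalytic_weights)
  coupling <- if (!is.null(config$coupling)) unlist(config$coupling) else NULL
  double_drug_scheme(ens, mk_lig("ortho"), mk_lig("allo"),
                     catalytic_weights = cw, coupling = coupling)
}

#' Write a double-drugging scheme to a JSON config file
#'
#' @param scheme a [double_drug_scheme()].
#' @param path output path.
#' @return Invisibly `path`.
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "double_drug_scheme"))
  as_kd_nM <- function(kd) {
    out <- lapply(seq_along(kd), function(i) {
      if (is.finite(kd[i])) kd[i] * 1e9 else NULL
    })
    names(out) <- names(kd)
    out
  }
  lig_block <- function(lig) {
    b <- list(name = lig$name, site = lig$site, kd_nM = as_kd_nM(lig$kd))
    if (!is.null(lig$dh)) b$dh_kJ_per_mol <- as.list(lig$dh)
    b
  }
  config <- list(
    ensemble = list(states = names(scheme$ensemble),
                    weights = unname(unclass(scheme$ensemble))),
    ligands = list(ortho = lig_block(scheme$ortho),
                   allo = lig_block(scheme$allo)),
    catalytic_weights = as.list(scheme$catalytic_weights))
  if (any(scheme$coupling != 1)) config$coupling <- as.list(scheme$coupling)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read / write the CSV table schemas
#'
#' `read_itc_csv` expects columns `injection_index`, `volume_uL`, `heat_uJ`
#' and returns a [titration_experiment()] (heats converted to J) given the
#' cell/syringe composition. `read_fret_csv` expects `conc_nM`,
#' `fluorescence_au`, `replicate`; `read_dose_csv` expects `conc_nM`,
#' `kobs_per_s`, `replicate`, `co_inhibitor_nM`. Concentrations are
#' converted to molar in the returned objects.
#'
#' @param path CSV file path.
#' @param cell,syringe,cell_volume composition of the ITC experiment
#'   (molar, molar, L), as in [titration_experiment()].
#' @return See each reader's description.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
read_itc_csv <- function(path, cell, syringe, cell_volume = 170e-6) {
  df <- utils::read.csv(path)
  need <- c("injection_index", "volume_uL", "heat_uJ")
  if (!all(need %in% names(df))) {
    stop("ITC csv needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$injection_index), ]
  titration_experiment(cell_volume = cell_volume, cell = cell,
                       syringe = syringe,
                       injection_volumes = df$volume_uL * 1e-6,
                       heats = df$heat_uJ * 1e-6)
}

#' @rdname csv_io
#' @export
read_fret_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("conc_nM", "fluorescence_au")
  if (!all(need %in% names(df))) {
    stop("FRET csv needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  df$conc <- df$conc_nM * 1e-9
  df
}

#' @rdname csv_io
#' @export
read_dose_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("conc_nM", "kobs_per_s")
  if (!all(need %in% names(df))) {
    stop("dose csv needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  if (!"co_inhibitor_nM" %in% names(df)) df$co_inhibitor_nM <- 0
  df$conc <- df$conc_nM * 1e-9
  df
}
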