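# Expected user units for configuration values. A config value may be a
# plain number (assumed to be in the documented unit) or a string
# "<value> <unit>", in which case the unit must match (synonyms accepted).
.config_units <- list(
  physiology = c(
    V_S = "mL", Q_S = "mL/min", R_in = "ug/min",
    A_SM = "cm2", A_SB = "cm2", A_SP = "cm2", A_BP = "cm2",
    Gamma_max = "ug/cm2", k_ads = "mL/cm2/min", k_des = "1/min",
    P_SM = "cm/min", K_p_T = "-", V_T = "mL", CL_local = "mL/min",
    D_eff = "cm2/s", k_bind = "1/s", L_B = "cm",
    V_P = "uL", Q_GCF = "uL/min", P_SP = "cm/min"))

.unit_synonyms <- list(
  "uL" = c("uL", "ul", "µL", "microliter", "microlitre"),
  "uL/min" = c("uL/min", "ul/min", "µL/min"),
  "mL" = c("mL", "ml"),
  "mL/min" = c("mL/min", "ml/min"),
  "ug/min" = c("ug/min", "µg/min"),
  "ug/cm2" = c("ug/cm2", "µg/cm2"),
  "mL/cm2/min" = c("mL/cm2/min", "mL.cm-2.min-1", "ml/cm2/min"),
  "-" = c("-", "dimensionless", ""),
  "cm2" = c("cm2", "cm^2"),
  "cm2/s" = c("cm2/s", "cm^2/s"),
  "cm/min" = c("cm/min"),
  "1/min" = c("1/min", "min-1", "/min"),
  "1/s" = c("1/s", "s-1", "/s"),
  "cm" = c("cm"))

.parse_valued_unit <- function(key, value, expected) {
  if (is.numeric(value)) return(as.numeric(value))
  if (is.character(value) && length(value) == 1L) {
    parts <- strsplit(trimws(value), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(num)) stop("config key '", key, "': cannot parse value '",
                         value, "'")
    unit <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else ""
    ok <- .unit_synonyms[[expected]]
    if (is.null(ok)) ok <- expected
    if (!(unit %in% ok) && unit != "")
      stop("config key '", key, "': unit mismatch, got '", unit,
           "' but expected '", expected, "'")
    return(num)
  }
  stop("config key '", key, "': expected a number or '<value> <unit>' string")
}

.check_keys <- function(section, allowed, where) {
  unknown <- setdiff(names(section), allowed)
  if (length(unknown))
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
}

#' Parse a structured-text run configuration
#'
#' Reads a YAML configuration with sections \code{physiology},
#' \code{formulation} (release family, coefficients, dose),
#' \code{dosing} (list of events), \code{simulation} (grid and
#' far-boundary mode) and \code{pkpd} (MIC, evaluation interval, effect
#' parameters). Unknown keys are rejected with the offending key named;
#' physiology values may carry unit strings which are checked against the
#' documented unit for that key. Returns the fully constructed domain
#' objects ready for [simulate_oral()].
#'
#' @param path path to a YAML file, or a list already parsed from one
#' @return object of class \code{run_config}: \code{name}, \code{note},
#'   \code{physiology} ([oral_physiology()], user units), \code{release}
#'   ([release_model()] or NULL), \code{doses} (list of [dose_event()]),
#'   \code{grid} ([simulation_grid()] or NULL), \code{mode}, \code{pkpd}
#'   (list with MIC, interval, effect parameters or NULL)
#' @export
parse_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else path
  .check_keys(raw, c("name", "note", "physiology", "formulation", "dosing",
                     "simulation", "pkpd"), "top level")

  phys_units <- .config_units$physiology
  phys <- raw$physiology
  if (is.null(phys)) stop("config is missing the 'physiology' section")
  .check_keys(phys, names(phys_units), "physiology")
  phys_vals <- list()
  for (key in names(phys))
    phys_vals[[key]] <- .parse_valued_unit(paste0("physiology.", key),
                                           phys[[key]], phys_units[[key]])
  physiology <- do.call(oral_physiology, phys_vals)

  release <- NULL
  dose_amount <- NULL
  if (!is.null(raw$formulation)) {
    .check_keys(raw$formulation, c("family", "coefficients", "dose"),
                "formulation")
    if (is.null(raw$formulation$family))
      stop("formulation section needs a 'family'")
    dose_amount <- raw$formulation$dose
    release <- release_model(raw$formulation$family,
                             raw$formulation$coefficients,
                             M_inf = if (is.null(dose_amount)) 1
                                     else dose_amount)
  }

  doses <- list()
  if (!is.null(raw$dosing)) {
    for (i in seq_along(raw$dosing)) {
      ev <- raw$dosing[[i]]
      .check_keys(ev, c("route", "amount", "start", "duration"),
                  sprintf("dosing[%d]", i))
      doses[[i]] <- dose_event(
        amount = ev$amount,
        route = ev$route,
        start = if (is.null(ev$start)) 0 else ev$start,
        duration = if (is.null(ev$duration)) 0 else ev$duration)
    }
  }

  grid <- NULL; mode <- "auto"
  if (!is.null(raw$simulation)) {
    .check_keys(raw$simulation,
                c("t_end", "dt_out", "N_x", "rtol", "atol", "mode"),
                "simulation")
    s <- raw$simulation
    if (is.null(s$t_end)) stop("simulation section needs 't_end'")
    args <- list(t_end = s$t_end)
    for (k in c("dt_out", "N_x", "rtol", "atol"))
      if (!is.null(s[[k]])) args[[k]] <- s[[k]]
    grid <- do.call(simulation_grid, args)
    if (!is.null(s$mode)) {
      if (!s$mode %in% c("auto", "sealed", "coupled"))
        stop("simulation.mode must be auto, sealed or coupled")
      mode <- s$mode
    }
  }

  pkpd <- NULL
  if (!is.null(raw$pkpd)) {
    .check_keys(raw$pkpd,
                c("MIC", "interval", "Emax", "EC50", "h", "k_in", "k_out",
                  "k_e0", "Imax", "IC50", "growth_rate"), "pkpd")
    pkpd <- raw$pkpd
  }

  structure(list(name = raw$name, note = raw$note,
                 physiology = physiology, release = release,
                 doses = doses, grid = grid, mode = mode, pkpd = pkpd),
            class = "run_config")
}

#' Serialize a run configuration back to YAML
#'
#' Writes the resolved configuration (user units, all defaults filled in)
#' so that re-parsing reproduces an identical \code{run_config}.
#'
#' @param config a [parse_config()] result
#' @param path output file
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  p <- from_canonical(config$physiology)
  out <- list(name = config$name, note = config$note,
              physiology = lapply(unclass(p), as.numeric))
  if (!is.null(config$release))
    out$formulation <- list(family = config$release$family,
                            coefficients = lapply(config$release$coefficients,
                                                  as.numeric),
                            dose = config$release$M_inf)
  if (length(config$doses))
    out$dosing <- lapply(config$doses, function(d)
      list(route = d$route, amount = d$amount, start = d$start,
           duration = d$duration))
  if (!is.null(config$grid))
    out$simulation <- c(unclass(config$grid), list(mode = config$mode))
  if (!is.null(config$pkpd)) out$pkpd <- config$pkpd
  yaml::write_yaml(out, path)
  invisible(path)
}
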