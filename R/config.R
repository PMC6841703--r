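#' Incubation design
#'
#' Bundles the experimental constants of a glucose-addition incubation:
#' the measurement schedule, incubation temperature, soil mass per bottle,
#' headspace volume, the atom% \eqn{^{13}}C of the added glucose, the dosing
#' rule and the CO2 accumulation window before each headspace sampling.
#'
#' @param schedule Numeric vector of measurement days since glucose addition,
#'   strictly increasing. Default `c(1, 3, 8, 15, 35, 65)`.
#' @param temperature_c Incubation temperature in deg C. Default 15.
#' @param soil_mass_g Dry soil mass per bottle in g. Default 20.
#' @param headspace_volume_l Bottle headspace in litres. Default 0.1.
#' @param glucose_atom_pc atom% 13C of the added glucose. Default 3.0.
#' @param glucose_dose_rule Glucose-C dose as a fraction of microbial biomass
#'   C. Default 1 (dose equals 100% of MBC).
#' @param accumulation_hours Hours each bottle accumulates CO2 before
#'   sampling, either a scalar or one value per scheduled day. Default
#'   2 h on days 1--15 and 8 h on days 35 and 65.
#'
#' @return An object of class `incubation_design` (a named list).
#' @examples
#' d <- incubation_design()
#' d$schedule
#' @export
incubation_design <- function(schedule = c(1, 3, 8, 15, 35, 65),
                              temperature_c = 15,
                              soil_mass_g = 20,
                              headspace_volume_l = 0.1,
                              glucose_atom_pc = 3.0,
                              glucose_dose_rule = 1,
                              accumulation_hours = c(2, 2, 2, 2, 8, 8)) {
  schedule <- as.numeric(schedule)
  if (length(schedule) < 1L || any(diff(schedule) <= 0)) {
    stop("`schedule` must be a strictly increasing vector of days", call. = FALSE)
  }
  if (any(schedule < 0)) stop("`schedule` days must be >= 0", call. = FALSE)
  if (!(glucose_atom_pc > 1 && glucose_atom_pc < 100)) {
    stop("`glucose_atom_pc` must lie in (1, 100)", call. = FALSE)
  }
  if (length(accumulation_hours) == 1L) {
    accumulation_hours <- rep(accumulation_hours, length(schedule))
  }
  if (length(accumulation_hours) != length(schedule)) {
    stop("`accumulation_hours` must be scalar or match `schedule` length",
         call. = FALSE)
  }
  if (any(accumulation_hours <= 0)) {
    stop("`accumulation_hours` must be > 0", call. = FALSE)
  }
  structure(
    list(
      schedule = schedule,
      temperature_c = as.numeric(temperature_c),
      soil_mass_g = as.numeric(soil_mass_g),
      headspace_volume_l = as.numeric(headspace_volume_l),
      glucose_atom_pc = as.numeric(glucose_atom_pc),
      glucose_dose_rule = as.numeric(glucose_dose_rule),
      accumulation_hours = as.numeric(accumulation_hours)
    ),
    class = "incubation_design"
  )
}

#' @export
print.incubation_design <- function(x, ...) {
  cat("<incubation_design>\n")
  cat("  schedule (d):      ", paste(x$schedule, collapse = ", "), "\n")
  cat("  temperature (degC):", x$temperature_c, "\n")
  cat("  soil mass (g):     ", x$soil_mass_g, "\n")
  cat("  headspace (L):     ", x$headspace_volume_l, "\n")
  cat("  glucose atom% 13C: ", x$glucose_atom_pc, "\n")
  cat("  accumulation (h):  ", paste(x$accumulation_hours, collapse = ", "), "\n")
  invisible(x)
}

#' Physical and isotopic constants
#'
#' @param r_vpdb 13C/12C isotope ratio of the VPDB standard used for
#'   delta-to-atom% conversion. Default 0.0111802; the alternative
#'   literature value 0.011237 may be supplied.
#' @param blank_atom_pc atom% 13C assumed for blank-bottle CO2 when no
#'   isotope measurement is available (near natural abundance). Default 1.08.
#' @param pressure_atm Headspace pressure in atm for the ideal-gas
#'   concentration-to-flux conversion. Default 1.
#'
#' @return A named list of class `priming_constants`.
#' @export
priming_constants <- function(r_vpdb = 0.0111802,
                              blank_atom_pc = 1.08,
                              pressure_atm = 1) {
  stopifnot(r_vpdb > 0, pressure_atm > 0,
            blank_atom_pc > 0, blank_atom_pc < 100)
  structure(
    list(r_vpdb = r_vpdb, blank_atom_pc = blank_atom_pc,
         pressure_atm = pressure_atm),
    class = "priming_constants"
  )
}

#' Read a pipeline configuration file
#'
#' Reads a plain-text YAML configuration with `design` and `constants`
#' sections (any omitted key falls back to the package default) and returns
#' the corresponding [incubation_design()] and [priming_constants()] objects.
#'
#' @param path Path to a YAML file. `NULL` returns all defaults.
#' @return A list with elements `design`, `constants`, and `raw` (the parsed
#'   file contents).
#' @examples
#' cfg <- read_priming_config(NULL)
#' cfg$design$schedule
#' @export
read_priming_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  d <- raw$design %||% list()
  k <- raw$constants %||% list()
  design <- do.call(incubation_design, d[names(d) %in% names(formals(incubation_design))])
  constants <- do.call(priming_constants, k[names(k) %in% names(formals(priming_constants))])
  list(design = design, constants = constants, raw = raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
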