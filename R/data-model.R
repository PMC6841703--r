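#' Convert delta 13C (VPDB) to atom% 13C
#'
#' atom% = 100 R / (1 + R) with R = R_VPDB (delta/1000 + 1). The inverse
#' is [atom_percent_to_delta()]; the round trip is exact to machine
#' precision.
#'
#' @param delta delta 13C in permil vs VPDB; must be > -1000.
#' @param r_vpdb 13C/12C ratio of the VPDB standard (see
#'   [priming_constants()]).
#' @return atom% 13C, same length as `delta`.
#' @examples
#' delta_to_atom_percent(0)      # natural abundance, ~1.1057
#' delta_to_atom_percent(1000)   # strongly enriched
#' @export
delta_to_atom_percent <- function(delta, r_vpdb = priming_constants()$r_vpdb) {
  if (any(delta <= -1000, na.rm = TRUE)) {
    stop("delta 13C must be > -1000 permil", call. = FALSE)
  }
  r <- r_vpdb * (delta / 1000 + 1)
  100 * r / (1 + r)
}

#' Convert atom% 13C to delta 13C (VPDB)
#'
#' @param atom_pc atom% 13C in (0, 100).
#' @inheritParams delta_to_atom_percent
#' @return delta 13C in permil vs VPDB.
#' @export
atom_percent_to_delta <- function(atom_pc, r_vpdb = priming_constants()$r_vpdb) {
  if (any(atom_pc <= 0 | atom_pc >= 100, na.rm = TRUE)) {
    stop("atom% 13C must lie in (0, 100)", call. = FALSE)
  }
  r <- atom_pc / (100 - atom_pc)
  1000 * (r / r_vpdb - 1)
}

# J mol^-1 K^-1 and Pa per atm; molar mass of carbon in g mol^-1
.R_GAS <- 8.314462618
.PA_PER_ATM <- 101325
.M_C <- 12.011

#' Convert net headspace CO2 concentration to a CO2-C flux
#'
#' Ideal-gas conversion of the blank-corrected headspace CO2 accumulated
#' over the sampling window into a soil respiration rate. The moles of
#' headspace air are \eqn{n = PV/RT}; the net CO2 (mmol CO2 per mol air)
#' then yields a CO2-C mass that is normalised by dry soil mass and scaled
#' from the accumulation window to a daily rate.
#'
#' @param conc_soil Headspace CO2 concentration in the soil bottle,
#'   mmol CO2 mol^-1.
#' @param conc_blank Concentration in the blank bottle, mmol mol^-1.
#' @param design An [incubation_design()].
#' @param accumulation_hours Sampling window in hours; defaults to the first
#'   element of `design$accumulation_hours`.
#' @param constants A [priming_constants()] (supplies pressure).
#' @param tol Negative net concentrations larger (in magnitude) than `tol`
#'   raise an error; tolerance-sized ones are clamped to zero with a warning.
#' @return Flux in ug CO2-C g^-1 dry soil d^-1.
#' @examples
#' d <- incubation_design()
#' concentration_to_cflux(2.0, 0.05, d, accumulation_hours = 2)
#' @export
concentration_to_cflux <- function(conc_soil, conc_blank, design,
                                   accumulation_hours = design$accumulation_hours[1],
                                   constants = priming_constants(),
                                   tol = 1e-9) {
  stopifnot(inherits(design, "incubation_design"))
  net <- conc_soil - conc_blank
  if (any(net < -tol, na.rm = TRUE)) {
    stop("soil-bottle CO2 concentration below blank: negative net flux",
         call. = FALSE)
  }
  if (any(net < 0, na.rm = TRUE)) {
    warning("tolerance-sized negative net CO2 concentration clamped to 0")
    net <- pmax(net, 0)
  }
  t_k <- design$temperature_c + 273.15
  n_air <- constants$pressure_atm * .PA_PER_ATM *
    (design$headspace_volume_l / 1000) / (.R_GAS * t_k) # mol air
  mol_co2 <- net * 1e-3 * n_air
  ug_c <- mol_co2 * .M_C * 1e6
  ug_c / design$soil_mass_g / (accumulation_hours / 24)
}

#' Invert [concentration_to_cflux()]
#'
#' Net headspace concentration (mmol mol^-1) that corresponds to a given
#' CO2-C flux; used by the simulator to lay fluxes back onto the
#' concentration scale the instrument reports.
#'
#' @param flux ug CO2-C g^-1 d^-1.
#' @inheritParams concentration_to_cflux
#' @return Net concentration in mmol CO2 mol^-1.
#' @export
cflux_to_net_concentration <- function(flux, design,
                                       accumulation_hours = design$accumulation_hours[1],
                                       constants = priming_constants()) {
  per_unit <- concentration_to_cflux(1, 0, design,
                                     accumulation_hours = accumulation_hours,
                                     constants = constants)
  flux / per_unit
}

.TREATMENTS <- c("control", "glucose", "blank")

#' Read and validate an incubation measurement table
#'
#' Expects a CSV with columns `site_id, bottle_id, treatment, replicate, day,
#' co2_conc_mmol_mol, flux_ugC_g_d, atom_pc, delta13c_permil` (empty cells =
#' missing). Each row is one bottle at one measurement day. Validation
#' enforces the treatment vocabulary (`control`, `glucose`, `blank`),
#' uniqueness of (bottle, day), presence of at least one of concentration or
#' flux, and -- for non-blank CO2-bearing rows -- exactly one isotope column.
#' delta 13C values are converted to atom% at ingest so downstream code sees
#' a single isotope scale.
#'
#' @param path CSV file path.
#' @param design An [incubation_design()]; used to sanity-check days.
#' @param constants A [priming_constants()] (VPDB ratio for conversion,
#'   default blank atom%).
#' @return A tibble of validated measurement records with a unified
#'   `atom_pc` column.
#' @export
read_incubation_table <- function(path, design = incubation_design(),
                                  constants = priming_constants()) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    bottle_id = readr::col_character(),
    treatment = readr::col_character(),
    replicate = readr::col_integer(),
    day = readr::col_double(),
    co2_conc_mmol_mol = readr::col_double(),
    flux_ugC_g_d = readr::col_double(),
    atom_pc = readr::col_double(),
    delta13c_permil = readr::col_double()
  ), show_col_types = FALSE)
  if (nrow(raw) == 0L) {
    warning("incubation table ", path, " has a header but no rows")
    return(validate_incubation(raw, constants = constants))
  }
  validate_incubation(raw, constants = constants)
}

#' Validate an in-memory incubation table
#'
#' Same checks as [read_incubation_table()] for records built in code.
#'
#' @param records Data frame with the incubation-table columns (missing
#'   optional columns are tolerated).
#' @param constants A [priming_constants()].
#' @return A validated tibble with a unified `atom_pc` column.
#' @export
validate_incubation <- function(records, constants = priming_constants()) {
  x <- tibble::as_tibble(records)
  for (col in c("co2_conc_mmol_mol", "flux_ugC_g_d", "atom_pc", "delta13c_permil")) {
    if (!col %in% names(x)) x[[col]] <- NA_real_
  }
  need <- c("site_id", "bottle_id", "treatment", "replicate", "day")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("incubation table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0L) return(x)

  bad <- which(!x$treatment %in% .TREATMENTS)
  if (length(bad)) {
    stop(sprintf("row %d: unknown treatment label '%s' (expected %s)",
                 bad[1], x$treatment[bad[1]],
                 paste(.TREATMENTS, collapse = "/")), call. = FALSE)
  }
  dup <- which(duplicated(x[, c("bottle_id", "day")]))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate (bottle_id, day) = ('%s', %g)",
                 dup[1], x$bottle_id[dup[1]], x$day[dup[1]]), call. = FALSE)
  }
  no_signal <- which(is.na(x$co2_conc_mmol_mol) & is.na(x$flux_ugC_g_d))
  if (length(no_signal)) {
    stop(sprintf("row %d: neither co2_conc_mmol_mol nor flux_ugC_g_d present",
                 no_signal[1]), call. = FALSE)
  }
  if (any(x$day < 0, na.rm = TRUE)) {
    stop("day must be >= 0", call. = FALSE)
  }
  if (any(x$co2_conc_mmol_mol < 0, na.rm = TRUE)) {
    stop("co2_conc_mmol_mol must be >= 0", call. = FALSE)
  }
  if (any(x$replicate < 1, na.rm = TRUE)) {
    stop("replicate must be >= 1", call. = FALSE)
  }

  both <- which(!is.na(x$atom_pc) & !is.na(x$delta13c_permil))
  if (length(both)) {
    stop(sprintf("row %d: supply atom_pc or delta13c_permil, not both", both[1]),
         call. = FALSE)
  }
  conv <- !is.na(x$delta13c_permil)
  x$atom_pc[conv] <- delta_to_atom_percent(x$delta13c_permil[conv],
                                           r_vpdb = constants$r_vpdb)
  non_blank <- x$treatment != "blank"
  iso_missing <- which(non_blank & is.na(x$atom_pc))
  if (length(iso_missing)) {
    stop(sprintf(
      "row %d: non-blank record needs exactly one of atom_pc/delta13c_permil",
      iso_missing[1]), call. = FALSE)
  }
  # blanks without an isotope measurement fall back to the configured default
  x$atom_pc[!non_blank & is.na(x$atom_pc)] <- constants$blank_atom_pc
  if (any(x$atom_pc <= 0 | x$atom_pc >= 100, na.rm = TRUE)) {
    stop("atom_pc must lie in (0, 100)", call. = FALSE)
  }
  x$delta13c_permil <- NULL
  x
}

#' Read a site-covariate table
#'
#' Long format: `site_id, group, variable, value`, one row per site and
#' variable, with `group` one of `plant`, `soil`, `microbial`,
#' `som_stability`.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_covariates_table <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    group = readr::col_character(),
    variable = readr::col_character(),
    value = readr::col_double()
  ), show_col_types = FALSE)
  validate_covariates(x)
}

#' Validate a site-covariate table
#'
#' @param x Data frame with columns `site_id, group, variable, value`.
#' @return The input as a tibble, after checks.
#' @export
validate_covariates <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("site_id", "group", "variable", "value")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("covariate table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  groups <- c("plant", "soil", "microbial", "som_stability")
  bad <- which(!x$group %in% groups)
  if (length(bad)) {
    stop(sprintf("row %d: unknown covariate group '%s'", bad[1], x$group[bad[1]]),
         call. = FALSE)
  }
  dup <- which(duplicated(x[, c("site_id", "group", "variable")]))
  if (length(dup)) {
    stop(sprintf("row %d: duplicate (site_id, group, variable)", dup[1]),
         call. = FALSE)
  }
  x
}

#' Pivot a long covariate table to a site-by-variable matrix for one group
#'
#' @param covariates Long covariate tibble (see [read_covariates_table()]).
#' @param group Which variable group to extract; `NULL` keeps all.
#' @return A tibble with one row per site and one column per variable.
#' @export
covariates_wide <- function(covariates, group = NULL) {
  x <- tibble::as_tibble(covariates)
  if (!is.null(group)) x <- dplyr::filter(x, .data$group %in% !!group)
  tidyr::pivot_wider(x[, c("site_id", "variable", "value")],
                     names_from = "variable", values_from = "value")
}
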