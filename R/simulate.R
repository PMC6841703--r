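# map u in (0,1) into a range, optionally on the log scale so broad,
# right-skewed soil variables (SOC, MBC, metal/SOC ratios) stay realistic
bounded <- function(u, lo, hi, log = FALSE) {
  if (log) exp(log(lo) + u * (log(hi) - log(lo))) else lo + u * (hi - lo)
}

zstd <- function(v) {
  if (length(v) < 2L || stats::sd(v) == 0) return(rep(0, length(v)))
  as.numeric(scale(v))
}

#' Generating model of the true priming amplitude
#'
#' The synthetic transect generates each site's priming amplitude as a
#' linear function of its (standardised) recalcitrant-pool proportion and,
#' negatively, its mineral-protection ratio, plus Gaussian noise -- so the
#' driver-screening statistics have a known signal to recover.
#'
#' @return A list: `intercept`, `coef` (named vector over the generating
#'   covariates, applied to the standardised recalcitrant-pool proportion
#'   and the standardised log of the Fe/Al-to-SOC ratio `feal_d_soc`),
#'   `sd` (residual SD).
#' @export
priming_amplitude_model <- function() {
  list(intercept = 0.45,
       coef = c(recalcitrant_pool = 0.30, feal_d_soc = -0.20),
       sd = 0.10)
}

#' Generate a synthetic incubation transect with known ground truth
#'
#' Draws `n_sites` sites along a synthetic precipitation gradient
#' (89--534 mm): the wettest 40% are classed `meadow`, the rest `steppe`,
#' mirroring an 18-steppe / 12-meadow design at the default 30 sites.
#' Covariates in the four driver groups co-vary with the gradient within
#' realistic ranges (SOC 1.1--118 g kg^-1, MBC 23--1101 mg C kg^-1, pH
#' 6.2--9.4). Each site carries a true two-pool parameter set, a glucose
#' dose equal to its microbial biomass C, and a true priming amplitude
#' generated from [priming_amplitude_model()].
#'
#' @param n_sites Number of sites (default 30).
#' @param seed Integer seed; identical seeds give identical transects.
#' @param meadow_fraction Fraction of (wettest) sites classed meadow.
#' @param lambda True priming decay rate, d^-1.
#' @param k_g Glucose mineralisation rate, d^-1.
#' @param phi Fraction of the glucose dose that is mineralised.
#' @param som_atom_pc atom% 13C of native SOM respiration.
#' @return A list with `truth` (one row per site: ecosystem, precipitation,
#'   two-pool parameters, `soc_g_kg`, `pi0`, `lambda`, `glucose_dose_ug_g`,
#'   `k_g`, `phi`, `som_atom_pc`) and `covariates` (long tibble
#'   `site_id, group, variable, value`).
#' @examples
#' tr <- generate_transect(5, seed = 1)
#' tr$truth$ecosystem
#' @export
generate_transect <- function(n_sites = 30, seed = 42,
                              meadow_fraction = 0.4,
                              lambda = 0.02, k_g = 0.3, phi = 0.6,
                              som_atom_pc = 1.08) {
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (!(phi > 0 && phi <= 1)) stop("phi must lie in (0, 1]", call. = FALSE)
  set.seed(as.integer(seed))

  precip <- sort(stats::runif(n_sites, 89, 534))
  z_p <- zstd(precip)
  n_meadow <- round(meadow_fraction * n_sites)
  ecosystem <- c(rep("steppe", n_sites - n_meadow), rep("meadow", n_meadow))
  site_id <- sprintf("S%02d", seq_len(n_sites))

  # latent mix of gradient signal and site-level noise, squashed to (0,1)
  latent <- function(w_grad, w_noise = sqrt(1 - w_grad^2)) {
    stats::plogis(w_grad * z_p + w_noise * stats::rnorm(n_sites))
  }

  cov <- list(
    plant = tibble::tibble(
      npp = bounded(latent(0.85), 38, 488),
      anpp = bounded(latent(0.8), 15, 300),
      grass_cover = bounded(latent(-0.5), 5, 85),
      forb_cover = bounded(latent(0.4), 2, 50)
    ),
    soil = tibble::tibble(
      soc = bounded(latent(0.9), 1.1, 118, log = TRUE),
      tn = bounded(latent(0.8), 0.1, 9),
      ph = 9.4 - 3.2 * latent(0.85),
      clay = bounded(latent(0.4), 3, 35),
      bd = 1.5 - 0.5 * latent(0.7)
    ),
    microbial = tibble::tibble(
      mbc = bounded(latent(0.85), 23, 1101, log = TRUE),
      plfa_total = bounded(latent(0.75), 1, 60, log = TRUE),
      fb_ratio = bounded(latent(0.2), 0.1, 1.5),
      c_enzyme = bounded(latent(0.6), 10, 200, log = TRUE)
    ),
    som_stability = tibble::tibble(
      labile_pool_1 = bounded(latent(0.35), 5, 40),
      labile_pool_2 = bounded(latent(0.25), 3, 20),
      recalcitrant_pool = bounded(latent(0.45), 30, 80),
      feal_d_soc = bounded(latent(-0.55), 0.3, 20, log = TRUE),
      ca_soc = bounded(latent(-0.5), 0.1, 10, log = TRUE),
      macroagg_c = bounded(latent(0.5), 10, 60)
    )
  )

  model <- priming_amplitude_model()
  z_rec <- zstd(cov$som_stability$recalcitrant_pool)
  z_min <- zstd(log(cov$som_stability$feal_d_soc))
  pi0 <- model$intercept +
    model$coef[["recalcitrant_pool"]] * z_rec +
    model$coef[["feal_d_soc"]] * z_min +
    stats::rnorm(n_sites, 0, model$sd)
  pi0 <- pmax(pi0, -0.9)  # SOM flux in the treated soil must stay positive

  # two-pool truths: larger fast pools in soils with more labile C
  u_f1 <- stats::plogis(-0.6 * z_rec + 0.8 * stats::rnorm(n_sites))
  truth <- tibble::tibble(
    site_id = site_id,
    ecosystem = ecosystem,
    precip_mm = precip,
    f1 = bounded(u_f1, 0.008, 0.12, log = TRUE),
    k1 = bounded(stats::runif(n_sites), 0.04, 0.35, log = TRUE),
    k2 = bounded(stats::runif(n_sites), 5e-5, 1.5e-3, log = TRUE),
    c_tot = 1000,
    soc_g_kg = cov$soil$soc,
    pi0 = as.numeric(pi0),
    lambda = lambda,
    glucose_dose_ug_g = cov$microbial$mbc,  # mg C kg^-1 == ug C g^-1
    k_g = k_g,
    phi = phi,
    som_atom_pc = som_atom_pc
  )

  covariates <- purrr::imap_dfr(cov, function(tbl, grp) {
    tbl |>
      dplyr::mutate(site_id = site_id) |>
      tidyr::pivot_longer(-"site_id", names_to = "variable",
                          values_to = "value") |>
      dplyr::mutate(group = grp, .after = "site_id")
  }) |>
    dplyr::arrange(.data$site_id, .data$group, .data$variable)

  list(truth = truth, covariates = validate_covariates(covariates))
}

# true per-day fluxes (ug C g^-1 soil d^-1) for one truth row
true_fluxes <- function(tr, day) {
  params <- two_pool_params(tr$f1, tr$k1, tr$k2, tr$c_tot)
  control <- two_pool_rate(day, params) * tr$soc_g_kg / tr$c_tot * 1000
  som_treat <- control * (1 + tr$pi0 * exp(-tr$lambda * day))
  glucose <- tr$glucose_dose_ug_g * tr$phi * tr$k_g * exp(-tr$k_g * day)
  tibble::tibble(day = day, control = control, som_treat = som_treat,
                 glucose = glucose,
                 priming = som_treat - control,
                 treat_total = som_treat + glucose)
}

#' True priming rate of a synthetic site
#'
#' @param truth One row of the `truth` tibble from [generate_transect()].
#' @param day Days since glucose addition (vectorised).
#' @return Priming rate in ug C g^-1 d^-1.
#' @export
true_priming_rate <- function(truth, day) {
  stopifnot(nrow(truth) == 1L)
  true_fluxes(truth, day)$priming
}

#' Analytic cumulative true priming of a synthetic site
#'
#' Because priming is modelled as an exponentially decaying multiplier on
#' the two-pool SOM flux, its time integral has the closed form
#' `pi0 * soc * sum_j k_j f_j / (k_j + lambda) * (1 - exp(-(k_j + lambda) T))`.
#'
#' @param truth One row of the `truth` tibble from [generate_transect()].
#' @param t_max Upper integration limit in days (default 65).
#' @return Cumulative priming, ug C g^-1.
#' @export
true_cumulative_priming <- function(truth, t_max = 65) {
  stopifnot(nrow(truth) == 1L)
  with(truth, {
    lam <- lambda
    # flux scale: R(t) [mg C g-1 SOC d-1] x soc/c_tot x 1000 -> ug C g-1 d-1
    term <- function(k, f) k * f * c_tot * (1 - exp(-(k + lam) * t_max)) / (k + lam)
    pi0 * soc_g_kg / c_tot * 1000 * (term(k1, f1) + term(k2, 1 - f1))
  })
}

#' Simulate incubation measurements for a synthetic transect
#'
#' Forward model: the control SOM-derived flux follows each site's two-pool
#' truth scaled to per-g-soil; the treated SOM flux is amplified by
#' `1 + pi0 exp(-lambda t)`; glucose-derived CO2 decays as first-order
#' mineralisation of the mineralisable dose. Fluxes are laid back onto the
#' headspace-concentration scale (inverse ideal-gas conversion), mixed with
#' the ambient blank CO2, and measured by triplicate bottles per treatment
#' with independent multiplicative flux noise and additive atom% noise,
#' plus shared blank bottles. With zero noise the partitioning stage
#' recovers the generator truth exactly.
#'
#' @param transect Output of [generate_transect()] (or its `truth` tibble).
#' @param design An [incubation_design()].
#' @param noise_flux_rel Relative SD of per-bottle flux noise (default
#'   0.05).
#' @param noise_atom_abs Absolute SD of atom% noise (default 0.005).
#' @param seed Integer root seed (per-site child streams).
#' @param n_replicates Bottles per treatment (default 3).
#' @param n_blanks Shared blank bottles (default 5).
#' @param blank_conc Ambient CO2 in blank bottles, mmol mol^-1.
#' @param constants A [priming_constants()] (blank atom%).
#' @return A validated measurement tibble (see [read_incubation_table()]).
#' @export
simulate_incubation <- function(transect, design = incubation_design(),
                                noise_flux_rel = 0.05,
                                noise_atom_abs = 0.005,
                                seed = 42, n_replicates = 3, n_blanks = 5,
                                blank_conc = 0.05,
                                constants = priming_constants()) {
  truth <- if (is.data.frame(transect)) transect else transect$truth
  if (noise_flux_rel < 0 || noise_atom_abs < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  days <- design$schedule
  acc <- design$accumulation_hours
  per_unit <- vapply(acc, function(h) {
    concentration_to_cflux(1, 0, design, accumulation_hours = h,
                           constants = constants)
  }, numeric(1))

  bottle_rows <- function(site, treat, rep_id, flux_true, at_resp, s) {
    set.seed(s)
    flux <- flux_true * (1 + stats::rnorm(length(flux_true), 0, noise_flux_rel))
    flux <- pmax(flux, 0)
    net <- flux / per_unit
    conc <- blank_conc + net
    at <- ifelse(net > 0,
                 (at_resp * net + constants$blank_atom_pc * blank_conc) / conc,
                 constants$blank_atom_pc)
    at <- at + stats::rnorm(length(at), 0, noise_atom_abs)
    tibble::tibble(
      site_id = site,
      bottle_id = paste(site, treat, rep_id, sep = "_"),
      treatment = treat, replicate = rep_id, day = days,
      co2_conc_mmol_mol = conc, flux_ugC_g_d = NA_real_, atom_pc = at
    )
  }

  site_records <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    fl <- true_fluxes(tr, days)
    at_treat <- ifelse(
      fl$treat_total > 0,
      (tr$som_atom_pc * fl$som_treat + design$glucose_atom_pc * fl$glucose) /
        fl$treat_total,
      tr$som_atom_pc)
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      dplyr::bind_rows(
        bottle_rows(tr$site_id, "control", r, fl$control, tr$som_atom_pc,
                    site_seed(seed, paste0(tr$site_id, "_c", r))),
        bottle_rows(tr$site_id, "glucose", r, fl$treat_total, at_treat,
                    site_seed(seed, paste0(tr$site_id, "_g", r)))
      )
    })
  })

  blank_records <- purrr::map_dfr(seq_len(n_blanks), function(b) {
    set.seed(site_seed(seed, paste0("__blank_", b)))
    conc <- blank_conc * (1 + stats::rnorm(length(days), 0, noise_flux_rel))
    at <- constants$blank_atom_pc + stats::rnorm(length(days), 0, noise_atom_abs)
    tibble::tibble(
      site_id = "blank", bottle_id = paste0("blank_", b),
      treatment = "blank", replicate = b, day = days,
      co2_conc_mmol_mol = pmax(conc, 0), flux_ugC_g_d = NA_real_, atom_pc = at
    )
  })

  validate_incubation(dplyr::bind_rows(site_records, blank_records),
                      constants = constants)
}

#' Write synthetic fixtures to disk
#'
#' Emits `incubation.csv`, `covariates.csv` and `truth.csv` in the schemas
#' the readers expect, so a written fixture round-trips through
#' [read_incubation_table()] / [read_covariates_table()] exactly.
#'
#' @param transect Output of [generate_transect()].
#' @param records Output of [simulate_incubation()].
#' @param out_dir Writable directory (created if missing).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_fixtures <- function(transect, records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  inc <- tibble::as_tibble(records)
  inc$delta13c_permil <- NA_real_
  paths <- c(
    incubation = file.path(out_dir, "incubation.csv"),
    covariates = file.path(out_dir, "covariates.csv"),
    truth = file.path(out_dir, "truth.csv")
  )
  readr::write_csv(inc[, c("site_id", "bottle_id", "treatment", "replicate",
                           "day", "co2_conc_mmol_mol", "flux_ugC_g_d",
                           "atom_pc", "delta13c_permil")],
                   paths["incubation"], na = "")
  readr::write_csv(transect$covariates, paths["covariates"], na = "")
  readr::write_csv(transect$truth, paths["truth"], na = "")
  invisible(paths)
}
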