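#' Error propagation for the treated SOM-derived flux
#'
#' Combines the relative uncertainties of the treated total flux and of the
#' SOM fraction in quadrature, `rel = sqrt((s_ct/c_treat)^2 +
#' (s_f/f_som)^2)`, and returns the absolute SD of the SOM-derived flux,
#' `som_flux_mean * rel`.
#'
#' @param sigma_ctreat SD (or standard error) of the treated total flux.
#' @param c_treat Mean treated total flux (> 0).
#' @param sigma_fsom SD (or standard error) of the SOM fraction.
#' @param f_som Mean SOM fraction (> 0).
#' @param som_flux_mean Mean SOM-derived flux of the treated soil.
#' @return SD of the treated SOM-derived flux, same units as
#'   `som_flux_mean`.
#' @examples
#' som_flux_sd(10, 100, 0.08, 0.8, 80) # 80 * sqrt(0.02)
#' @export
som_flux_sd <- function(sigma_ctreat, c_treat, sigma_fsom, f_som,
                        som_flux_mean) {
  if (any(sigma_ctreat < 0 | sigma_fsom < 0, na.rm = TRUE)) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  if (any((c_treat <= 0 & sigma_ctreat > 0) | (f_som <= 0 & sigma_fsom > 0),
          na.rm = TRUE)) {
    stop("zero or negative mean with nonzero SD: relative error undefined",
         call. = FALSE)
  }
  rel2 <- ifelse(sigma_ctreat > 0, (sigma_ctreat / c_treat)^2, 0) +
    ifelse(sigma_fsom > 0, (sigma_fsom / f_som)^2, 0)
  som_flux_mean * sqrt(rel2)
}

# Deterministic per-site child seed below 2^31, insensitive to site order.
site_seed <- function(seed, site_id) {
  h <- sum(utf8ToInt(as.character(site_id)) *
             (seq_along(utf8ToInt(as.character(site_id))) + 31L))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Build Monte-Carlo inputs from an incubation table
#'
#' Per site and day: mean and standard error of the treated SOM-derived flux
#' (via [som_flux_sd()], combining replicate scatter of the treated total
#' flux and of the SOM fraction from [partition_replicates()]) and mean and
#' standard error of the control (basal) flux. Standard errors are the
#' replicate SDs divided by sqrt(n), so the resulting confidence interval
#' describes the site-level mean cumulative priming.
#'
#' @inheritParams partition_incubation
#' @return A tibble `site_id, day, som_treat_mean, som_treat_sd,
#'   control_mean, control_sd, n_treat, n_control`.
#' @export
build_uncertainty_inputs <- function(records, design = incubation_design(),
                                     constants = priming_constants(),
                                     at_som_override = NULL) {
  base <- partition_incubation(records, design, constants, at_som_override)
  reps <- partition_replicates(records, design, constants, at_som_override)

  rep_stats <- reps |>
    dplyr::group_by(.data$site_id, .data$day) |>
    dplyr::summarise(
      n_treat = dplyr::n(),
      se_ctreat = stats::sd(.data$c_treat_rep) / sqrt(dplyr::n()),
      se_fsom = stats::sd(.data$f_som_rep) / sqrt(dplyr::n()),
      .groups = "drop"
    )

  agg <- aggregate_replicates(records)
  blanks <- blank_summary(agg, constants)
  hrs <- tibble::tibble(day = design$schedule,
                        acc_hours = design$accumulation_hours)
  ctl <- tibble::as_tibble(records) |>
    dplyr::filter(.data$treatment == "control") |>
    dplyr::left_join(blanks, by = "day") |>
    dplyr::left_join(hrs, by = "day")
  ctl$acc_hours[is.na(ctl$acc_hours)] <- design$accumulation_hours[1]
  ctl$blank_conc[is.na(ctl$blank_conc)] <- 0
  ctl$flux <- ifelse(is.na(ctl$flux_ugC_g_d),
                     concentration_to_cflux(ctl$co2_conc_mmol_mol,
                                            ctl$blank_conc, design,
                                            ctl$acc_hours, constants),
                     ctl$flux_ugC_g_d)
  ctl_stats <- ctl |>
    dplyr::group_by(.data$site_id, .data$day) |>
    dplyr::summarise(
      n_control = dplyr::n(),
      control_mean = mean(.data$flux),
      control_sd = stats::sd(.data$flux) / sqrt(dplyr::n()),
      .groups = "drop"
    )

  base |>
    dplyr::left_join(rep_stats, by = c("site_id", "day")) |>
    dplyr::left_join(ctl_stats, by = c("site_id", "day")) |>
    dplyr::mutate(
      som_treat_mean = .data$som_flux_treat,
      som_treat_sd = som_flux_sd(
        dplyr::coalesce(.data$se_ctreat, 0), .data$c_treat,
        dplyr::coalesce(.data$se_fsom, 0), .data$f_som,
        .data$som_flux_treat),
      control_sd = dplyr::coalesce(.data$control_sd, 0)
    ) |>
    dplyr::select("site_id", "day", "som_treat_mean", "som_treat_sd",
                  "control_mean", "control_sd", "n_treat", "n_control") |>
    dplyr::arrange(.data$site_id, .data$day)
}

#' Monte-Carlo confidence interval for cumulative priming at one site
#'
#' For each draw, per-day SOM-derived fluxes of the treated and control
#' soils are sampled independently from normal distributions with the
#' supplied means and SDs, differenced into a per-day priming series,
#' and integrated with [cumulative_priming()]. The 2.5th and 97.5th
#' percentiles over draws give the 95% confidence interval. Negative draws
#' are permitted (priming may be negative); nothing is truncated.
#'
#' @param inputs A tibble for one site with columns `day`,
#'   `som_treat_mean`, `som_treat_sd`, `control_mean`, `control_sd`,
#'   sorted or sortable by day.
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed; identical seed and inputs give identical
#'   intervals.
#' @param leading_rectangle Passed to [cumulative_priming()].
#' @return A one-row tibble: `cumulative_mean` (deterministic integral of
#'   the mean priming series), `ci_low`, `ci_high`, `n_draws`, `seed`.
#' @export
monte_carlo_priming <- function(inputs, n_draws = 1000, seed = 1L,
                                leading_rectangle = TRUE) {
  x <- dplyr::arrange(tibble::as_tibble(inputs), .data$day)
  if (nrow(x) < 1L) stop("no per-day inputs supplied", call. = FALSE)
  if (any(is.na(x$som_treat_mean) | is.na(x$control_mean))) {
    stop("means must be available at every scheduled day", call. = FALSE)
  }
  if (any(x$som_treat_sd < 0 | x$control_sd < 0)) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)

  nd <- nrow(x)
  # trapezoid + optional leading-rectangle weights; linear in the rates, so
  # the integral of each draw is weights %*% priming-draw
  w <- integration_weights(x$day, leading_rectangle)

  set.seed(seed)
  treat <- matrix(stats::rnorm(n_draws * nd, mean = rep(x$som_treat_mean, each = n_draws),
                               sd = rep(x$som_treat_sd, each = n_draws)),
                  nrow = n_draws)
  ctrl <- matrix(stats::rnorm(n_draws * nd, mean = rep(x$control_mean, each = n_draws),
                              sd = rep(x$control_sd, each = n_draws)),
                 nrow = n_draws)
  draws <- as.vector((treat - ctrl) %*% w)
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 7)
  tibble::tibble(
    cumulative_mean = sum(w * (x$som_treat_mean - x$control_mean)),
    ci_low = qs[1], ci_high = qs[2],
    n_draws = as.integer(n_draws), seed = as.integer(seed)
  )
}

# quadrature weights such that sum(w * rates) == cumulative_priming()
integration_weights <- function(days, leading_rectangle = TRUE) {
  n <- length(days)
  w <- numeric(n)
  if (n > 1L) {
    d <- diff(days)
    w[1:(n - 1)] <- w[1:(n - 1)] + d / 2
    w[2:n] <- w[2:n] + d / 2
  }
  if (leading_rectangle) w[1] <- w[1] + days[1]
  w
}

#' Monte-Carlo priming confidence intervals for all sites
#'
#' Runs [monte_carlo_priming()] per site with deterministic per-site child
#' seeds derived from one root seed, so the result does not depend on site
#' order.
#'
#' @inheritParams partition_incubation
#' @param n_draws Draws per site (default 1000).
#' @param seed Root seed.
#' @param leading_rectangle Passed to [cumulative_priming()].
#' @return A tibble `site_id, cumulative_mean, ci_low, ci_high, n_draws,
#'   seed`.
#' @export
priming_ci <- function(records, design = incubation_design(),
                       constants = priming_constants(),
                       n_draws = 1000, seed = 1L,
                       leading_rectangle = TRUE,
                       at_som_override = NULL) {
  inputs <- build_uncertainty_inputs(records, design, constants,
                                     at_som_override)
  inputs |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(df, key) {
      monte_carlo_priming(df, n_draws = n_draws,
                          seed = site_seed(seed, key$site_id),
                          leading_rectangle = leading_rectangle)
    }) |>
    dplyr::ungroup()
}
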