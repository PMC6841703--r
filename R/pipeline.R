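#' Run the full priming pipeline
#'
#' Orchestrates simulate -> partition -> priming-ci -> fit-twopool ->
#' drivers as one reproducible run. Each stage writes its CSV into
#' `out_dir`; the run ends with a machine-readable `summary.json` (per-site
#' cumulative priming with its Monte-Carlo CI, day-1 relative priming,
#' two-pool estimates, headline driver statistics) and a `manifest.json`
#' (config snapshot, seeds, file hashes, package version, timestamp).
#' `summary.json` contains no timestamps, so identical configuration and
#' seed reproduce it byte-for-byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed for every stochastic stage.
#' @param config Path to a YAML config file, or `NULL` for defaults.
#' @param simulate Generate the inputs with [generate_transect()] /
#'   [simulate_incubation()] (default). If `FALSE`, `incubation` and
#'   `covariates` CSV paths must be supplied.
#' @param incubation,covariates Input CSV paths when `simulate = FALSE`.
#' @param n_sites Sites to simulate.
#' @param n_draws Monte-Carlo draws per site.
#' @param mcmc_chains,mcmc_iter MCMC settings for the two-pool stage. The
#'   pipeline default (3 x 4000) is a screening setting; raise `mcmc_iter`
#'   for production two-pool estimates.
#' @param noise_flux_rel,noise_atom_abs Simulator noise settings.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, the manifest list.
#' @export
run_priming_pipeline <- function(out_dir, seed = 42, config = NULL,
                                 simulate = TRUE,
                                 incubation = NULL, covariates = NULL,
                                 n_sites = 30, n_draws = 1000,
                                 mcmc_chains = 3, mcmc_iter = 4000,
                                 noise_flux_rel = 0.05,
                                 noise_atom_abs = 0.005,
                                 quiet = FALSE) {
  cfg <- read_priming_config(config)
  design <- cfg$design
  constants <- cfg$constants
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  outputs <- character()
  warn_counts <- list(clamped_fractions = 0L, truncated_fractions = 0L)

  # -- simulate ---------------------------------------------------------
  if (simulate) {
    say("stage simulate: ", n_sites, " sites, seed ", seed)
    sim <- stage("simulate", {
      tr <- generate_transect(n_sites, seed = seed)
      rec <- simulate_incubation(tr, design,
                                 noise_flux_rel = noise_flux_rel,
                                 noise_atom_abs = noise_atom_abs,
                                 seed = seed, constants = constants)
      paths <- write_fixtures(tr, rec, out_dir)
      list(truth = tr$truth, covariates = tr$covariates, records = rec,
           paths = paths)
    })
    records <- sim$records
    covariates_tbl <- sim$covariates
    outputs <- c(outputs, sim$paths)
  } else {
    if (is.null(incubation) || is.null(covariates)) {
      stop("supply `incubation` and `covariates` paths or set simulate = TRUE",
           call. = FALSE)
    }
    records <- stage("read", read_incubation_table(incubation, design, constants))
    covariates_tbl <- stage("read", read_covariates_table(covariates))
  }

  # -- partition --------------------------------------------------------
  say("stage partition")
  part <- stage("partition", {
    withCallingHandlers(
      partition_incubation(records, design, constants),
      warning = function(w) {
        if (grepl("clamped", conditionMessage(w))) {
          warn_counts$clamped_fractions <<- warn_counts$clamped_fractions + 1L
          invokeRestart("muffleWarning")
        }
      })
  })
  cum <- cumulative_priming_by_site(part)
  partition_path <- file.path(out_dir, "partition.csv")
  readr::write_csv(part, partition_path)
  outputs <- c(outputs, partition = partition_path)

  # -- priming-ci -------------------------------------------------------
  say("stage priming-ci: ", n_draws, " draws per site")
  ci <- stage("priming-ci",
              priming_ci(records, design, constants,
                         n_draws = n_draws, seed = seed))
  ci_path <- file.path(out_dir, "priming_ci.csv")
  readr::write_csv(ci, ci_path)
  outputs <- c(outputs, priming_ci = ci_path)

  # -- fit-twopool ------------------------------------------------------
  say("stage fit-twopool: ", mcmc_chains, " chains x ", mcmc_iter, " iter")
  soc <- covariates_tbl |>
    dplyr::filter(.data$group == "soil", .data$variable == "soc") |>
    dplyr::select("site_id", soc_g_kg = "value")
  tp <- stage("fit-twopool",
              fit_twopool_sites(part, soc, n_chains = mcmc_chains,
                                n_iter = mcmc_iter, seed = seed))
  tp_path <- file.path(out_dir, "twopool_fit.csv")
  readr::write_csv(tp, tp_path)
  outputs <- c(outputs, twopool = tp_path)

  # -- drivers ----------------------------------------------------------
  say("stage drivers")
  drv <- stage("drivers", {
    # absolute cumulative priming plus its scale-free counterpart (percent
    # of cumulative basal respiration): magnitude-driven covariates (SOC,
    # MBC) dominate the former, amplitude drivers show up in the latter
    basal <- part |>
      dplyr::group_by(.data$site_id) |>
      dplyr::arrange(.data$day, .by_group = TRUE) |>
      dplyr::summarise(
        cum_basal = cumulative_priming(.data$day, .data$c_control),
        .groups = "drop")
    resp <- dplyr::select(cum, "site_id", value = "cumulative_priming")
    resp_rel <- cum |>
      dplyr::inner_join(basal, by = "site_id") |>
      dplyr::transmute(.data$site_id,
                       value = 100 * .data$cumulative_priming / .data$cum_basal)
    pc1 <- covariate_group_pc1(covariates_tbl)
    n_pred <- length(unique(paste(covariates_tbl$group,
                                  covariates_tbl$variable)))
    varpart_one <- function(rsp) {
      if (nrow(rsp) > n_pred + 1L) {
        partition_covariate_groups(covariates_tbl, rsp)
      } else {
        # too few sites for the full variable set: partition over the
        # per-group PC1 indices instead (one predictor per group)
        say("drivers: partitioning on per-group PC1 scores (n <= predictors)")
        groups <- purrr::map(split(pc1, pc1$group), function(g) {
          matrix(g$score[match(rsp$site_id, g$site_id)],
                 dimnames = list(NULL, "pc1"))
        })
        variation_partitioning(rsp$value, groups)
      }
    }
    vp <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(varpart_one(resp)),
                    response = "absolute_priming", .before = 1),
      dplyr::mutate(tibble::as_tibble(varpart_one(resp_rel)),
                    response = "relative_priming", .before = 1)
    )
    drv_data <- covariates_wide(covariates_tbl) |>
      dplyr::inner_join(resp, by = "site_id")
    non_som <- covariates_tbl |>
      dplyr::filter(.data$group != "som_stability") |>
      dplyr::pull(.data$variable) |> unique()
    som_vars <- covariates_tbl |>
      dplyr::filter(.data$group == "som_stability") |>
      dplyr::pull(.data$variable) |> unique()
    pcorr <- correlate_drivers(drv_data, "value", non_som, som_vars)
    list(varpart = vp, pc1 = pc1, pcorr = pcorr,
         change = coefficient_change(pcorr))
  })
  warn_counts$truncated_fractions <- sum(drv$varpart$was_truncated)
  vp_path <- file.path(out_dir, "varpart.csv")
  pc1_path <- file.path(out_dir, "pc1.csv")
  pcorr_path <- file.path(out_dir, "partial_corr.csv")
  readr::write_csv(tibble::as_tibble(drv$varpart), vp_path)
  readr::write_csv(drv$pc1, pc1_path)
  readr::write_csv(drv$pcorr, pcorr_path)
  outputs <- c(outputs, varpart = vp_path, pc1 = pc1_path,
               partial_corr = pcorr_path)

  # -- summary + manifest ----------------------------------------------
  rel_day1 <- part |>
    dplyr::filter(.data$day == min(.data$day)) |>
    dplyr::select("site_id", relative_priming_day1 = "relative_priming")
  site_summary <- cum |>
    dplyr::left_join(ci, by = "site_id") |>
    dplyr::left_join(rel_day1, by = "site_id")
  tp_wide <- tp |>
    dplyr::select("site_id", "parameter", "estimate") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
  unique_frac <- drv$varpart |>
    dplyr::filter(.data$is_unique) |>
    dplyr::select("fraction", "raw", "truncated")
  summary <- list(
    seed = as.integer(seed),
    n_sites = length(unique(site_summary$site_id)),
    sites = site_summary,
    twopool_estimates = tp_wide,
    twopool_fit = list(median_r2 = stats::median(tp$r2[!duplicated(tp$site_id)]),
                       median_rmse = stats::median(tp$rmse[!duplicated(tp$site_id)])),
    varpart_unique = unique_frac,
    mean_abs_coefficient_change_pc = mean(abs(drv$change$pct_change),
                                          na.rm = TRUE)
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  outputs <- c(outputs, summary = summary_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("primingkit")),
    seed = as.integer(seed),
    config = list(design = unclass(design), constants = unclass(constants)),
    settings = list(n_sites = n_sites, n_draws = n_draws,
                    mcmc_chains = mcmc_chains, mcmc_iter = mcmc_iter,
                    noise_flux_rel = noise_flux_rel,
                    noise_atom_abs = noise_atom_abs,
                    simulate = simulate),
    warnings = warn_counts,
    outputs = as.list(stats::setNames(basename(outputs), names(outputs))),
    hashes = as.list(tools::md5sum(outputs)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  names(manifest$hashes) <- basename(outputs)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  say("wrote ", length(outputs), " outputs + manifest to ", out_dir)
  invisible(manifest)
}
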