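#' Plot partitioned fluxes and priming over the incubation
#'
#' Per-site time courses of the treated SOM-derived flux, the control
#' (basal) flux and the resulting priming rate.
#'
#' @param partition Output of [partition_incubation()].
#' @param sites Optional subset of site ids.
#' @return A ggplot object.
#' @export
plot_priming_curves <- function(partition, sites = NULL) {
  x <- tibble::as_tibble(partition)
  if (!is.null(sites)) x <- dplyr::filter(x, .data$site_id %in% sites)
  long <- x |>
    dplyr::select("site_id", "day", `SOM flux (treated)` = "som_flux_treat",
                  `basal flux (control)` = "c_control", priming = "priming") |>
    tidyr::pivot_longer(-c("site_id", "day"), names_to = "series",
                        values_to = "flux")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$flux,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~site_id, scales = "free_y") +
    ggplot2::labs(x = "day", y = expression(mu * g ~ C ~ g^-1 ~ d^-1),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cumulative priming with Monte-Carlo confidence intervals
#'
#' @param ci Output of [priming_ci()].
#' @return A ggplot object.
#' @export
plot_priming_ci <- function(ci) {
  x <- dplyr::arrange(tibble::as_tibble(ci), .data$cumulative_mean)
  x$site_id <- factor(x$site_id, levels = x$site_id)
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cumulative_mean, y = .data$site_id)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.3) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(cumulative ~ priming ~ (mu * g ~ C ~ g^-1)),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot variation-partitioning fractions
#'
#' Raw and truncated unique fractions per predictor group.
#'
#' @param fractions A `varpart_fractions` object (see
#'   [variation_partitioning()]).
#' @return A ggplot object.
#' @export
plot_varpart <- function(fractions) {
  x <- tibble::as_tibble(fractions) |>
    dplyr::filter(.data$is_unique) |>
    tidyr::pivot_longer(c("raw", "truncated"), names_to = "kind",
                        values_to = "fraction_value")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$fraction,
                                  y = 100 * .data$fraction_value,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "unique variance explained (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
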