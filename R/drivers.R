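#' Partial correlation between two variables given controls
#'
#' Correlation of `y` and `x` after removing the linear effect of the
#' control variables from both, computed from the inverse of the joint
#' correlation matrix (`r = -P_xy / sqrt(P_xx P_yy)` with `P` the precision
#' matrix), which equals the correlation of least-squares residuals. With no
#' controls this reduces exactly to the Pearson correlation. Significance is
#' from `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - n_controls`. Rows
#' with any missing value among `y`, `x` and the controls are dropped
#' (listwise deletion), and the effective `n` is reported.
#'
#' @param y,x Numeric vectors.
#' @param controls Optional numeric matrix / data frame of control
#'   variables (columns), or `NULL` for the zero-order correlation.
#' @return A one-row tibble: `r`, `p`, `n`, `df`, `n_controls`.
#' @examples
#' set.seed(1)
#' z <- rnorm(30); x <- z + rnorm(30); y <- x + z + rnorm(30)
#' partial_correlation(y, x, cbind(z = z))
#' @export
partial_correlation <- function(y, x, controls = NULL) {
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    storage.mode(controls) <- "double"
    if (nrow(controls) != length(y)) {
      stop("controls must have one row per observation", call. = FALSE)
    }
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  keep <- stats::complete.cases(cbind(y, x, controls))
  y <- y[keep]; x <- x[keep]
  if (!is.null(controls)) controls <- controls[keep, , drop = FALSE]
  n <- length(y)
  q <- if (is.null(controls)) 0L else ncol(controls)
  df <- n - 2L - q
  if (df < 1L) stop("not enough observations for ", q, " control(s)",
                    call. = FALSE)

  mat <- cbind(y = y, x = x, controls)
  if (any(apply(mat, 2, stats::sd) == 0)) {
    stop("constant column among y, x or controls", call. = FALSE)
  }
  cm <- stats::cor(mat)
  prec <- tryCatch(solve(cm), error = function(e) {
    stop("controls perfectly predict y or x; partial correlation undefined",
         call. = FALSE)
  })
  r <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  if (!is.finite(r) || abs(r) > 1 + 1e-8) {
    stop("controls perfectly predict y or x; partial correlation undefined",
         call. = FALSE)
  }
  r <- max(min(r, 1), -1)
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tibble::tibble(r = r, p = p, n = n, df = df, n_controls = q)
}

#' Driver screening by zero-order and controlled correlations
#'
#' For each predictor in `x_vars`, computes the zero-order correlation with
#' the response plus one partial correlation per control variable (controls
#' applied one at a time, matching per-factor screening tables; supply
#' `block = TRUE` to control for all `control_vars` jointly).
#'
#' @param data A data frame with one row per site.
#' @param response Name of the response column.
#' @param x_vars Character vector of predictor columns.
#' @param control_vars Character vector of control columns (may be empty).
#' @param block Control for all `control_vars` at once instead of one at a
#'   time.
#' @return A tibble: `x_var, y_var, control, r, p, n`, with `control =
#'   "zero_order"` for the unadjusted rows.
#' @export
correlate_drivers <- function(data, response, x_vars, control_vars = character(),
                              block = FALSE) {
  data <- tibble::as_tibble(data)
  runs <- if (block && length(control_vars)) {
    list(list(label = paste(control_vars, collapse = "+"), vars = control_vars))
  } else {
    purrr::map(control_vars, function(cv) list(label = cv, vars = cv))
  }
  runs <- c(list(list(label = "zero_order", vars = character())), runs)
  purrr::map_dfr(x_vars, function(xv) {
    purrr::map_dfr(runs, function(run) {
      ctl <- if (length(run$vars)) as.matrix(data[, run$vars, drop = FALSE]) else NULL
      res <- partial_correlation(data[[response]], data[[xv]], ctl)
      tibble::tibble(x_var = xv, y_var = response, control = run$label,
                     r = res$r, p = res$p, n = res$n)
    })
  })
}

#' Percent change in correlation strength after controlling
#'
#' `100 * (|r_zero| - |r_controlled|) / |r_zero|` per (predictor, control)
#' pair: positive values are loss of correlation once the control is
#' accounted for; negative values indicate gained correlation.
#'
#' @param correlations Output of [correlate_drivers()] (must contain
#'   `control == "zero_order"` rows).
#' @return A tibble `x_var, y_var, control, r_zero, r_controlled,
#'   pct_change` (`NA` with a warning where `r_zero` is 0).
#' @export
coefficient_change <- function(correlations) {
  zero <- dplyr::filter(correlations, .data$control == "zero_order") |>
    dplyr::select("x_var", "y_var", r_zero = "r")
  ctl <- dplyr::filter(correlations, .data$control != "zero_order")
  if (nrow(ctl) == 0L) stop("no controlled correlations supplied", call. = FALSE)
  out <- ctl |>
    dplyr::inner_join(zero, by = c("x_var", "y_var")) |>
    dplyr::mutate(
      pct_change = ifelse(.data$r_zero == 0, NA_real_,
                          100 * (abs(.data$r_zero) - abs(.data$r)) /
                            abs(.data$r_zero))
    ) |>
    dplyr::select("x_var", "y_var", "control", "r_zero",
                  r_controlled = "r", "pct_change")
  if (any(is.na(out$pct_change))) {
    warning("zero-order coefficient of 0: percent change undefined")
  }
  out
}

#' Variation partitioning of a response across predictor groups
#'
#' Fits ordinary least squares for every non-empty union of the predictor
#' groups (2^g - 1 models), computes Ezekiel-adjusted R-squared per model,
#' and decomposes the full-model adjusted R-squared into unique and shared
#' fractions by Moebius inversion of the subset R-squared lattice. Raw
#' fractions may be negative; the headline `truncated` column sets negative
#' fractions to zero, following the convention that a group explaining less
#' than random normal variables explains nothing.
#'
#' @param y Numeric response vector.
#' @param groups Named list of numeric matrices / data frames (one per
#'   predictor group, columns = variables, rows aligned with `y`).
#' @return An object of class `varpart_fractions`: a tibble with one row
#'   per fraction (`fraction` label such as `"plant"` or
#'   `"plant:soil"`, `raw`, `truncated`, `is_unique`, `was_truncated`)
#'   plus rows for `residual`; the full-model adjusted R-squared is the
#'   `full_adj_r2` attribute.
#' @examples
#' set.seed(2)
#' a <- matrix(rnorm(60), 30); b <- matrix(rnorm(30), 30)
#' y <- a %*% c(1, 0.5) + rnorm(30)
#' variation_partitioning(y, list(A = a, B = b))
#' @export
variation_partitioning <- function(y, groups) {
  y <- as.numeric(y)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    stop("`groups` must be a fully named list", call. = FALSE)
  }
  groups <- purrr::map(groups, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    if (nrow(g) != length(y)) stop("group rows must match length(y)", call. = FALSE)
    if (ncol(g) == 0L) stop("groups must be non-empty", call. = FALSE)
    g
  })
  g_names <- names(groups)
  ng <- length(groups)
  n <- length(y)
  p_full <- sum(vapply(groups, ncol, integer(1)))
  if (n <= p_full + 1L) {
    stop("n must exceed the total predictor count of the full model",
         call. = FALSE)
  }

  adj_r2 <- function(x_mat) {
    p <- ncol(x_mat)
    fit <- stats::lm.fit(cbind(1, x_mat), y)
    if (fit$rank < p + 1L) {
      stop("rank-deficient model; collinear columns among: ",
           paste(colnames(x_mat), collapse = ", "), call. = FALSE)
    }
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- 1 - ss_res / ss_tot
    1 - (1 - r2) * (n - 1) / (n - p - 1)  # Ezekiel correction
  }

  subsets <- 1:(2^ng - 1)
  in_subset <- function(s) which(bitwAnd(s, 2^(seq_len(ng) - 1)) > 0)
  a <- vapply(subsets, function(s) {
    adj_r2(do.call(cbind, groups[in_subset(s)]))
  }, numeric(1))

  # A(S) = sum over components T with T intersecting S of x_T; solve for x
  inter <- outer(subsets, subsets, function(s, t) bitwAnd(s, t) > 0)
  x <- solve(inter * 1, a)

  label <- vapply(subsets, function(s) {
    paste(g_names[in_subset(s)], collapse = ":")
  }, character(1))
  full <- a[length(a)]
  frac <- tibble::tibble(
    fraction = label,
    n_groups = vapply(subsets, function(s) length(in_subset(s)), integer(1)),
    raw = x,
    truncated = pmax(x, 0),
    is_unique = vapply(subsets, function(s) length(in_subset(s)) == 1L, logical(1)),
    was_truncated = x < 0
  )
  frac <- dplyr::bind_rows(
    frac,
    tibble::tibble(fraction = "residual", n_groups = 0L,
                   raw = 1 - full, truncated = max(1 - full, 0),
                   is_unique = FALSE, was_truncated = (1 - full) < 0)
  )
  structure(frac, full_adj_r2 = full, class = c("varpart_fractions",
                                                class(frac)))
}

#' First principal component of one variable group
#'
#' Standardises the columns (zero mean, unit SD), extracts the first
#' principal component and orients it to correlate positively with the
#' first column, so the sign convention is reproducible.
#'
#' @param mat Site-by-variable numeric matrix or data frame (no identifier
#'   columns).
#' @return A list with `scores` (per-site PC1 scores, zero mean),
#'   `variance_explained` (% of total variance) and `loadings`.
#' @export
group_pc1 <- function(mat) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (nrow(mat) < 2L) stop("need >= 2 sites", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column: ", paste(colnames(mat)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  z <- scale(mat)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  s <- stats::cor(scores, z[, 1])
  if (is.finite(s) && s < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(
    scores = as.numeric(scores),
    variance_explained = 100 * pc$sdev[1]^2 / sum(pc$sdev^2),
    loadings = loadings
  )
}

#' PC1 scores for each covariate group
#'
#' Convenience wrapper running [group_pc1()] on each of the four covariate
#' groups of a long covariate table; these per-group indices are the usual
#' inputs to downstream structural models.
#'
#' @param covariates Long covariate tibble (`site_id, group, variable,
#'   value`).
#' @return A tibble `site_id, group, score, variance_explained`.
#' @export
covariate_group_pc1 <- function(covariates) {
  covariates <- validate_covariates(covariates)
  purrr::map_dfr(sort(unique(covariates$group)), function(g) {
    wide <- covariates_wide(covariates, g)
    m <- as.matrix(wide[, -1, drop = FALSE])
    res <- group_pc1(m)
    tibble::tibble(site_id = wide$site_id, group = g, score = res$scores,
                   variance_explained = res$variance_explained)
  })
}

#' Variation partitioning from a long covariate table
#'
#' @param covariates Long covariate tibble.
#' @param response Tibble `site_id, value` with the response (e.g.
#'   cumulative priming).
#' @return A `varpart_fractions` tibble (see [variation_partitioning()]).
#' @export
partition_covariate_groups <- function(covariates, response) {
  covariates <- validate_covariates(covariates)
  response <- tibble::as_tibble(response)
  stopifnot(all(c("site_id", "value") %in% names(response)))
  sites <- response$site_id
  groups <- purrr::map(sort(unique(covariates$group)), function(g) {
    wide <- covariates_wide(covariates, g)
    m <- as.matrix(wide[match(sites, wide$site_id), -1, drop = FALSE])
    rownames(m) <- sites
    m
  })
  names(groups) <- sort(unique(covariates$group))
  variation_partitioning(response$value, groups)
}
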