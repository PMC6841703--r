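test_that("two-pool rate evaluates the double exponential", {
  p <- two_pool_params(0.01, 0.1, 1e-4, c_tot = 1000)
  expect_equal(two_pool_rate(0, p), 0.1 * 0.01 * 1000 + 1e-4 * 0.99 * 1000,
               tolerance = 1e-14)
  # strictly decreasing, vanishing at long times
  tt <- seq(0, 2000, by = 5)
  r <- two_pool_rate(tt, p)
  expect_true(all(diff(r) < 0))
  expect_lt(two_pool_rate(1e6, p), 1e-12)
  # near-total pool collapse approaches a single exponential
  p1 <- two_pool_params(1 - 1e-12, 0.2, 1e-9)
  expect_equal(two_pool_rate(3, p1), 0.2 * 1000 * exp(-0.2 * 3),
               tolerance = 1e-6)
})

test_that("parameter validation enforces ordering and support", {
  expect_error(two_pool_params(0, 0.1, 1e-4), "0, 1")
  expect_error(two_pool_params(0.1, 1e-4, 0.1), "k1 > k2")
  expect_error(two_pool_params(0.1, 0.1, -1), "k1 > k2")
  expect_error(two_pool_rate(-1, two_pool_params(0.1, 0.1, 1e-4)), ">= 0")
  expect_error(two_pool_priors(f1 = c(0.5, 0.1)), "min, max")
})

test_that("log-posterior is the Gaussian likelihood over the prior box", {
  obs <- tibble::tibble(day = c(1, 8, 35), rate = c(2.0, 1.1, 0.5))
  priors <- two_pool_priors()
  # brute-force summation oracle
  th <- list(f1 = 0.03, k1 = 0.12, k2 = 3e-4)
  pred <- 0.12 * 0.03 * 1000 * exp(-0.12 * obs$day) +
    3e-4 * 0.97 * 1000 * exp(-3e-4 * obs$day)
  oracle <- sum(dnorm(obs$rate, pred, 0.2, log = TRUE))
  expect_equal(log_posterior(th, obs, priors, 0.2), oracle, tolerance = 1e-12)
  # perfect fit: -n/2 log(2 pi sigma^2)
  obs2 <- tibble::tibble(day = obs$day, rate = pred)
  expect_equal(log_posterior(th, obs2, priors, 0.2),
               -3 / 2 * log(2 * pi * 0.04), tolerance = 1e-12)
  # outside the prior box and label-switching guard
  expect_identical(log_posterior(list(f1 = 0.9, k1 = 0.1, k2 = 1e-4),
                                 obs, priors, 0.2), -Inf)
  expect_identical(log_posterior(list(f1 = 0.03, k1 = 0.004, k2 = 0.0045),
                                 obs, priors, 0.2), -Inf)
  expect_error(log_posterior(th, obs, priors, 0), "> 0")
})

test_that("fit quality matches its definition", {
  p <- two_pool_params(0.02, 0.15, 2e-4)
  obs <- tibble::tibble(day = c(1, 3, 8, 15, 35, 65),
                        rate = two_pool_rate(c(1, 3, 8, 15, 35, 65), p))
  fq <- fit_quality(obs, p)
  expect_equal(fq$r2, 1, tolerance = 1e-10)
  expect_equal(fq$rmse, 0, tolerance = 1e-10)
  # r2 = 0 when the model explains exactly as much as the mean
  v <- two_pool_rate(5, p)
  obs2 <- tibble::tibble(day = c(5, 5), rate = c(v - 1, v + 1))
  fq2 <- fit_quality(obs2, p)
  expect_equal(fq2$r2, 0, tolerance = 1e-12)
  expect_equal(fq2$rmse, 1, tolerance = 1e-12)
  # permutation invariance
  set.seed(3)
  obs3 <- tibble::tibble(day = c(1, 3, 8, 15), rate = c(3, 2, 1.2, 0.9))
  expect_equal(fit_quality(obs3, p), fit_quality(obs3[sample(4), ], p))
  expect_warning(fq4 <- fit_quality(tibble::tibble(day = c(1, 2),
                                                   rate = c(1, 1)), p),
                 "zero variance")
  expect_true(is.na(fq4$r2))
})

test_that("MCMC fits are reproducible and respect the prior support", {
  set.seed(10)
  p <- two_pool_params(0.03, 0.12, 3e-4)
  obs <- tibble::tibble(day = c(1, 3, 8, 15, 35, 65))
  obs$rate <- two_pool_rate(obs$day, p) * (1 + rnorm(6, 0, 0.05))
  a <- mcmc_fit(obs, n_chains = 3, n_iter = 2000, seed = 77)
  b <- mcmc_fit(obs, n_chains = 3, n_iter = 2000, seed = 77)
  expect_identical(a$summary, b$summary)
  expect_identical(a$draws, b$draws)
  pr <- two_pool_priors()
  expect_true(all(a$draws$f1 >= pr$f1[1] & a$draws$f1 <= pr$f1[2]))
  expect_true(all(a$draws$k1 >= pr$k1[1] & a$draws$k1 <= pr$k1[2]))
  expect_true(all(a$draws$k2 >= pr$k2[1] & a$draws$k2 <= pr$k2[2]))
  expect_true(all(a$draws$k1 > a$draws$k2))
  expect_true(a$acceptance_rate > 0.01 && a$acceptance_rate < 1)
  expect_true(all(a$summary$estimate >= c(pr$f1[1], pr$k1[1], pr$k2[1])))
})

test_that("MAP recovers dense, low-noise synthetic parameters within 10%", {
  set.seed(123)
  truth <- two_pool_params(0.02, 0.15, 2e-4)
  days <- seq(1, 65, by = 2)
  obs <- tibble::tibble(day = days,
                        rate = two_pool_rate(days, truth) * (1 + rnorm(length(days), 0, 0.02)))
  fit <- mcmc_fit(obs, n_chains = 3, n_iter = 6000, seed = 9)
  map <- setNames(fit$summary$map, fit$summary$parameter)
  expect_lt(abs(map["f1"] - 0.02) / 0.02, 0.10)
  expect_lt(abs(map["k1"] - 0.15) / 0.15, 0.10)
  expect_lt(abs(map["k2"] - 2e-4) / 2e-4, 0.10)
  expect_true(all(fit$summary$gelman_rubin < 1.1))
  # dense data constrain the fast pool well
  cls <- setNames(fit$summary$constraint_class, fit$summary$parameter)
  expect_equal(unname(cls["f1"]), "well_constrained")
  expect_equal(unname(cls["k1"]), "well_constrained")
  expect_gt(fit$r2, 0.95)
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(4)
  p <- two_pool_params(0.05, 0.2, 5e-4)
  obs <- tibble::tibble(day = c(1, 3, 8, 15, 35, 65))
  obs$rate <- two_pool_rate(obs$day, p) * (1 + rnorm(6, 0, 0.03))
  fit <- mcmc_fit(obs, n_chains = 3, n_iter = 1500, seed = 2)
  td <- tidy(fit)
  expect_setequal(td$parameter, c("f1", "k1", "k2"))
  expect_true(all(td$q2.5 <= td$q97.5))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$max_gelman_rubin >= 1)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("site-level fitting normalises control fluxes per g SOC", {
  case <- noiseless_case(2, seed = 31)
  part <- partition_incubation(case$records, default_design)
  soc <- dplyr::select(case$transect$truth, site_id, soc_g_kg)
  res <- fit_twopool_sites(part, soc, n_chains = 3, n_iter = 2000, seed = 5,
                           noise = "fixed_relative", rel_error = 0.05)
  expect_setequal(unique(res$site_id), case$transect$truth$site_id)
  expect_equal(nrow(res), 2 * 3)
  # noiseless rates: the model reproduces the data nearly perfectly
  expect_true(all(res$r2 > 0.999))
  fits <- attr(res, "fits")
  expect_s3_class(fits[[case$transect$truth$site_id[1]]], "twopool_fit")
})
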