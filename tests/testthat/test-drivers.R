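test_that("partial correlation reduces to Pearson with no controls", {
  set.seed(21)
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  res <- partial_correlation(y, x)
  expect_equal(res$r, cor(y, x), tolerance = 1e-14)
  ct <- cor.test(y, x)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$df, 28L)
})

test_that("partial correlation equals brute-force residual-on-residual correlation", {
  set.seed(22)
  for (i in 1:10) {
    z <- matrix(rnorm(30 * 2), 30, dimnames = list(NULL, c("z1", "z2")))
    x <- z %*% c(1, -0.5) + rnorm(30)
    y <- x + z %*% c(0.8, 0.3) + rnorm(30)
    res <- partial_correlation(y, x, z)
    brute <- cor(resid(lm(y ~ z)), resid(lm(x ~ z)))
    expect_equal(res$r, as.numeric(brute), tolerance = 1e-12)
    expect_equal(res$df, 30L - 2L - 2L)
  }
})

test_that("one-control partial correlation matches the recursive closed form", {
  set.seed(23)
  for (i in 1:10) {
    z <- rnorm(30)
    x <- z + rnorm(30)
    y <- x + z + rnorm(30)
    rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
    closed <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(partial_correlation(y, x, cbind(z))$r, closed,
                 tolerance = 1e-12)
  }
})

test_that("degenerate partial correlations are refused", {
  set.seed(24)
  z <- rnorm(30)
  expect_error(partial_correlation(z, rnorm(30), cbind(z)),
               "perfectly predict|constant")
  expect_error(partial_correlation(rep(1, 30), rnorm(30)), "constant")
  expect_error(partial_correlation(rnorm(10), rnorm(10),
                                   matrix(rnorm(90), 10)),
               "not enough")
})

test_that("listwise deletion drops incomplete rows and reports n", {
  set.seed(25)
  x <- rnorm(20); y <- x + rnorm(20); z <- rnorm(20)
  x[3] <- NA; z[7] <- NA
  res <- partial_correlation(y, x, cbind(z))
  expect_equal(res$n, 18L)
  keep <- complete.cases(cbind(y, x, z))
  expect_equal(res$r, cor(resid(lm(y[keep] ~ z[keep])),
                          resid(lm(x[keep] ~ z[keep]))), tolerance = 1e-12)
})

test_that("coefficient change is the percent loss of correlation strength", {
  tbl <- tibble::tibble(
    x_var = c("a", "a", "b", "b", "c", "c"),
    y_var = "y",
    control = rep(c("zero_order", "z"), 3),
    r = c(0.50, 0.10, 0.30, -0.45, 0.6, 0.6),
    p = 0.01, n = 30L
  )
  ch <- coefficient_change(tbl)
  expect_equal(ch$pct_change[ch$x_var == "a"], 80, tolerance = 1e-12)
  expect_equal(ch$pct_change[ch$x_var == "b"], -50, tolerance = 1e-12)
  expect_equal(ch$pct_change[ch$x_var == "c"], 0)
  tbl0 <- tbl
  tbl0$r[1] <- 0
  expect_warning(ch0 <- coefficient_change(tbl0), "undefined")
  expect_true(is.na(ch0$pct_change[ch0$x_var == "a"]))
})

test_that("correlate_drivers screens one control at a time and in block mode", {
  set.seed(26)
  dat <- tibble::tibble(y = rnorm(30), a = rnorm(30), b = rnorm(30),
                        c1 = rnorm(30), c2 = rnorm(30))
  out <- correlate_drivers(dat, "y", c("a", "b"), c("c1", "c2"))
  expect_equal(nrow(out), 2 * 3)
  expect_setequal(unique(out$control), c("zero_order", "c1", "c2"))
  blk <- correlate_drivers(dat, "y", "a", c("c1", "c2"), block = TRUE)
  expect_equal(blk$r[blk$control == "c1+c2"],
               partial_correlation(dat$y, dat$a, dat[, c("c1", "c2")])$r)
})

test_that("variation partitioning matches brute-force inclusion-exclusion", {
  set.seed(27)
  n <- 40
  a <- matrix(rnorm(n), n, dimnames = list(NULL, "a1"))
  b <- matrix(rnorm(n), n, dimnames = list(NULL, "b1"))
  y <- 1.5 * a[, 1] + 0.8 * b[, 1] + rnorm(n)
  vp <- variation_partitioning(y, list(A = a, B = b))
  adj <- function(xm) {
    f <- lm(y ~ xm)
    1 - (1 - summary(f)$r.squared) * (n - 1) / (n - ncol(xm) - 1)
  }
  r_a <- adj(a); r_b <- adj(b); r_ab <- adj(cbind(a, b))
  expect_equal(vp$raw[vp$fraction == "A"], r_ab - r_b, tolerance = 1e-10)
  expect_equal(vp$raw[vp$fraction == "B"], r_ab - r_a, tolerance = 1e-10)
  expect_equal(vp$raw[vp$fraction == "A:B"], r_a + r_b - r_ab,
               tolerance = 1e-10)
  expect_equal(attr(vp, "full_adj_r2"), r_ab, tolerance = 1e-12)
})

test_that("variation partitioning agrees with vegan on two groups", {
  set.seed(28)
  n <- 35
  a <- matrix(rnorm(2 * n), n, dimnames = list(NULL, c("a1", "a2")))
  b <- matrix(rnorm(n), n, dimnames = list(NULL, "b1"))
  y <- a %*% c(1, -0.6) + 0.5 * b[, 1] + rnorm(n)
  vp <- variation_partitioning(as.numeric(y), list(A = a, B = b))
  vg <- vegan::varpart(as.numeric(y), a, b)
  # vegan rows: [a] = X1 unique, [b] = X2 unique, [c] = shared
  ind <- vg$part$indfract$Adj.R.square
  expect_equal(vp$raw[vp$fraction == "A"], ind[1], tolerance = 1e-8)
  expect_equal(vp$raw[vp$fraction == "B"], ind[2], tolerance = 1e-8)
  expect_equal(vp$raw[vp$fraction == "A:B"], ind[3], tolerance = 1e-8)
})

test_that("raw fractions sum to the full-model adjusted R2 with four groups", {
  set.seed(29)
  n <- 50
  groups <- lapply(1:4, function(i) {
    m <- matrix(rnorm(2 * n), n)
    colnames(m) <- paste0("g", i, "_", 1:2)
    m
  })
  names(groups) <- c("plant", "soil", "microbial", "som_stability")
  y <- groups$plant %*% c(1, 0.3) + groups$som_stability %*% c(0.8, -0.5) +
    rnorm(n)
  vp <- variation_partitioning(as.numeric(y), groups)
  expect_equal(sum(vp$raw[vp$fraction != "residual"]),
               attr(vp, "full_adj_r2"), tolerance = 1e-10)
  expect_equal(nrow(vp), 2^4 - 1 + 1)
})

test_that("a pure-noise group gets a negative raw fraction truncated to zero", {
  set.seed(30)
  n <- 20
  signal <- matrix(rnorm(n), n, dimnames = list(NULL, "s1"))
  noise <- matrix(rnorm(3 * n), n, dimnames = list(NULL, paste0("n", 1:3)))
  y <- 2 * signal[, 1] + rnorm(n, 0, 0.5)
  vp <- variation_partitioning(y, list(signal = signal, noise = noise))
  raw_noise <- vp$raw[vp$fraction == "noise"]
  expect_lt(raw_noise, 0)
  expect_equal(vp$truncated[vp$fraction == "noise"], 0)
  expect_true(vp$was_truncated[vp$fraction == "noise"])
  # single-group degenerate partition: unique fraction is the model adj R2
  vp1 <- variation_partitioning(y, list(signal = signal))
  f <- lm(y ~ signal)
  expect_equal(vp1$raw[1],
               1 - (1 - summary(f)$r.squared) * (n - 1) / (n - 2),
               tolerance = 1e-12)
})

test_that("rank-deficient groups are refused with column context", {
  set.seed(31)
  n <- 25
  a <- matrix(rnorm(n), n, dimnames = list(NULL, "a1"))
  dup <- cbind(a1 = a[, 1], a2 = a[, 1])
  expect_error(variation_partitioning(rnorm(n), list(A = dup)),
               "rank-deficient")
})

test_that("group PC1 matches the eigendecomposition of the correlation matrix", {
  set.seed(32)
  m <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("v", 1:5)))
  res <- group_pc1(m)
  eig <- eigen(cor(m))
  expect_equal(res$variance_explained, 100 * eig$values[1] / 5,
               tolerance = 1e-10)
  ref <- scale(m) %*% eig$vectors[, 1]
  if (cor(ref, scale(m)[, 1]) < 0) ref <- -ref
  expect_equal(res$scores, as.numeric(ref), tolerance = 1e-10)
  expect_equal(mean(res$scores), 0, tolerance = 1e-12)
  expect_gt(cor(res$scores, m[, 1]), 0)
})

test_that("group PC1 handles degenerate inputs", {
  set.seed(33)
  single <- matrix(rnorm(20), 20, dimnames = list(NULL, "only"))
  res <- group_pc1(single)
  expect_equal(res$scores, as.numeric(scale(single)), tolerance = 1e-12)
  expect_equal(res$variance_explained, 100)
  v <- rnorm(15)
  collinear <- cbind(a = v, b = 2 * v + 3)
  expect_equal(group_pc1(collinear)$variance_explained, 100, tolerance = 1e-10)
  expect_error(group_pc1(cbind(a = v, b = rep(1, 15))), "constant column: b")
})

test_that("per-group PC1 covers all four covariate groups", {
  tr <- generate_transect(12, seed = 44)
  pc1 <- covariate_group_pc1(tr$covariates)
  expect_setequal(unique(pc1$group),
                  c("plant", "soil", "microbial", "som_stability"))
  expect_equal(nrow(pc1), 4 * 12)
  expect_true(all(pc1$variance_explained > 0 & pc1$variance_explained <= 100))
  for (g in unique(pc1$group)) {
    expect_equal(mean(pc1$score[pc1$group == g]), 0, tolerance = 1e-10)
  }
})
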