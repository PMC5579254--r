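test_that("univariate outlier removal is a single pass", {
  x <- data.frame(v = c(rep(1, 9), 10))
  rep1 <- univariate_outliers(x, k = 2.5)
  expect_equal(rep1$n_after, 9L)
  expect_equal(rep1$removed$id, "10")

  expect_warning(rep2 <- univariate_outliers(data.frame(v = rep(3, 5))),
                 "zero variance")
  expect_equal(rep2$n_after, 5L)

  # the outlier inflates the SD enough to mask itself (documented behaviour)
  x3 <- data.frame(v = c(1, 2, 3, 4, 100))
  expect_equal(univariate_outliers(x3, k = 2.5)$n_after, 5L)
  expect_lt(abs((100 - mean(x3$v)) / sd(x3$v)), 2.5)
})

test_that("the normality gate log-transforms only right-skewed failures", {
  set.seed(50)
  normal <- rnorm(200)
  r1 <- transform_to_gaussian(normal)
  expect_false(r1$transformed)

  ln <- exp(rnorm(200, 0, 0.8))
  r2 <- transform_to_gaussian(ln)
  expect_true(r2$transformed)
  expect_gt(r2$ks_p_after, 0.05)
  expect_equal(r2$values, log(ln))

  expect_error(transform_to_gaussian(c(0, ln)), "non-positive")
})

test_that("the Mahalanobis filter removes gross outliers under the cap", {
  set.seed(51)
  x <- matrix(rnorm(74 * 4), 74, 4)
  x[5, ] <- x[5, ] + 10
  f <- mahalanobis_filter(x, df = 4, cap = 0.05)
  expect_equal(f$removed$id[1], "5")
  expect_lte(nrow(f$removed), floor(0.05 * 74))

  f0 <- mahalanobis_filter(x, df = 4, cap = 0)
  expect_equal(f0$n_after, 74L)

  # clean multivariate normal data: mean removed fraction stays below 5%
  fracs <- vapply(1:50, function(i) {
    set.seed(100 + i)
    xm <- matrix(rnorm(74 * 4), 74, 4)
    1 - mahalanobis_filter(xm, df = 4, cap = 0.05)$n_after / 74
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("regression output matches a brute-force normal-equations oracle", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(30:60, 1)
    k <- sample(2:4, 1)
    X <- matrix(rnorm(n * k), n, k)
    y <- X %*% rnorm(k) + rnorm(n)
    tab <- data.frame(y = y, X)
    preds <- names(tab)[-1]
    fit <- fit_vascular_model(tab, "y", preds, n_boot = 0)
    cf <- fit$coefficients

    Xf <- cbind(1, X)
    beta <- solve(crossprod(Xf), crossprod(Xf, y))
    res <- y - Xf %*% beta
    s2 <- sum(res^2) / (n - k - 1)
    covb <- s2 * solve(crossprod(Xf))
    expect_equal(cf$b, beta[-1], tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(cf$se, sqrt(diag(covb))[-1], tolerance = 1e-8,
                 ignore_attr = TRUE)
    # semi-partial via explicit residualization of each predictor
    for (j in seq_len(k)) {
      others <- Xf[, -(j + 1), drop = FALSE]
      xr <- X[, j] - others %*% solve(crossprod(others),
                                      crossprod(others, X[, j]))
      expect_equal(cf$semi_partial[j], cor(as.vector(y), as.vector(xr)),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("orthogonal predictors give semi-partial = zero-order and VIF 1", {
  n <- 40
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, 1), each = n / 2)
  x1 <- (x1 - mean(x1)) / sd(x1); x2 <- (x2 - mean(x2)) / sd(x2)
  set.seed(53)
  y <- 0.8 * x1 - 0.3 * x2 + rnorm(n, 0, 0.5)
  fit <- fit_vascular_model(data.frame(y = y, x1 = x1, x2 = x2), "y",
                            c("x1", "x2"), n_boot = 0)
  cf <- fit$coefficients
  expect_equal(cf$semi_partial, cf$zero_order, tolerance = 1e-10)
  expect_equal(cf$vif, c(1, 1), tolerance = 1e-10)
})

test_that("bootstrap CIs and degraded mode behave as declared", {
  set.seed(54)
  tab <- data.frame(y = rnorm(40), x = rnorm(40))
  f0 <- fit_vascular_model(tab, "y", "x", n_boot = 0)
  expect_true(all(is.na(f0$coefficients$ci_lower)))
  f1 <- fit_vascular_model(tab, "y", "x", n_boot = 200, seed = 8)
  f2 <- fit_vascular_model(tab, "y", "x", n_boot = 200, seed = 8)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_true(f1$coefficients$ci_lower < f1$coefficients$b &
                f1$coefficients$b < f1$coefficients$ci_upper)

  tab$x2 <- 2 * tab$x
  expect_error(fit_vascular_model(tab, "y", c("x", "x2"), n_boot = 0),
               "collinear")
})

test_that("group term recovery matches the planted coefficient", {
  set.seed(55)
  est <- replicate(50, {
    n <- 71
    g <- rep(c(1, 0), c(28, 43))
    cbf <- rnorm(n, 50, 10)
    y <- -0.6 * g + 0 * cbf + rnorm(n, 0, 0.3)
    fit <- fit_vascular_model(data.frame(y = y, group = g, cbf = cbf),
                              "y", c("group", "cbf"), n_boot = 100,
                              seed = sample.int(1e6, 1))
    cf <- fit$coefficients[1, ]
    c(b = cf$b, excl = cf$ci_upper < 0)
  })
  expect_lt(abs(mean(est["b", ]) + 0.6), 0.1)
  expect_gte(mean(est["excl", ]), 0.95)
})

test_that("the sex-composition chi-square matches its printed value", {
  res <- chi_square_2x2(matrix(c(20, 8, 11, 32), 2, byrow = TRUE))
  expect_equal(res$statistic, 14.49, tolerance = 0.01)
  expect_equal(res$df, 1)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(c(30, 10, 10, 30), 2))$statistic, 20)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("within-subject coupling is a plain Pearson r with guards", {
  set.seed(56)
  sd_map <- runif(100, 1, 2)
  expect_equal(within_subject_coupling(sd_map, 2 * sd_map + 1), 1)
  expect_equal(within_subject_coupling(sd_map, -sd_map), -1)
  expect_error(within_subject_coupling(sd_map, rep(1, 100)), "variance")

  rho <- 0.5
  z1 <- rnorm(2000); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(2000)
  expect_lt(abs(within_subject_coupling(z1, z2) - rho), 0.06)
})

test_that("coupling group models recover planted differences", {
  set.seed(57)
  b <- replicate(100, {
    ry <- rnorm(29, 0.15, 0.12)
    ro <- rnorm(42, 0.25, 0.12)
    fit <- coupling_group_models(c(ry, ro),
                                 rep(c("young", "old"), c(29, 42)),
                                 n_boot = 50, seed = sample.int(1e6, 1))
    fit$coefficients$b
  })
  expect_lt(abs(mean(b) + 0.10), 0.03)

  fit <- coupling_group_models(rnorm(20), rep(c("young", "old"), 10),
                               n_boot = 100, seed = 1)
  expect_true(is.na(fit$coefficients$partial))
})

test_that("voxelwise group coupling maps difference structure", {
  set.seed(58)
  n <- 20; nv <- 500
  g <- factor(rep(c("young", "old"), each = n), c("young", "old"))
  latent <- matrix(rnorm(2 * n * nv), 2 * n, nv)
  sd_mat <- latent + matrix(rnorm(2 * n * nv), 2 * n, nv)
  vasc <- matrix(rnorm(2 * n * nv), 2 * n, nv)
  vasc[g == "old", ] <- 0.6 * latent[g == "old", ] +
    0.8 * vasc[g == "old", ]
  res <- voxelwise_group_coupling(sd_mat, vasc, g)
  expect_true(all(abs(res$difference) <= 2))
  expect_lt(mean(res$difference), 0)      # coupling planted in old only

  null <- voxelwise_group_coupling(latent,
                                   matrix(rnorm(2 * n * nv), 2 * n, nv), g)
  expect_lt(abs(mean(null$difference)), 0.1)
  expect_equal(sum(null$histogram$count), nv)
})
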