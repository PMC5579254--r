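test_that("the group-by-voxel SVD matches hand calculations", {
  # equal group means: centering annihilates everything
  x <- rbind(matrix(1:6, 2, 3, byrow = TRUE),
             matrix(1:6, 2, 3, byrow = TRUE))
  g <- factor(c("young", "young", "old", "old"), c("young", "old"))
  expect_lt(max(task_pls(x, g)$s), 1e-12)

  # group means young (4, 0), old (0, 0): centered rows +-(2, 0)
  x2 <- rbind(c(4, 0), c(4, 0), c(0, 0), c(0, 0)) + 0
  res <- task_pls(x2, g)
  expect_equal(res$s[1], 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(abs(res$v[, 1]), c(1, 0), tolerance = 1e-12)
  expect_gt(res$u[1, 1], 0)   # sign convention: young salience positive

  # permuting voxels permutes V rows, leaves S alone
  set.seed(31)
  x3 <- matrix(rnorm(6 * 10), 6, 10)
  g3 <- factor(rep(c("young", "old"), each = 3), c("young", "old"))
  perm <- sample(10)
  a <- task_pls(x3, g3); b <- task_pls(x3[, perm], g3)
  expect_equal(a$s, b$s, tolerance = 1e-12)
  expect_equal(abs(a$v[perm, 1]), abs(b$v[, 1]), tolerance = 1e-12)

  expect_error(task_pls(x3[1:4, ], factor(c("y", "y", "y", "o"))),
               "2 subjects")
})

test_that("U and V are orthonormal and reconstruct the covariance matrix", {
  set.seed(32)
  for (i in 1:5) {
    x <- matrix(rnorm(20 * 15), 20, 15)
    g <- factor(rep(c("young", "old"), each = 10), c("young", "old"))
    res <- task_pls(x, g)
    expect_lt(max(abs(crossprod(res$u) - diag(2))), 1e-10)
    expect_lt(max(abs(crossprod(res$v) - diag(2))), 1e-10)
    expect_lt(max(abs(res$u %*% diag(res$s) %*% t(res$v) - res$cov)), 1e-10)
  }
})

test_that("permutation p-values are deterministic and detect planted effects", {
  set.seed(33)
  n <- 20
  x <- matrix(rnorm(2 * n * 100), 2 * n, 100)
  g <- factor(rep(c("young", "old"), each = n), c("young", "old"))
  x[g == "young", 1:30] <- x[g == "young", 1:30] + 1.5
  p <- permutation_test(x, g, n_perm = 200, seed = 7)
  expect_equal(p$p[1], 1 / 201)
  p2 <- permutation_test(x, g, n_perm = 200, seed = 7)
  expect_identical(p, p2)
})

test_that("bootstrap ratios are sign-equivariant and calibrated under the null", {
  set.seed(34)
  n <- 60
  x <- matrix(rnorm(2 * n * 300), 2 * n, 300)
  g <- factor(rep(c("young", "old"), each = n), c("young", "old"))
  bsr <- bootstrap_bsr(x, g, n_boot = 100, seed = 3)
  expect_lte(mean(abs(bsr$bsr) >= 2.70), 0.02)

  flip <- bootstrap_bsr(-x, g, n_boot = 100, seed = 3)
  expect_equal(abs(flip$bsr), abs(bsr$bsr), tolerance = 1e-10)
})

test_that("brain scores are the salience dot product and linear", {
  v <- c(0.5, -0.5, sqrt(0.5))
  expect_equal(brain_scores(v, c(2, 1, 1)), 0.5 * 2 - 0.5 + sqrt(0.5))
  expect_equal(brain_scores(v, c(2, 1, 1)), 1.2071, tolerance = 1e-4)
  expect_equal(brain_scores(v, rep(0, 3)), 0)
  x1 <- rnorm(3); x2 <- rnorm(3)
  expect_equal(brain_scores(v, 2 * x1 + 3 * x2),
               2 * brain_scores(v, x1) + 3 * brain_scores(v, x2),
               tolerance = 1e-12)
  expect_error(brain_scores(v, c(1, 2)), "mismatch")
})

test_that("brain scores separate groups in the direction of the contrast", {
  set.seed(35)
  x <- matrix(rnorm(20 * 50), 20, 50)
  g <- factor(rep(c("young", "old"), each = 10), c("young", "old"))
  x[g == "young", 1:10] <- x[g == "young", 1:10] + 1
  res <- task_pls(x, g)
  sc <- brain_scores(res$v[, 1], x)
  expect_gt(mean(sc[g == "young"]), mean(sc[g == "old"]))
})

test_that("region thresholding builds cluster tables and nests", {
  d <- c(8, 8, 4)
  mask <- array(TRUE, d)
  z <- array(0, d)
  zero_map <- voxel_map(z, mask, "bsr")
  expect_warning(empty <- threshold_regions(zero_map, 2.7), "no voxels")
  expect_equal(empty$n_voxels, 0L)

  z[2:4, 2:3, 1:2] <- 3.2          # 12-voxel blob
  z[3, 2, 1] <- 4.1                # its peak
  z[7, 7, 4] <- -5                 # opposite-sign voxel must not enter
  m <- voxel_map(z, mask, "bsr")
  reg <- threshold_regions(m, 2.70, "young_higher")
  expect_equal(reg$n_voxels, 12L)
  expect_equal(nrow(reg$clusters), 1L)
  expect_equal(reg$clusters$size, 12)
  expect_equal(reg$clusters$peak_bsr, 4.1)
  expect_equal(unlist(reg$clusters[1, c("peak_x", "peak_y", "peak_z")]),
               c(peak_x = 3L, peak_y = 2L, peak_z = 1L))

  tighter <- threshold_regions(m, 3.5, "young_higher")
  expect_true(all(tighter$mask$values <= reg$mask$values))

  neg <- threshold_regions(m, 2.70, "old_higher")
  expect_equal(neg$n_voxels, 1L)
})

test_that("connected-component labelling respects the connectivity choice", {
  m <- array(FALSE, c(5, 5, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 1] <- TRUE                 # diagonal neighbour
  l26 <- label_clusters(m, 26)
  l6 <- label_clusters(m, 6)
  expect_equal(max(l26), 1L)
  expect_equal(max(l6), 2L)
})
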