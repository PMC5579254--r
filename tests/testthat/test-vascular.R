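test_that("the block GLM recovers planted effects exactly on noise-free data", {
  d <- make_design("hypercapnia")
  reg <- build_task_regressor(d$design, d$n_frames, "hypercapnia")
  y <- matrix(100 + 2 * reg, nrow = 1)
  fit <- fit_block_glm(y, d$design)
  expect_equal(fit$effect, 2, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$constant, 100, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$fractional_change, 0.02, tolerance = 1e-8,
               ignore_attr = TRUE)

  u <- seq(-1, 1, length.out = d$n_frames)
  drift <- matrix(5 + u + 0.5 * u^2 - 2 * u^3, nrow = 1)
  expect_lt(abs(fit_block_glm(drift, d$design)$effect), 1e-8)

  zero <- fit_block_glm(matrix(0, 1, d$n_frames), d$design)
  expect_equal(zero$effect, 0, ignore_attr = TRUE)
  expect_equal(zero$constant, 0, ignore_attr = TRUE)
})

test_that("the block GLM recovers effects within 3 SE under Gaussian noise", {
  d <- make_design("hypercapnia")
  reg <- build_task_regressor(d$design, d$n_frames, "hypercapnia")
  set.seed(14)
  ok <- 0L
  for (i in 1:20) {
    y <- matrix(100 + 2 * reg + rnorm(d$n_frames, 0, 1), nrow = 1)
    fit <- fit_block_glm(y, d$design)
    X <- cbind(reg, 1, stats::poly(seq(-1, 1, length.out = d$n_frames), 3))
    se <- sqrt(solve(crossprod(X))[1, 1])
    if (abs(fit$effect - 2) <= 3 * se) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})

test_that("CBF quantification matches the closed form", {
  p <- acquisition_params()
  expect_equal(quantify_cbf(0, 100, p), 0)
  # direct arithmetic oracle for dM/M0 = 0.01 at default constants
  m0 <- 100 / (1 - exp(-3 / 1.4))
  oracle <- 6000 * 0.9 * (0.01 * m0) * exp(0.9 / 1.49) /
    (2 * 0.80 * 1.49 * m0 * (1 - exp(-1.5 / 1.49)))
  expect_equal(quantify_cbf(0.01 * m0, 100, p), oracle, tolerance = 1e-12)
  expect_equal(oracle, 65.3, tolerance = 1e-3)
  expect_equal(quantify_cbf(0.02 * m0, 100, p), 2 * oracle,
               tolerance = 1e-12)
  expect_error(quantify_cbf(1, -5, p), "positive")
})

test_that("CVR is the BOLD change per mmHg", {
  expect_equal(compute_cvr(2.0, 5), 0.40)
  expect_equal(compute_cvr(0, 5), 0)
  expect_equal(compute_cvr(-1.5, 5), -0.3)
  expect_error(compute_cvr(2, 0), "stimulus")
})

test_that("venous saturation follows Severinghaus plus the Fick principle", {
  sv <- estimate_svo2(100, 1)
  expect_equal(sv$sao2, 0.9775, tolerance = 1e-4)
  expect_equal(sv$svo2, sv$svo2_0)

  # find the PO2 at which SaO2 = 0.98, then check the Fick arithmetic
  po2_98 <- uniroot(function(p) 1 / (23400 / (p^3 + 150 * p) + 1) - 0.98,
                    c(50, 500))$root
  sv2 <- estimate_svo2(po2_98, 1.2, oef0 = 0.30)
  expect_equal(sv2$svo2_0, 0.98 * 0.7, tolerance = 1e-6)
  expect_equal(sv2$svo2, 0.98 * (1 - 0.30 / 1.2), tolerance = 1e-6)

  expect_error(estimate_svo2(100, 0.2, oef0 = 0.30), "desaturated")
})

test_that("the calibration model reproduces its printed arithmetic", {
  expect_equal(compute_m(0, 1.3, dhb_ratio = 0.9)$m, 0)
  got <- compute_m(0.02, 1.6, dhb_ratio = 0.8)
  expect_equal(got$denominator, 1 - 1.6^0.18 - 0.8^1.5, tolerance = 1e-12)
  expect_equal(got$denominator, -0.8038, tolerance = 1e-3)
  expect_equal(got$m, -0.02488, tolerance = 1e-3)
  expect_false(got$physiological)

  # constructed zero denominator: cbf_ratio^alpha = dhb^beta = 0.5
  r0 <- 0.5^(1 / 0.18); dhb0 <- 0.5^(1 / 1.5)
  expect_error(compute_m(0.02, r0, dhb_ratio = dhb0), "zero")

  # dhb_ratio form is positive for physiological hypercapnia inputs
  sv <- estimate_svo2(100, 1.3)
  alt <- compute_m(0.0175, 1.3, svo2 = sv$svo2, svo2_0 = sv$svo2_0,
                   form = "dhb_ratio")
  expect_true(alt$physiological)
})

test_that("the calibration model matches brute-force re-evaluation", {
  set.seed(15)
  for (i in 1:100) {
    db <- runif(1, 0.005, 0.05)
    r <- runif(1, 1.05, 2)
    dhb <- runif(1, 0.5, 0.95)
    a <- runif(1, 0.1, 0.4); b <- runif(1, 1, 2)
    for (form in c("printed", "dhb_ratio")) {
      den <- if (form == "printed") 1 - r^a - dhb^b else 1 - r^(a - b) * dhb^b
      expect_equal(compute_m(db, r, dhb_ratio = dhb, alpha = a, beta = b,
                             form = form)$m,
                   db / den, tolerance = 1e-12)
    }
  }
})

test_that("planted CBF and CVR are recovered from generated runs", {
  # near-noise-free: planted BOLD fluctuations shrunk to 0.02% of the mean
  spec <- tiny_spec(seed = 30, sd_young = 0.02, sd_old = 0.02,
                    sd_background = 0.02, sd_bs_sd = 0.002)
  co <- generate_cohort(spec)
  truth <- co$truth
  gm_vec <- as.vector(spec$masks$gm)
  params <- co$subjects[[1]]$fixation$params
  for (s in c(1, 5)) {
    fx <- co$subjects[[s]]$fixation
    flow <- as_voxel_matrix(surround_subtract(fx$echo1, fx$tag_parity))$m
    e1 <- as_voxel_matrix(fx$echo1)$m
    cbf_hat <- quantify_cbf(rowMeans(flow[gm_vec, ]),
                            rowMeans(e1[gm_vec, ]), params)
    expect_rel_equal(cbf_hat, truth$cbf_true[s, ], 0.03)

    hy <- co$subjects[[s]]$hypercapnia
    bold <- as_voxel_matrix(surround_add(hy$echo2))$m[gm_vec, ]
    fit <- fit_block_glm(bold, hy$design)
    dpco2 <- max(hy$endtidal$pco2) - min(hy$endtidal$pco2)
    expect_equal(dpco2, 5)
    cvr_hat <- compute_cvr(fit$fractional_change * 100, dpco2)
    # ROI-level recovery within 3%; voxelwise within 10% (the surround
    # addition mildly attenuates the response ramps)
    expect_lt(abs(mean(cvr_hat) / mean(truth$cvr_true[s, ]) - 1), 0.03)
    expect_rel_equal(cvr_hat, truth$cvr_true[s, ], 0.10)
  }
})
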