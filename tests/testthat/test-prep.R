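test_that("surround subtraction recovers the tag/control difference", {
  x <- matrix(c(98, 100, 98, 100), nrow = 1)
  expect_equal(as.vector(surround_subtract(x, "even")), rep(2, 4))
  expect_equal(as.vector(surround_subtract(matrix(7, 1, 6), "even")),
               rep(0, 6))
  y <- matrix(rnorm(8), nrow = 1)
  expect_equal(surround_subtract(y, "odd"), -surround_subtract(y, "even"))
  expect_error(surround_subtract(matrix(1, 1, 2)), "3 frames")
})

test_that("surround addition averages out the modulation and keeps trends", {
  x <- matrix(c(98, 100, 98, 100), nrow = 1)
  expect_equal(as.vector(surround_add(x))[2:3], c(99, 99))
  expect_equal(as.vector(surround_add(matrix(100, 1, 5))), rep(100, 5))
  tr <- matrix(seq(1, 20), nrow = 1)
  out <- as.vector(surround_add(tr))
  expect_equal(out[2:19], seq(2, 19))  # 3-point average is exact on a line
})

test_that("surround operations jointly separate carrier and perfusion", {
  set.seed(3)
  n <- 60
  carrier <- 100 + 2 * sin(2 * pi * (1:n) / 40)   # slow BOLD modulation
  delta <- 3
  sign <- ifelse(tag_frame_mask(n, "even"), -0.5, 0.5)
  x <- matrix(carrier + delta * sign, nrow = 1)
  flow <- as.vector(surround_subtract(x, "even"))
  bold <- as.vector(surround_add(x))
  interior <- 5:(n - 4)
  expect_true(max(abs(flow[interior] / delta - 1)) < 0.02)
  expect_true(max(abs(bold[interior] / carrier[interior] - 1)) < 0.02)
})

test_that("high-pass filter separates stop and pass bands", {
  tr <- 3
  t0 <- (0:299) * tr
  slow <- matrix(sin(2 * pi * 0.002 * t0), nrow = 1)
  fast <- matrix(sin(2 * pi * 0.05 * t0), nrow = 1)
  mid <- 101:200
  amp <- function(v) max(abs(v[mid]))
  expect_lt(amp(as.vector(highpass_filter(slow, 0.01, tr))), 0.1)
  expect_gt(amp(as.vector(highpass_filter(fast, 0.01, tr))), 0.9)
  expect_equal(as.vector(highpass_filter(matrix(0, 1, 50), 0.01, tr)),
               rep(0, 50))
  expect_error(highpass_filter(slow, 0.2, tr), "Nyquist")
})

test_that("spatial smoothing matches the explicit kernel and preserves DC", {
  vol <- array(0, c(9, 9, 9))
  vol[5, 5, 5] <- 1
  fwhm <- 8; vs <- 4
  out <- smooth_spatial(vol, fwhm, vs)
  sigma <- fwhm / 2.3548 / vs
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  expect_equal(out[5, 5, 5], k[r + 1]^3, tolerance = 1e-12)

  expect_identical(smooth_spatial(vol, 0, vs), vol)
  const <- array(7, c(6, 6, 4))
  expect_equal(smooth_spatial(const, 8, 4), const, tolerance = 1e-12)
  expect_error(smooth_spatial(vol, -1, vs), "non-negative")
})

test_that("planted artifact components are all rejected and a clean
           component is kept", {
  spec <- tiny_spec(seed = 5)
  co <- generate_cohort(spec, runs = "fixation")
  masks <- spec$masks
  inj <- inject_artifacts(co$subjects[[1]]$fixation,
                          c("spike", "drift", "highfreq", "scattered"),
                          masks, seed = 9)
  tr <- spec$tr
  for (cmp in inj$components) {
    fl <- classify_component(cmp, masks, tr)
    expect_true(fl$flags[[cmp$type]],
                label = paste(cmp$type, "criterion fires"))
    expect_equal(fl$decision, "reject")
  }
  # negative control: smooth focal GM blob with a mid-frequency course
  gmv <- which(masks$gm, arr.ind = TRUE)
  blob <- array(0, dim(masks$gm))
  ctr <- round(colMeans(gmv))
  sel <- abs(gmv[, 1] - ctr[1]) <= 1 & abs(gmv[, 2] - ctr[2]) <= 1 &
    abs(gmv[, 3] - ctr[3]) <= 1
  blob[gmv[sel, , drop = FALSE]] <- 10
  blob[masks$brain & blob == 0] <- rnorm(sum(masks$brain) - sum(sel), 0, 0.1)
  nf <- dim(co$subjects[[1]]$fixation$echo2)[4]
  clean <- list(timecourse = sin(2 * pi * 0.03 * (0:(nf - 1)) * tr) +
                  rnorm(nf, 0, 0.05),
                spatial_map = blob, id = "ic_clean")
  fl <- classify_component(clean, masks, tr)
  expect_false(any(fl$flags))
  expect_equal(fl$decision, "keep")
  # white-matter/CSF component
  wmmap <- array(0, dim(masks$gm))
  wmmap[masks$wm_csf] <- 10
  fl <- classify_component(list(timecourse = clean$timecourse,
                                spatial_map = wmmap, id = "ic_wm"),
                           masks, tr)
  expect_true(fl$flags[["wm_csf"]])
  expect_equal(fl$decision, "reject")
})

test_that("component removal is a partial regression", {
  set.seed(11)
  n <- 80
  sig <- sin(2 * pi * (0:(n - 1)) / 20)  # whole periods: orthogonal to the
                                         # alternating course and mean-free
  art <- rep(c(1, -1), n / 2)          # orthogonal to sig by symmetry
  art <- art - mean(art)
  y <- matrix(sig + 3 * art, nrow = 1)
  courses <- cbind(keep = sig, bad = art)
  cleaned <- regress_out_components(y, courses, "bad")
  expect_lt(max(abs(as.vector(cleaned) - sig)), 1e-8)
  expect_lt(abs(cor(as.vector(cleaned), art)), 1e-6)

  expect_identical(regress_out_components(y, courses, integer(0)), y)
  expect_error(regress_out_components(y, courses, "nope"), "unknown")

  # correlated courses: the kept course's fitted contribution is unchanged
  c1 <- rnorm(n); c2 <- 0.6 * c1 + rnorm(n)
  b <- c(2, -1.5)
  y2 <- matrix(5 + b[1] * c1 + b[2] * c2, nrow = 1)
  X <- cbind(1, c1, c2)
  beta_oracle <- solve(crossprod(X), crossprod(X, as.vector(y2)))
  cleaned2 <- regress_out_components(y2, cbind(c1 = c1, c2 = c2), "c2")
  expect_equal(as.vector(cleaned2),
               as.vector(y2) - c2 * beta_oracle[3], tolerance = 1e-10)
})

test_that("removal never increases correlation with a rejected course", {
  set.seed(21)
  n <- 60
  courses <- matrix(rnorm(n * 3), n, 3)
  y <- matrix(rnorm(5 * n), 5, n) + outer(rnorm(5), courses[, 2])
  cleaned <- regress_out_components(y, courses, 2)
  for (v in 1:5) {
    expect_lte(abs(cor(cleaned[v, ], courses[, 2])),
               abs(cor(y[v, ], courses[, 2])) + 1e-12)
  }
})

test_that("block centering and normalization follow the two-step scheme", {
  m <- matrix(c(1, 3, 5, 7), nrow = 1)
  fs <- list(1:2, 3:4)
  expect_equal(as.vector(center_blocks(m, fs)), c(-1, 1, -1, 1))

  des <- two_block_design()
  x <- matrix(c(25, 75, 25, 75, 125, 175, 125, 175), nrow = 1)  # grand mean 100... scaled
  x <- x / 2                                                    # grand mean 50
  norm <- normalize_blocks(x, des, mask = TRUE)
  expect_equal(norm$scale, 2)
  expect_lt(max(abs(tapply(norm$series[1, ], norm$block_id, mean))), 1e-10)
  expect_lt(abs(mean(norm$series)), 1e-10)

  # per-block additive offsets do not change the centered output
  x2 <- x
  x2[, 5:8] <- x2[, 5:8] + 40
  norm2 <- normalize_blocks(x2, des, mask = TRUE)
  expect_equal(norm2$series / norm2$scale, norm$series / norm$scale,
               tolerance = 1e-12)

  expect_error(normalize_blocks(-x, des, mask = TRUE), "positive")
})
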