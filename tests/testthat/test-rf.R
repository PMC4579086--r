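make_grating <- function(theta, n = 16, frames = 3, lambda = 5) {
  xg <- outer(rep(1, n), seq_len(n))
  yg <- outer(seq_len(n), rep(1, n))
  frame <- sin(2 * pi * (xg * cos(theta) + yg * sin(theta)) / lambda)
  array(rep(frame, frames), c(n, n, frames))
}

square_rf <- function(center = c(8, 8), hw = 5) {
  structure(list(center = center, halfwidth_px = hw, side_px = 2 * hw + 1,
                 undefined = FALSE), class = "receptive_field")
}

test_that("reverse correlation recovers a planted receptive field", {
  set.seed(1)
  hits <- replicate(10, {
    movie <- array(runif(16 * 16 * 300), c(16, 16, 300))
    lum <- apply(movie[9:12, 5:8, ], 3, mean)
    power <- c(rep(0, 4), lum[1:296]) + rnorm(300, sd = sd(lum) / 3)
    m <- reverse_correlation_map(power, movie, n_svd_remove = 0)
    rf <- rf_from_map(m)
    # true centre (10.5, 6.5) maps to down-sampled (3.375, 2.375)
    max(abs(rf$center - c(3.375, 2.375))) <= 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("reverse correlation map is calibrated when power is independent", {
  set.seed(2)
  mx <- replicate(20, {
    movie <- array(runif(16 * 16 * 300), c(16, 16, 300))
    max(abs(reverse_correlation_map(rnorm(300), movie, n_svd_remove = 0)$z))
  })
  expect_gte(mean(mx < 3), 0.95)
})

test_that("SVD removal with zero components is a no-op", {
  set.seed(3)
  movie <- array(runif(12 * 12 * 100), c(12, 12, 100))
  p <- rnorm(100)
  m0 <- reverse_correlation_map(p, movie, n_svd_remove = 0)
  m0b <- reverse_correlation_map(p, movie, n_svd_remove = 0)
  expect_identical(m0$z, m0b$z)
  m1 <- reverse_correlation_map(p, movie, n_svd_remove = 1)
  expect_false(identical(m0$z, m1$z))
  expect_error(reverse_correlation_map(rnorm(99), movie), "same number")
})

test_that("RF extent grows to the 75% border contour", {
  m <- matrix(0, 15, 15); m[8, 8] <- 1
  rf <- rf_from_map(m)
  expect_equal(rf$center, c(8, 8))
  expect_equal(rf$side_px, 3)   # first border fully below threshold
  # isotropic Gaussian bump: border must fall below 0.75 of the peak,
  # i.e. halfwidth >= sigma * sqrt(-2 log 0.75)
  sigma <- 3
  g <- outer(1:25, 1:25, function(i, j)
    exp(-((i - 13)^2 + (j - 13)^2) / (2 * sigma^2)))
  rfg <- rf_from_map(g)
  r75 <- sigma * sqrt(-2 * log(0.75))
  expect_lte(abs(rfg$halfwidth_px - ceiling(r75)), 1)
  expect_true(rf_from_map(matrix(1, 5, 5))$undefined)
})

test_that("time contrast measures frame-to-frame luminance change", {
  static <- array(0.5, c(10, 10, 5))
  rf <- square_rf(c(5, 5), 3)
  expect_equal(time_contrast(static, rf), rep(0, 5))
  # homogeneity: a mean-preserving luminance flip of amplitude a gives TC
  # proportional to a
  sgn <- matrix(rep(c(1, -1), 50), 10, 10)
  flip1 <- static; flip1[, , 3] <- 0.5 + 0.1 * sgn
  flip2 <- static; flip2[, , 3] <- 0.5 + 0.2 * sgn
  tc1 <- time_contrast(flip1, rf); tc2 <- time_contrast(flip2, rf)
  expect_equal(tc2[3] / tc1[3], 2, tolerance = 0.02)
  expect_equal(tc1[1], 0)
  # zero-luminance movie: unnormalised fallback is flagged
  z <- time_contrast(array(0, c(10, 10, 3)), rf)
  expect_true(isTRUE(attr(z, "unnormalised")))
  expect_error(time_contrast(array(0, c(10, 10, 1)), rf), "2 frames")
})

test_that("orientation activation matches cos^2 tuning on gratings", {
  rf <- square_rf(c(8, 8), 5)
  oa_pref <- orientation_activation(make_grating(pi / 4), rf, pi / 4)
  oa_orth <- orientation_activation(make_grating(pi / 4), rf, pi / 4 + pi / 2)
  oa_45 <- orientation_activation(make_grating(pi / 4), rf, 0)
  expect_gt(mean(oa_pref, na.rm = TRUE), 0.95)
  expect_lt(mean(oa_orth, na.rm = TRUE), 0.05)
  expect_equal(mean(oa_45, na.rm = TRUE), 0.5, tolerance = 0.02)
  # bounds and gain/offset invariance
  set.seed(4)
  movie <- array(runif(16 * 16 * 10), c(16, 16, 10))
  oa <- orientation_activation(movie, rf, 0.3)
  expect_true(all(oa >= 0 & oa <= 1, na.rm = TRUE))
  oa_sc <- orientation_activation(3 * movie + 2, rf, 0.3)
  expect_equal(oa, oa_sc, tolerance = 1e-9)
  # gradient-free frame is masked
  flat <- array(1, c(16, 16, 2))
  expect_true(all(is.na(orientation_activation(flat, rf, 0))))
})

test_that("orientation tuning recovers a planted preference", {
  set.seed(5)
  rf <- square_rf(c(8, 8), 6)
  thetas <- runif(200, 0, pi)
  movie <- array(0, c(16, 16, 200))
  for (f in 1:200) movie[, , f] <- make_grating(thetas[f], frames = 1)[, , 1]
  # firing driven by energy at 45 degrees
  mua <- cos(thetas - pi / 4)^2 + rnorm(200, sd = 0.1)
  tc <- orientation_tuning(mua, movie, rf)
  expect_lt(abs(tc$preferred - pi / 4), pi / 8 + 1e-9)
  # independent MUA: flat curve, near-zero covariance with any tuning
  tc0 <- orientation_tuning(rnorm(200), movie, rf)
  expect_lt(abs(tuning_similarity(tc0, tc)), 0.05)
  # matched planted tunings agree, opposed ones anti-correlate
  mua2 <- cos(thetas - pi / 4)^2 + rnorm(200, sd = 0.1)
  tc2 <- orientation_tuning(mua2, movie, rf)
  expect_gt(tuning_similarity(tc, tc2), 0)
  mua3 <- cos(thetas - 3 * pi / 4)^2 + rnorm(200, sd = 0.1)
  tc3 <- orientation_tuning(mua3, movie, rf)
  expect_lt(tuning_similarity(tc, tc3), 0)
  expect_error(orientation_tuning(rep(1, 200), movie, rf), "constant")
})

test_that("directed motion takes the positive part of the projected flow", {
  send <- c(0, 0); recv <- c(2, 0)
  expect_equal(directed_motion(rigid_translation_flow(5, c(3, 0)), send, recv),
               rep(3, 5))
  expect_equal(directed_motion(rigid_translation_flow(5, c(-3, 0)), send, recv),
               rep(0, 5))
  expect_equal(directed_motion(rigid_translation_flow(5, c(0, 4)), send, recv),
               rep(0, 5))
  # complementarity: dm(a,b) + dm(b,a) = |F . u|
  set.seed(6)
  fl <- matrix(rnorm(20), 10, 2)
  dm_ab <- directed_motion(fl, send, recv)
  dm_ba <- directed_motion(fl, recv, send)
  expect_equal(dm_ab + dm_ba, abs(fl %*% c(1, 0))[, 1], tolerance = 1e-12)
  expect_error(directed_motion(fl, send, send), "coincident")
})

test_that("feature-signal correlation supports the four combinations", {
  set.seed(7)
  f1 <- runif(100); f2 <- runif(100)
  expect_equal(feature_signal_correlation(f1, target = f1, combine = "send"), 1)
  expect_equal(feature_signal_correlation(f1, f2, target = f1 - f2,
                                          combine = "diff"), 1)
  expect_equal(feature_signal_correlation(f1, f2, target = f1 + f2,
                                          combine = "sum"), 1)
  r0 <- replicate(100, feature_signal_correlation(runif(50), target = runif(50),
                                                  combine = "send"))
  expect_lt(abs(mean(r0)), 0.05)
  expect_error(feature_signal_correlation(rep(1, 50), target = runif(50),
                                          combine = "send"), "constant")
  expect_error(feature_signal_correlation(f1, target = f1, combine = "diff"),
               "feat_recv")
})
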