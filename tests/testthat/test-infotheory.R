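test_that("equipopulated binning balances occupancies and flags bad input", {
  b <- equipopulated_bin(c(1, 2, 3, 4), 2)
  expect_equal(b$symbols, c(1L, 1L, 2L, 2L))
  set.seed(1)
  b4 <- equipopulated_bin(runif(1000), 4)
  expect_equal(unname(table(b4$symbols)), rep(250L, 4), ignore_attr = TRUE)
  expect_error(equipopulated_bin(rep(3, 100), 4), "constant")
  expect_error(equipopulated_bin(1:10, 1), "n_bins")
  # NA passthrough
  bna <- equipopulated_bin(c(1, NA, 2, 3, 4), 2)
  expect_true(is.na(bna$symbols[2]))
})

test_that("entropy matches closed forms", {
  expect_equal(entropy_bits(rep(5, 4)), 2)
  expect_equal(entropy_bits(c(10, 0, 0)), 0)
  expect_equal(entropy_bits(c(3, 1)),
               -0.75 * log2(0.75) - 0.25 * log2(0.25), tolerance = 1e-12)
  expect_error(entropy_bits(c(0, 0)), "all-zero")
  expect_error(entropy_bits(c(-1, 2)), "nonnegative")
})

test_that("mutual information matches plug-in oracles", {
  s <- rep(1:4, each = 25)
  expect_equal(mutual_information(s, s, correction = "none")$value, 2)
  # joint table (2,1 ; 1,2)/6
  r <- c(1, 1, 2, 1, 2, 2); st <- c(1, 1, 1, 2, 2, 2)
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  oracle <- h(c(.5, .5)) + h(c(.5, .5)) - h(c(2, 1, 1, 2) / 6)
  expect_equal(mutual_information(r, st, correction = "none")$value, oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 0.0817, tolerance = 1e-4)
  expect_error(mutual_information(r, rep(1, 6)), "2 stimulus classes")
})

test_that("bias-corrected MI of independent variables is near zero", {
  set.seed(2)
  vals <- replicate(200, {
    r <- equipopulated_bin(runif(200), 4)
    s <- sample(1:4, 200, TRUE)
    mutual_information(r, s, correction = "panzeri-treves")$value
  })
  expect_lt(abs(mean(vals)), 0.02)
  vals_sh <- replicate(50, {
    r <- equipopulated_bin(runif(200), 4)
    s <- sample(1:4, 200, TRUE)
    mutual_information(r, s, correction = "shuffle")$value
  })
  expect_lt(abs(mean(vals_sh)), 0.02)
})

test_that("MI is bounded by the marginal entropies", {
  set.seed(3)
  for (i in 1:20) {
    r <- sample(1:4, 150, TRUE)
    s <- sample(1:3, 150, TRUE)
    v <- mutual_information(r, s, correction = "none")$value
    expect_lte(v, min(entropy_bits(tabulate(r)), entropy_bits(tabulate(s))) +
                 1e-12)
    expect_gte(v, -1e-12)
  }
})

test_that("conditional MI matches the enumeration oracle on small alphabets", {
  set.seed(4)
  for (i in 1:25) {
    kx <- sample(2:4, 1); ky <- sample(2:4, 1); kz <- sample(2:4, 1)
    n <- 300
    xs <- sample(seq_len(kx), n, TRUE)
    ys <- sample(seq_len(ky), n, TRUE)
    # induce some three-way structure
    flip <- runif(n) < 0.4
    xs[flip] <- pmin(ys[flip], kx)
    zs <- sample(seq_len(kz), n, TRUE)
    v_pkg <- conditional_mutual_information(xs, ys, zs,
                                            correction = "none")$value
    v_fast <- gammawave:::fast_cmi(xs, ys, zs, kx, ky, kz, "none")
    v_oracle <- cmi_oracle(xs, ys, zs)
    expect_equal(v_pkg, v_oracle, tolerance = 1e-10)
    expect_equal(v_fast, v_oracle, tolerance = 1e-10)
  }
})

test_that("transfer entropy of a copy channel is exactly one bit", {
  # X_t = Y_{t-1}, Y iid fair bits, X_past uninformative
  set.seed(5)
  y <- sample(1:2, 4000, TRUE)
  x <- c(1L, y[-4000])
  xp <- sample(1:2, 4000, TRUE)   # uninformative stand-in for X_past
  v <- conditional_mutual_information(x[-1], y[-4000], xp[-1],
                                      correction = "none")$value
  expect_equal(v, 1, tolerance = 0.01)
})

test_that("lagged conditional information handles degenerate conditioners", {
  set.seed(6)
  y <- sample(1:3, 500, TRUE)
  x <- sample(1:3, 500, TRUE)
  # conditioning on Y itself removes all information
  expect_equal(conditional_mutual_information(x, y, y,
                                              correction = "none")$value,
               0, tolerance = 1e-12)
  # X = Y xor noise bit, Z independent: enumeration gives the exact value
  yb <- sample(0:1, 2000, TRUE)
  nb <- sample(0:1, 2000, TRUE, prob = c(0.8, 0.2))
  xb <- bitwXor(yb, nb)
  zb <- sample(0:1, 2000, TRUE)
  v <- conditional_mutual_information(xb + 1L, yb + 1L, zb + 1L,
                                      correction = "none")$value
  expect_equal(v, cmi_oracle(xb + 1L, yb + 1L, zb + 1L), tolerance = 1e-10)
  expect_gt(v, 0)
})

test_that("TE estimates are invariant to monotone transforms of the inputs", {
  cfg <- coupled_pair_config(seed = 11, n_trials = 4, n_scenes = 5)
  ss <- generate_session(cfg)
  x <- ss$rate[, 2, ]; y <- ss$phase[, 1, ]
  v1 <- transfer_entropy(x, y, fs_hz = 1000)$value
  v2 <- transfer_entropy(exp(x), 2 * y + 1, fs_hz = 1000)$value
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("TE detects a planted edge and its direction", {
  cfg <- coupled_pair_config(seed = 12)
  ss <- generate_session(cfg)
  fwd <- transfer_entropy(ss$rate[, 2, ], ss$phase[, 1, ], fs_hz = 1000,
                          n_boot = 40, seed = 1)
  rev <- transfer_entropy(ss$rate[, 1, ], ss$phase[, 2, ], fs_hz = 1000,
                          n_boot = 40, seed = 2)
  expect_gt(fwd$z, 3)
  expect_lt(abs(rev$z), 3)
  expect_gt(fwd$value, 10 * max(rev$value, 1e-4))
  # independent series: corrected TE near zero
  set.seed(13)
  xi <- matrix(rnorm(4 * 2000), 4)
  for (tt in 2:2000) xi[, tt] <- 0.6 * xi[, tt - 1] + rnorm(4)
  yi <- matrix(runif(4 * 2000), 4)
  ind <- transfer_entropy(xi, yi, fs_hz = 1000, n_boot = 40, seed = 3)
  expect_lt(abs(ind$z), 2)
})

test_that("LCI remains positive when conditioning on the sender's rate", {
  cfg <- coupled_pair_config(seed = 14)
  ss <- generate_session(cfg)
  lci <- lagged_conditional_information(ss$rate[, 2, ], ss$phase[, 1, ],
                                        cond = ss$rate[, 1, ], fs_hz = 1000,
                                        n_boot = 40, seed = 4)
  expect_gt(lci$z, 3)
  # localized LCI: conditioning on the receiver's past phase
  loc <- lagged_conditional_information(ss$rate[, 2, ], ss$phase[, 1, ],
                                        cond = ss$phase[, 2, ], fs_hz = 1000,
                                        n_boot = 40, seed = 5)
  expect_gt(loc$z, 3)
})

test_that("bootstrap bookkeeping: Z is zero when the estimate equals the null mean",
{
  est <- gammawave:::info_estimate(0.5, n = 100L)
  est$null_mean <- 0.5; est$null_sd <- 0.1
  est$z <- (est$value - est$null_mean) / est$null_sd
  expect_equal(est$z, 0)
  expect_error(transfer_entropy(matrix(1:100, 1), matrix(runif(100), 1),
                                fs_hz = 1000, n_boot = 10),
               "at least 2 trials")
})

test_that("sensory information recovers scene-locked responses", {
  # response equal to the scene index: maximal information
  scene <- rep(1:4, each = 100)
  resp <- matrix(rep(scene, 8), nrow = 8, byrow = TRUE) +
    matrix(rnorm(8 * 400, sd = 1e-3), 8)
  si <- sensory_information(resp, scene, type = "slow", n_bins = 4)
  expect_gt(si$value, 1.9)
  # constant response: guarded to zero bits
  si0 <- sensory_information(matrix(1, 8, 400), scene, type = "slow")
  expect_equal(si0$value, 0)
  expect_error(sensory_information(matrix(1, 1, 400), scene), "2 trials")
})

test_that("period-scene labels tile time with one-period scenes", {
  lab <- period_scenes(1000, 1000, 65)
  expect_equal(lab[1], 1L)
  expect_equal(max(diff(lab)), 1L)
  runs <- rle(lab)$lengths
  expect_true(all(runs %in% c(15L, 16L)))   # 1000/65 = 15.38 samples
})
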