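test_that("phase shift follows the sender-leads sign convention", {
  expect_equal(phase_shift(30 * pi / 180, 0), 30 * pi / 180)
  expect_equal(phase_shift(170 * pi / 180, -170 * pi / 180),
               -20 * pi / 180, tolerance = 1e-12)
  expect_equal(phase_shift(1.2, 1.2), 0)
  # antisymmetry at every sample
  set.seed(1)
  a <- runif(500, -pi, pi); b <- runif(500, -pi, pi)
  expect_equal(wrap_phase(phase_shift(a, b) + phase_shift(b, a)),
               rep(0, 500), tolerance = 1e-12)
})

test_that("asymmetry index arithmetic", {
  expect_equal(asymmetry_index(5, 5), 0)
  expect_equal(asymmetry_index(5, 0), 1)
  expect_equal(asymmetry_index(8, 4), 0.5)
  expect_equal(asymmetry_index(8, -2), 1)   # clipped at zero
  expect_true(is.na(asymmetry_index(-1, -3)))
})

test_that("pair classification implements the exclusion and threshold rules", {
  pairs <- data.frame(
    a = 1:6, b = 7:12,
    te_ab = c(10, 6,   9, 8, 0.05, 7),
    te_ba = c(0.5, 5.5, 9, 2, 0.02, 7.1))
  cls <- classify_pairs(pairs)
  expect_equal(cls$category[5], "excluded_low_TE")   # lowest 20% (1 of 6)
  expect_equal(cls$category[1], "strongly_asymmetric")  # ratio 20 >= 10
  expect_equal(cls$leading[1], "ab")
  expect_equal(cls$category[2], "symmetric")            # rel diff 8.3% < 20%
  expect_equal(cls$category[3], "symmetric")
  expect_equal(cls$category[6], "symmetric")
  expect_equal(cls$category[4], "other")                # ratio 4, diff 75%
  # identical TE everywhere: all surviving pairs symmetric
  eq <- data.frame(a = 1:5, b = 6:10, te_ab = rep(4, 5), te_ba = rep(4, 5))
  cls_eq <- classify_pairs(eq)
  kept <- cls_eq$category != "excluded_low_TE"
  expect_true(all(cls_eq$category[kept] == "symmetric"))
  expect_warning(classify_pairs(pairs[1:3, ]), "fewer than 5")
  # invariant to relabeling of pair order
  swapped <- pairs
  swapped$te_ab <- pairs$te_ba; swapped$te_ba <- pairs$te_ab
  cls_sw <- classify_pairs(swapped)
  expect_equal(cls_sw$category, cls$category)
})

test_that("shift-causation correlation behaves on planted relations", {
  set.seed(2)
  te <- runif(20, 0, 10)
  expect_equal(correlate_shift_causation(0.1 * te + 0.2, te)$rho, 1)
  rhos <- replicate(200, correlate_shift_causation(sample(te), te)$rho)
  expect_lt(abs(mean(rhos)), 0.1)
  expect_error(correlate_shift_causation(rep(1, 20), te), "ties-only|degenerate")
  expect_error(correlate_shift_causation(te[1:5], te[1:5]), "at least 10")
})

test_that("block segmentation uses majority vote with tie breaks", {
  fs <- 1000
  allpos <- matrix(0.5, 3, 1200)
  seg <- segment_blocks(allpos, fs, min_ms = 300)
  expect_equal(nrow(seg$blocks), 1L)
  expect_equal(seg$blocks$start, 1L)
  expect_equal(seg$blocks$end, 1200L)
  # alternating 100 ms runs never reach 300 ms
  alt <- matrix(rep(rep(c(0.5, -0.5), each = 100), 6), 3, 1200, byrow = TRUE)
  expect_equal(nrow(segment_blocks(alt, fs, 300)$blocks), 0L)
  # majority bookkeeping: trials vote (+,+,-) then (-,-,+)
  m <- rbind(c(rep(0.3, 400), rep(-0.3, 600)),
             c(rep(0.3, 400), rep(-0.3, 600)),
             c(rep(-0.3, 400), rep(0.3, 600)))
  seg2 <- segment_blocks(m, fs, 300)
  expect_equal(seg2$blocks$sign, c(1L, -1L))
  expect_equal(seg2$blocks$start, c(1L, 401L))
  expect_equal(seg2$blocks$end, c(400L, 1000L))
  # exact ties leave samples unlabeled
  tie <- matrix(c(0.5, -0.5, 0.5, -0.5), 4, 1000)
  expect_true(all(segment_blocks(tie, fs)$label == 0L))
  expect_error(segment_blocks(matrix(1, 2, 100), fs), "3 trials")
})

test_that("block-conditioned TE balances condition durations within 10%", {
  set.seed(3)
  lab <- rep(rep(c(0.4, -0.4), times = c(400, 320)), 5)
  sh <- matrix(rep(lab, 3), 3, length(lab), byrow = TRUE)
  seg <- segment_blocks(sh, 1000, 300)
  x <- matrix(rnorm(3 * length(lab)), 3)
  y <- matrix(runif(3 * length(lab), -pi, pi), 3)
  bt <- block_conditioned_te(x, y, seg, fs_hz = 1000, seed = 4)
  expect_lte(abs(bt$durations["pos"] - bt$durations["neg"]) /
               max(bt$durations), 0.1)
})

test_that("projected distance applies the cone rule and sign convention", {
  pos <- rbind(c(0, 0), c(2, 0), c(0, 2), c(4, 0))
  # reference pair 1 -> 2 along +x
  expect_equal(projected_distance(pos, 1, 2, 2)$distance_mm, 0)
  pd_s <- projected_distance(pos, 1, 2, 1)
  expect_true(pd_s$included)
  expect_equal(pd_s$distance_mm, -2)
  # electrode at 90 degrees off the axis at the receiver: excluded at 45
  pos2 <- rbind(pos, c(2, 2))
  expect_false(projected_distance(pos2, 1, 2, 5)$included)
  # lateral electrode whose displacement to the receiver is at exactly 45
  # degrees stays inside the cone
  expect_true(projected_distance(pos, 1, 2, 3)$included)
  # electrode beyond the receiver (displacement antiparallel): excluded
  expect_false(projected_distance(pos, 1, 2, 4)$included)
  expect_error(projected_distance(pos, 1, 1, 2), "zero-length")
})

test_that("wave speed arithmetic and degenerate cases", {
  d <- seq(-6, 0, by = 0.5)
  prof <- data.frame(ref = 1, electrode = seq_along(d), distance_mm = d,
                     shift = -1.134 * d)
  ws <- wave_speed(prof, f_hz = 65)
  expect_equal(ws$speed_m_per_s, 2 * pi * 65 / 1134, tolerance = 0.01)
  expect_equal(ws$speed_m_per_s, 0.36, tolerance = 0.01)
  flat <- data.frame(ref = 1, electrode = seq_along(d), distance_mm = d,
                     shift = rep(0, length(d)))
  expect_true(wave_speed(flat, 65)$infinite)
  expect_error(wave_speed(prof[1:3, ], 65), "4 distinct")
})

test_that("speed recovery is invariant to a global phase constant", {
  cfg <- synth_config(n_rows = 4, n_cols = 4, spacing_mm = 2,
                      phase_noise_sd = 0.2, n_trials = 4, n_scenes = 6,
                      seed = 6)
  ss <- generate_session(cfg)
  refs <- data.frame(sender = c(1, 2, 3), receiver = c(2, 3, 4))
  prof1 <- wave_profile(ss$phase, ss$positions, refs)
  prof2 <- wave_profile(wrap_phase(ss$phase + 1.1), ss$positions, refs)
  v1 <- wave_speed(prof1, 65)$speed_m_per_s
  v2 <- wave_speed(prof2, 65)$speed_m_per_s
  expect_equal(v1, v2, tolerance = 1e-6)
  expect_equal(v1, 0.36, tolerance = 0.05)
})

test_that("noiseless planted wave yields the planted spline slope at origin", {
  cfg <- synth_config(n_rows = 4, n_cols = 4, spacing_mm = 2,
                      phase_noise_sd = 0, phase_drift_sd = 0,
                      trial_phase_offset = FALSE, n_trials = 2, n_scenes = 4,
                      seed = 7)
  ss <- generate_session(cfg)
  refs <- data.frame(sender = c(1, 2, 3, 5, 6, 7),
                     receiver = c(2, 3, 4, 6, 7, 8))
  prof <- wave_profile(ss$phase, ss$positions, refs)
  ws <- wave_speed(prof, 65)
  k_mm <- 2 * pi * 65 / 0.36 / 1000
  expect_equal(abs(ws$slope_rad_per_mm), k_mm, tolerance = 0.05 * k_mm)
})

test_that("the origin re-anchors to the true final target of the wave", {
  # reference pair A points against the true propagation: its included
  # upstream electrode 1 — the receiver of reference pair B — achieves the
  # minimum shift and must become the origin of A's profile
  positions <- rbind(c(0, 0), c(1, 0), c(2, 0))
  phase <- array(0, c(2, 3, 50))
  phase[, 1, ] <- 0
  phase[, 2, ] <- 0.5
  phase[, 3, ] <- 1.0
  refs <- data.frame(sender = c(1, 2), receiver = c(2, 1))
  prof <- wave_profile(phase, positions, refs)
  pA <- prof[prof$ref == 1, ]
  expect_equal(pA$distance_mm[pA$electrode == 1], 0)
  expect_equal(pA$shift[pA$electrode == 1], 0, tolerance = 1e-9)
  expect_equal(pA$distance_mm[pA$electrode == 2], 1)
  expect_equal(pA$shift[pA$electrode == 2], 0.5, tolerance = 1e-9)
  # pair B's own receiver already has the minimum shift: no re-anchoring
  pB <- prof[prof$ref == 2, ]
  expect_equal(pB$distance_mm[pB$electrode == 1], 0)
  expect_equal(pB$shift[pB$electrode == 2], 0.5, tolerance = 1e-9)
})
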