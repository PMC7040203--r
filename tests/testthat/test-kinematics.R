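test_that("velocity_norm recovers stationary and uniform motion exactly", {
  n <- 50
  still <- make_traj(matrix(5, n, 3))
  expect_equal(velocity_norm(still), rep(0, n))

  # 1 mm per frame at 100 Hz along x -> 100 mm/s everywhere (linear motion,
  # central and one-sided differences are exact)
  pos <- cbind(seq_len(n) * 1.0, numeric(n), numeric(n))
  expect_equal(velocity_norm(make_traj(pos)), rep(100, n))

  expect_error(velocity_norm(make_traj(matrix(0, 2, 3))), "insufficient")
})

test_that("discrete peak speed of a minimum-jerk reach matches 1.875 D/T within 1%", {
  D <- 400; T_ms <- 1000; n <- 101
  tau <- seq(0, 1, length.out = n)
  pos <- cbind(D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5), numeric(n),
               numeric(n))
  speed <- velocity_norm(make_traj(pos))
  expect_lt(abs(max(speed) - mj_peak_mms(D, T_ms)) / mj_peak_mms(D, T_ms),
            0.01)
})

test_that("optional low-pass smoothing attenuates high-frequency noise", {
  set.seed(1)
  n <- 200
  pos <- cbind(seq_len(n) * 2.0 + rnorm(n, 0, 0.5), numeric(n), numeric(n))
  raw <- velocity_norm(make_traj(pos))
  smooth <- velocity_norm(make_traj(pos),
                          segmentation_config(smoothing = 10))
  expect_lt(stats::sd(smooth[10:190]), stats::sd(raw[10:190]))
})

test_that("segment_movements applies the threshold/min-run criterion", {
  cfg <- segmentation_config()
  expect_equal(nrow(segment_movements(rep(0, 100), cfg)), 0)

  sp <- c(rep(0, 20), rep(100, 50), rep(0, 30))
  segs <- segment_movements(sp, cfg)
  expect_equal(segs$onset, 21L)
  expect_equal(segs$offset, 71L)

  # a 9-sample burst does not qualify (minimum of 10 successive samples)
  sp9 <- c(rep(0, 20), rep(100, 9), rep(0, 30))
  expect_equal(nrow(segment_movements(sp9, cfg)), 0)

  expect_error(segment_movements(numeric(0), cfg), "empty")
  expect_error(segment_movements(c(1, NA, 3), cfg), "finite")

  # still above threshold at the end: discarded with a warning
  expect_warning(
    out <- segment_movements(c(rep(0, 20), rep(100, 30)), cfg),
    "discarded")
  expect_equal(nrow(out), 0)
})

test_that("segmentation equals the brute-force run-length oracle on random series", {
  set.seed(2024)
  cfg <- segmentation_config(velocity_threshold = 30, min_run = 10)
  for (i in 1:200) {
    n <- sample(30:300, 1)
    # block-structured speeds so qualifying runs actually occur
    speed <- abs(rep(rnorm(ceiling(n / 8), 30, 25), each = 8)[1:n] +
                   rnorm(n, 0, 5))
    segs <- suppressWarnings(segment_movements(speed, cfg))
    oracle <- brute_force_segments(speed, 30, 10)
    expect_equal(segs$onset, oracle$onset)
    expect_equal(segs$offset, oracle$offset)
  }
})

test_that("segmentation is idempotent under sub-threshold padding", {
  cfg <- segmentation_config()
  sp <- c(rep(0, 15), rep(80, 40), rep(0, 15))
  base <- segment_movements(sp, cfg)
  padded <- segment_movements(c(rep(5, 25), sp, rep(5, 25)), cfg)
  expect_equal(padded$onset, base$onset + 25L)
  expect_equal(padded$offset, base$offset + 25L)
})

test_that("label_segments classifies reach/transport/other geometrically", {
  sim <- prehensr::simulate_trial(simulation_config(marker_noise_sd = 0),
                                  adjustment_ms = 900, transport_peak = 800,
                                  mga_mm = 120, mga_rel = 65,
                                  grip_deviation = 5, cup = cup_spec())
  tr <- sim$trial
  gc <- grip_center(tr)
  speed <- velocity_norm(gc)
  speed[!is.finite(speed)] <- 0
  segs <- segment_movements(speed)
  labs <- label_segments(segs, tr)
  expect_equal(labs$label, c("reach", "transport", "other"))

  # manual overrides win regardless of geometry
  forced <- label_segments(segs, tr,
                           manual = c("reach", "other", "transport"))
  expect_equal(forced$label, c("reach", "other", "transport"))

  # a trial whose only movement ends far from location A has no reach
  only_return <- segs[3, ]
  expect_error(label_segments(only_return, tr), "labeling error")
})

test_that("temporal features satisfy exact arithmetic identities", {
  cfg <- segmentation_config()
  sp <- c(rep(0, 20), seq(40, 400, length.out = 30),
          seq(390, 31, length.out = 60), rep(0, 30))
  segs <- segment_movements(sp, cfg)
  segs$label <- "reach"
  tf <- temporal_features(segs, sp, 100)
  expect_equal(tf$adjustment_time + tf$peak_ms, tf$duration)
  expect_equal(tf$peak_velocity, max(sp))
  # peak at 300 ms into the reach, end at 1100 ms -> adjustment 800 ms
  expect_equal(tf$peak_ms, (tf$peak_idx - tf$onset) * 10)

  # ties in peak velocity resolve to the earliest sample
  sp2 <- c(rep(0, 15), rep(100, 12), 250, 80, 250, rep(100, 12), rep(0, 15))
  segs2 <- segment_movements(sp2, cfg)
  segs2$label <- "reach"
  tf2 <- temporal_features(segs2, sp2, 100)
  expect_equal(tf2$peak_idx, 28L)  # first of the two equal maxima
})
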