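test_that("same seed reproduces trajectories exactly; different seeds differ", {
  a <- simulate_reach(noise_sd = 0.3, dropout_rate = 0.01, seed = 7)
  b <- simulate_reach(noise_sd = 0.3, dropout_rate = 0.01, seed = 7)
  expect_identical(a$trial$trajectories$thumb$positions,
                   b$trial$trajectories$thumb$positions)
  expect_identical(a$trial$trajectories$index$valid,
                   b$trial$trajectories$index$valid)
  c_ <- simulate_reach(noise_sd = 0.3, seed = 8)
  expect_false(identical(a$trial$trajectories$thumb$positions,
                         c_$trial$trajectories$thumb$positions))
})

test_that("symmetric two-piece profile: peak at closed form, adjustment = half the span", {
  sim <- simulate_reach(amplitude = 400, duration = 1000,
                        decel_fraction = 0.5, noise_sd = 0, seed = 1)
  speed <- velocity_norm(grip_center(sim$trial))
  segs <- segment_movements(speed)
  tf <- temporal_features(label_segments(segs, sim$trial), speed, 100)
  reach <- tf[tf$label == "reach", ]
  expect_lt(abs(reach$peak_velocity - 750) / 750, 0.01)
  expect_lte(abs(reach$adjustment_time - reach$duration / 2), 10)
  # generated speed never exceeds the two-piece peak
  expect_lte(max(speed), 750 * 1.001)
  # terminal reach speed sits below the threshold so segmentation terminates
  expect_lt(speed[reach$offset], 30)
})

test_that("asymmetric deceleration fraction shifts the measured adjustment time", {
  sim65 <- simulate_reach(duration = 1500, decel_fraction = 0.65,
                          noise_sd = 0, seed = 2)
  speed <- velocity_norm(grip_center(sim65$trial))
  tf <- temporal_features(label_segments(segment_movements(speed),
                                         sim65$trial), speed, 100)
  reach <- tf[tf$label == "reach", ]
  # measured adjustment tracks the analytic threshold-crossing ground truth
  expect_lte(abs(reach$adjustment_time - sim65$truth$true_adjustment), 20)
  expect_gt(reach$adjustment_time, reach$duration / 2)
})

test_that("noise-free trials reproduce every configured feature", {
  cfg <- simulation_config(marker_noise_sd = 0)
  sim <- simulate_trial(cfg, adjustment_ms = 1024, transport_peak = 657.46,
                        mga_mm = 119.61, mga_rel = 61.67,
                        grip_deviation = -8.285, cup = cup_spec_filled(),
                        condition = list(surface = "matte",
                                         content = "filled",
                                         feedback = "visible"))
  res <- analyze_trial(sim$trial)
  f <- res$features
  expect_lte(abs(f$adjustment_time - 1024), 20)           # 2 frames
  expect_lt(abs(f$transport_peak_velocity - 657.46) / 657.46, 0.01)
  expect_lt(abs(f$mga - 119.61), 0.01)
  expect_lte(abs(f$mga_time_rel - 61.67), 1)
  expect_lt(abs(f$grip_deviation - (-8.285)), 0.5)
  expect_equal(f$com, cup_com(cup_spec_filled()))
})

test_that("dataset generator honours the design size and substream determinism", {
  cfg <- simulation_config(n_participants = 2, n_blocks = 2, seed = 5)
  ds1 <- simulate_dataset(cfg)
  expect_length(ds1$trials, 2 * 2 * 8)
  expect_equal(nrow(ds1$truth), 32)
  expect_equal(sort(unique(ds1$truth$content)), c("empty", "filled"))
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$trials[[17]]$trajectories$thumb$positions,
                   ds2$trials[[17]]$trajectories$thumb$positions)
})

test_that("zero-effect dataset gives exchangeable condition means", {
  cfg <- simulation_config(
    n_participants = 3, n_blocks = 1,
    adjustment_target = c(empty = 950, filled = 950),
    transport_peak_target = c(empty = 745, filled = 745),
    mga_rel_target = c(empty = 64, filled = 64),
    grip_deviation_target = c(empty = 0, filled = 0),
    subject_sd = c(adjustment = 0, transport_peak = 0, mga_rel = 0,
                   grip_deviation = 0, mga = 0),
    trial_sd = c(adjustment = 0, transport_peak = 0, mga_rel = 0,
                 grip_deviation = 0, mga = 0),
    marker_noise_sd = 0.15, seed = 9)
  f <- extract_features(simulate_dataset(cfg)$trials)$features
  by_content <- tapply(f$adjustment_time, f$content, mean)
  expect_lte(abs(diff(by_content)), 15)
  by_content_tp <- tapply(f$transport_peak_velocity, f$content, mean)
  expect_lte(abs(diff(by_content_tp)) / mean(by_content_tp), 0.02)
})

test_that("dropouts come in contiguous runs and long gaps exclude trials", {
  cfg <- simulation_config(n_participants = 1, n_blocks = 1,
                           dropout_rate = 0.01, dropout_mean_run = 8,
                           seed = 3)
  ds <- simulate_dataset(cfg)
  any_invalid <- vapply(ds$trials, function(tr) {
    any(!tr$trajectories$thumb$valid)
  }, logical(1))
  expect_true(any(any_invalid))
  ex <- extract_features(ds$trials)
  expect_true(all(ex$dispositions$status %in% c("analyzed", "excluded")))
  if (any(ex$dispositions$status == "excluded")) {
    expect_match(paste(ex$dispositions$reason, collapse = " "),
                 "gap|unusable|labeling")
  }
})

test_that("ratings generator: determinism, null symmetry, strong surface effect", {
  r1 <- simulate_ratings(seed = 11)
  r2 <- simulate_ratings(seed = 11)
  expect_identical(r1$value, r2$value)
  expect_s3_class(r1, "rating_records")

  null <- simulate_ratings(n_participants = 60, effects = c(content = 0),
                           subject_sd = 0, seed = 12)
  expect_lt(abs(mean(null$value) - 4), 0.15)

  gl <- simulate_ratings(n_participants = 30, dimension = "glossiness",
                         seed = 13)
  gap <- mean(gl$value[gl$surface == "shiny"]) -
    mean(gl$value[gl$surface == "matte"])
  expect_gt(gap, 2)

  expect_error(simulate_ratings(thresholds = c(1, 2, 3, 3, 4, 5)),
               "config error")
})

test_that("feature-table fast path injects effects with subject structure", {
  null <- simulate_feature_table(n_participants = 20, n_blocks = 2, seed = 21)
  eff <- simulate_feature_table(n_participants = 20, n_blocks = 2,
                                content_effects = c(adjustment_time = 143),
                                seed = 21)
  d_null <- diff(tapply(null$adjustment_time, null$content, mean))
  d_eff <- diff(tapply(eff$adjustment_time, eff$content, mean))
  expect_lt(abs(d_null), 30)
  expect_equal(unname(d_eff - d_null), 143, tolerance = 1e-8)
  # subject intercepts induce within-subject correlation
  m <- stats::aggregate(adjustment_time ~ participant, null, mean)
  expect_gt(stats::sd(m$adjustment_time), 25)
})
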