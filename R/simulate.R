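# Synthetic reach-and-transport generator.
#
# The grip-centre path of each movement is a two-piece minimum-jerk profile:
# an accelerating half-profile of duration ta and a decelerating half-profile
# of duration td, joined at the common velocity peak so speed is continuous.
# For such a path the peak speed is always 1.875 * D / (ta + td) regardless
# of the asymmetry, and the deceleration piece occupies td of the total
# duration, which makes condition effects on the adjustment time directly
# injectable by stretching td.

# Minimum-jerk position easing (0 -> 1) and normalised speed shape (peak 1).
mj_pos <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
mj_shape <- function(tau) 16 * tau^2 * (1 - tau)^2

# Path length (mm) at time t (ms) into a two-piece minimum-jerk movement of
# amplitude D with accel/decel piece durations ta/td (ms). Vectorised over t.
two_piece_s <- function(t, ta, td, D) {
  T <- ta + td
  s <- numeric(length(t))
  a <- t <= ta
  s[a] <- (2 * D * ta / T) * mj_pos(pmin(pmax(t[a], 0), ta) / (2 * ta))
  s[!a] <- D * ta / T + (2 * D * td / T) *
    (mj_pos(0.5 + (pmin(t[!a], T) - ta) / (2 * td)) - 0.5)
  s
}

# Peak speed in mm/s of a two-piece minimum-jerk movement (D mm, times ms).
two_piece_peak <- function(ta, td, D) 1875 * D / (ta + td)

# Times (ms from movement start) at which the speed of a two-piece
# minimum-jerk movement crosses `threshold` (mm/s): the speed is
# vp * 16 tau^2 (1-tau)^2 within each half-profile, so the crossing solves
# 4 tau (1 - tau) = sqrt(r) with r = threshold / vp.
threshold_crossings <- function(ta, td, D, threshold) {
  vp <- two_piece_peak(ta, td, D)
  r <- threshold / vp
  if (any(r >= 1)) {
    stop("config error: peak speed does not exceed the segmentation threshold",
         call. = FALSE)
  }
  q <- sqrt(1 - sqrt(r))
  list(onset = ta * (1 - q),       # rising crossing
       offset = ta + td * q,       # falling crossing
       adjustment = td * q,        # falling crossing minus peak time (ta)
       peak = ta, peak_velocity = vp)
}

# Solve the decel duration td so that the *measured* adjustment time (peak to
# falling threshold crossing) equals `adjustment` ms. Fixed point on
# td = A / sqrt(1 - sqrt(thr (ta + td) / (1875 D))); contraction is strong
# because the crossing factor depends on td only through the peak speed.
calibrate_decel <- function(adjustment, ta, D, threshold) {
  td <- adjustment
  for (i in 1:40) {
    vp <- two_piece_peak(ta, td, D)
    td_new <- adjustment / sqrt(1 - sqrt(threshold / vp))
    if (max(abs(td_new - td)) < 1e-9) { td <- td_new; break }
    td <- td_new
  }
  td
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Piecewise scalar profile: value `v0` outside the pieces, raised-cosine
# eased between (t0, a0) and (t1, a1) per piece, constant between pieces.
# The raised cosine is C1 at the joins like the minimum-jerk easing, but its
# extremum is locally quadratic rather than cubically flat, which keeps the
# argmax of the aperture profile identifiable under measurement noise.
ease_profile <- function(times, v0, pieces) {
  out <- rep(v0, length(times))
  for (p in pieces) {
    out[times >= p$t0] <- p$a1
    ramp <- times >= p$t0 & times < p$t1
    tau <- (times[ramp] - p$t0) / (p$t1 - p$t0)
    out[ramp] <- p$a0 + (p$a1 - p$a0) * (1 - cos(pi * tau)) / 2
  }
  out
}

#' Simulate one reach movement
#'
#' Generates fingertip trajectories (thumb, index, middle) for a single reach
#' whose grip-centre path is a two-piece minimum-jerk profile of total
#' `duration` with the deceleration piece occupying `decel_fraction` of it.
#' The grip aperture rises from `aperture_rest` to `mga` (peaking at
#' `mga_rel_time` % of the *measured* movement span under the segmentation
#' threshold) and closes to `aperture_contact` by the end of the reach.
#' Gaussian marker noise and contiguous dropout runs are applied last.
#'
#' @param amplitude Reach amplitude D in mm (straight-line path).
#' @param duration Total movement duration in ms.
#' @param decel_fraction Fraction of `duration` after the velocity peak
#'   (0 < f < 1).
#' @param origin,direction Path origin (mm) and direction (any length-3
#'   vector, normalised internally).
#' @param sample_rate Sampling rate in Hz.
#' @param mga,mga_rel_time,aperture_rest,aperture_contact Aperture profile
#'   parameters (mm, % of measured reach span, mm, mm).
#' @param noise_sd Gaussian marker noise SD per coordinate (mm).
#' @param dropout_rate Per-sample probability that a dropout run starts.
#' @param dropout_mean_run Mean length of a dropout run (geometric).
#' @param pre_ms,post_ms Stationary padding before and after the movement.
#' @param threshold Segmentation threshold (mm/s) used to anchor the aperture
#'   peak to the measured movement span.
#' @param seed Integer seed; the same seed reproduces the trial exactly.
#' @param participant_id,block,condition Trial metadata passed through.
#' @param landmarks Landmarks for the returned trial; defaults to placing
#'   location A at the movement endpoint.
#' @return List with `trial` (a [trial()]) and `truth` (one-row tibble of
#'   ground-truth quantities: true onset/offset/peak times in ms from
#'   movement start, expected measured adjustment time, peak velocity, MGA
#'   and its timing).
#' @export
simulate_reach <- function(amplitude = 400, duration = 1000,
                           decel_fraction = 0.5,
                           origin = c(0, 0, 20), direction = c(1, 0, 0),
                           sample_rate = 100,
                           mga = 119.61, mga_rel_time = 65,
                           aperture_rest = 40, aperture_contact = 70,
                           noise_sd = 0, dropout_rate = 0,
                           dropout_mean_run = 3,
                           pre_ms = 300, post_ms = 300, threshold = 30,
                           seed = 1L, participant_id = "P01", block = 1L,
                           condition = list(surface = "matte",
                                            content = "empty",
                                            feedback = "visible"),
                           landmarks = NULL) {
  if (decel_fraction <= 0 || decel_fraction >= 1) {
    stop("config error: decel_fraction must lie in (0, 1)", call. = FALSE)
  }
  ta <- duration * (1 - decel_fraction)
  td <- duration * decel_fraction
  u <- unit3(direction)
  endpoint <- origin + amplitude * u
  if (is.null(landmarks)) {
    landmarks <- list(start = c(origin[1], origin[2], 0),
                      A = c(endpoint[1], endpoint[2], 0),
                      B = c(endpoint[1], endpoint[2] + 400, 0))
  }
  cross <- threshold_crossings(ta, td, amplitude, threshold)
  period <- 1000 / sample_rate
  total <- pre_ms + duration + post_ms
  times <- seq(0, total, by = period)
  tmove <- times - pre_ms
  s <- numeric(length(times))
  inmove <- tmove > 0 & tmove < duration
  s[inmove] <- two_piece_s(tmove[inmove], ta, td, amplitude)
  s[tmove >= duration] <- amplitude
  centre <- outer(s, u) + matrix(origin, length(times), 3, byrow = TRUE)

  t_on <- pre_ms + cross$onset
  t_off <- pre_ms + cross$offset
  t_mga <- t_on + (mga_rel_time / 100) * (t_off - t_on)
  aperture <- ease_profile(times, aperture_rest, list(
    list(t0 = pre_ms, t1 = t_mga, a0 = aperture_rest, a1 = mga),
    list(t0 = t_mga, t1 = pre_ms + duration, a0 = mga, a1 = aperture_contact)
  ))
  trial <- assemble_fingers(centre, aperture, u, times, sample_rate,
                            noise_sd, dropout_rate, dropout_mean_run, seed,
                            participant_id, block, condition, landmarks)
  truth <- tibble::tibble(
    true_onset_ms = cross$onset, true_offset_ms = cross$offset,
    true_peak_ms = cross$peak, true_adjustment = cross$adjustment,
    true_peak_velocity = cross$peak_velocity,
    true_mga = mga, true_mga_rel = mga_rel_time
  )
  list(trial = trial, truth = truth)
}

# Place thumb/index half an aperture either side of the grip centre along a
# horizontal transverse axis, the middle fingertip 15 mm ahead along the
# path; add noise, then dropouts, then wrap into a trial.
assemble_fingers <- function(centre, aperture, u, times, sample_rate,
                             noise_sd, dropout_rate, dropout_mean_run, seed,
                             participant_id, block, condition, landmarks) {
  w <- unit3(c(-u[2], u[1], 0))
  if (!all(is.finite(w))) w <- c(0, 1, 0)
  ah <- unit3(c(u[1], u[2], 0))          # horizontal: no leak into grip z
  if (!all(is.finite(ah))) ah <- c(1, 0, 0)
  n <- nrow(centre)
  off <- outer(aperture / 2, w)
  ahead <- matrix(15 * ah, n, 3, byrow = TRUE)
  fingers <- list(thumb = centre + off, index = centre - off,
                  middle = centre + ahead)
  set.seed(seed)
  trajs <- vector("list", length(fingers))
  names(trajs) <- names(fingers)
  for (nm in names(fingers)) {
    pos <- fingers[[nm]]
    if (noise_sd > 0) pos <- pos + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
    valid <- rep(TRUE, n)
    if (dropout_rate > 0) {
      starts <- which(stats::runif(n) < dropout_rate)
      for (st in starts) {
        len <- 1L + stats::rgeom(1L, 1 / dropout_mean_run)
        valid[st:min(n, st + len - 1L)] <- FALSE
      }
      pos[!valid, ] <- NA_real_
    }
    colnames(pos) <- c("x", "y", "z")
    trajs[[nm]] <- new_marker_trajectory(pos, sample_rate = sample_rate,
                                         valid = valid, times = times,
                                         marker_id = nm)
  }
  trial(trajs, participant_id = participant_id, block = block,
        condition = condition, landmarks = landmarks)
}

#' Full factorial condition grid
#'
#' The 2 x 2 x 2 design: surface (matte/shiny) x content (empty/filled) x
#' feedback (visible/hidden); eight stimuli per block.
#'
#' @return Tibble with columns `surface`, `content`, `feedback` and
#'   `stimulus` (1-8).
#' @export
condition_grid <- function() {
  g <- tidyr::expand_grid(surface = c("matte", "shiny"),
                          content = c("empty", "filled"),
                          feedback = c("visible", "hidden"))
  dplyr::mutate(g, stimulus = dplyr::row_number())
}

#' Simulation configuration
#'
#' Defines the generating conditions for a synthetic dataset: the design
#' size, the per-condition kinematic targets, subject- and trial-level
#' variability, and measurement noise. All condition targets are expressed as
#' the *measured* quantities under the segmentation criterion (30 mm/s over
#' 10 samples); the generator inverts the threshold-crossing geometry so the
#' expected measured value equals the target. Defaults reproduce the study
#' conditions: adjustment times 881/1024 ms and transport peaks
#' 834.01/657.46 mm/s for empty/filled cups, MGA 119.61 mm peaking at
#' 66.78%/61.67% of the reach, and grip deviations of +-8.285 mm about the
#' respective cup COM (a content effect of -16.57 mm).
#'
#' @param n_participants,n_blocks Design size (default 14 x 5; with the
#'   eight-cell condition grid this gives 560 trials).
#' @param sample_rate Hz.
#' @param reach_amplitude,transport_amplitude Horizontal start-to-A and
#'   A-to-B distances (mm).
#' @param adjustment_target Named vector (`empty`, `filled`): measured reach
#'   adjustment time targets in ms.
#' @param reach_accel_ms Duration of the accelerating reach piece (ms).
#' @param transport_peak_target Named vector: transport peak velocity targets
#'   (mm/s).
#' @param transport_decel_fraction Decel fraction of the transport movement.
#' @param mga_mm Mean maximum grip aperture (mm).
#' @param mga_rel_target Named vector: MGA timing as % of measured reach span.
#' @param grip_deviation_target Named vector: signed grip deviation from the
#'   cup COM (mm).
#' @param surface_effects,feedback_effects Optional named vectors
#'   (`adjustment`, `transport_peak`, `mga_rel`, `grip_deviation`) of
#'   additive shifts applied for shiny surface / hidden feedback; default all
#'   zero (the content factor carries the effects, as in the study).
#' @param subject_sd,trial_sd Named vectors (`adjustment`, `transport_peak`,
#'   `mga_rel`, `grip_deviation`, `mga`) of between-subject and within-subject
#'   SDs on the targets.
#' @param marker_noise_sd Gaussian marker noise per coordinate (mm).
#' @param dropout_rate,dropout_mean_run Contiguous dropout model (default off).
#' @param z_rest Resting fingertip height above the table (mm).
#' @param aperture_rest,aperture_contact Aperture at rest / at contact (mm).
#' @param velocity_threshold,min_run Segmentation criterion the targets are
#'   calibrated against.
#' @param pre_ms,hold_ms,return_ms,post_ms Trial padding and hold durations.
#' @param seed Integer master seed; per-trial substreams are derived by
#'   counter, so the full dataset is byte-reproducible.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_participants = 14, n_blocks = 5,
                              sample_rate = 100,
                              reach_amplitude = 400, transport_amplitude = 400,
                              adjustment_target = c(empty = 881, filled = 1024),
                              reach_accel_ms = 500,
                              transport_peak_target = c(empty = 834.01,
                                                        filled = 657.46),
                              transport_decel_fraction = 0.5,
                              mga_mm = 119.61,
                              mga_rel_target = c(empty = 66.78, filled = 61.67),
                              grip_deviation_target = c(empty = 8.285,
                                                        filled = -8.285),
                              surface_effects = NULL, feedback_effects = NULL,
                              subject_sd = c(adjustment = 100,
                                             transport_peak = 60,
                                             mga_rel = 4, grip_deviation = 3,
                                             mga = 9),
                              trial_sd = c(adjustment = 120,
                                           transport_peak = 90,
                                           mga_rel = 5, grip_deviation = 4,
                                           mga = 9),
                              marker_noise_sd = 0.15,
                              dropout_rate = 0, dropout_mean_run = 3,
                              z_rest = 20,
                              aperture_rest = 40, aperture_contact = 70,
                              velocity_threshold = 30, min_run = 10,
                              pre_ms = 300, hold_ms = 350, return_ms = 800,
                              post_ms = 300, seed = 1L) {
  zero <- c(adjustment = 0, transport_peak = 0, mga_rel = 0,
            grip_deviation = 0)
  fill_effects <- function(x) {
    out <- zero
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_blocks = as.integer(n_blocks), sample_rate = sample_rate,
    reach_amplitude = reach_amplitude,
    transport_amplitude = transport_amplitude,
    adjustment_target = adjustment_target, reach_accel_ms = reach_accel_ms,
    transport_peak_target = transport_peak_target,
    transport_decel_fraction = transport_decel_fraction,
    mga_mm = mga_mm, mga_rel_target = mga_rel_target,
    grip_deviation_target = grip_deviation_target,
    surface_effects = fill_effects(surface_effects),
    feedback_effects = fill_effects(feedback_effects),
    subject_sd = subject_sd, trial_sd = trial_sd,
    marker_noise_sd = marker_noise_sd,
    dropout_rate = dropout_rate, dropout_mean_run = dropout_mean_run,
    z_rest = z_rest, aperture_rest = aperture_rest,
    aperture_contact = aperture_contact,
    velocity_threshold = velocity_threshold, min_run = as.integer(min_run),
    pre_ms = pre_ms, hold_ms = hold_ms, return_ms = return_ms,
    post_ms = post_ms, seed = as.integer(seed)
  )
  if (cfg$transport_decel_fraction <= 0 || cfg$transport_decel_fraction >= 1) {
    stop("transport_decel_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (any(c(cfg$subject_sd, cfg$trial_sd) < 0)) {
    stop("all SD terms must be >= 0", call. = FALSE)
  }
  for (nm in c("adjustment_target", "transport_peak_target",
               "mga_rel_target", "grip_deviation_target")) {
    if (!all(c("empty", "filled") %in% names(cfg[[nm]]))) {
      stop(nm, " must be a named vector with 'empty' and 'filled'",
           call. = FALSE)
    }
  }
  if (any(cfg$mga_rel_target <= 0 | cfg$mga_rel_target >= 100)) {
    stop("mga_rel_target must lie in (0, 100)", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Per-trial substream seed: deterministic in (master seed, trial counter),
# kept below 2^31.
trial_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 69621) %% 2147483647)
}

#' Simulate one full reach-and-transport trial
#'
#' Composes rest, reach (to the stimulus at location A), hold, transport (to
#' location B), hold, and return-to-start movements into one trial, with the
#' aperture profile and measurement noise of [simulate_reach()]. The
#' kinematic parameters are given as measured targets; the deceleration piece
#' of the reach is calibrated so the expected measured adjustment time equals
#' `adjustment_ms`.
#'
#' @param cfg A [simulation_config()].
#' @param adjustment_ms Target measured adjustment time for this trial (ms).
#' @param transport_peak Target transport peak velocity (mm/s).
#' @param mga_mm,mga_rel Aperture peak (mm) and its relative timing (%).
#' @param grip_deviation Signed deviation of the grip centre from the cup COM
#'   at contact (mm).
#' @param cup A [cup_spec()] for the grasped cup (sets the contact height).
#' @param participant_id,block,condition Trial metadata.
#' @param counter Trial counter for the random substream.
#' @return List with `trial` and a one-row `truth` tibble.
#' @export
simulate_trial <- function(cfg, adjustment_ms, transport_peak, mga_mm,
                           mga_rel, grip_deviation, cup,
                           participant_id = "P01", block = 1L,
                           condition = list(surface = "matte",
                                            content = "empty",
                                            feedback = "visible"),
                           counter = 1L) {
  landmarks <- list(start = c(0, 0, 0),
                    A = c(cfg$reach_amplitude, 0, 0),
                    B = c(cfg$reach_amplitude, cfg$transport_amplitude, 0))
  grasp_z <- cup$base_z + cup_com(cup) + grip_deviation
  p_start <- c(0, 0, cfg$z_rest)
  p_A <- c(landmarks$A[1], landmarks$A[2], grasp_z)
  p_B <- c(landmarks$B[1], landmarks$B[2], grasp_z)

  # reach: decel piece calibrated to the measured adjustment-time target
  D_r <- sqrt(sum((p_A - p_start)^2))
  ta_r <- cfg$reach_accel_ms
  td_r <- calibrate_decel(adjustment_ms, ta_r, D_r, cfg$velocity_threshold)
  cross_r <- threshold_crossings(ta_r, td_r, D_r, cfg$velocity_threshold)

  # transport: symmetric-ish movement with the requested peak speed
  D_t <- sqrt(sum((p_B - p_A)^2))
  T_t <- 1875 * D_t / transport_peak
  ta_t <- T_t * (1 - cfg$transport_decel_fraction)
  td_t <- T_t * cfg$transport_decel_fraction
  cross_t <- threshold_crossings(ta_t, td_t, D_t, cfg$velocity_threshold)

  T_ret <- cfg$return_ms
  t_reach0 <- cfg$pre_ms
  t_trans0 <- t_reach0 + (ta_r + td_r) + cfg$hold_ms
  t_ret0 <- t_trans0 + T_t + cfg$hold_ms
  total <- t_ret0 + T_ret + cfg$post_ms
  period <- 1000 / cfg$sample_rate
  times <- seq(0, floor(total / period) * period, by = period)

  seg_pos <- function(t0, ta, td, from, to) {
    D <- sqrt(sum((to - from)^2))
    u <- unit3(to - from)
    tt <- times - t0
    idx <- tt > 0 & tt < ta + td
    s <- numeric(length(times))
    s[idx] <- two_piece_s(tt[idx], ta, td, D)
    s[tt >= ta + td] <- D
    outer(s, u)
  }
  centre <- matrix(p_start, length(times), 3, byrow = TRUE) +
    seg_pos(t_reach0, ta_r, td_r, p_start, p_A) +
    seg_pos(t_trans0, ta_t, td_t, p_A, p_B) +
    seg_pos(t_ret0, T_ret / 2, T_ret / 2, p_B, p_start)

  t_on <- t_reach0 + cross_r$onset
  t_off <- t_reach0 + cross_r$offset
  t_mga <- t_on + (mga_rel / 100) * (t_off - t_on)
  aperture <- ease_profile(times, cfg$aperture_rest, list(
    list(t0 = t_reach0, t1 = t_mga, a0 = cfg$aperture_rest, a1 = mga_mm),
    list(t0 = t_mga, t1 = t_reach0 + ta_r + td_r, a0 = mga_mm,
         a1 = cfg$aperture_contact),
    list(t0 = t_ret0, t1 = t_ret0 + T_ret / 2, a0 = cfg$aperture_contact,
         a1 = cfg$aperture_rest)
  ))
  u_r <- unit3(p_A - p_start)
  tr <- assemble_fingers(centre, aperture, u_r, times, cfg$sample_rate,
                         cfg$marker_noise_sd, cfg$dropout_rate,
                         cfg$dropout_mean_run,
                         trial_seed(cfg$seed, counter),
                         participant_id, block, condition, landmarks)
  truth <- tibble::new_tibble(list(
    participant = participant_id, block = as.integer(block),
    surface = condition$surface, content = condition$content,
    feedback = condition$feedback,
    true_adjustment = adjustment_ms,
    true_transport_peak = transport_peak,
    true_reach_peak = cross_r$peak_velocity,
    true_mga = mga_mm, true_mga_rel = mga_rel,
    true_grip_deviation = grip_deviation,
    expected_onset_ms = t_on, expected_offset_ms = t_off,
    expected_reach_span_ms = t_off - t_on
  ), nrow = 1L)
  list(trial = tr, truth = truth)
}

#' Simulate a full factorial dataset
#'
#' Generates `n_participants x n_blocks x 8` trials with per-subject random
#' intercepts on the adjustment time, transport peak, MGA (size and relative
#' timing) and grip deviation, plus trial-level jitter, under the condition
#' targets of the configuration. Ground truth for every downstream feature is
#' returned alongside and is never consulted by the analysis path.
#'
#' @param cfg A [simulation_config()].
#' @return List with `trials` (named list of [trial()] objects), `truth`
#'   (tibble, one row per trial), `manifest` (design tibble) and `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  grid <- condition_grid()
  set.seed(trial_seed(cfg$seed, 0L))
  subj <- tibble::tibble(
    participant = sprintf("P%02d", seq_len(cfg$n_participants)),
    u_adj = stats::rnorm(cfg$n_participants, 0, cfg$subject_sd[["adjustment"]]),
    u_tp = stats::rnorm(cfg$n_participants, 0, cfg$subject_sd[["transport_peak"]]),
    u_rel = stats::rnorm(cfg$n_participants, 0, cfg$subject_sd[["mga_rel"]]),
    u_dev = stats::rnorm(cfg$n_participants, 0, cfg$subject_sd[["grip_deviation"]]),
    u_mga = stats::rnorm(cfg$n_participants, 0, cfg$subject_sd[["mga"]])
  )
  design <- tidyr::expand_grid(participant = subj$participant,
                               block = seq_len(cfg$n_blocks), grid)
  n <- nrow(design)
  design$trial_id <- sprintf("T%04d", seq_len(n))
  set.seed(trial_seed(cfg$seed, 1L))
  jit <- list(
    adj = stats::rnorm(n, 0, cfg$trial_sd[["adjustment"]]),
    tp = stats::rnorm(n, 0, cfg$trial_sd[["transport_peak"]]),
    rel = stats::rnorm(n, 0, cfg$trial_sd[["mga_rel"]]),
    dev = stats::rnorm(n, 0, cfg$trial_sd[["grip_deviation"]]),
    mga = stats::rnorm(n, 0, cfg$trial_sd[["mga"]])
  )
  design <- dplyr::left_join(design, subj, by = "participant")
  shiny <- design$surface == "shiny"
  hidden <- design$feedback == "hidden"
  eff <- function(dv) cfg$surface_effects[[dv]] * shiny +
    cfg$feedback_effects[[dv]] * hidden
  adj <- pmax(250, cfg$adjustment_target[design$content] +
                eff("adjustment") + design$u_adj + jit$adj)
  tp <- pmin(2500, pmax(200, cfg$transport_peak_target[design$content] +
                          eff("transport_peak") + design$u_tp + jit$tp))
  rel <- pmin(92, pmax(15, cfg$mga_rel_target[design$content] +
                         eff("mga_rel") + design$u_rel + jit$rel))
  dev <- cfg$grip_deviation_target[design$content] +
    eff("grip_deviation") + design$u_dev + jit$dev
  mga <- pmax(cfg$aperture_contact + 10,
              cfg$mga_mm + design$u_mga + jit$mga)
  cups <- list(empty = cup_spec(), filled = cup_spec_filled())

  out <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    sim <- simulate_trial(
      cfg, adjustment_ms = adj[i], transport_peak = tp[i],
      mga_mm = mga[i], mga_rel = rel[i], grip_deviation = dev[i],
      cup = cups[[design$content[i]]],
      participant_id = design$participant[i], block = design$block[i],
      condition = list(surface = design$surface[i],
                       content = design$content[i],
                       feedback = design$feedback[i]),
      counter = i + 1L
    )
    out[[i]] <- sim$trial
    tru <- sim$truth; tru$trial_id <- design$trial_id[i]
    truths[[i]] <- tru
  }
  names(out) <- design$trial_id
  list(trials = out, truth = dplyr::bind_rows(truths),
       manifest = design[, c("trial_id", "participant", "block", "surface",
                             "content", "feedback", "stimulus")],
       config = cfg)
}

#' Simulate ordinal ratings from a cumulative-link generative model
#'
#' Latent-variable twin of the proportional-odds model used for analysis: for
#' each participant x stimulus, a latent value
#' `sum(effects * covariates) + subject intercept + logistic noise` is binned
#' by the ordered thresholds into a 1-7 category. Covariates are centred
#' (+-0.5), so symmetric thresholds with zero effects give a mean rating
#' near 4. Default effects are the study-scale coefficients for the requested
#' dimension (e.g. content 1.98 on heaviness, surface 6.89 on glossiness).
#'
#' @param n_participants Number of raters.
#' @param dimension `"heaviness"`, `"hardness"` or `"glossiness"` (selects
#'   the default effects).
#' @param effects Named vector of latent effects for `content`, `surface`,
#'   `feedback` (any subset); overrides the dimension defaults.
#' @param thresholds Six strictly increasing latent thresholds.
#' @param subject_sd SD of the participant random intercept.
#' @param phase `"pre"` or `"post"` label for the records.
#' @param seed Integer seed.
#' @return A [rating_records()] tibble (one row per participant x stimulus).
#' @export
simulate_ratings <- function(n_participants = 14, dimension = "heaviness",
                             effects = NULL,
                             thresholds = seq(-2.5, 2.5, by = 1),
                             subject_sd = 1, phase = "pre", seed = 1L) {
  if (length(thresholds) != 6L || any(diff(thresholds) <= 0)) {
    stop("config error: need 6 strictly increasing thresholds", call. = FALSE)
  }
  defaults <- list(
    heaviness = c(content = 1.98, surface = 0.36),
    hardness = c(content = 1.41, surface = 0.63),
    glossiness = c(surface = 6.89, content = 0.13)
  )
  if (is.null(effects)) effects <- defaults[[dimension]]
  grid <- condition_grid()
  design <- tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(n_participants)), grid)
  x <- cbind(content = (design$content == "filled") - 0.5,
             surface = (design$surface == "shiny") - 0.5,
             feedback = (design$feedback == "hidden") - 0.5)
  eta <- as.numeric(x[, names(effects), drop = FALSE] %*% effects)
  set.seed(seed)
  u <- stats::rnorm(n_participants, 0, subject_sd)
  latent <- eta + u[match(design$participant,
                          sprintf("P%02d", seq_len(n_participants)))] +
    stats::rlogis(nrow(design))
  value <- findInterval(latent, thresholds) + 1L
  rating_records(tibble::tibble(
    participant = design$participant,
    stimulus = design$stimulus,
    surface = design$surface, content = design$content,
    feedback = design$feedback,
    dimension = dimension, phase = phase, value = value))
}

#' Simulate a feature table directly (fast path)
#'
#' Generates the per-trial feature table the trajectory pipeline would
#' produce, without synthesising trajectories: each dependent variable is
#' `condition mean + subject intercept + residual`. Used for statistical
#' calibration studies (type-I error, permutation nulls) where thousands of
#' replicate datasets are needed and the kinematic layer is not under test.
#'
#' @param n_participants,n_blocks Design size.
#' @param content_effects Named vector of content (filled minus empty)
#'   effects for any of `adjustment_time`, `transport_peak_velocity`,
#'   `mga_time_rel`, `grip_deviation`; defaults to all zero (a null dataset).
#' @param means Named vector of grand means for the four variables.
#' @param subject_sd,resid_sd Named vectors of subject-intercept and residual
#'   SDs for the four variables.
#' @param seed Integer seed.
#' @return Feature tibble with design columns and the four dependent
#'   variables.
#' @export
simulate_feature_table <- function(n_participants = 14, n_blocks = 5,
                                   content_effects = NULL,
                                   means = c(adjustment_time = 950,
                                             transport_peak_velocity = 745,
                                             mga_time_rel = 64,
                                             grip_deviation = 0),
                                   subject_sd = c(adjustment_time = 100,
                                                  transport_peak_velocity = 60,
                                                  mga_time_rel = 4,
                                                  grip_deviation = 3),
                                   resid_sd = c(adjustment_time = 120,
                                                transport_peak_velocity = 90,
                                                mga_time_rel = 5,
                                                grip_deviation = 4),
                                   seed = 1L) {
  zero <- c(adjustment_time = 0, transport_peak_velocity = 0,
            mga_time_rel = 0, grip_deviation = 0)
  eff <- zero
  if (!is.null(content_effects)) eff[names(content_effects)] <- content_effects
  design <- tidyr::expand_grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    block = seq_len(n_blocks), condition_grid())
  n <- nrow(design)
  filled <- design$content == "filled"
  set.seed(seed)
  for (dv in names(zero)) {
    u <- stats::rnorm(n_participants, 0, subject_sd[[dv]])
    design[[dv]] <- means[[dv]] + eff[[dv]] * filled +
      u[as.integer(factor(design$participant))] +
      stats::rnorm(n, 0, resid_sd[[dv]])
  }
  design
}
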