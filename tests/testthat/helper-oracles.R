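# Shared fixtures and independent oracles used across the suite.

# Trajectory from a position matrix (or function of time) at 100 Hz.
make_traj <- function(pos, sample_rate = 100, valid = NULL, id = "marker") {
  marker_trajectory(pos, sample_rate = sample_rate, valid = valid,
                    marker_id = id)
}

# A tiny stationary three-finger trial with the default geometry.
make_static_trial <- function(n = 20, sample_rate = 100) {
  at <- function(p) make_traj(matrix(rep(p, each = n), n, 3),
                              sample_rate = sample_rate)
  trial(list(thumb = at(c(0, 50, 30)), index = at(c(0, -50, 30)),
             middle = at(c(15, 0, 30))))
}

# Brute-force run-length segmenter: scans every sample with an explicit state
# machine, no rle. Independent of the implementation under test.
brute_force_segments <- function(speed, threshold = 30, min_run = 10) {
  n <- length(speed)
  above <- speed > threshold
  onsets <- integer(); offsets <- integer()
  i <- 1L; in_move <- FALSE
  while (i <= n) {
    run_len <- 0L
    j <- i
    while (j <= n && above[j] == above[i]) { run_len <- run_len + 1L; j <- j + 1L }
    if (!in_move && above[i] && run_len >= min_run) {
      onsets <- c(onsets, i); in_move <- TRUE
    } else if (in_move && !above[i] && run_len >= min_run) {
      offsets <- c(offsets, i); in_move <- FALSE
    }
    i <- j
  }
  if (in_move) onsets <- onsets[seq_along(offsets)]
  data.frame(onset = onsets, offset = offsets)
}

# Solid-frustum centroid by numerical quadrature of z * A(z) over the solid,
# A(z) = pi r(z)^2 with r linear in z.
frustum_centroid_quad <- function(h, r1, r2) {
  r <- function(z) r1 + (r2 - r1) * z / h
  num <- stats::integrate(function(z) z * pi * r(z)^2, 0, h,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(function(z) pi * r(z)^2, 0, h,
                          rel.tol = 1e-12)$value
  num / den
}

# Per-axis linear interpolation oracle for gap filling, via stats::approx on
# the valid samples only (rule 1: no extrapolation at the edges).
fill_gaps_oracle <- function(pos, valid, max_gap) {
  n <- nrow(pos)
  out <- pos
  new_valid <- valid
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    len <- r$lengths[k]
    if (len > max_gap || starts[k] == 1L || ends[k] == n) next
    for (j in 1:3) {
      out[starts[k]:ends[k], j] <-
        stats::approx(x = which(valid), y = pos[valid, j],
                      xout = starts[k]:ends[k])$y
    }
    new_valid[starts[k]:ends[k]] <- TRUE
  }
  list(positions = out, valid = new_valid)
}

# Closed-form minimum-jerk peak speed (mm/s) for amplitude D (mm) over T (ms).
mj_peak_mms <- function(D, T_ms) 1.875 * D / (T_ms / 1000)
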