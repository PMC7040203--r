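#' Movement segmentation configuration
#'
#' Holds the velocity-threshold criterion used to segment hand movements:
#' a movement starts at the first sample of a run of at least `min_run`
#' consecutive samples with speed above `velocity_threshold`, and ends at the
#' first sample of the subsequent run of at least `min_run` consecutive
#' samples below it. The defaults (30 mm/s over 10 successive samples at
#' 100 Hz) are the standard criterion for seated reach-to-grasp data.
#'
#' @param velocity_threshold Speed threshold in mm/s (> 0).
#' @param min_run Minimum run length in samples (>= 1).
#' @param smoothing `NULL` for no smoothing (the default), or a low-pass
#'   cutoff frequency in Hz; when set, positions are filtered with a
#'   zero-phase 2nd-order Butterworth filter before differentiation.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(velocity_threshold = 30, min_run = 10L,
                                smoothing = NULL) {
  if (!is.numeric(velocity_threshold) || velocity_threshold <= 0) {
    stop("velocity_threshold must be > 0", call. = FALSE)
  }
  if (!is.numeric(min_run) || min_run < 1) {
    stop("min_run must be >= 1", call. = FALSE)
  }
  if (!is.null(smoothing) && (!is.numeric(smoothing) || smoothing <= 0)) {
    stop("smoothing must be NULL or a positive cutoff in Hz", call. = FALSE)
  }
  structure(list(velocity_threshold = velocity_threshold,
                 min_run = as.integer(min_run), smoothing = smoothing),
            class = "segmentation_config")
}

#' Scalar speed of a marker trajectory
#'
#' Differentiates the 3-D position series by central differences (forward and
#' backward differences at the edges) and returns the per-sample Euclidean
#' norm of the velocity vector in mm/s — one informative speed series instead
#' of three per-axis ones. Optional zero-phase low-pass smoothing of the
#' positions is applied first when `cfg$smoothing` is set.
#'
#' @param traj A [marker_trajectory()], gap-free over the span of interest.
#' @param cfg A [segmentation_config()].
#' @return Numeric vector of speeds (mm/s), same length as the trajectory.
#'   Samples whose velocity estimate touches an invalid position are `NA`.
#' @export
velocity_norm <- function(traj, cfg = segmentation_config()) {
  stopifnot(inherits(traj, "marker_trajectory"))
  n <- length(traj)
  if (n < 3) stop("insufficient data: need at least 3 samples", call. = FALSE)
  pos <- traj$positions
  if (!is.null(cfg$smoothing)) {
    ny <- traj$sample_rate / 2
    bf <- signal::butter(2, min(cfg$smoothing / ny, 0.99))
    for (j in 1:3) {
      if (!anyNA(pos[, j])) pos[, j] <- signal::filtfilt(bf, pos[, j])
    }
  }
  dt <- 1 / traj$sample_rate  # seconds, so speeds come out in mm/s
  vel <- matrix(NA_real_, n, 3L)
  for (j in 1:3) {
    p <- pos[, j]
    vel[2:(n - 1), j] <- (p[3:n] - p[1:(n - 2)]) / (2 * dt)
    vel[1, j] <- (p[2] - p[1]) / dt
    vel[n, j] <- (p[n] - p[n - 1]) / dt
  }
  sqrt(rowSums(vel^2))
}

#' Segment movements from a speed series
#'
#' Applies the velocity-threshold criterion of [segmentation_config()]: an
#' onset is the first sample of a run of at least `min_run` consecutive
#' samples above the threshold (after the previous offset), and the matching
#' offset is the first sample of the subsequent run of at least `min_run`
#' consecutive samples below it. Segments are half-open `[onset, offset)`,
#' non-overlapping and ordered. A movement still above threshold at the end
#' of the series has no offset and is discarded with a warning.
#'
#' @param speed Numeric vector of speeds (mm/s); must be finite.
#' @param cfg A [segmentation_config()].
#' @return Tibble with integer columns `onset` and `offset` (1-based sample
#'   indices; onset inclusive, offset exclusive).
#' @export
segment_movements <- function(speed, cfg = segmentation_config()) {
  if (length(speed) == 0) stop("empty speed series", call. = FALSE)
  if (any(!is.finite(speed))) {
    stop("speed series must be finite (fill or exclude gaps first)",
         call. = FALSE)
  }
  above <- speed > cfg$velocity_threshold
  r <- rle(above)
  run_start <- cumsum(r$lengths) - r$lengths + 1L
  onsets <- integer()
  offsets <- integer()
  in_move <- FALSE
  for (k in seq_along(r$lengths)) {
    if (!in_move && r$values[k] && r$lengths[k] >= cfg$min_run) {
      onsets <- c(onsets, run_start[k])
      in_move <- TRUE
    } else if (in_move && !r$values[k] && r$lengths[k] >= cfg$min_run) {
      offsets <- c(offsets, run_start[k])
      in_move <- FALSE
    }
  }
  if (in_move) {
    warning("movement still above threshold at end of series; discarded",
            call. = FALSE)
    onsets <- onsets[seq_along(offsets)]
  }
  tibble::new_tibble(list(onset = onsets, offset = offsets),
                     nrow = length(onsets))
}

#' Label movement segments as reach, transport or other
#'
#' Automatic geometric labelling against the trial landmarks: a segment whose
#' terminal grip-centre position lies within `radius` mm (horizontally) of
#' location A — the stimulus position — is a candidate reach (nearest
#' terminal wins); a segment starting within `radius` of A and ending within
#' `radius` of B is a transport; everything else (e.g. the return to the
#' start position) is `"other"`. Manual labels, when supplied, always win.
#'
#' @param segments Tibble from [segment_movements()].
#' @param x The [trial()] the segments belong to.
#' @param manual Optional character vector of labels (length `nrow(segments)`,
#'   `NA` to keep the automatic label) overriding the geometric rule.
#' @param radius Landmark radius in mm (default 60).
#' @param gc Precomputed [grip_center()] trajectory (computed if omitted).
#' @return `segments` with a `label` column.
#' @export
label_segments <- function(segments, x, manual = NULL, radius = 60,
                           gc = grip_center(x)) {
  stopifnot(inherits(x, "trial"))
  n <- nrow(segments)
  label <- rep("other", n)
  if (n > 0) {
    term_pos <- gc$positions[segments$offset, , drop = FALSE]
    start_pos <- gc$positions[segments$onset, , drop = FALSE]
    dist_xy <- function(p, q) sqrt((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2)
    d_term_A <- dist_xy(term_pos, x$landmarks$A)
    d_start_A <- dist_xy(start_pos, x$landmarks$A)
    d_term_B <- dist_xy(term_pos, x$landmarks$B)
    reach_cand <- which(is.finite(d_term_A) & d_term_A <= radius)
    if (length(reach_cand)) {
      label[reach_cand[which.min(d_term_A[reach_cand])]] <- "reach"
    }
    is_transport <- is.finite(d_start_A) & is.finite(d_term_B) &
      d_start_A <= radius & d_term_B <= radius & label != "reach"
    label[is_transport] <- "transport"
  }
  if (!is.null(manual)) {
    keep <- !is.na(manual)
    label[keep] <- manual[keep]
  }
  if (!any(label == "reach")) {
    stop("labeling error: no segment qualifies as a reach", call. = FALSE)
  }
  segments$label <- label
  segments
}

#' Temporal features of movement segments
#'
#' For each segment: duration, peak velocity (maximum speed over the span,
#' earliest sample on ties), its timing, and — for reach segments — the
#' adjustment time, i.e. the deceleration interval from the velocity peak to
#' the end of the reach (object contact), the grasp-planning phase of the
#' movement. By construction `adjustment_time + (peak_time - onset_time) =
#' duration` exactly.
#'
#' @param segments Labelled segment tibble from [label_segments()] (or any
#'   tibble with `onset`, `offset` and optionally `label`).
#' @param speed Speed series the segments were detected on (mm/s).
#' @param sample_rate Sampling rate in Hz.
#' @return Tibble with one row per segment: `label`, `onset`, `offset`,
#'   `onset_ms`, `offset_ms`, `duration` (ms), `peak_velocity` (mm/s),
#'   `peak_idx`, `peak_ms`, `adjustment_time` (ms; `NA` for non-reach
#'   segments) and a `degenerate` flag (peak at the first or last sample).
#' @export
temporal_features <- function(segments, speed, sample_rate) {
  period <- 1000 / sample_rate
  if (!"label" %in% names(segments)) segments$label <- "other"
  onset <- segments$onset
  offset <- segments$offset
  label <- segments$label
  if (any(offset <= onset)) {
    stop("degenerate segment: offset <= onset", call. = FALSE)
  }
  peak_idx <- vapply(seq_along(onset), function(i) {
    onset[i] - 1L + which.max(speed[onset[i]:(offset[i] - 1L)])
  }, integer(1))  # which.max takes the earliest sample on ties
  tibble::new_tibble(list(
    label = label, onset = onset, offset = offset,
    onset_ms = (onset - 1L) * period, offset_ms = (offset - 1L) * period,
    duration = (offset - onset) * period,
    peak_velocity = speed[peak_idx], peak_idx = peak_idx,
    peak_ms = (peak_idx - onset) * period,
    adjustment_time = ifelse(label == "reach", (offset - peak_idx) * period,
                             NA_real_),
    degenerate = peak_idx == onset | peak_idx == offset - 1L
  ), nrow = length(onset))
}
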