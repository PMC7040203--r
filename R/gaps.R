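#' Fill short tracking gaps by linear interpolation
#'
#' Motion-capture markers drop out when occluded; short gaps are routinely
#' bridged before analysis. Runs of at most `max_gap` consecutive invalid
#' samples that are flanked by valid samples on both sides are linearly
#' interpolated per coordinate and marked valid. Longer runs, and runs
#' touching either end of the recording, are left invalid; whether a
#' remaining gap disqualifies a trial is decided downstream, once the
#' movement spans are known (see [segment_movements()]).
#'
#' Valid samples are never modified.
#'
#' @param traj A [marker_trajectory()].
#' @param max_gap Maximum gap length, in samples, that may be interpolated
#'   (default 5, i.e. 50 ms at 100 Hz).
#' @return A [marker_trajectory()] with short gaps filled.
#' @export
fill_gaps <- function(traj, max_gap = 5L) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (max_gap < 0) stop("max_gap must be >= 0", call. = FALSE)
  if (!any(traj$valid)) {
    stop("unusable trajectory: no valid samples to interpolate from",
         call. = FALSE)
  }
  if (all(traj$valid) || max_gap == 0L) return(traj)
  r <- rle(traj$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- traj$positions
  valid <- traj$valid
  for (k in which(!r$values)) {
    len <- r$lengths[k]
    if (len > max_gap) next
    i0 <- starts[k] - 1L     # flanking valid sample before the gap
    i1 <- ends[k] + 1L       # flanking valid sample after the gap
    if (i0 < 1L || i1 > length(valid)) next  # gap touches a recording edge
    w <- seq_len(len) / (len + 1)
    for (j in 1:3) {
      pos[starts[k]:ends[k], j] <- pos[i0, j] + w * (pos[i1, j] - pos[i0, j])
    }
    valid[starts[k]:ends[k]] <- TRUE
  }
  new_marker_trajectory(pos, sample_rate = traj$sample_rate, valid = valid,
                        times = traj$times, marker_id = traj$marker_id)
}

# Indices (1-based, inclusive) of invalid samples within [from, to]; used by
# the pipeline to disqualify trials with unfilled gaps inside analysis windows.
invalid_within <- function(traj, from, to) {
  idx <- from:to
  idx[!traj$valid[idx]]
}
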