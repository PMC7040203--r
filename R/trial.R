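#' Marker trajectory
#'
#' A single reflective marker's time-stamped 3-D position series, sampled
#' uniformly (typically at 100 Hz), with a per-sample validity mask marking
#' frames on which the tracking system actually saw the marker.
#'
#' Coordinates follow the capture convention: X front-back, Y left-right,
#' Z up-down, all in millimetres; time in milliseconds from trial start.
#'
#' @param positions Numeric matrix with `n` rows and columns x, y, z (mm).
#' @param sample_rate Sampling rate in Hz.
#' @param valid Logical vector of length `n`; defaults to rows with all
#'   coordinates finite. Invalid samples may hold `NA` positions.
#' @param times Optional time stamps in ms; defaults to a uniform grid
#'   starting at 0. Must be uniform with spacing `1000 / sample_rate`
#'   (tolerance 1e-6 ms).
#' @param marker_id Marker label, e.g. `"thumb"`.
#'
#' @return An object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(positions, sample_rate, valid = NULL,
                              times = NULL, marker_id = "marker") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) {
    stop("`positions` must have three columns (x, y, z)", call. = FALSE)
  }
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y", "z")
  n <- nrow(positions)
  if (is.null(valid)) valid <- rowSums(!is.finite(positions)) == 0L
  valid <- as.logical(valid)
  if (is.null(times)) times <- (seq_len(n) - 1) * 1000 / sample_rate
  obj <- structure(
    list(marker_id = marker_id, times = as.numeric(times),
         positions = positions, valid = valid,
         sample_rate = as.numeric(sample_rate)),
    class = "marker_trajectory"
  )
  validate_marker_trajectory(obj)
}

# Internal fast path: wrap already-consistent components without the
# uniform-sampling / finiteness re-checks (generator and derived series).
new_marker_trajectory <- function(positions, sample_rate, valid, times,
                                  marker_id) {
  structure(list(marker_id = marker_id, times = times, positions = positions,
                 valid = valid, sample_rate = sample_rate),
            class = "marker_trajectory")
}

validate_marker_trajectory <- function(x) {
  n <- nrow(x$positions)
  if (length(x$times) != n || length(x$valid) != n) {
    stop("times, positions and valid mask must have equal length", call. = FALSE)
  }
  if (!is.finite(x$sample_rate) || x$sample_rate <= 0) {
    stop("sample_rate must be positive", call. = FALSE)
  }
  if (n > 1) {
    dt <- diff(x$times)
    period <- 1000 / x$sample_rate
    if (any(abs(dt - period) > 1e-6)) {
      stop("non-uniform sampling: time deltas must equal 1000/sample_rate ",
           "within 1e-6 ms", call. = FALSE)
    }
  }
  if (any(x$valid & rowSums(!is.finite(x$positions)) > 0L)) {
    stop("positions must be finite wherever the valid mask is TRUE", call. = FALSE)
  }
  x
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory '%s': %d samples @ %g Hz, %d invalid>\n",
              x$marker_id, nrow(x$positions), x$sample_rate, sum(!x$valid)))
  invisible(x)
}

#' @export
length.marker_trajectory <- function(x) nrow(x$positions)

frame_period_ms <- function(x) 1000 / x$sample_rate

#' Reach-and-transport trial
#'
#' Bundles the fingertip marker trajectories of one reach-and-transport
#' execution with its design metadata: participant, block (1-5) and the three
#' binary condition factors (surface matte/shiny, content empty/filled,
#' feedback visible/hidden). At least thumb, index and middle trajectories are
#' required and must share an identical time base.
#'
#' Landmarks give the start position and stimulus locations A and B in the
#' world frame (mm). When omitted they default to the task geometry used
#' throughout: start at the origin, A 400 mm ahead, B 400 mm to the right
#' of A.
#'
#' @param trajectories Named list of [marker_trajectory()] objects including
#'   `thumb`, `index` and `middle`.
#' @param participant_id Participant identifier.
#' @param block Integer block number 1-5.
#' @param condition Named list or vector with elements `surface`
#'   (`"matte"`/`"shiny"`), `content` (`"empty"`/`"filled"`) and `feedback`
#'   (`"visible"`/`"hidden"`).
#' @param landmarks Named list of 3-vectors `start`, `A`, `B` (mm), or `NULL`
#'   for the default geometry.
#'
#' @return An object of class `trial`.
#' @export
trial <- function(trajectories, participant_id = "P01", block = 1L,
                  condition = list(surface = "matte", content = "empty",
                                   feedback = "visible"),
                  landmarks = NULL) {
  if (is.null(names(trajectories)) ||
      !all(c("thumb", "index", "middle") %in% names(trajectories))) {
    stop("`trajectories` must be a named list including thumb, index and middle",
         call. = FALSE)
  }
  for (tr in trajectories) {
    if (!inherits(tr, "marker_trajectory")) {
      stop("all trajectories must be marker_trajectory objects", call. = FALSE)
    }
  }
  fingers <- trajectories[c("thumb", "index", "middle")]
  t0 <- fingers[[1]]$times
  for (tr in fingers[-1]) {
    if (length(tr$times) != length(t0) || any(tr$times != t0)) {
      stop("thumb, index and middle trajectories must share an identical time base",
           call. = FALSE)
    }
  }
  condition <- as.list(condition)
  check_level <- function(name, levels) {
    v <- condition[[name]]
    if (is.null(v) || !v %in% levels) {
      stop(sprintf("condition$%s must be one of: %s", name,
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
  }
  check_level("surface", c("matte", "shiny"))
  check_level("content", c("empty", "filled"))
  check_level("feedback", c("visible", "hidden"))
  block <- as.integer(block)
  if (is.na(block) || block < 1L) stop("block must be a positive integer", call. = FALSE)
  if (is.null(landmarks)) landmarks <- default_landmarks()
  for (nm in c("start", "A", "B")) {
    if (is.null(landmarks[[nm]]) || length(landmarks[[nm]]) != 3L) {
      stop("landmarks must contain 3-vectors start, A and B", call. = FALSE)
    }
    landmarks[[nm]] <- as.numeric(landmarks[[nm]])
  }
  if (horiz_dist(landmarks$start, landmarks$A) <= 0 ||
      horiz_dist(landmarks$A, landmarks$B) <= 0) {
    stop("start-to-A and A-to-B horizontal distances must be positive",
         call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, block = block,
         condition = condition, trajectories = trajectories,
         landmarks = landmarks,
         sample_rate = fingers[[1]]$sample_rate),
    class = "trial"
  )
}

#' Default task geometry landmarks
#'
#' Start at the origin, stimulus location A 400 mm ahead of the start, and
#' location B 400 mm to the right of A, all on the table plane (z = 0).
#'
#' @return Named list of 3-vectors `start`, `A`, `B` in mm.
#' @export
default_landmarks <- function() {
  list(start = c(0, 0, 0), A = c(400, 0, 0), B = c(400, 400, 0))
}

horiz_dist <- function(a, b) sqrt(sum((a[1:2] - b[1:2])^2))

#' @export
print.trial <- function(x, ...) {
  cat(sprintf(
    "<trial %s block %d [%s/%s/%s]: %d markers x %d frames @ %g Hz>\n",
    x$participant_id, x$block, x$condition$surface, x$condition$content,
    x$condition$feedback, length(x$trajectories),
    length(x$trajectories[[1]]), x$sample_rate))
  invisible(x)
}

#' Grip-centre trajectory of a trial
#'
#' The grip centre is the per-frame mean of the thumb, index and middle
#' fingertip positions; it drives movement segmentation and, at the contact
#' frame, the vertical grip position. A frame is valid only when all three
#' fingertips are valid on it.
#'
#' @param x A [trial()] object.
#' @return A [marker_trajectory()] labelled `"grip_center"`.
#' @export
grip_center <- function(x) {
  stopifnot(inherits(x, "trial"))
  th <- x$trajectories$thumb
  ix <- x$trajectories$index
  md <- x$trajectories$middle
  pos <- (th$positions + ix$positions + md$positions) / 3
  valid <- th$valid & ix$valid & md$valid
  pos[!valid, ] <- NA_real_
  colnames(pos) <- c("x", "y", "z")
  new_marker_trajectory(pos, sample_rate = x$sample_rate, valid = valid,
                        times = th$times, marker_id = "grip_center")
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.marker_trajectory <- function(x, ...) {
  tibble::tibble(
    marker = x$marker_id,
    frame = seq_along(x$times),
    time_ms = x$times,
    x = x$positions[, 1], y = x$positions[, 2], z = x$positions[, 3],
    valid = x$valid
  )
}

#' @export
as_tibble.trial <- function(x, ...) {
  out <- purrr::map(x$trajectories, tibble::as_tibble)
  dplyr::bind_rows(out) |>
    dplyr::mutate(
      participant = x$participant_id, block = x$block,
      surface = x$condition$surface, content = x$condition$content,
      feedback = x$condition$feedback,
      .before = 1
    )
}

#' Ordinal rating record table
#'
#' Builds and validates a tidy table of 7-point semantic-differential ratings:
#' one row per participant x stimulus x dimension x phase with an integer
#' value in 1..7. Dimensions are heaviness, hardness and glossiness; the phase
#' separates ratings collected before the first reach (`"pre"`) from ratings
#' collected after the final transport (`"post"`).
#'
#' @param data Data frame with columns `participant`, `stimulus`, `dimension`,
#'   `phase` and `value`.
#' @return A validated tibble of class `rating_records`.
#' @export
rating_records <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("participant", "stimulus", "dimension", "phase", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing rating columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(data$dimension %in% c("heaviness", "hardness", "glossiness"))) {
    stop("dimension must be heaviness, hardness or glossiness", call. = FALSE)
  }
  if (!all(data$phase %in% c("pre", "post"))) {
    stop("phase must be 'pre' or 'post'", call. = FALSE)
  }
  if (!all(data$value %in% 1:7)) {
    stop("rating values must be integers in 1..7", call. = FALSE)
  }
  data$value <- as.integer(data$value)
  class(data) <- c("rating_records", class(data))
  data
}
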