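#' Read a trial from a tab-separated marker export
#'
#' Parses the fixed tabular dialect used by this package for marker exports:
#' a header row `frame<TAB>time<TAB><marker>_X<TAB><marker>_Y<TAB><marker>_Z ...`,
#' one row per frame, tab separated, dot decimal, time in ms, positions in mm.
#' Missing samples (marker not tracked on that frame) are encoded as empty
#' fields and are flagged in the validity mask, never silently interpolated.
#'
#' @param path Path to the TSV file.
#' @param metadata Named list of trial metadata (`participant_id`, `block`,
#'   `condition`, `landmarks`); anything omitted falls back to the [trial()]
#'   defaults.
#' @param marker_map Optional named character vector mapping canonical names
#'   (`thumb`, `index`, `middle`, ...) to the marker names used in the file,
#'   e.g. `c(thumb = "R_THUMB")`. By default file names are used as-is.
#'
#' @return A [trial()] object with a uniform time base.
#' @export
read_trial_tsv <- function(path, metadata = list(), marker_map = NULL) {
  dat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  if (!all(c("frame", "time") %in% names(dat))) {
    stop("format error: header must start with 'frame' and 'time' columns",
         call. = FALSE)
  }
  coord_cols <- grep("_(X|Y|Z)$", names(dat), value = TRUE)
  markers <- unique(sub("_(X|Y|Z)$", "", coord_cols))
  for (m in markers) {
    if (!all(paste0(m, "_", c("X", "Y", "Z")) %in% names(dat))) {
      stop("format error: marker '", m, "' lacks a full X/Y/Z triplet",
           call. = FALSE)
    }
  }
  times <- dat$time
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(abs(dt - dt[1]) > 1e-6) || dt[1] <= 0) {
      stop("format error: non-uniform sampling in 'time' column", call. = FALSE)
    }
    sample_rate <- 1000 / dt[1]
  } else {
    sample_rate <- if (!is.null(metadata$sample_rate)) metadata$sample_rate else 100
  }
  if (!is.null(marker_map)) {
    missing_src <- setdiff(unname(marker_map), markers)
    if (length(missing_src)) {
      stop("mapping error: marker(s) not in file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
  } else {
    marker_map <- stats::setNames(markers, markers)
  }
  for (f in c("thumb", "index", "middle")) {
    if (!f %in% names(marker_map)) {
      stop("mapping error: no marker mapped to '", f, "'", call. = FALSE)
    }
  }
  trajs <- purrr::imap(marker_map, function(src, canon) {
    pos <- as.matrix(dat[, paste0(src, "_", c("X", "Y", "Z"))])
    valid <- rowSums(is.na(pos)) == 0L
    marker_trajectory(pos, sample_rate = sample_rate, valid = valid,
                      times = times, marker_id = canon)
  })
  trial(
    trajectories = trajs,
    participant_id = metadata$participant_id %||% "P01",
    block = metadata$block %||% 1L,
    condition = metadata$condition %||% list(surface = "matte",
                                             content = "empty",
                                             feedback = "visible"),
    landmarks = metadata$landmarks
  )
}

#' Write a trial to the tab-separated marker dialect
#'
#' Inverse of [read_trial_tsv()]: one row per frame, columns `frame`, `time`
#' and an X/Y/Z triplet per marker, tab separated, dot decimal. Invalid
#' samples are written as empty fields. Numeric fields are printed with six
#' decimals, so write-read-write is byte-stable.
#'
#' @param x A [trial()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_tsv <- function(x, path) {
  stopifnot(inherits(x, "trial"))
  markers <- names(x$trajectories)
  header <- c("frame", "time",
              unlist(lapply(markers, function(m) paste0(m, "_", c("X", "Y", "Z")))))
  n <- length(x$trajectories[[1]])
  fmt_num <- function(v) sprintf("%.6f", v)
  cols <- vector("list", length(header))
  cols[[1]] <- as.character(seq_len(n))
  cols[[2]] <- fmt_num(x$trajectories[[1]]$times)
  k <- 3L
  for (m in markers) {
    tr <- x$trajectories[[m]]
    for (j in 1:3) {
      v <- fmt_num(tr$positions[, j])
      v[!tr$valid | !is.finite(tr$positions[, j])] <- ""
      cols[[k]] <- v
      k <- k + 1L
    }
  }
  lines <- c(paste(header, collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Write a set of trials plus a manifest
#'
#' Writes each trial in the TSV dialect and a flat `manifest.csv` (one row per
#' trial: file, participant, block, condition factors, sample rate, landmark
#' coordinates) so a dataset round-trips through [read_dataset()].
#'
#' @param trials List of [trial()] objects.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(trials)
  if (is.null(ids)) ids <- sprintf("T%04d", seq_along(trials))
  rows <- purrr::map(seq_along(trials), function(i) {
    tr <- trials[[i]]
    file <- sprintf("trial_%s.tsv", gsub("[^A-Za-z0-9_-]", "_", ids[i]))
    write_trial_tsv(tr, file.path(dir, file))
    lm <- tr$landmarks
    tibble::tibble(
      trial_id = ids[i], file = file,
      participant = tr$participant_id, block = tr$block,
      surface = tr$condition$surface, content = tr$condition$content,
      feedback = tr$condition$feedback, sample_rate = tr$sample_rate,
      start_x = lm$start[1], start_y = lm$start[2], start_z = lm$start[3],
      A_x = lm$A[1], A_y = lm$A[2], A_z = lm$A[3],
      B_x = lm$B[1], B_y = lm$B[2], B_z = lm$B[3]
    )
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` and the per-trial TSV files.
#' @return Named list of [trial()] objects (names are the trial ids).
#' @export
read_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  trials <- purrr::pmap(manifest, function(trial_id, file, participant, block,
                                           surface, content, feedback, sample_rate,
                                           start_x, start_y, start_z,
                                           A_x, A_y, A_z, B_x, B_y, B_z, ...) {
    read_trial_tsv(
      file.path(dir, file),
      metadata = list(
        participant_id = participant, block = block,
        condition = list(surface = surface, content = content,
                         feedback = feedback),
        landmarks = list(start = c(start_x, start_y, start_z),
                         A = c(A_x, A_y, A_z), B = c(B_x, B_y, B_z)),
        sample_rate = sample_rate
      )
    )
  })
  stats::setNames(trials, manifest$trial_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
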