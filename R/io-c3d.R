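# Minimal standard C3D support: 512-byte blocks, Intel (PC) processor type,
# point data stored as floats or scaled integers, residual < 0 = invalid
# sample. Covers the subset of the format that fingertip-marker exports use;
# analog channels and event sections are ignored.

rd_i8 <- function(raw, pos) readBin(raw[pos], "integer", size = 1L, signed = TRUE)
rd_u8 <- function(raw, pos) as.integer(raw[pos])
rd_i16 <- function(raw, pos, n = 1L) {
  readBin(raw[pos:(pos + 2L * n - 1L)], "integer", size = 2L, n = n,
          signed = TRUE, endian = "little")
}
rd_f32 <- function(raw, pos, n = 1L) {
  readBin(raw[pos:(pos + 4L * n - 1L)], "double", size = 4L, n = n,
          endian = "little")
}
rd_chr <- function(raw, pos, n) rawToChar(raw[pos:(pos + n - 1L)])

#' Read a trial from a C3D file
#'
#' Reads standard C3D point data (Intel byte order, float or integer
#' storage). Samples whose residual is negative are marked invalid, following
#' the C3D convention for untracked markers. The contract matches
#' [read_trial_tsv()]: uniform time base, missing samples flagged, never
#' interpolated.
#'
#' @param path Path to a C3D file.
#' @param marker_map Named character vector mapping canonical marker names to
#'   C3D point labels, e.g. `c(thumb = "R_THUMB", index = "R_INDEX",
#'   middle = "R_MIDDLE")`. Defaults to using the labels as-is.
#' @param metadata Trial metadata list as in [read_trial_tsv()].
#' @return A [trial()] object.
#' @export
read_trial_c3d <- function(path, marker_map = NULL, metadata = list()) {
  pts <- read_c3d_points(path)
  labels <- pts$labels
  if (is.null(marker_map)) marker_map <- stats::setNames(labels, labels)
  for (f in c("thumb", "index", "middle")) {
    if (!f %in% names(marker_map)) {
      stop("mapping error: no marker mapped to '", f, "'", call. = FALSE)
    }
  }
  missing_src <- setdiff(unname(marker_map), labels)
  if (length(missing_src)) {
    stop("mapping error: marker(s) not in C3D file: ",
         paste(missing_src, collapse = ", "), call. = FALSE)
  }
  trajs <- purrr::imap(as.list(marker_map), function(src, canon) {
    j <- match(src, labels)
    pos <- pts$positions[, , j, drop = FALSE]
    dim(pos) <- dim(pos)[1:2]
    valid <- pts$residuals[, j] >= 0
    pos[!valid, ] <- NA_real_
    marker_trajectory(pos, sample_rate = pts$rate, valid = valid,
                      marker_id = canon)
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

# Low-level C3D parse: returns positions [frame, xyz, point], residuals,
# labels, rate.
read_c3d_points <- function(path) {
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 512L || rd_u8(raw, 2L) != 0x50) {
    stop("format error: not a C3D file (missing 0x50 key)", call. = FALSE)
  }
  param_block <- rd_u8(raw, 1L)
  n_points <- rd_i16(raw, 3L)
  first_frame <- rd_i16(raw, 7L)
  last_frame <- rd_i16(raw, 9L)
  scale <- rd_f32(raw, 13L)
  data_start_block <- rd_i16(raw, 17L)
  rate <- rd_f32(raw, 21L)
  n_frames <- last_frame - first_frame + 1L

  poff <- (param_block - 1L) * 512L
  proc <- rd_u8(raw, poff + 4L)
  if (proc != 84L) {
    stop("format error: only Intel (PC) processor type C3D files are supported",
         call. = FALSE)
  }
  params <- parse_c3d_params(raw, poff)
  point <- params[["POINT"]]
  if (!is.null(point)) {
    if (!is.null(point$USED)) n_points <- point$USED[1]
    if (!is.null(point$FRAMES)) n_frames <- point$FRAMES[1]
    if (!is.null(point$SCALE)) scale <- point$SCALE[1]
    if (!is.null(point$RATE)) rate <- point$RATE[1]
    if (!is.null(point$DATA_START)) data_start_block <- point$DATA_START[1]
  }
  labels <- if (!is.null(point$LABELS)) {
    trimws(point$LABELS)[seq_len(n_points)]
  } else {
    paste0("point", seq_len(n_points))
  }

  dpos <- (data_start_block - 1L) * 512L + 1L
  positions <- array(NA_real_, c(n_frames, 3L, n_points))
  residuals <- matrix(NA_real_, n_frames, n_points)
  res_mat <- function(arr) {
    res <- arr[4L, , , drop = FALSE]
    dim(res) <- c(n_points, n_frames)
    t(res)
  }
  if (scale < 0) {
    vals <- rd_f32(raw, dpos, n = n_frames * n_points * 4L)
    arr <- array(vals, c(4L, n_points, n_frames))
    positions <- aperm(arr[1:3, , , drop = FALSE], c(3L, 1L, 2L))
    residuals <- res_mat(arr)
  } else {
    vals <- rd_i16(raw, dpos, n = n_frames * n_points * 4L)
    arr <- array(vals, c(4L, n_points, n_frames))
    positions <- aperm(arr[1:3, , , drop = FALSE], c(3L, 1L, 2L)) * scale
    res <- res_mat(arr)
    residuals <- ifelse(res < 0, -1,
                        bitwAnd(as.integer(res), 0xFFL) * scale)
  }
  list(positions = positions, residuals = residuals, labels = labels,
       rate = rate, first_frame = first_frame)
}

parse_c3d_params <- function(raw, poff) {
  pos <- poff + 5L
  groups <- list()   # id -> name
  params <- list()   # name -> list of parameter values
  repeat {
    if (pos > length(raw)) break
    nname <- rd_i8(raw, pos)
    if (nname == 0L) break
    gid <- rd_i8(raw, pos + 1L)
    name <- rd_chr(raw, pos + 2L, abs(nname))
    p <- pos + 2L + abs(nname)
    offset <- rd_i16(raw, p)
    next_pos <- p + offset
    p <- p + 2L
    if (gid < 0L) {
      groups[[as.character(-gid)]] <- name
    } else {
      esize <- rd_i8(raw, p); p <- p + 1L
      ndim <- rd_u8(raw, p); p <- p + 1L
      dims <- if (ndim > 0L) vapply(seq_len(ndim), function(i) rd_u8(raw, p + i - 1L), 1L) else integer()
      p <- p + ndim
      nelem <- prod(c(1L, dims))
      value <- switch(as.character(esize),
        "-1" = {
          chars <- rd_chr(raw, p, nelem)
          if (length(dims) >= 2L) {
            w <- dims[1]
            vapply(seq_len(prod(dims[-1])),
                   function(i) substr(chars, (i - 1L) * w + 1L, i * w), "")
          } else chars
        },
        "1" = vapply(seq_len(nelem), function(i) rd_i8(raw, p + i - 1L), 1L),
        "2" = rd_i16(raw, p, nelem),
        "4" = rd_f32(raw, p, nelem),
        stop("format error: bad parameter element size", call. = FALSE)
      )
      params[[as.character(gid)]] <- c(params[[as.character(gid)]] %||% list(),
                                       stats::setNames(list(value), name))
    }
    if (offset == 0L) break
    pos <- next_pos
  }
  out <- list()
  for (id in names(params)) {
    gname <- groups[[id]] %||% paste0("GROUP", id)
    out[[gname]] <- params[[id]]
  }
  out
}

wr_i8 <- function(con, x) writeBin(as.integer(x), con, size = 1L)
wr_i16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
wr_f32 <- function(con, x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

#' Write a trial to a C3D file
#'
#' Emits a standard minimal C3D: Intel processor type, float point storage
#' (scale -1), POINT group with USED/FRAMES/SCALE/RATE/DATA_START/LABELS/UNITS.
#' Invalid samples get residual -1.
#'
#' @param x A [trial()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_c3d <- function(x, path) {
  stopifnot(inherits(x, "trial"))
  markers <- names(x$trajectories)
  n_points <- length(markers)
  n_frames <- length(x$trajectories[[1]])
  rate <- x$sample_rate

  label_w <- max(4L, max(nchar(markers)))
  labels_pad <- formatC(markers, width = label_w, flag = "-")

  # Parameter section depends on its own size through DATA_START, so build it
  # twice: once to measure, once with the real block number patched in.
  build_params <- function(n_pblocks, data_start) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con), add = TRUE)
    wr_i8(con, c(1L, 0x50, n_pblocks, 84L))
    write_group <- function(id, name) {
      wr_i8(con, c(nchar(name), -id)); writeChar(name, con, eos = NULL)
      wr_i16(con, 3L)  # to next record: offset field (2) + desc length (1)
      wr_i8(con, 0L)
    }
    write_param <- function(id, name, value, esize, dims = integer()) {
      wr_i8(con, c(nchar(name), id)); writeChar(name, con, eos = NULL)
      nelem <- prod(c(1L, dims))
      wr_i16(con, 2L + 1L + 1L + length(dims) + abs(esize) * nelem + 1L)
      wr_i8(con, c(esize, length(dims)))
      if (length(dims)) wr_i8(con, dims)
      if (esize == -1L) {
        writeChar(paste(value, collapse = ""), con, eos = NULL)
      } else if (esize == 2L) wr_i16(con, value) else wr_f32(con, value)
      wr_i8(con, 0L)
    }
    write_group(1L, "POINT")
    write_param(1L, "USED", n_points, 2L)
    write_param(1L, "FRAMES", n_frames, 2L)
    write_param(1L, "SCALE", -1, 4L)
    write_param(1L, "RATE", rate, 4L)
    write_param(1L, "DATA_START", data_start, 2L)
    write_param(1L, "UNITS", "mm  ", -1L, c(4L))
    write_param(1L, "LABELS", labels_pad, -1L, c(label_w, n_points))
    wr_i8(con, 0L)  # terminator record
    rawConnectionValue(con)
  }
  psize <- length(build_params(1L, 3L))
  n_pblocks <- as.integer(ceiling(psize / 512))
  data_start <- 2L + n_pblocks
  praw <- build_params(n_pblocks, data_start)
  praw <- c(praw, raw(n_pblocks * 512L - length(praw)))

  # ---- header block ----
  hcon <- rawConnection(raw(0), "wb")
  wr_i8(hcon, c(2L, 0x50))
  wr_i16(hcon, c(n_points, 0L, 1L, n_frames, 0L))
  wr_f32(hcon, -1)
  wr_i16(hcon, c(data_start, 1L))
  wr_f32(hcon, rate)
  hraw <- rawConnectionValue(hcon); close(hcon)
  hraw <- c(hraw, raw(512L - length(hraw)))

  # ---- data section ----
  dat <- array(0, c(4L, n_points, n_frames))
  for (j in seq_len(n_points)) {
    tr <- x$trajectories[[j]]
    pos <- tr$positions
    pos[!tr$valid | !is.finite(pos)] <- 0
    dat[1:3, j, ] <- t(pos)
    dat[4L, j, ] <- ifelse(tr$valid, 0, -1)
  }
  dcon <- rawConnection(raw(0), "wb")
  wr_f32(dcon, as.numeric(dat))
  draw <- rawConnectionValue(dcon); close(dcon)
  pad <- (512L - length(draw) %% 512L) %% 512L
  draw <- c(draw, raw(pad))

  writeBin(c(hraw, praw, draw), path)
  invisible(path)
}
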