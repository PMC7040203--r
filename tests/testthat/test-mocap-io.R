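test_that("marker_trajectory enforces its invariants", {
  pos <- matrix(rnorm(30), 10, 3)
  tr <- make_traj(pos)
  expect_s3_class(tr, "marker_trajectory")
  expect_length(tr$times, 10)
  expect_equal(diff(tr$times), rep(10, 9))

  expect_error(marker_trajectory(pos[, 1:2, drop = FALSE], 100), "three columns")
  expect_error(marker_trajectory(pos, 100, times = c(0, 10, 20, 31, 40, 50,
                                                     60, 70, 80, 90)),
               "non-uniform")
  bad <- pos; bad[3, 1] <- NA
  expect_error(marker_trajectory(bad, 100, valid = rep(TRUE, 10)), "finite")
  # NA positions allowed where the mask is FALSE
  v <- rep(TRUE, 10); v[3] <- FALSE
  expect_silent(marker_trajectory(bad, 100, valid = v))
})

test_that("trial requires shared time bases and valid conditions", {
  n <- 10
  at <- function(p, rate = 100) make_traj(matrix(rep(p, each = n), n, 3),
                                          sample_rate = rate)
  fingers <- list(thumb = at(c(0, 50, 30)), index = at(c(0, -50, 30)),
                  middle = at(c(15, 0, 30)))
  expect_s3_class(trial(fingers), "trial")
  expect_error(trial(fingers[c("thumb", "index")]), "thumb, index and middle")

  off <- fingers
  off$middle <- make_traj(matrix(0, n + 1, 3))
  expect_error(trial(off), "identical time base")

  expect_error(trial(fingers, condition = list(surface = "glossy",
                                               content = "empty",
                                               feedback = "visible")),
               "surface")
  expect_error(trial(fingers, landmarks = list(start = c(0, 0, 0),
                                               A = c(0, 0, 100),
                                               B = c(400, 0, 0))),
               "positive")
})

test_that("TSV round-trip preserves positions, times and masks", {
  set.seed(42)
  n <- 5
  mk <- function() matrix(round(rnorm(n * 3, 0, 100), 3), n, 3)
  tr <- trial(list(thumb = make_traj(mk()), index = make_traj(mk()),
                   middle = make_traj(mk())))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial_tsv(tr, path)
  back <- read_trial_tsv(path)
  expect_equal(length(back$trajectories), 3)
  for (m in c("thumb", "index", "middle")) {
    expect_equal(back$trajectories[[m]]$positions,
                 tr$trajectories[[m]]$positions, tolerance = 1e-9)
    expect_true(all(back$trajectories[[m]]$valid))
    expect_equal(back$trajectories[[m]]$times, tr$trajectories[[m]]$times)
  }
})

test_that("missing samples become masked, never interpolated, and write-read-write is byte-stable", {
  set.seed(7)
  n <- 6
  pos <- matrix(rnorm(n * 3, 0, 50), n, 3)
  pos[3, ] <- NA
  v <- rep(TRUE, n); v[3] <- FALSE
  tr <- trial(list(thumb = make_traj(pos, valid = v),
                   index = make_traj(matrix(1, n, 3)),
                   middle = make_traj(matrix(2, n, 3))))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_trial_tsv(tr, p1)
  back <- read_trial_tsv(p1)
  expect_equal(back$trajectories$thumb$valid, v)
  expect_true(all(is.na(back$trajectories$thumb$positions[3, ])))
  # write(read(write(x))) must reproduce the file byte for byte
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_trial_tsv(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("TSV reader rejects malformed files and bad marker maps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\ttime\tthumb_X\tthumb_Y\tthumb_Z",
               "1\t0.0\t1\t2\t3", "2\t10.0\t1\t2\t3", "3\t25.0\t1\t2\t3"),
             path)
  expect_error(read_trial_tsv(path), "non-uniform")

  tr <- make_static_trial()
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_trial_tsv(tr, p2)
  expect_error(read_trial_tsv(p2, marker_map = c(thumb = "nosuch",
                                                 index = "index",
                                                 middle = "middle")),
               "mapping error")
  # file with only unknown names cannot satisfy thumb/index/middle
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("frame\ttime\tm1_X\tm1_Y\tm1_Z",
               "1\t0.0\t1\t2\t3", "2\t10.0\t1\t2\t3"), p3)
  expect_error(read_trial_tsv(p3), "mapping error")
})

test_that("dataset write/read round-trips trials with metadata", {
  dir <- withr::local_tempdir()
  trs <- list(T1 = make_static_trial(), T2 = make_static_trial())
  trs$T2$condition$content <- "filled"
  manifest <- write_dataset(trs, dir)
  expect_equal(nrow(manifest), 2)
  back <- read_dataset(dir)
  expect_equal(names(back), c("T1", "T2"))
  expect_equal(back[[2]]$condition$content, "filled")
  expect_equal(back[[1]]$trajectories$thumb$positions,
               trs$T1$trajectories$thumb$positions, tolerance = 1e-9)
})

test_that("rating records validate dimension, phase and range", {
  ok <- data.frame(participant = "P01", stimulus = 1,
                   dimension = "heaviness", phase = "pre", value = 4)
  expect_s3_class(rating_records(ok), "rating_records")
  bad <- ok; bad$value <- 8
  expect_error(rating_records(bad), "1..7")
  bad <- ok; bad$dimension <- "weight"
  expect_error(rating_records(bad), "dimension")
})
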