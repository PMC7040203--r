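test_that("frustum centroid closed form: cup value, cylinder and cone limits", {
  # the study cup: 114 mm tall, radii 28.5 / 43.5 mm -> 65 mm after rounding
  com <- frustum_centroid(114, 28.5, 43.5)
  expect_equal(round(com), 65)
  expect_equal(com, 64.8038, tolerance = 1e-4)

  expect_equal(frustum_centroid(80, 25, 25), 40)        # cylinder: h/2
  expect_equal(frustum_centroid(60, 0, 30), 45)         # cone, apex at base
  expect_error(frustum_centroid(-1, 10, 10), "positive")
  expect_error(frustum_centroid(10, 0, 0), "not both zero")
})

test_that("frustum centroid agrees with numerical quadrature on random frusta", {
  set.seed(314)
  for (i in 1:200) {
    h <- runif(1, 5, 500)
    r1 <- runif(1, 0.1, 100)
    r2 <- runif(1, 0.1, 100)
    expect_equal(frustum_centroid(h, r1, r2), frustum_centroid_quad(h, r1, r2),
                 tolerance = 1e-8)
  }
})

test_that("frustum centroid symmetries: scaling and radius swap", {
  set.seed(99)
  for (i in 1:50) {
    h <- runif(1, 10, 200); r1 <- runif(1, 1, 60); r2 <- runif(1, 1, 60)
    c_ <- runif(1, 0.1, 10)
    expect_equal(frustum_centroid(c_ * h, c_ * r1, c_ * r2),
                 c_ * frustum_centroid(h, r1, r2), tolerance = 1e-12)
    expect_equal(frustum_centroid(h, r2, r1),
                 h - frustum_centroid(h, r1, r2), tolerance = 1e-9)
  }
})

test_that("combined_com: exact empty-cup limit, midpoint, betweenness", {
  # zero liquid mass returns the cup centroid bitwise
  set.seed(41)
  for (i in 1:200) {
    com <- runif(1, 1, 200)
    expect_identical(combined_com(com, runif(1, 0.1, 500), runif(1), 0), com)
  }
  expect_equal(combined_com(60, 5, 40, 5), 50)  # equal masses -> midpoint
  expect_error(combined_com(60, 0, 40, 0), "total mass")
  # strictly between the component centroids when both masses positive
  for (i in 1:100) {
    c1 <- runif(1, 0, 100); c2 <- runif(1, 0, 100)
    m1 <- runif(1, 0.01, 100); m2 <- runif(1, 0.01, 100)
    if (abs(c1 - c2) < 1e-9) next
    out <- combined_com(c1, m1, c2, m2)
    expect_gt(out, min(c1, c2))
    expect_lt(out, max(c1, c2))
  }
})

test_that("filled study cup reproduces the printed 46 mm COM", {
  expect_equal(round(cup_com(cup_spec_filled())), 46)
  expect_equal(cup_com(cup_spec()), frustum_centroid(114, 28.5, 43.5))
})

test_that("aperture series equals the per-sample distance oracle", {
  n <- 40
  same <- make_traj(matrix(3, n, 3))
  expect_equal(aperture_series(same, same), rep(0, n))

  a <- make_traj(cbind(numeric(n), numeric(n), numeric(n)))
  b <- make_traj(cbind(rep(100, n), numeric(n), numeric(n)))
  expect_equal(aperture_series(a, b), rep(100, n))

  set.seed(8)
  pa <- matrix(cumsum(rnorm(n * 3)), n, 3)
  pb <- matrix(cumsum(rnorm(n * 3)), n, 3)
  ap <- aperture_series(make_traj(pa), make_traj(pb))
  oracle <- vapply(seq_len(n), function(i) sqrt(sum((pa[i, ] - pb[i, ])^2)),
                   numeric(1))
  expect_equal(ap, oracle, tolerance = 1e-12)

  expect_error(aperture_series(a, b, window = 35:45), "window")
})

test_that("MGA features: maximum, timing, monotone and tie cases", {
  reach <- tibble::tibble(onset = 1L, offset = 101L)
  # monotonically closing aperture: MGA at the first sample, small rel time
  ap <- seq(120, 70, length.out = 100)
  m <- mga_features(ap, reach, 100)
  expect_equal(m$mga, 120)
  expect_equal(m$mga_time_abs, 0)
  expect_lt(m$mga_time_rel, 1)

  # interior peak
  ap2 <- c(seq(40, 119, length.out = 62), seq(118, 70, length.out = 38))
  m2 <- mga_features(ap2, reach, 100)
  expect_equal(m2$mga, 119)
  expect_equal(m2$mga_time_rel, 61, tolerance = 0.01)

  # two equal maxima: the earlier is reported
  ap3 <- c(rep(50, 10), 119, rep(60, 10), 119, rep(50, 78))
  m3 <- mga_features(ap3, reach, 100)
  expect_equal(m3$mga_time_abs, 100)

  expect_error(mga_features(numeric(0), reach, 100), "empty")
  expect_error(mga_features(ap[1:50], reach, 100), "exactly")
})

test_that("grip features: centre averaging and signed deviation convention", {
  n <- 10
  at_z <- function(z, y) make_traj(matrix(c(400, y, z), n, 3, byrow = TRUE))
  cup <- cup_spec()  # empty: com 64.8 mm
  g <- grip_features(at_z(50, 40), at_z(60, -40), at_z(70, 0), 5L, cup)
  expect_equal(g$grip_center_z, 60)
  expect_equal(g$grip_deviation, 60 - cup_com(cup))

  # grips above the COM are positive, below negative
  above <- grip_features(at_z(80, 40), at_z(80, -40), at_z(80, 0), 5L, cup)
  below <- grip_features(at_z(30, 40), at_z(30, -40), at_z(30, 0), 5L, cup)
  expect_gt(above$grip_deviation, 0)
  expect_lt(below$grip_deviation, 0)

  # fingertips exactly at base_z + com -> zero deviation
  z0 <- cup_com(cup) + 12
  cup12 <- cup_spec(base_z = 12)
  g0 <- grip_features(at_z(z0, 40), at_z(z0, -40), at_z(z0, 0), 5L, cup12)
  expect_equal(g0$grip_deviation, 0, tolerance = 1e-12)

  # invalid fingertip at contact: refuse to impute
  pos <- matrix(c(400, 0, 50), n, 3, byrow = TRUE)
  pos[5, ] <- NA
  v <- rep(TRUE, n); v[5] <- FALSE
  bad <- make_traj(pos, valid = v)
  expect_error(grip_features(bad, at_z(60, -40), at_z(70, 0), 5L, cup),
               "invalid fingertip")
})
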