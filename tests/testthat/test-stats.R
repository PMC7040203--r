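test_that("two-condition rm_anova equals the squared paired t statistic", {
  set.seed(60)
  n <- 12
  d <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:n), each = 2),
    content = rep(c("empty", "filled"), n),
    surface = "matte", feedback = "visible",
    dv = rnorm(2 * n, 500, 50) + rep(c(0, 30), n))
  fit <- rm_anova(d, "dv", within = "content")
  tt <- t.test(dv ~ content, data = d, paired = TRUE)
  expect_equal(fit$table$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(fit$table$df, 1)
  expect_equal(fit$table$df_error, n - 1)
  expect_equal(fit$table$p.value, tt$p.value, tolerance = 1e-8)
})

test_that("generalized eta squared matches the direct SS computation (one factor)", {
  set.seed(61)
  n <- 10
  d <- tibble::tibble(
    participant = rep(sprintf("P%02d", 1:n), each = 2),
    content = rep(c("empty", "filled"), n),
    dv = rnorm(2 * n, 100, 20) + rep(c(0, 15), n))
  fit <- rm_anova(d, "dv", within = "content")
  # direct decomposition: SS_A, SS_subject, SS_error from scratch
  y <- matrix(d$dv, ncol = 2, byrow = TRUE)
  grand <- mean(y)
  ss_a <- n * sum((colMeans(y) - grand)^2)
  ss_s <- 2 * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_a - ss_s
  expect_equal(fit$table$ges, ss_a / (ss_a + ss_s + ss_err), tolerance = 1e-10)
})

test_that("rm_anova flags degenerate data and missing cells", {
  d <- simulate_feature_table(n_participants = 4, n_blocks = 1, seed = 1)
  d$const <- 1
  expect_true(rm_anova(d, "const")$degenerate)
  holey <- d[!(d$participant == "P01" & d$content == "filled"), ]
  expect_error(rm_anova(holey, "adjustment_time"), "aggregation error")
})

test_that("three-factor rm_anova reports all seven effects with sane stats", {
  d <- simulate_feature_table(n_participants = 8, n_blocks = 2,
                              content_effects = c(adjustment_time = 150),
                              seed = 62)
  fit <- rm_anova(d, "adjustment_time")
  expect_equal(nrow(fit$table), 7)
  expect_true(all(fit$table$p.value >= 0 & fit$table$p.value <= 1))
  expect_true(all(fit$table$ges >= 0 & fit$table$ges <= 1))
  expect_lt(fit$table$p.value[fit$table$term == "content"], 0.01)
  # F is invariant under affine rescaling of the dv
  d2 <- d; d2$adjustment_time <- 3.7 * d2$adjustment_time + 11
  fit2 <- rm_anova(d2, "adjustment_time")
  expect_equal(fit2$table$statistic, fit$table$statistic, tolerance = 1e-9)
})

test_that("Kruskal-Wallis: two-group case equals the rank-sum normal approximation", {
  set.seed(63)
  d <- tibble::tibble(block = rep(1:2, c(18, 15)),
                      dv = rnorm(33))  # continuous: no ties
  kw <- kruskal_wallis(d, "dv", "block")
  r <- rank(d$dv)
  n1 <- 18; n2 <- 15; N <- n1 + n2
  z <- (sum(r[d$block == 1]) - n1 * (N + 1) / 2) /
    sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(kw$statistic, z^2, tolerance = 1e-8)
  expect_equal(kw$df, 1)

  expect_true(kruskal_wallis(tibble::tibble(block = rep(1:3, 4), dv = 7),
                             "dv")$degenerate)
  expect_error(kruskal_wallis(tibble::tibble(block = 1, dv = 1:5), "dv"),
               "2 groups")
})

test_that("Kruskal-Wallis p-values are uniform under block permutation", {
  set.seed(64)
  d <- simulate_feature_table(n_participants = 7, n_blocks = 5, seed = 64)
  ps <- replicate(200, {
    d$block <- sample(d$block)
    kruskal_wallis(d, "adjustment_time", "block")$p.value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("lmm_fit reduces to ordinary least squares when subject variance is zero", {
  d <- simulate_feature_table(n_participants = 10, n_blocks = 2,
                              content_effects = c(adjustment_time = 100),
                              subject_sd = c(adjustment_time = 0,
                                             transport_peak_velocity = 0,
                                             mga_time_rel = 0,
                                             grip_deviation = 0),
                              seed = 65)
  fit <- suppressWarnings(lmm_fit(d, "adjustment_time"))
  ols <- lm(adjustment_time ~ surface + content + feedback, data = d)
  expect_equal(fit$table$estimate,
               unname(coef(ols)[c("surfaceshiny", "contentfilled",
                                  "feedbackvisible")]),
               tolerance = 1e-4)
  expect_true(fit$singular)
})

test_that("lmm_fit recovers an injected content effect with chi-squared term tests", {
  d <- simulate_feature_table(n_participants = 14, n_blocks = 5,
                              content_effects = c(adjustment_time = 143),
                              seed = 66)
  fit <- lmm_fit(d, "adjustment_time")
  row <- fit$table[fit$table$term == "content", ]
  expect_lt(abs(row$estimate - 143), 3 * row$std.error)
  expect_gte(row$chisq, 0)
  expect_lt(row$p.value, 0.001)
  expect_equal(row$df, 1)
  # estimates are equivariant in the dv units, chi-squared is invariant
  d2 <- d; d2$adjustment_time <- d2$adjustment_time / 1000
  fit2 <- lmm_fit(d2, "adjustment_time")
  expect_equal(fit2$table$estimate, fit$table$estimate / 1000,
               tolerance = 1e-6)
  expect_equal(fit2$table$chisq, fit$table$chisq, tolerance = 1e-4)
})

test_that("likelihood-ratio statistics are non-negative and p-values uniform under the null", {
  set.seed(67)
  d <- simulate_feature_table(n_participants = 10, n_blocks = 2, seed = 67)
  ps <- replicate(150, {
    d$adjustment_time <- sample(d$adjustment_time)
    fit <- suppressWarnings(lmm_fit(d, "adjustment_time",
                                    fixed = "content"))
    expect_gte(fit$table$chisq[1], 0)
    fit$table$p.value[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
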