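test_that("learning curves average animals per day and tolerate missing days", {
  s1 <- fixed_session(c(0.5, 0.6, NA), c(NA, NA), animal_id = "a1")
  cur1 <- build_curve(list(s1))
  expect_equal(cur1$days, 1L)
  expect_equal(unname(cur1$aroc$mean), session_aroc(s1))

  # two animals on one day -> unweighted mean
  sA <- fixed_session(c(0.4, 0.5, NA, NA), c(NA, NA, 1.2, NA), "aA", day = 2)
  sB <- fixed_session(c(0.4, 0.5, 0.6, NA), c(NA, NA, NA, NA), "aB", day = 2)
  cur2 <- build_curve(list(sA, sB))
  expect_equal(unname(cur2$aroc$mean),
               mean(c(session_aroc(sA), session_aroc(sB))))

  # animal missing a day drops from that day's population mean
  sA1 <- fixed_session(c(0.5, NA), c(NA, NA), "aA", day = 1)
  cur3 <- build_curve(list(sA1, sA, sB))
  expect_equal(unname(cur3$aroc$mean[1]), session_aroc(sA1))
  expect_true(is.na(cur3$aroc$per_animal["aB", "1"]))
})

test_that("slope fits agree with closed-form OLS and flag exact fits", {
  d <- 1:14
  v <- 0.5 + 0.028 * (d - 1)
  f <- fit_slope(d, v, c(1, 14))
  expect_equal(f$slope, 0.028, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  fc <- fit_slope(d, rep(0.7, 14))
  expect_equal(fc$slope, 0)
  expect_equal(fc$p_value, 1)

  set.seed(10)
  for (i in 1:20) {
    x <- sort(sample(1:30, 12))
    y <- 0.4 + 0.02 * x + rnorm(12, 0, 0.05)
    f2 <- fit_slope(x, y)
    o <- ols_oracle(x, y)
    expect_equal(f2$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f2$intercept, unname(o["intercept"]), tolerance = 1e-10)
  }
  expect_error(fit_slope(1:2, c(0.5, 0.6)), class = "too_few_points")
  # day-range restriction actually restricts
  y <- c(rep(0.5, 7), seq(0.5, 0.9, length.out = 7))
  expect_equal(fit_slope(1:14, y, c(1, 7))$slope, 0)
})

test_that("criterion day is the completion day of the first strict run", {
  expect_equal(criterion_day(c(0.6, 0.81, 0.82, 0.85, 0.90)), 5L)
  expect_true(is.na(criterion_day(c(0.7, 0.8, 0.79, 0.8, 0.8))))
  expect_true(is.na(criterion_day(rep(0.8, 10))))  # strict >
  expect_equal(criterion_day(rep(0.8, 10), strict = FALSE), 4L)
  expect_equal(criterion_day(c(0.9, 0.9, 0.9, 0.9, 0.2, 0.9), days = 11:16),
               14L)
  # raising the threshold never yields an earlier day
  set.seed(2)
  for (i in 1:20) {
    x <- runif(12, 0.5, 1)
    lo <- criterion_day(x, 0.7)
    hi <- criterion_day(x, 0.85)
    if (!is.na(lo) && !is.na(hi)) expect_gte(hi, lo)
    if (is.na(lo)) expect_true(is.na(hi))
  }
})

test_that("slope comparison is a two-sided normal z on the difference", {
  f <- list(slope = 0.03, se_slope = 0.004)
  class(f) <- "slope_fit"
  g <- list(slope = 0.03, se_slope = 0.004)
  class(g) <- "slope_fit"
  cmp <- compare_slopes(f, g)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p_value, 1)

  g$slope <- f$slope - 1.96 * sqrt(2) * 0.004
  cmp2 <- compare_slopes(f, g)
  expect_equal(cmp2$p_value, 0.05, tolerance = 1e-3)
  cmp3 <- compare_slopes(g, f)
  expect_equal(cmp3$z, -cmp2$z)
  expect_equal(cmp3$p_value, cmp2$p_value)
})

test_that("rank tests dispatch to Mann-Whitney / signed-rank with degeneracy flag", {
  r <- rank_tests(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)  # all ranks below
  expect_equal(r$method, "Mann-Whitney U")
  same <- rank_tests(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  # p invariant under within-sample shuffling
  set.seed(8)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  p1 <- rank_tests(a, b)$p_value
  p2 <- rank_tests(sample(a), sample(b))$p_value
  expect_equal(p1, p2)
  expect_error(rank_tests(a, b[1:5], paired = TRUE), class = "length_mismatch")
})

test_that("intact synthetic cohorts learn: the population curve rises day 1 to 14", {
  p <- default_profiles()
  coh <- simulate_cohort(p$intact, 4, 14, n_trials_per_day = 160, seed = 21)
  cur <- build_curve(coh)
  expect_gt(cur$aroc$mean[14], cur$aroc$mean[1] + 0.2)
  f <- fit_slope(cur$days, cur$aroc$mean, c(1, 14))
  expect_gt(f$slope, 0)
  expect_lt(f$p_value, 0.001)
  # trained animals reach the >0.8-for-4-days criterion
  expect_false(is.na(criterion_day(cur$aroc$mean, days = cur$days)))
})
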