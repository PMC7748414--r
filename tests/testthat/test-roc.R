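test_that("censoring maps Miss/CR to the surrogate timestamp", {
  s <- fixed_session(c(0.5, NA), c(NA, NA, NA))
  cl <- censored_latencies(s$trials)
  expect_equal(cl$stim$values_s, c(0.5, 4.1))
  expect_equal(cl$blank$values_s, c(4.1, 4.1, 4.1))
  # latencies are carried through unbinned
  s2 <- fixed_session(c(3.999), c(NA))
  expect_equal(censored_latencies(s2$trials)$stim$values_s, 3.999)
  # aborted trials are excluded
  s3 <- fixed_session(c(0.5), c(NA))
  s3$trials <- c(s3$trials, list(stim_trial(3, c(-0.4, 0.7))))
  expect_length(censored_latencies(s3$trials)$stim$values_s, 1)
  expect_error(censored_latencies(list()), class = "empty_input")
})

test_that("aROC reproduces hand-computed pairwise values and analytic limits", {
  expect_equal(aroc(latency_sample(c(0.5, 1.5)), latency_sample(c(1.0, 2.0))),
               0.75)  # 3 wins of 4 pairs
  expect_equal(aroc(latency_sample(c(0.5, 4.1)), latency_sample(c(4.1, 4.1))),
               0.75)  # 2 wins + 2 half-ties
  x <- latency_sample(c(0.11, 0.52, 2.3, 4.1))
  expect_identical(aroc(x, x), 0.5)
  # full separation, including censored blanks
  expect_identical(aroc(latency_sample(runif(20, 0.2, 0.9)),
                        latency_sample(rep(4.1, 15))), 1)
  expect_error(aroc(latency_sample(numeric()), x), class = "empty_input")
})

test_that("aROC equals the exhaustive pairwise oracle and is complement-symmetric", {
  set.seed(42)
  for (i in 1:60) {
    a <- random_latency_sample(sample(1:50, 1))
    b <- random_latency_sample(sample(1:50, 1))
    expect_equal(aroc(a, b), pairwise_aroc(a, b), tolerance = 1e-12)
    expect_equal(aroc(a, b) + aroc(b, a), 1, tolerance = 1e-12)
    expect_gte(aroc(a, b), 0)
    expect_lte(aroc(a, b), 1)
  }
})

test_that("earlier stimulus licks never decrease the aROC", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_latency_sample(30)
    b <- random_latency_sample(30)
    base <- aroc(a, b)
    shifted <- a$values_s
    notc <- shifted != a$censor_s
    shifted[notc] <- pmax(shifted[notc] - 0.1, 0)  # one full bin earlier
    expect_gte(aroc(latency_sample(shifted), b), base - 1e-12)
  }
})

test_that("windowed rates give the normal-quantile d-prime", {
  # 9/10 hits and 5/10 FAs within 2 s
  s <- fixed_session(c(runif(9, 0.3, 1.9), 3.5), c(runif(5, 0.3, 1.9), rep(NA, 5)))
  sm <- rates_and_dprime(s$trials, window_s = 2)
  expect_equal(sm$hit_rate, 0.9)
  expect_equal(sm$fa_rate, 0.5)
  expect_equal(sm$d_prime, qnorm(0.9) - qnorm(0.5), tolerance = 1e-12)
  expect_equal(qnorm(0.9) - qnorm(0.5), 1.2816, tolerance = 1e-4)
  # hit = fa -> d' = 0
  s2 <- fixed_session(c(0.5, NA), c(0.5, NA))
  expect_equal(rates_and_dprime(s2$trials)$d_prime, 0)
  # pooled day-4 rates under the quantile oracle
  n <- 1000
  s3 <- fixed_session(c(runif(899, 0.3, 3.9), rep(NA, 101)),
                      c(runif(816, 0.3, 3.9), rep(NA, 184)))
  sm3 <- rates_and_dprime(s3$trials)
  expect_equal(sm3$d_prime, qnorm(0.899) - qnorm(0.816), tolerance = 1e-10)
  expect_equal(sm3$d_prime, 0.376, tolerance = 5e-3)
  # antisymmetry under swapping hit/fa roles
  s4 <- fixed_session(c(runif(816, 0.3, 3.9), rep(NA, 184)),
                      c(runif(899, 0.3, 3.9), rep(NA, 101)))
  expect_equal(rates_and_dprime(s4$trials)$d_prime, -sm3$d_prime,
               tolerance = 0.02)
})

test_that("extreme rates are clipped before the quantile transform", {
  s <- fixed_session(rep(0.5, 10), rep(NA, 10))  # hit 1, fa 0
  sm <- rates_and_dprime(s$trials)
  expect_equal(sm$d_prime, qnorm(1 - 1 / 20) - qnorm(1 / 20), tolerance = 1e-12)
  expect_true(is.finite(sm$d_prime))
})

test_that("optimal window maximizes d-prime with shortest-window tie break", {
  set.seed(3)
  s <- fixed_session(runif(60, 0.3, 1.0), runif(60, 0, 4))
  grid <- seq(0.5, 4, by = 0.5)
  ow <- optimal_window(s$trials, grid)
  # exhaustive oracle over the grid
  dps <- sapply(grid, function(w) rates_and_dprime(s$trials, w)$d_prime)
  expect_equal(ow$window_s, grid[which.max(dps)])
  expect_true(all(ow$summary$d_prime >= dps - 1e-12))
  expect_gte(ow$window_s, 1)  # all stimulus licks precede 1 s
  # single-window grid returns that window
  expect_equal(optimal_window(s$trials, 2)$window_s, 2)
  # hit == fa everywhere: tie resolved to the shortest window
  s2 <- fixed_session(c(0.5, 1.5, NA), c(0.5, 1.5, NA))
  expect_equal(optimal_window(s2$trials, grid)$window_s, 0.5)
  expect_error(optimal_window(s$trials, numeric()), class = "bad_grid")
})

test_that("latency variability is the n-1 variance over the mean", {
  expect_equal(variability(c(0.5, 0.5, 0.5)), 0)
  expect_equal(variability(c(0.4, 0.6)), 0.04)  # var 0.02 / mean 0.5
  x <- c(0.3, 0.5, 0.9, 1.4)
  expect_equal(variability(3 * x), 3 * variability(x))  # scales like seconds
  expect_error(variability(0.5), class = "undefined_result")
})

test_that("inter-lick intervals pool successive differences across trains", {
  expect_equal(inter_lick_intervals(list(c(0, 1.3, 2.6))), 1.3)
  expect_equal(inter_lick_intervals(list(c(0, 1), c(0, 2))), 1.5)
  expect_equal(inter_lick_intervals(list(c(0, 1), 5, c(0, 2))), 1.5)
  expect_error(inter_lick_intervals(list(1, 2)), class = "undefined_result")
})

test_that("spontaneous trains recover the generating inter-lick interval", {
  p <- default_profiles()
  s <- simulate_session(p$intact, 1, n_trials = 500, seed = 11,
                        iti_s = 20, jitter_max_s = 0)
  # with a long gray period, window censoring barely biases the pooled ILI
  ili <- inter_lick_intervals(spontaneous_lick_trains(s))
  expect_equal(ili, 1.3, tolerance = 0.1)
})
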