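test_that("the hyperbolic ratio obeys its algebraic identities", {
  expect_equal(crf(20, 1, 2, 20), 0.5)        # half saturation at x50
  expect_equal(crf(1e9, 1.4, 2, 20), 1.4, tolerance = 1e-9)
  expect_equal(crf(0, 1, 2, 20), 0)
  x <- seq(0.5, 100, by = 0.5)
  expect_true(all(diff(crf(x, 1, 3, 25)) > 0))  # monotone in contrast
  expect_error(crf(10, 0, 2, 20), class = "bad_parameters")
})

test_that("noiseless contrast-response data are recovered to high precision", {
  xx <- c(2, 4, 8, 16, 32, 64, 100)
  fit <- fit_crf(xx, crf(xx, 1, 2, 20))
  expect_lt(abs(fit$r_max - 1), 1e-3)
  expect_lt(abs(fit$n_exp - 2) / 2, 1e-3)
  expect_lt(abs(fit$x50 - 20) / 20, 1e-3)
  # fitted curve is monotone and saturates at r_max
  expect_equal(crf(1e8, fit$r_max, fit$n_exp, fit$x50), fit$r_max,
               tolerance = 1e-6)
  expect_error(fit_crf(c(10, 20, 30), c(0.1, 0.2, 0.3)),
               class = "too_few_points")
})

test_that("bounded optimization matches a dense-grid minimizer within loss tolerance", {
  set.seed(31)
  r_grid <- seq(0.1, 2, length.out = 16)
  n_grid <- seq(0.3, 6, length.out = 16)
  x_grid <- seq(2, 100, length.out = 25)
  for (i in 1:15) {
    truth <- c(runif(1, 0.4, 1.4), runif(1, 0.8, 4), runif(1, 5, 60))
    xx <- c(4, 8, 16, 32, 64, 100)
    yy <- crf(xx, truth[1], truth[2], truth[3]) + rnorm(6, 0, 0.03)
    fit <- fit_crf(xx, yy)
    grid_best <- Inf
    for (r in r_grid) for (n in n_grid) {
      pred <- outer(xx, x_grid, function(x, x50) r * x^n / (x^n + x50^n))
      loss <- colSums((yy - pred)^2)
      grid_best <- min(grid_best, min(loss))
    }
    expect_lte(fit$rss, grid_best + 1e-8)
  }
})

test_that("PSTHs estimate known Poisson rates and vanish without spikes", {
  set.seed(17)
  onsets <- seq(5, 5 + 3 * 199, by = 3)
  ev <- data.frame(onset_s = onsets, contrast = 100, led_on = FALSE)
  # homogeneous 10 Hz Poisson train spanning the whole recording
  tmax <- max(onsets) + 2
  spikes <- sort(runif(rpois(1, 10 * tmax), 0, tmax))
  rec <- spike_record(500, spikes, ev)
  ps <- psth(rec, pre_s = 0.2, post_s = 0.5, bin_s = 0.1)
  se <- sqrt(10 / (200 * 0.1))  # Poisson SE per bin
  expect_true(all(abs(ps$rate - 10) < 3.5 * se))
  expect_equal(unname(ps$n_trials), 200)

  empty <- spike_record(500, numeric(), ev)
  expect_true(all(psth(empty)$rate == 0))
  expect_error(psth(rec, pre_s = 0.21, post_s = 0.5, bin_s = 0.1),
               class = "bad_bins")
})

test_that("evoked responses are baseline-subtracted and self-normalized", {
  set.seed(23)
  recs <- simulate_sc_activity(600, contrasts = c(4, 16, 100),
                               cortical_weight_by_depth = 0,
                               training_scale = 0, n_trials = 150, seed = 3)
  er <- evoked_response(recs[[1]], led_on = FALSE)
  expect_equal(max(er$response), 1)  # normalized to the control maximum
  expect_true(all(diff(er$raw) > 0))  # stronger response at higher contrast

  # response rate identical to baseline -> zero evoked response
  ev <- data.frame(onset_s = seq(5, 308, by = 3), contrast = c(4, 16, 100),
                   led_on = FALSE)
  tmax <- 313
  flat <- spike_record(500, sort(runif(3000, 0, tmax)), ev)
  er0 <- evoked_response(flat, normalize = FALSE)
  expect_true(all(abs(er0$raw) < 4.5))
  # no spikes at all: the control maximum is zero, normalization must fail
  silent <- spike_record(500, numeric(), ev)
  expect_error(evoked_response(silent, normalize = TRUE),
               class = "normalization_failure")
})

test_that("the simulated cortical contribution behaves as specified", {
  # same seed -> identical records
  a <- simulate_sc_activity(c(300, 900), n_trials = 10, seed = 7)
  b <- simulate_sc_activity(c(300, 900), n_trials = 10, seed = 7)
  expect_identical(a, b)

  # training_scale = 0: LED has no effect on expected rates
  recs0 <- simulate_sc_activity(900, cortical_weight_by_depth = 0.8,
                                training_scale = 0, n_trials = 250, seed = 9)
  er_on <- evoked_response(recs0[[1]], led_on = TRUE, normalize = FALSE)
  er_off <- evoked_response(recs0[[1]], led_on = FALSE, normalize = FALSE)
  expect_equal(mean(er_on$raw), mean(er_off$raw), tolerance = 0.15)

  # LED removes the cortical term in expectation (w=0.5, scale=1 at 100%):
  # control evoked = retinal + 0.5*cortical_gain, silenced = retinal
  recs1 <- simulate_sc_activity(900, contrasts = 100,
                                cortical_weight_by_depth = 0.5,
                                training_scale = 1, n_trials = 400, seed = 11)
  g100 <- 1  # generator CRF is normalized to 1 at 100% contrast
  on1 <- evoked_response(recs1[[1]], led_on = TRUE, normalize = FALSE)$raw
  off1 <- evoked_response(recs1[[1]], led_on = FALSE, normalize = FALSE)$raw
  expect_equal(off1 - on1, 30 * 0.5 * g100, tolerance = 0.2)
})

test_that("the depth profile isolates the cortico-recipient layers", {
  depths <- seq(100, 1500, by = 200)
  w <- ifelse(depths >= 700 & depths <= 1100, 0.6, 0)
  recs <- simulate_sc_activity(depths, cortical_weight_by_depth = w,
                               training_scale = 1, n_trials = 120, seed = 13)
  prof <- silencing_depth_profile(recs)
  expect_equal(prof$control, rep(1, length(depths)))
  mid <- prof$silenced[depths >= 700 & depths <= 1100]
  sup <- prof$silenced[depths < 700]
  expect_true(all(abs(mid - 0.4) < 0.12))   # retinal 12 / (12 + 18) = 0.4
  expect_true(all(abs(sup - 1) < 0.15))

  # with no cortical contribution the ratio is 1 everywhere
  recs0 <- simulate_sc_activity(depths[1:3],
                                cortical_weight_by_depth = rep(0, 3),
                                training_scale = 1, n_trials = 120, seed = 14)
  prof0 <- silencing_depth_profile(recs0)
  expect_true(all(abs(prof0$silenced - 1) < 0.15))

  # swapping LED labels inverts the profile around the control normalization
  swapped <- lapply(recs, function(r) {
    r$trial_events$led_on <- !r$trial_events$led_on
    r
  })
  prof_sw <- silencing_depth_profile(swapped)
  expect_equal(prof_sw$silenced, 1 / prof$silenced, tolerance = 1e-9)

  bad <- recs[[1]]
  bad$trial_events <- bad$trial_events[!bad$trial_events$led_on, ]
  expect_error(silencing_depth_profile(list(bad, recs[[2]])),
               class = "missing_condition")
})
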