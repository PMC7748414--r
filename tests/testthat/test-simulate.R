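test_that("identical profile and seed give byte-identical sessions", {
  p <- default_profiles()
  a <- simulate_session(p$intact, 3, n_trials = 80, seed = 123)
  b <- simulate_session(p$intact, 3, n_trials = 80, seed = 123)
  expect_identical(a, b)
  d <- simulate_session(p$intact, 3, n_trials = 80, seed = 124)
  expect_false(identical(a, d))
  # simulation does not disturb the caller's RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(simulate_session(p$intact, 1, seed = 9))
  expect_identical(runif(3), before)
})

test_that("degenerate schedules hit the aROC limits", {
  perfect <- group_profile("perfect", list(
    day_schedule(q_stim = 1, mu_stim_s = 0.4, cv_stim = 0.05,
                 q_blank = 0, mu_blank_s = 2, cv_blank = 0.5)))
  s <- simulate_session(perfect, 1, n_trials = 200, seed = 1)
  expect_identical(session_aroc(s), 1)

  naive <- group_profile("naive", list(
    day_schedule(0.8, 1.0, 0.7, 0.8, 1.0, 0.7)))
  ar <- vapply(1:5, function(sd) {
    session_aroc(simulate_session(naive, 1, n_trials = 2500, seed = sd))
  }, numeric(1))
  expect_lt(abs(mean(ar) - 0.5), 0.02)
})

test_that("cohorts have one session per mouse-day on independent substreams", {
  p <- default_profiles()
  coh <- simulate_cohort(p$intact, 8, 14, n_trials_per_day = 20, seed = 1)
  expect_length(coh, 112)
  ids <- vapply(coh, `[[`, character(1), "animal_id")
  days <- vapply(coh, `[[`, integer(1), "day")
  expect_equal(nrow(unique(data.frame(ids, days))), 112)
  # same master seed, different mice -> different realizations
  d1 <- Filter(function(s) s$day == 1, coh)
  expect_false(identical(d1[[1]]$trials, d1[[2]]$trials))
})

test_that("day-1 schedules are at chance by construction", {
  p <- default_profiles()
  ar <- vapply(1:8, function(m) {
    session_aroc(simulate_session(p$intact, 1, n_trials = 240,
                                  seed = lickroc:::mix_seed(1, m)))
  }, numeric(1))
  expect_lt(abs(mean(ar) - 0.5), 0.05)
})

test_that("detection probability is monotone in contrast and LED shifts it", {
  p <- default_profiles()
  s <- simulate_session(p$intact, 14, n_trials = 3000, seed = 4,
                        contrasts = c(4, 8, 16, 32, 64, 100),
                        led_fraction = 0.5)
  for (led in c(FALSE, TRUE)) {
    trs <- Filter(function(tr) tr$kind == "stimulus" && tr$led_on == led,
                  s$trials)
    cs <- vapply(trs, `[[`, numeric(1), "contrast")
    licked <- vapply(trs, function(tr)
      classify_trial(tr)$label == "Hit", logical(1))
    rate <- tapply(licked, cs, mean)
    # empirical lick rate rises with contrast (allowing sampling slack)
    expect_gt(rate[["100"]], rate[["4"]])
  }
  # exactly floor(led_fraction * n) LED trials
  expect_equal(sum(vapply(s$trials, `[[`, logical(1), "led_on")), 1500)
})

test_that("generated Miss/CR trials have no in-window licks", {
  p <- default_profiles()
  s <- simulate_session(p$intact, 5, n_trials = 400, seed = 6)
  for (tr in s$trials) {
    oc <- classify_trial(tr)
    if (oc$label %in% c("Miss", "CR")) {
      expect_false(any(tr$lick_times_s >= tr$delay_s &
                         tr$lick_times_s <= tr$response_window_s))
    }
    expect_false(oc$label == "Aborted")  # generator keeps the timeout window clear
  }
})

test_that("default profiles carry the anchored training statistics", {
  p <- default_profiles()
  d4 <- schedule_for_day(p$intact, 4)
  expect_equal(d4$q_stim, 0.899)
  expect_equal(d4$q_blank, 0.816)
  expect_equal(d4$mu_stim_s, 0.77)
  expect_equal(d4$mu_blank_s, 1.01)
  d14 <- schedule_for_day(p$intact, 14)
  expect_equal(d14$mu_stim_s, 0.52)
  # ablation of collicular-projecting neurons leaves learning untouched
  expect_equal(p$`CT-ablated`$days, p$intact$days)
  expect_equal(p$`retroAAV-Cre`$days, p$intact$days)
  # lesion recapitulates the striatal-projection ablation
  expect_equal(p$`VC-lesion`$days, p$`CSt-ablated`$days)
  expect_error(schedule_for_day(p$intact, 99), class = "bad_day")
})

test_that("profiles round-trip through YAML and JSON configs", {
  p <- default_profiles()[c("intact", "CSt-ablated")]
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_profiles(p, path)
    back <- read_profiles(path)
    expect_equal(lapply(back, unclass), lapply(p, unclass),
                 tolerance = 1e-9)
  }
})
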