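# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation calls are referentially pure.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Day schedule of the generative behavior model
#'
#' The per-training-day parameters of the session generator: the probability
#' that a full-contrast stimulus trial elicits a response lick, the mean and
#' coefficient of variation of the stimulus-evoked first-lick latency, and
#' the same three quantities for blank trials. Training shows up as these
#' schedules changing with day: latencies shorten and tighten on stimulus
#' trials while blank-trial licking becomes rarer and later.
#'
#' @param q_stim Probability a full-contrast stimulus trial yields a lick.
#' @param mu_stim_s Mean stimulus-evoked first-lick latency (s).
#' @param cv_stim Coefficient of variation of that latency.
#' @param q_blank Probability a blank trial yields a lick.
#' @param mu_blank_s Mean blank-trial first-lick latency (s).
#' @param cv_blank Its coefficient of variation.
#' @return An object of class `"day_schedule"`.
#' @export
day_schedule <- function(q_stim, mu_stim_s, cv_stim, q_blank, mu_blank_s,
                         cv_blank) {
  stopifnot(q_stim >= 0, q_stim <= 1, q_blank >= 0, q_blank <= 1,
            mu_stim_s > 0, mu_blank_s > 0, cv_stim > 0, cv_blank > 0)
  structure(list(q_stim = q_stim, mu_stim_s = mu_stim_s, cv_stim = cv_stim,
                 q_blank = q_blank, mu_blank_s = mu_blank_s,
                 cv_blank = cv_blank),
            class = "day_schedule")
}

#' Generative profile of a training group
#'
#' Bundles the day-by-day behavioral schedules of one experimental group
#' with its psychometric generating parameters: the contrast threshold and
#' slope of the underlying Weibull detection function, and the
#' multiplicative threshold shift imposed by cortical silencing (early in
#' training and after prolonged training).
#'
#' @param name Group label.
#' @param days List of [day_schedule()] objects, element `d` applying to
#'   training day `d`; days beyond the list reuse the last schedule.
#' @param alpha_gen Generating contrast threshold (%, in (0, 100\]).
#' @param beta_gen Generating psychometric slope (dimensionless > 0).
#' @param silencing_fold Multiplicative threshold shift under the LED
#'   (dimensionless >= 1).
#' @param silencing_fold_late The same shift after prolonged training.
#' @return An object of class `"group_profile"`.
#' @export
group_profile <- function(name, days, alpha_gen = 7.75, beta_gen = 1.8,
                          silencing_fold = 3.4, silencing_fold_late = 1.5) {
  stopifnot(length(days) >= 1, alpha_gen > 0, alpha_gen <= 100,
            beta_gen > 0, silencing_fold >= 1, silencing_fold_late >= 1)
  structure(list(name = name, days = days, alpha_gen = alpha_gen,
                 beta_gen = beta_gen, silencing_fold = silencing_fold,
                 silencing_fold_late = silencing_fold_late),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf(
    "<group_profile> %s: %d scheduled days, alpha %.2f%%, beta %.2f, silencing fold %.2f -> %.2f\n",
    x$name, length(x$days), x$alpha_gen, x$beta_gen, x$silencing_fold,
    x$silencing_fold_late))
  invisible(x)
}

#' @export
#' @rdname group_profile
schedule_for_day <- function(profile, day) {
  stopifnot(day >= 1)
  if (day > length(profile$days)) {
    stop_lickroc(sprintf("day %d outside the %d-day schedule of profile '%s'",
                         day, length(profile$days), profile$name),
                 "bad_day")
  }
  profile$days[[day]]
}

# Piecewise-linear interpolation of every schedule field between anchor days.
.interp_schedules <- function(anchors, n_days) {
  ad <- as.integer(names(anchors))
  stopifnot(!is.unsorted(ad), ad[1] == 1)
  fields <- names(anchors[[1]])
  lapply(seq_len(n_days), function(d) {
    vals <- lapply(fields, function(f) {
      y <- vapply(anchors, `[[`, numeric(1), f)
      stats::approx(ad, y, xout = min(d, max(ad)), rule = 2)$y
    })
    names(vals) <- fields
    do.call(day_schedule, vals)
  })
}

# Calibrated schedule constants. Day-1 and day-4 anchors carry the reference
# early-training statistics; the day-14 stimulus anchors carry the reference
# trained-state statistics. Remaining day-14/21 fields are free constants
# calibrated by cohort simulation (scripts/calibrate_profiles.R) so that the
# emergent population learning curves hit the trained-state anchors
# (day-14 aROC, day 1-14 slope, latency variance/mean).
.intact_anchors <- function() list(
  `1` = list(q_stim = 0.90, mu_stim_s = 1.00, cv_stim = 0.8,
             q_blank = 0.90, mu_blank_s = 1.00, cv_blank = 0.8),
  `4` = list(q_stim = 0.899, mu_stim_s = 0.77, cv_stim = 0.6,
             q_blank = 0.816, mu_blank_s = 1.01, cv_blank = 0.6),
  `14` = list(q_stim = 0.97, mu_stim_s = 0.52, cv_stim = 0.56,
              q_blank = 0.70, mu_blank_s = 1.60, cv_blank = 0.80),
  `21` = list(q_stim = 0.98, mu_stim_s = 0.45, cv_stim = 0.52,
              q_blank = 0.58, mu_blank_s = 1.80, cv_blank = 0.80))

.cst_anchors <- function() list(
  `1` = list(q_stim = 0.90, mu_stim_s = 1.00, cv_stim = 0.8,
             q_blank = 0.90, mu_blank_s = 1.00, cv_blank = 0.8),
  `14` = list(q_stim = 0.942, mu_stim_s = 0.79, cv_stim = 0.62,
              q_blank = 0.815, mu_blank_s = 1.20, cv_blank = 0.70),
  `21` = list(q_stim = 0.97, mu_stim_s = 0.58, cv_stim = 0.56,
              q_blank = 0.72, mu_blank_s = 1.50, cv_blank = 0.78))

#' Default group profiles
#'
#' Calibrated generative profiles for the five experimental groups: `intact`,
#' `retroAAV-Cre` (injection control, behaviorally identical to intact),
#' `CT-ablated` (ablation of collicular-projecting cortical neurons, which
#' leaves task learning intact), `CSt-ablated` (ablation of
#' striatal-projecting neurons, which halves the learning rate), and
#' `VC-lesion` (surgical cortical lesion, which recapitulates the CSt
#' impairment). Schedules are piecewise-linear in training day between the
#' anchor days; days 15–21 continue toward the intact plateau.
#'
#' @param n_days Number of scheduled days per profile (default 21).
#' @return Named list of [group_profile()] objects.
#' @export
default_profiles <- function(n_days = 21) {
  intact_days <- .interp_schedules(.intact_anchors(), n_days)
  cst_days <- .interp_schedules(.cst_anchors(), n_days)
  list(
    `intact` = group_profile("intact", intact_days),
    `retroAAV-Cre` = group_profile("retroAAV-Cre", intact_days),
    `CT-ablated` = group_profile("CT-ablated", intact_days),
    `CSt-ablated` = group_profile("CSt-ablated", cst_days),
    `VC-lesion` = group_profile("VC-lesion", cst_days)
  )
}

#' Serialize group profiles to a config file
#'
#' Writes (or reads back) profiles as YAML or JSON with the same field names
#' as [group_profile()] and [day_schedule()]; the format is chosen by the
#' file extension (`.json` for JSON, anything else YAML).
#'
#' @param profiles Named list of [group_profile()] objects.
#' @param path Output (or input) file path.
#' @return `write_profiles()`: `path` invisibly. `read_profiles()`: a named
#'   list of profiles.
#' @export
write_profiles <- function(profiles, path) {
  lst <- lapply(profiles, function(p) {
    list(name = p$name, days = lapply(p$days, unclass),
         alpha_gen = p$alpha_gen, beta_gen = p$beta_gen,
         silencing_fold = p$silencing_fold,
         silencing_fold_late = p$silencing_fold_late)
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = 10)
  } else {
    writeLines(yaml::as.yaml(lst, precision = 12), path)
  }
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(lst, function(p) {
    group_profile(p$name, lapply(p$days, function(d) do.call(day_schedule, d)),
                  alpha_gen = p$alpha_gen, beta_gen = p$beta_gen,
                  silencing_fold = p$silencing_fold,
                  silencing_fold_late = p$silencing_fold_late)
  })
}

# Weibull detection CDF used by the generator (0 at c = 0, saturating at 1).
.fw <- function(contrast, alpha, beta) 1 - exp(-(contrast / alpha)^beta)

# Slowing of the evoked latency near threshold: the mean is inflated by
# 1 + 0.5 * (1 - F_w(c)), so full-contrast latencies are unchanged and
# near-threshold ones up to 1.5x slower.
.latency_slowing <- 0.5

#' Simulate one behavioral session
#'
#' Draws a seeded synthetic session from a group profile. Stimulus trials
#' lick with probability `q(c) = q_blank + (q_stim - q_blank) * F_w(c)`,
#' where `F_w` is the group's generating Weibull detection function and its
#' threshold is multiplied by the silencing fold on LED trials. First-lick
#' latencies are Gamma-distributed with the scheduled mean and CV, truncated
#' to the `[delay, response window]` interval; near-threshold contrasts slow
#' the evoked latency. Blank trials use the blank schedule. Spontaneous
#' gray-screen licks are generated as an exponential renewal train during
#' the inter-trial interval (outside the pre-stimulus timeout window, so
#' generated trials are never aborted). Identical arguments and seed yield a
#' byte-identical session.
#'
#' @param profile A [group_profile()].
#' @param day Training day (within the profile's schedule).
#' @param n_trials Number of trials (default 240).
#' @param p_blank Fraction of blank trials (default 0.25); realized as
#'   exactly `round(p_blank * n_trials)` blank trials at random positions.
#' @param contrasts Stimulus contrasts (%) cycled in shuffled blocks over
#'   stimulus trials (default 100, full-contrast training).
#' @param led_fraction Fraction of LED (silencing) trials; realized as
#'   exactly `floor(led_fraction * n_trials)` trials at positions drawn
#'   without replacement.
#' @param seed Integer seed; all randomness in the session flows from it.
#' @param animal_id,iti_s,jitter_max_s Session metadata (see [session()]).
#' @param delay_s Unrewarded delay after stimulus onset (s).
#' @param response_window_s Response window (s).
#' @param ili_mean_s Mean inter-lick interval of spontaneous licking (s),
#'   default 1.3.
#' @param silencing_fold Override of the profile's silencing fold (used by
#'   training-duration sweeps); `NULL` uses `profile$silencing_fold`.
#' @return A [session()] object.
#' @export
simulate_session <- function(profile, day, n_trials = 240, p_blank = 0.25,
                             contrasts = 100, led_fraction = 0, seed = 1,
                             animal_id = "m1", iti_s = 3, jitter_max_s = 2,
                             delay_s = 0.25, response_window_s = 4,
                             ili_mean_s = 1.3, silencing_fold = NULL) {
  stopifnot(n_trials >= 1, p_blank >= 0, p_blank < 1,
            led_fraction >= 0, led_fraction <= 1, all(contrasts > 0))
  sch <- schedule_for_day(profile, day)
  fold <- silencing_fold %||% profile$silencing_fold
  with_seed(seed, {
    n_blank <- round(p_blank * n_trials)
    blank_pos <- sample.int(n_trials, n_blank)
    is_blank <- seq_len(n_trials) %in% blank_pos
    n_led <- floor(led_fraction * n_trials)
    led <- seq_len(n_trials) %in% sample.int(n_trials, n_led)

    contrast <- numeric(n_trials)
    n_stim <- n_trials - n_blank
    cvec <- rep(contrasts, length.out = n_stim)
    contrast[!is_blank] <- cvec[sample.int(n_stim)]

    alpha_eff <- ifelse(led, profile$alpha_gen * fold, profile$alpha_gen)
    fw <- ifelse(is_blank, 0, .fw(contrast, alpha_eff, profile$beta_gen))
    p_lick <- ifelse(is_blank, sch$q_blank,
                     sch$q_blank + (sch$q_stim - sch$q_blank) * fw)
    licked <- stats::runif(n_trials) < p_lick

    mu <- ifelse(is_blank, sch$mu_blank_s,
                 sch$mu_stim_s * (1 + .latency_slowing * (1 - fw)))
    cv <- ifelse(is_blank, sch$cv_blank, sch$cv_stim)
    lat <- rep(NA_real_, n_trials)
    # vector draw: qgamma vectorizes over shape/rate, one uniform per trial
    shape <- 1 / cv^2
    rate <- shape / mu
    p_lo <- stats::pgamma(delay_s, shape, rate)
    p_hi <- stats::pgamma(response_window_s, shape, rate)
    u <- stats::runif(n_trials, p_lo, p_hi)
    lat_all <- stats::qgamma(u, shape, rate)
    lat[licked] <- lat_all[licked]

    # spontaneous gray-screen licks during the ITI + jitter, kept clear of
    # the timeout window so no generated trial aborts
    jit <- stats::runif(n_trials, 0, jitter_max_s)
    gray <- pmax(iti_s + jit - 1.5, 0)
    kmax <- max(1L, ceiling(max(gray) / ili_mean_s) + 4L)
    gaps <- matrix(stats::rexp(n_trials * kmax, rate = 1 / ili_mean_s),
                   nrow = n_trials)
    at <- t(apply(gaps, 1, cumsum))

    trs <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      spont <- at[i, at[i, ] < gray[i]] - 1.5 - gray[i]
      licks <- c(spont, if (licked[i]) lat[i])
      trs[[i]] <- trial(i, if (is_blank[i]) "blank" else "stimulus",
                        contrast = if (is_blank[i]) 0 else contrast[i],
                        led_on = led[i], delay_s = delay_s,
                        response_window_s = response_window_s,
                        lick_times_s = licks)
    }
    session(animal_id, day, profile$name, trs, iti_s = iti_s,
            jitter_max_s = jitter_max_s, pre_stim_timeout_window_s = 1.5)
  })
}

#' Simulate a training cohort
#'
#' One session per mouse per training day, with per-mouse, per-day random
#' substreams derived deterministically from the master seed (a counter-based
#' mixing scheme, platform-stable), so cohorts are reproducible and mice are
#' mutually independent.
#'
#' @param profile A [group_profile()].
#' @param n_mice Number of mice.
#' @param n_days Number of training days.
#' @param n_trials_per_day Trials per session (default 240).
#' @param seed Master integer seed.
#' @param ... Further arguments passed to [simulate_session()].
#' @return List of `n_mice * n_days` [session()] objects, ordered by mouse
#'   then day.
#' @export
simulate_cohort <- function(profile, n_mice, n_days, n_trials_per_day = 240,
                            seed = 1, ...) {
  stopifnot(n_mice >= 1, n_days >= 1, n_trials_per_day >= 1)
  out <- vector("list", n_mice * n_days)
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (d in seq_len(n_days)) {
      k <- k + 1L
      out[[k]] <- simulate_session(
        profile, d, n_trials = n_trials_per_day,
        seed = mix_seed(seed, m, d),
        animal_id = sprintf("%s_m%02d", profile$name, m), ...)
    }
  }
  out
}
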