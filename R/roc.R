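#' Latency sample with censoring metadata
#'
#' Container for first-lick latencies of one trial type. Trials without an
#' in-window lick (Misses, Correct Rejections) carry the censor value, a
#' surrogate timestamp just outside the response window, so that changes in
#' lick probability — not only lick timing — enter the ROC comparison.
#'
#' @param values_s Numeric vector of latencies (s); each value is either in
#'   \[0, `window_s`\] or equal to `censor_s`.
#' @param censor_s Censor timestamp (s), default 4.1; must exceed `window_s`.
#' @param window_s Response-window duration (s), default 4.
#' @param bin_s Latency bin width (s), default 0.1.
#' @return An object of class `"latency_sample"`.
#' @export
latency_sample <- function(values_s, censor_s = 4.1, window_s = 4,
                           bin_s = 0.1) {
  stopifnot(censor_s > window_s, bin_s > 0)
  values_s <- as.numeric(values_s)
  ok <- (values_s >= 0 & values_s <= window_s) | values_s == censor_s
  if (!all(ok)) {
    stop_lickroc("latencies must lie in [0, window_s] or equal censor_s",
                 "malformed_sample")
  }
  structure(list(values_s = values_s, censor_s = censor_s,
                 window_s = window_s, bin_s = bin_s),
            class = "latency_sample")
}

#' Censored first-lick latency samples for a set of trials
#'
#' Classifies trials, drops aborted ones, and returns the stimulus- and
#' blank-trial latency samples with Misses and Correct Rejections mapped to
#' the censor timestamp (default 4.1 s, i.e. just outside the 4 s window).
#'
#' @param trials List of [trial()] objects.
#' @param censor_s Censor timestamp (s).
#' @param bin_s Bin width (s) recorded on the samples (binning itself happens
#'   inside [aroc()]).
#' @param pre_stim_timeout_window_s Abort-window width (s) passed to
#'   [classify_trial()].
#' @return A list with elements `stim` and `blank`, both [latency_sample()]
#'   objects; their lengths equal the non-aborted stimulus and blank trial
#'   counts.
#' @export
censored_latencies <- function(trials, censor_s = 4.1, bin_s = 0.1,
                               pre_stim_timeout_window_s = 1.5) {
  if (length(trials) == 0) stop_lickroc("no trials", "empty_input")
  window_s <- trials[[1]]$response_window_s
  oc <- classify_trials(trials, pre_stim_timeout_window_s)
  lab <- vapply(oc, `[[`, character(1), "label")
  lat <- vapply(oc, `[[`, numeric(1), "first_lick_latency_s")
  kind <- vapply(trials, `[[`, character(1), "kind")
  keep <- lab != "Aborted"
  cens <- ifelse(is.na(lat), censor_s, lat)
  list(stim = latency_sample(cens[keep & kind == "stimulus"], censor_s,
                             window_s, bin_s),
       blank = latency_sample(cens[keep & kind == "blank"], censor_s,
                              window_s, bin_s))
}

# Map latencies to 100 ms bin indices over [0, window]; the censor value gets
# its own terminal bin. A latency exactly at the window edge falls in the
# last in-window bin.
.bin_latencies <- function(s) {
  nb <- ceiling(s$window_s / s$bin_s - 1e-9)
  idx <- pmin(floor(s$values_s / s$bin_s), nb - 1)
  idx[s$values_s == s$censor_s] <- nb
  idx
}

#' Area under the ROC curve for censored latency samples
#'
#' The core performance statistic: both samples are binned (default 100 ms
#' bins over the 0–4 s response window, plus one terminal bin holding the
#' censored no-lick trials), an ROC curve is traced by sweeping a latency
#' threshold over the bin edges with "stimulus lick earlier" as the positive
#' direction, and the area is integrated by the trapezoid rule. With this
#' construction the area equals the rank statistic
#' P(L_stim < L_blank) + 1/2 P(L_stim = L_blank) on binned values: 0.5 means
#' the two latency distributions are indistinguishable, 1 means every
#' stimulus-trial lick preceded every blank-trial one.
#'
#' @param stim,blank [latency_sample()] objects for stimulus and blank
#'   trials; must share the window, bin and censor settings.
#' @return The area, a probability in \[0, 1\].
#' @examples
#' s <- latency_sample(c(0.5, 1.5)); b <- latency_sample(c(1.0, 2.0))
#' aroc(s, b)  # 0.75
#' @export
aroc <- function(stim, blank) {
  stopifnot(inherits(stim, "latency_sample"), inherits(blank, "latency_sample"))
  if (length(stim$values_s) == 0 || length(blank$values_s) == 0) {
    stop_lickroc("empty latency sample", "empty_input")
  }
  if (stim$bin_s != blank$bin_s || stim$window_s != blank$window_s ||
      stim$censor_s != blank$censor_s) {
    stop_lickroc("samples must share window/bin/censor settings",
                 "malformed_sample")
  }
  nb <- ceiling(stim$window_s / stim$bin_s - 1e-9)
  bs <- .bin_latencies(stim)
  bb <- .bin_latencies(blank)
  # cumulative "licked before edge k" proportions, k = 0..nb+1
  edges <- 0:(nb + 1)
  tpr <- vapply(edges, function(k) mean(bs < k), numeric(1))
  fpr <- vapply(edges, function(k) mean(bb < k), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Windowed hit/false-alarm rates and d-prime
#'
#' Lick probabilities, unlike the censored-latency aROC, depend strongly on
#' how much of the response window is counted. This computes the hit and
#' false-alarm rates for licks occurring within `window_s` seconds of onset
#' and the sensitivity index d' = qnorm(hit) - qnorm(fa). Rates are clipped
#' to \[1/(2N), 1 - 1/(2N)\] (N the trial count of that type) before the
#' quantile transform so extreme rates stay finite.
#'
#' @param trials List of [trial()] objects.
#' @param window_s Analysis window (s), in (0, full response window\].
#' @param pre_stim_timeout_window_s Abort-window width (s).
#' @return A list of class `"sdt_summary"`: `hit_rate`, `fa_rate`, `d_prime`,
#'   `window_s`, `n_stim`, `n_blank`.
#' @export
rates_and_dprime <- function(trials, window_s = NULL,
                             pre_stim_timeout_window_s = 1.5) {
  full <- trials[[1]]$response_window_s
  window_s <- window_s %||% full
  stopifnot(window_s > 0, window_s <= full)
  cl <- censored_latencies(trials,
                           pre_stim_timeout_window_s = pre_stim_timeout_window_s)
  ns <- length(cl$stim$values_s)
  nbl <- length(cl$blank$values_s)
  if (ns == 0 || nbl == 0) stop_lickroc("need both trial types", "empty_input")
  hit <- mean(cl$stim$values_s <= window_s)
  fa <- mean(cl$blank$values_s <= window_s)
  clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  dp <- stats::qnorm(clip(hit, ns)) - stats::qnorm(clip(fa, nbl))
  structure(list(hit_rate = hit, fa_rate = fa, d_prime = dp,
                 window_s = window_s, n_stim = ns, n_blank = nbl),
            class = "sdt_summary")
}

#' @export
print.sdt_summary <- function(x, ...) {
  cat(sprintf("window %.2f s: hit %.3f, FA %.3f, d' = %.3f (n=%d/%d)\n",
              x$window_s, x$hit_rate, x$fa_rate, x$d_prime, x$n_stim,
              x$n_blank))
  invisible(x)
}

#' Optimal response window maximizing d-prime
#'
#' Evaluates [rates_and_dprime()] on a grid of candidate window durations and
#' returns the one with maximal d'; ties go to the shortest window. The
#' default grid steps in 0.1 s from 0.1 to 4 s, matching the latency binning.
#'
#' @param trials List of [trial()] objects.
#' @param grid Ascending vector of window durations (s).
#' @param pre_stim_timeout_window_s Abort-window width (s).
#' @return A list with `window_s` (the optimum) and `summary` (its
#'   `"sdt_summary"`).
#' @export
optimal_window <- function(trials, grid = seq(0.1, 4, by = 0.1),
                           pre_stim_timeout_window_s = 1.5) {
  if (length(grid) == 0 || is.unsorted(grid, strictly = TRUE)) {
    stop_lickroc("grid must be non-empty and ascending", "bad_grid")
  }
  best <- NULL
  for (w in grid) {
    s <- rates_and_dprime(trials, w, pre_stim_timeout_window_s)
    if (is.null(best) || s$d_prime > best$d_prime) best <- s
  }
  list(window_s = best$window_s, summary = best)
}

#' Trial-to-trial variability of first-lick latencies
#'
#' The variance-to-mean ratio (in seconds) of first-lick latencies, computed
#' with the n-1 variance denominator. By convention it is evaluated on Hit
#' latencies of a training day (or FA latencies, when blank-trial timing is
#' of interest).
#'
#' @param latencies_s Numeric vector of at least two latencies (s).
#' @return Variance/mean, in seconds.
#' @export
variability <- function(latencies_s) {
  if (length(latencies_s) < 2 || anyNA(latencies_s)) {
    stop_lickroc("need >= 2 latencies", "undefined_result")
  }
  stats::var(latencies_s) / mean(latencies_s)
}

#' Mean inter-lick interval of spontaneous lick trains
#'
#' Pools successive lick-time differences over all trains and returns their
#' mean. Trains with fewer than two licks contribute nothing; if no train has
#' two licks the result is undefined and an error is raised.
#'
#' @param lick_trains List of ascending numeric vectors of lick times (s).
#' @return Mean inter-lick interval (s).
#' @export
inter_lick_intervals <- function(lick_trains) {
  difs <- unlist(lapply(lick_trains, function(tr) {
    if (length(tr) >= 2) {
      if (any(diff(tr) <= 0)) stop_lickroc("train not ascending",
                                           "malformed_trial")
      diff(tr)
    } else numeric()
  }))
  if (length(difs) == 0) stop_lickroc("no train with >= 2 licks",
                                      "undefined_result")
  mean(difs)
}

#' Spontaneous (gray-screen) lick trains of a session
#'
#' Extracts, per trial, the pre-stimulus lick times that fall before the
#' timeout window — i.e. licks emitted during the gray-screen inter-trial
#' period — for use with [inter_lick_intervals()].
#'
#' @param session A [session()] object.
#' @return List of ascending lick-time vectors (s, relative to onset), one
#'   per trial with any such licks.
#' @export
spontaneous_lick_trains <- function(session) {
  w <- session$pre_stim_timeout_window_s
  trains <- lapply(session$trials, function(tr) {
    tr$lick_times_s[tr$lick_times_s < -w]
  })
  trains[vapply(trains, length, integer(1)) > 0]
}

#' Censored-latency aROC of one session
#'
#' Convenience wrapper: classify, censor, and compute the area under the ROC
#' curve for a whole session (optionally restricted to one contrast and/or
#' LED condition).
#'
#' @param session A [session()] object.
#' @param contrast If non-`NULL`, restrict stimulus trials to this contrast
#'   (%); blank trials are always included.
#' @param led_on If non-`NULL`, restrict to trials with this LED state.
#' @param censor_s,bin_s Censoring timestamp and bin width (s).
#' @return aROC in \[0, 1\].
#' @export
session_aroc <- function(session, contrast = NULL, led_on = NULL,
                         censor_s = 4.1, bin_s = 0.1) {
  trs <- session$trials
  if (!is.null(led_on)) {
    trs <- Filter(function(tr) tr$led_on == led_on, trs)
  }
  if (!is.null(contrast)) {
    trs <- Filter(function(tr) tr$kind == "blank" || tr$contrast == contrast,
                  trs)
  }
  cl <- censored_latencies(trs, censor_s = censor_s, bin_s = bin_s,
                           pre_stim_timeout_window_s =
                             session$pre_stim_timeout_window_s)
  aroc(cl$stim, cl$blank)
}
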