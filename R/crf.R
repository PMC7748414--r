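#' Spike record at one recording depth
#'
#' Event-aligned multi-unit spike data from one electrode site: absolute
#' spike times plus the trial events (stimulus onsets with contrast and LED
#' state) they are aligned to. Spike sorting is upstream of this package;
#' the record consumes multi-unit event times directly.
#'
#' @param depth_um Recording depth (micrometers below the surface), > 0.
#' @param spike_times_s Ascending numeric vector of spike times (s).
#' @param trial_events Data frame with columns `onset_s`, `contrast`
#'   (percent), `led_on` (logical).
#' @return Object of class `"spike_record"`.
#' @export
spike_record <- function(depth_um, spike_times_s, trial_events) {
  stopifnot(depth_um > 0,
            all(c("onset_s", "contrast", "led_on") %in% names(trial_events)))
  spike_times_s <- as.numeric(spike_times_s)
  if (is.unsorted(spike_times_s)) {
    stop_lickroc("spike times must be ascending", "malformed_record")
  }
  structure(list(depth_um = depth_um, spike_times_s = spike_times_s,
                 trial_events = trial_events),
            class = "spike_record")
}

#' Peristimulus time histogram
#'
#' Spike counts aligned to stimulus onsets, binned, averaged over the trials
#' of each condition (contrast x LED combination) and divided by the bin
#' width to give firing rates in Hz.
#'
#' @param record A [spike_record()].
#' @param pre_s Seconds before onset to include (default 0.2).
#' @param post_s Seconds after onset (default 0.5).
#' @param bin_s Bin width (s, default 0.01); must divide `pre_s + post_s`
#'   evenly.
#' @return List with `time_s` (bin centers relative to onset), `rate` (a
#'   conditions x bins matrix of Hz, rows named `contrast/led`), and
#'   `n_trials` per condition.
#' @export
psth <- function(record, pre_s = 0.2, post_s = 0.5, bin_s = 0.01) {
  total <- pre_s + post_s
  nb <- total / bin_s
  if (abs(nb - round(nb)) > 1e-9) {
    stop_lickroc("bin_s must divide pre_s + post_s evenly", "bad_bins")
  }
  nb <- as.integer(round(nb))
  ev <- record$trial_events
  cond <- paste0(ev$contrast, "/", ifelse(ev$led_on, "on", "off"))
  levs <- unique(cond)
  edges <- seq(-pre_s, post_s, by = bin_s)
  counts <- matrix(0, length(levs), nb, dimnames = list(levs, NULL))
  ntr <- stats::setNames(integer(length(levs)), levs)
  for (i in seq_len(nrow(ev))) {
    rel <- record$spike_times_s - ev$onset_s[i]
    rel <- rel[rel >= -pre_s & rel < post_s]
    h <- tabulate(pmin(floor((rel + pre_s) / bin_s) + 1L, nb), nbins = nb)
    counts[cond[i], ] <- counts[cond[i], ] + h
    ntr[cond[i]] <- ntr[cond[i]] + 1L
  }
  rate <- counts / ntr / bin_s
  list(time_s = edges[-length(edges)] + bin_s / 2, rate = rate,
       n_trials = ntr)
}

# Mean firing rate (Hz) in [onset + from, onset + to) averaged over events.
.epoch_rate <- function(spikes, onsets, from, to) {
  if (length(onsets) == 0) return(NA_real_)
  n <- vapply(onsets, function(o) {
    sum(spikes >= o + from & spikes < o + to)
  }, numeric(1))
  mean(n) / (to - from)
}

#' Baseline-subtracted evoked response per contrast
#'
#' For each stimulus contrast of one LED condition, the mean firing rate in
#' the evoked epoch (default the first 100 ms after onset) minus the mean
#' rate in the baseline epoch (default the 100 ms before onset), normalized
#' to the maximum across contrasts of the control (LED-off) condition. Both
#' epochs are configurable.
#'
#' @param record A [spike_record()].
#' @param led_on Condition to evaluate (default `FALSE`, control).
#' @param baseline_s,evoked_s Epoch durations (s), default 0.1 each.
#' @param normalize Divide by the control-condition maximum (default TRUE).
#' @param norm_max Optional externally supplied normalization constant.
#' @return Data frame with `contrast`, `response` (normalized when
#'   requested) and `raw` (Hz).
#' @export
evoked_response <- function(record, led_on = FALSE, baseline_s = 0.1,
                            evoked_s = 0.1, normalize = TRUE,
                            norm_max = NULL) {
  ev <- record$trial_events
  sel <- ev[ev$led_on == led_on, , drop = FALSE]
  if (nrow(sel) == 0) stop_lickroc("no trials in requested condition",
                                   "empty_input")
  cs <- sort(unique(sel$contrast))
  raw <- vapply(cs, function(cc) {
    on <- sel$onset_s[sel$contrast == cc]
    .epoch_rate(record$spike_times_s, on, 0, evoked_s) -
      .epoch_rate(record$spike_times_s, on, -baseline_s, 0)
  }, numeric(1))
  if (normalize) {
    if (is.null(norm_max)) {
      ctrl <- ev[!ev$led_on, , drop = FALSE]
      norm_max <- max(vapply(sort(unique(ctrl$contrast)), function(cc) {
        on <- ctrl$onset_s[ctrl$contrast == cc]
        .epoch_rate(record$spike_times_s, on, 0, evoked_s) -
          .epoch_rate(record$spike_times_s, on, -baseline_s, 0)
      }, numeric(1)))
    }
    if (!is.finite(norm_max) || norm_max <= 0) {
      stop_lickroc("control maximum is not positive; cannot normalize",
                   "normalization_failure")
    }
    resp <- raw / norm_max
  } else resp <- raw
  data.frame(contrast = cs, response = resp, raw = raw)
}

#' Hyperbolic-ratio contrast response function
#'
#' `r(x) = r_max * x^n / (x^n + x50^n)`: saturating contrast dependence with
#' saturation level `r_max`, shape exponent `n` and semi-saturation contrast
#' `x50` (the contrast at which the response reaches `r_max / 2`).
#'
#' @param x Contrast (%) (vectorized).
#' @param r_max Saturation level, > 0.
#' @param n Exponent, > 0.
#' @param x50 Semi-saturation contrast (%), > 0.
#' @return Response value(s).
#' @export
crf <- function(x, r_max, n, x50) {
  if (r_max <= 0 || n <= 0 || x50 <= 0) {
    stop_lickroc("all parameters must be positive", "bad_parameters")
  }
  r_max * x^n / (x^n + x50^n)
}

#' Fit the hyperbolic-ratio contrast response function
#'
#' Bounded least squares (`r_max` in (0, 2\], `n` in (0, 6\], `x50` in
#' (0, 100\]) via multi-start L-BFGS-B on normalized evoked responses.
#'
#' @param contrasts Contrasts (%), >= 4 points.
#' @param responses Evoked responses, same length.
#' @return Object of class `"crf_fit"` with `r_max`, `n_exp`, `x50`, `rss`,
#'   data, and convergence diagnostics.
#' @export
fit_crf <- function(contrasts, responses) {
  stopifnot(length(contrasts) == length(responses))
  keep <- !is.na(responses)
  x <- contrasts[keep]; y <- responses[keep]
  if (length(x) < 4) stop_lickroc("need >= 4 points", "too_few_points")
  loss <- function(p) sum((y - crf(x, p[1], p[2], p[3]))^2)
  lower <- c(1e-3, 1e-2, 1e-2)
  upper <- c(2, 6, 100)
  best <- NULL
  for (x0 in c(5, 10, 20, 40, 80)) {
    for (n0 in c(1, 2, 4)) {
      fit <- tryCatch(
        stats::optim(c(max(min(max(y), 2), 0.1), n0, x0), loss,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) stop_lickroc("CRF fit failed to converge", "fit_failure")
  structure(list(r_max = best$par[1], n_exp = best$par[2], x50 = best$par[3],
                 rss = best$value, contrasts = x, responses = y,
                 convergence = list(code = best$convergence)),
            class = "crf_fit")
}

#' @export
print.crf_fit <- function(x, ...) {
  cat(sprintf(
    "hyperbolic-ratio CRF fit: r_max = %.3f, n = %.2f, x50 = %.2f%% (RSS %.2e)\n",
    x$r_max, x$n_exp, x$x50, x$rss))
  invisible(x)
}

#' @export
coef.crf_fit <- function(object, ...) {
  c(r_max = object$r_max, n = object$n_exp, x50 = object$x50)
}

#' @export
predict.crf_fit <- function(object, contrasts = object$contrasts, ...) {
  crf(contrasts, object$r_max, object$n_exp, object$x50)
}

#' @export
residuals.crf_fit <- function(object, ...) {
  object$responses - predict(object)
}

#' @export
plot.crf_fit <- function(x, ...) {
  xx <- seq(min(x$contrasts[x$contrasts > 0]) / 2, 100, length.out = 200)
  graphics::plot(x$contrasts, x$responses, pch = 16, log = "x",
                 xlab = "contrast (%)", ylab = "normalized response", ...)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(v = x$x50, lty = 3)
  invisible(x)
}

#' Depth profile of evoked activity under cortical silencing
#'
#' For each recording depth, the baseline-subtracted evoked response under
#' both LED conditions, with the silenced response expressed relative to the
#' control response at that depth (control = 1). The dip of the silenced
#' profile across intermediate depths quantifies the cortical contribution
#' to collicular visual responses.
#'
#' @param records List of [spike_record()] objects at >= 2 distinct depths.
#' @param ... Passed to [evoked_response()] (epoch settings).
#' @return Data frame with `depth_um`, `control` (always 1), `silenced`
#'   (ratio), `raw_control`, `raw_silenced` (Hz), ordered by depth.
#' @export
silencing_depth_profile <- function(records, ...) {
  if (length(records) < 2) stop_lickroc("need >= 2 depths", "too_few_points")
  rows <- lapply(records, function(r) {
    ev <- r$trial_events
    if (!any(ev$led_on) || !any(!ev$led_on)) {
      stop_lickroc(sprintf("missing LED condition at depth %.0f um",
                           r$depth_um), "missing_condition")
    }
    ctl <- evoked_response(r, led_on = FALSE, normalize = FALSE, ...)
    sil <- evoked_response(r, led_on = TRUE, normalize = FALSE, ...)
    # pool over contrasts: mean evoked rate per condition
    rc <- mean(ctl$raw); rs <- mean(sil$raw)
    data.frame(depth_um = r$depth_um, control = 1, silenced = rs / rc,
               raw_control = rc, raw_silenced = rs)
  })
  out <- do.call(rbind, rows)
  out[order(out$depth_um), , drop = FALSE]
}

#' Simulate collicular multi-unit activity across depths
#'
#' Poisson spike generator for the silencing experiment: the firing rate of
#' a site at depth `d` on a trial of contrast `c` is
#' `baseline + [retinal_hz + cortical_gain_hz * w(d) * training_scale * (1 - led)] * g(c)`
#' during the evoked epoch and `baseline` otherwise, where `g` is a
#' hyperbolic-ratio contrast function normalized to 1 at saturation and
#' `w(d)` is the depth profile of the cortical contribution. Silencing
#' (`led = 1`) removes exactly the cortical term in expectation; with
#' `training_scale = 0` the LED has no effect, emulating the vanishing
#' cortical dependence after prolonged training.
#'
#' @param depths_um Recording depths (um).
#' @param contrasts Stimulus contrasts (%).
#' @param cortical_weight_by_depth Weights `w(d)` in \[0, 1\], same length as
#'   `depths_um`.
#' @param training_scale Scale of the cortical contribution in \[0, 1\]
#'   (1 = early training, 0 = fully trained).
#' @param n_trials Trials per contrast x LED condition.
#' @param seed Integer seed.
#' @param baseline_hz,retinal_hz,cortical_gain_hz Rate components (Hz).
#' @param crf_n,crf_x50 Parameters of the generating contrast function.
#' @param evoked_dur_s Duration of the evoked epoch (s, default 0.1).
#' @return List of [spike_record()] objects, one per depth; each contrast
#'   appears `n_trials` times per LED state, randomly interleaved.
#' @export
simulate_sc_activity <- function(depths_um, contrasts = c(4, 8, 16, 32, 64, 100),
                                 cortical_weight_by_depth =
                                   rep(0.5, length(depths_um)),
                                 training_scale = 1, n_trials = 50, seed = 1,
                                 baseline_hz = 5, retinal_hz = 12,
                                 cortical_gain_hz = 30, crf_n = 2,
                                 crf_x50 = 20, evoked_dur_s = 0.1) {
  stopifnot(length(cortical_weight_by_depth) == length(depths_um),
            all(cortical_weight_by_depth >= 0),
            all(cortical_weight_by_depth <= 1),
            training_scale >= 0, training_scale <= 1, n_trials >= 1)
  # hyperbolic-ratio contrast weighting normalized so g(100) = 1
  g <- (contrasts^crf_n / (contrasts^crf_n + crf_x50^crf_n)) /
    (100^crf_n / (100^crf_n + crf_x50^crf_n))
  grid <- expand.grid(contrast = contrasts, led_on = c(FALSE, TRUE),
                      rep = seq_len(n_trials))
  lapply(seq_along(depths_um), function(k) {
    with_seed(mix_seed(seed, k), {
      ord <- sample.int(nrow(grid))
      ev <- grid[ord, c("contrast", "led_on")]
      ev$onset_s <- 3 * seq_len(nrow(ev))
      w <- cortical_weight_by_depth[k]
      gain <- retinal_hz +
        cortical_gain_hz * w * training_scale * (1 - ev$led_on)
      evoked_rate <- baseline_hz +
        gain * g[match(ev$contrast, contrasts)]
      # piecewise-constant Poisson process around each onset
      spikes <- unlist(lapply(seq_len(nrow(ev)), function(i) {
        o <- ev$onset_s[i]
        nb <- stats::rpois(1, baseline_hz * 1.0)          # [-0.5, 0.5) base
        ne <- stats::rpois(1, (evoked_rate[i] - baseline_hz) * evoked_dur_s)
        c(stats::runif(nb, o - 0.5, o + 0.5),
          stats::runif(ne, o, o + evoked_dur_s))
      }))
      spike_record(depths_um[k], sort(spikes),
                   ev[, c("onset_s", "contrast", "led_on")])
    })
  })
}
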