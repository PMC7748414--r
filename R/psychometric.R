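#' Weibull psychometric function
#'
#' `psi(x) = gamma + (1 - gamma - lam) * (1 - exp(-(x / alpha)^beta))`, the
#' standard Weibull form for detection performance against stimulus
#' contrast. `gamma` is the lower asymptote (performance at 0% contrast —
#' for an aROC-based curve, 0.5), `lam` the lapse rate (shortfall of the
#' upper asymptote from 1), `alpha` the detection threshold (the contrast at
#' which the curve has covered `1 - exp(-1)` of its range) and `beta` the
#' slope.
#'
#' @param x Contrast (%) >= 0 (vectorized).
#' @param alpha Threshold contrast (%), > 0.
#' @param beta Slope, > 0.
#' @param gamma Lower asymptote in \[0, 1\] (default 0.5).
#' @param lam Lapse rate in \[0, 1 - gamma) (default 0).
#' @return Predicted performance value(s).
#' @export
weibull <- function(x, alpha, beta, gamma = 0.5, lam = 0) {
  if (alpha <= 0 || beta <= 0) {
    stop_lickroc("alpha and beta must be positive", "bad_parameters")
  }
  gamma + (1 - gamma - lam) * (1 - exp(-(x / alpha)^beta))
}

#' Fit the Weibull psychometric function to aROC-vs-contrast data
#'
#' Unweighted least squares with the lower asymptote fixed at the measured
#' 0%-contrast performance (0.5 when no 0% point is supplied), the lapse
#' rate bounded in \[0, `lam_max`\], the threshold in (0, 100\] and the
#' slope in (0, 10\]. Optimization is bounded quasi-Newton (L-BFGS-B) with
#' multiple threshold starts; the fit is invariant to the order of the data
#' points. The detection threshold is reported as `alpha` itself.
#'
#' @param contrasts Contrasts (%), ascending or not; a 0% entry is used only
#'   to fix `gamma` and is excluded from the fitted domain.
#' @param aroc Performance values in \[0, 1\], same length.
#' @param gamma Lower asymptote; default the 0%-contrast value when present,
#'   else 0.5.
#' @param lam_max Upper bound of the lapse rate (default 0.1).
#' @param condition Optional label (`"control"` / `"silenced"`) stored on the
#'   fit.
#' @return Object of class `"psychometric_fit"` with `alpha`, `beta`,
#'   `gamma`, `lam`, `rss`, `threshold` (= alpha), the data, and
#'   `convergence` diagnostics.
#' @export
fit_psychometric <- function(contrasts, aroc, gamma = NULL, lam_max = 0.1,
                             condition = NULL) {
  stopifnot(length(contrasts) == length(aroc))
  zero <- contrasts == 0
  if (is.null(gamma)) gamma <- if (any(zero)) mean(aroc[zero]) else 0.5
  x <- contrasts[!zero]; y <- aroc[!zero]
  if (length(x) < 4) stop_lickroc("need >= 4 non-zero-contrast points",
                                  "too_few_points")
  loss <- function(p) {
    sum((y - weibull(x, p[1], p[2], gamma, p[3]))^2)
  }
  lower <- c(1e-3, 1e-3, 0)
  upper <- c(100, 10, lam_max)
  best <- NULL
  for (a0 in c(4, 8, 16, 32, 64)) {
    for (b0 in c(1, 2.5)) {
      fit <- tryCatch(
        stats::optim(c(a0, b0, min(lam_max / 2, lam_max)), loss,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 500)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
  }
  if (is.null(best)) {
    stop_lickroc("psychometric fit failed to converge from every start",
                 "fit_failure")
  }
  at_bound <- best$par[1] >= upper[1] - 1e-6
  structure(list(alpha = best$par[1], beta = best$par[2], gamma = gamma,
                 lam = best$par[3], rss = best$value,
                 threshold = best$par[1], contrasts = x, aroc = y,
                 condition = condition,
                 convergence = list(code = best$convergence,
                                    alpha_at_bound = at_bound)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "Weibull psychometric fit%s: threshold alpha = %.2f%%, beta = %.2f, gamma = %.3f, lapse = %.3f (RSS %.2e)\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$alpha, x$beta, x$gamma, x$lam, x$rss))
  if (x$convergence$alpha_at_bound) {
    cat("  note: threshold at the upper bound - data carry no threshold information\n")
  }
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, gamma = object$gamma,
    lam = object$lam)
}

#' @export
predict.psychometric_fit <- function(object, contrasts = object$contrasts,
                                     ...) {
  weibull(contrasts, object$alpha, object$beta, object$gamma, object$lam)
}

#' @export
residuals.psychometric_fit <- function(object, ...) {
  object$aroc - predict(object)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  xx <- seq(min(x$contrasts) / 2, 100, length.out = 200)
  graphics::plot(x$contrasts, x$aroc, log = "x", pch = 16,
                 xlab = "contrast (%)", ylab = "aROC", ylim = c(0.4, 1), ...)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(v = x$alpha, lty = 3)
  invisible(x)
}

#' Silencing modulation index of the detection threshold
#'
#' `MI = (on - off) / (on + off)`: 0 when silencing leaves the threshold
#' unchanged, positive when silencing raises it, bounded in (-1, 1).
#'
#' @param threshold_on,threshold_off Detection thresholds (%) under LED-on
#'   (silencing) and LED-off (control); both > 0.
#' @return The modulation index.
#' @export
modulation_index <- function(threshold_on, threshold_off) {
  if (threshold_on <= 0 || threshold_off <= 0) {
    stop_lickroc("thresholds must be positive", "bad_parameters")
  }
  (threshold_on - threshold_off) / (threshold_on + threshold_off)
}

#' Threshold fold change under silencing
#'
#' The ratio of silenced to control detection thresholds.
#'
#' @inheritParams modulation_index
#' @return `threshold_on / threshold_off`.
#' @export
threshold_fold_change <- function(threshold_on, threshold_off) {
  if (threshold_on <= 0 || threshold_off <= 0) {
    stop_lickroc("thresholds must be positive", "bad_parameters")
  }
  threshold_on / threshold_off
}

#' Per-contrast aROC and psychometric fits from contrast sessions
#'
#' For sessions containing interleaved contrasts (and optionally LED
#' silencing trials), computes the censored-latency aROC of each contrast
#' against the blank trials, per condition, pooling trials across sessions,
#' and fits the Weibull psychometric function per condition.
#'
#' @param sessions List of [session()] objects.
#' @param by_led Split trials into LED-off (`control`) and LED-on
#'   (`silenced`) conditions (default `TRUE` when any LED trial is present).
#' @return List with `data` (data.frame: condition, contrast, aroc) and
#'   `fits` (named list of `"psychometric_fit"`, one per condition).
#' @export
psychometric_curves <- function(sessions, by_led = NULL) {
  if (inherits(sessions, "lick_session")) sessions <- list(sessions)
  trials <- unlist(lapply(sessions, `[[`, "trials"), recursive = FALSE)
  any_led <- any(vapply(trials, `[[`, logical(1), "led_on"))
  by_led <- by_led %||% any_led
  conds <- if (by_led) c(control = FALSE, silenced = TRUE) else
    c(control = NA)
  rows <- list(); fits <- list()
  for (cn in names(conds)) {
    sel <- if (is.na(conds[[cn]])) trials else
      Filter(function(tr) tr$led_on == conds[[cn]], trials)
    cl_all <- Filter(function(tr) tr$kind == "stimulus", sel)
    cs <- sort(unique(vapply(cl_all, `[[`, numeric(1), "contrast")))
    ar <- vapply(cs, function(cc) {
      sub <- Filter(function(tr) tr$kind == "blank" || tr$contrast == cc, sel)
      cl <- censored_latencies(sub)
      aroc(cl$stim, cl$blank)
    }, numeric(1))
    rows[[cn]] <- data.frame(condition = cn, contrast = cs, aroc = ar)
    fits[[cn]] <- fit_psychometric(cs, ar, condition = cn)
  }
  list(data = do.call(rbind, rows), fits = fits)
}
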