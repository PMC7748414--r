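#' Build day-wise learning curves from sessions
#'
#' Computes per-animal, per-day performance metrics — censored-latency aROC,
#' mean Hit first-lick latency, and latency variance/mean — then averages
#' across animals (unweighted) per day, retaining the SEM. Days on which an
#' animal has no usable session are missing cells and drop out of the
#' population mean for that day.
#'
#' @param sessions List of [session()] objects (one animal-day each).
#' @param censor_s,bin_s Censoring timestamp and bin width (s) for the aROC.
#' @return An object of class `"learning_curve"`: a list with `days`, and for
#'   each metric (`aroc`, `fl_latency_s`, `fl_variability_s`) the population
#'   mean and SEM vectors plus a `per_animal` matrix (animals x days).
#' @export
build_curve <- function(sessions, censor_s = 4.1, bin_s = 0.1) {
  if (length(sessions) == 0) stop_lickroc("no sessions", "empty_input")
  animals <- sort(unique(vapply(sessions, `[[`, character(1), "animal_id")))
  days <- sort(unique(vapply(sessions, `[[`, integer(1), "day")))
  metrics <- c("aroc", "fl_latency_s", "fl_variability_s")
  mats <- lapply(metrics, function(m) {
    matrix(NA_real_, length(animals), length(days),
           dimnames = list(animals, days))
  })
  names(mats) <- metrics
  for (s in sessions) {
    a <- match(s$animal_id, animals)
    d <- match(s$day, days)
    res <- tryCatch({
      cl <- censored_latencies(s$trials, censor_s = censor_s, bin_s = bin_s,
                               pre_stim_timeout_window_s =
                                 s$pre_stim_timeout_window_s)
      hits <- cl$stim$values_s[cl$stim$values_s != censor_s]
      list(aroc = aroc(cl$stim, cl$blank),
           fl_latency_s = if (length(hits)) mean(hits) else NA_real_,
           fl_variability_s = if (length(hits) >= 2) variability(hits)
                              else NA_real_)
    }, lickroc_error = function(e) NULL)
    if (is.null(res)) next  # zero usable trials: leave the cell missing
    for (m in metrics) mats[[m]][a, d] <- res[[m]]
  }
  pop <- lapply(mats, function(M) {
    mean_ <- apply(M, 2, mean, na.rm = TRUE)
    sem_ <- apply(M, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) >= 2) stats::sd(x) / sqrt(length(x)) else NA_real_
    })
    mean_[is.nan(mean_)] <- NA_real_
    list(mean = mean_, sem = sem_, per_animal = M)
  })
  structure(list(days = days, animals = animals,
                 aroc = pop$aroc, fl_latency_s = pop$fl_latency_s,
                 fl_variability_s = pop$fl_variability_s),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d animals, days %d-%d\n", length(x$animals),
              min(x$days), max(x$days)))
  print(round(rbind(aroc = x$aroc$mean, sem = x$aroc$sem), 3))
  invisible(x)
}

#' @export
as.data.frame.learning_curve <- function(x, ...) {
  do.call(rbind, lapply(c("aroc", "fl_latency_s", "fl_variability_s"),
    function(m) data.frame(day = x$days, metric = m, mean = x[[m]]$mean,
                           sem = x[[m]]$sem, row.names = NULL)))
}

#' @export
plot.learning_curve <- function(x, metric = "aroc", ...) {
  m <- x[[metric]]
  graphics::plot(x$days, m$mean, type = "b", pch = 16, xlab = "training day",
                 ylab = metric, ylim = range(c(m$mean - m$sem, m$mean + m$sem),
                                             na.rm = TRUE), ...)
  graphics::arrows(x$days, m$mean - m$sem, x$days, m$mean + m$sem,
                   angle = 90, code = 3, length = 0.03)
  if (metric == "aroc") graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Linear learning-rate fit
#'
#' Ordinary least squares of a day-wise performance series against training
#' day, restricted to `day_range`. The slope is the learning rate
#' (aROC/day when fitted to aROC); significance is the regression F-test of
#' slope = 0.
#'
#' @param days Day ordinals.
#' @param values Metric values, same length.
#' @param day_range Two-element inclusive range of days to fit (default the
#'   full range).
#' @return An object of class `"slope_fit"` with `slope`, `intercept`,
#'   `se_slope`, `r2`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
fit_slope <- function(days, values, day_range = range(days)) {
  keep <- days >= day_range[1] & days <= day_range[2] & !is.na(values)
  if (sum(keep) < 3) stop_lickroc("need >= 3 points in range", "too_few_points")
  d <- days[keep]; v <- values[keep]
  if (stats::sd(v) == 0) {
    # constant series: zero slope carries no evidence against itself
    return(structure(list(slope = 0, intercept = v[1], se_slope = 0,
                          r2 = 0, p_value = 1, n = sum(keep), lm = NULL),
                     class = "slope_fit"))
  }
  fit <- stats::lm(v ~ d)
  sm <- suppressWarnings(summary(fit))  # exact linear series are legitimate
  fstat <- sm$fstatistic
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 se_slope = unname(sm$coefficients[2, 2]),
                 r2 = sm$r.squared,
                 p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                            lower.tail = FALSE)),
                 n = sum(keep), lm = fit),
            class = "slope_fit")
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope %.4f +- %.4f per day (R2 = %.3f, p = %.3g, n = %d)\n",
              x$slope, x$se_slope, x$r2, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.slope_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.slope_fit <- function(object, days, ...) {
  object$intercept + object$slope * days
}

#' Learning-criterion day
#'
#' Learning is considered complete on the last day of the first run of
#' `run_length` consecutive sessions with aROC strictly above `threshold`
#' (default > 0.8 for 4 consecutive sessions). The strict inequality is
#' configurable through `strict`.
#'
#' @param aroc_series Day-ordered aROC values.
#' @param threshold aROC criterion (default 0.8).
#' @param run_length Required consecutive sessions (default 4).
#' @param days Optional day labels (default `seq_along(aroc_series)`).
#' @param strict Use `>` (default) rather than `>=`.
#' @return The day ordinal completing the first qualifying run, or
#'   `NA_integer_` when no run qualifies.
#' @export
criterion_day <- function(aroc_series, threshold = 0.8, run_length = 4,
                          days = seq_along(aroc_series), strict = TRUE) {
  if (length(aroc_series) == 0) stop_lickroc("empty series", "empty_input")
  above <- if (strict) aroc_series > threshold else aroc_series >= threshold
  above[is.na(above)] <- FALSE
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= run_length) return(as.integer(days[i]))
  }
  NA_integer_
}

#' Compare two learning-rate slopes
#'
#' Two-sided z-test on the difference of independent OLS slopes:
#' `z = (slope_a - slope_b) / sqrt(se_a^2 + se_b^2)`, with a normal p-value.
#'
#' @param fit_a,fit_b [fit_slope()] results.
#' @return List with `z` and `p_value`.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  se <- sqrt(fit_a$se_slope^2 + fit_b$se_slope^2)
  if (se == 0) {
    if (fit_a$slope == fit_b$slope) return(list(z = 0, p_value = 1))
    stop_lickroc("both slope standard errors are zero", "undefined_result")
  }
  z <- (fit_a$slope - fit_b$slope) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Rank tests for group comparisons
#'
#' Two-sided Mann–Whitney U test (unpaired) or Wilcoxon signed-rank test
#' (paired), as used for day-wise and group-wise behavioral comparisons.
#' A paired comparison whose differences are all zero is degenerate; it is
#' flagged and returns statistic 0 with p = 1.
#'
#' @param sample_a,sample_b Numeric samples (>= 3 each; equal lengths when
#'   paired).
#' @param paired Logical.
#' @return List with `statistic`, `p_value`, `method`, `degenerate`.
#' @export
rank_tests <- function(sample_a, sample_b, paired = FALSE) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop_lickroc("need >= 3 observations per sample", "too_few_points")
  }
  if (paired && length(sample_a) != length(sample_b)) {
    stop_lickroc("paired samples must have equal lengths", "length_mismatch")
  }
  if (paired && all(sample_a == sample_b)) {
    return(list(statistic = 0, p_value = 1,
                method = "Wilcoxon signed-rank", degenerate = TRUE))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, paired = paired, exact = FALSE,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U",
       degenerate = FALSE)
}
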