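#' Construct a single behavioral trial
#'
#' A trial of the go/no-go detection task: a drifting-grating stimulus (or a
#' blank gray screen) is shown for up to `response_window_s` seconds and the
#' animal reports detection by licking a waterspout. Lick times are stored in
#' seconds relative to stimulus onset; negative times are pre-stimulus licks.
#'
#' @param index Trial ordinal within the session (1-based).
#' @param kind `"stimulus"` or `"blank"`.
#' @param contrast Stimulus contrast as a percentage in \[0, 100\]; must be 0
#'   for blank trials.
#' @param led_on Logical; was the silencing LED on during this trial?
#' @param delay_s Post-onset delay (s) during which licks are not rewarded.
#' @param response_window_s Duration of the response window (s), default 4.
#' @param lick_times_s Strictly ascending numeric vector of lick times (s)
#'   relative to stimulus onset; may be empty and may contain negative
#'   pre-stimulus times.
#' @return An object of class `"lick_trial"`.
#' @export
trial <- function(index, kind = c("stimulus", "blank"), contrast = 100,
                  led_on = FALSE, delay_s = 0.25, response_window_s = 4,
                  lick_times_s = numeric()) {
  kind <- match.arg(kind)
  lick_times_s <- as.numeric(lick_times_s)
  if (length(lick_times_s) > 1 && any(diff(lick_times_s) <= 0)) {
    stop_lickroc("lick_times_s must be strictly ascending", "malformed_trial")
  }
  if (kind == "blank" && contrast != 0) {
    stop_lickroc("blank trials must have contrast 0", "malformed_trial")
  }
  if (!(response_window_s > 0) || delay_s < 0 || delay_s >= response_window_s) {
    stop_lickroc("need 0 <= delay_s < response_window_s", "malformed_trial")
  }
  structure(list(index = as.integer(index), kind = kind,
                 contrast = as.numeric(contrast), led_on = isTRUE(led_on),
                 delay_s = delay_s, response_window_s = response_window_s,
                 lick_times_s = lick_times_s),
            class = "lick_trial")
}

#' Construct a behavioral session
#'
#' One animal-day of training: an ordered list of trials plus the
#' trial-structure parameters shared by the session. All trials must share
#' one response-window duration.
#'
#' @param animal_id Animal identifier token.
#' @param day Training-day ordinal (>= 1).
#' @param group Group label (e.g. `"intact"`, `"CSt-ablated"`).
#' @param trials List of [trial()] objects (>= 1).
#' @param iti_s Fixed inter-trial interval (s).
#' @param jitter_max_s Maximum uniform jitter added to the ITI (s).
#' @param pre_stim_timeout_window_s Width of the pre-stimulus window (s) in
#'   which licking aborts the trial (default 1.5).
#' @return An object of class `"lick_session"`.
#' @export
session <- function(animal_id, day, group, trials, iti_s = 3,
                    jitter_max_s = 2, pre_stim_timeout_window_s = 1.5) {
  if (length(trials) < 1) stop_lickroc("session needs >= 1 trial", "malformed_session")
  rw <- unique(vapply(trials, `[[`, numeric(1), "response_window_s"))
  if (length(rw) != 1) {
    stop_lickroc("all trials in a session must share response_window_s",
                 "malformed_session")
  }
  structure(list(animal_id = as.character(animal_id), day = as.integer(day),
                 group = as.character(group), trials = trials, iti_s = iti_s,
                 jitter_max_s = jitter_max_s,
                 pre_stim_timeout_window_s = pre_stim_timeout_window_s),
            class = "lick_session")
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf("<lick_session> %s (%s), day %d: %d trials, window %.1f s\n",
              x$animal_id, x$group, x$day, length(x$trials),
              x$trials[[1]]$response_window_s))
  oc <- table(factor(vapply(classify_trials(x$trials,
                                            x$pre_stim_timeout_window_s),
                            `[[`, character(1), "label"),
                     levels = c("Hit", "Miss", "FA", "CR", "Aborted")))
  cat("  outcomes:", paste(names(oc), oc, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Classify a trial into its signal-detection outcome
#'
#' Outcome labels follow the standard go/no-go taxonomy: a Hit is a stimulus
#' trial with a first lick inside the response window, a Miss a stimulus trial
#' without one; a False Alarm (FA) is a blank trial with an in-window lick and
#' a Correct Rejection (CR) one without. Any lick inside the pre-stimulus
#' timeout window (default the 1.5 s preceding onset) marks the trial
#' Aborted; aborted trials are excluded from all downstream metrics.
#' Pre-stimulus licks earlier than the timeout window are ignored. The
#' response window is closed on both ends: a lick exactly at `delay_s` or at
#' `response_window_s` counts.
#'
#' @param trial A [trial()] object.
#' @param pre_stim_timeout_window_s Width (s) of the abort window before
#'   stimulus onset.
#' @return A list of class `"lick_outcome"` with elements `label` (one of
#'   `"Hit"`, `"Miss"`, `"FA"`, `"CR"`, `"Aborted"`) and
#'   `first_lick_latency_s` (the first in-window lick time, or `NA` when the
#'   label carries no latency).
#' @examples
#' classify_trial(trial(1, "stimulus", lick_times_s = 0.8))$label   # Hit
#' classify_trial(trial(2, "blank", contrast = 0))$label            # CR
#' @export
classify_trial <- function(trial, pre_stim_timeout_window_s = 1.5) {
  lt <- trial$lick_times_s
  if (length(lt) > 1 && any(diff(lt) <= 0)) {
    stop_lickroc("lick_times_s must be strictly ascending", "malformed_trial")
  }
  if (any(lt >= -pre_stim_timeout_window_s & lt < 0)) {
    return(structure(list(label = "Aborted", first_lick_latency_s = NA_real_),
                     class = "lick_outcome"))
  }
  inwin <- lt[lt >= trial$delay_s & lt <= trial$response_window_s]
  licked <- length(inwin) > 0
  lat <- if (licked) inwin[1] else NA_real_
  label <- if (trial$kind == "stimulus") {
    if (licked) "Hit" else "Miss"
  } else {
    if (licked) "FA" else "CR"
  }
  structure(list(label = label, first_lick_latency_s = lat),
            class = "lick_outcome")
}

# Vectorized classification over a list of trials.
classify_trials <- function(trials, pre_stim_timeout_window_s = 1.5) {
  lapply(trials, classify_trial,
         pre_stim_timeout_window_s = pre_stim_timeout_window_s)
}

# One data row per trial; lick times joined with ";" at full precision.
.session_to_df <- function(s) {
  data.frame(
    animal_id = s$animal_id, group = s$group, day = s$day,
    trial_index = vapply(s$trials, `[[`, integer(1), "index"),
    kind = vapply(s$trials, `[[`, character(1), "kind"),
    contrast = vapply(s$trials, `[[`, numeric(1), "contrast"),
    led_on = vapply(s$trials, `[[`, logical(1), "led_on"),
    delay_s = vapply(s$trials, `[[`, numeric(1), "delay_s"),
    response_window_s = vapply(s$trials, `[[`, numeric(1), "response_window_s"),
    lick_times_s = vapply(s$trials, function(tr) {
      paste(formatC(tr$lick_times_s, format = "g", digits = 15), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

.required_cols <- c("animal_id", "group", "day", "trial_index", "kind",
                    "contrast", "led_on", "delay_s", "response_window_s",
                    "lick_times_s")

#' Write sessions to a trials CSV
#'
#' One data row per trial, UTF-8, `.` decimal separator. Lick times are
#' serialized as a semicolon-joined list column at 15 significant digits so
#' that a write/read round trip is lossless to well below 1 ns.
#'
#' @param sessions A list of [session()] objects (a single session is
#'   accepted).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "lick_session")) sessions <- list(sessions)
  df <- do.call(rbind, lapply(sessions, .session_to_df))
  meta <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(animal_id = s$animal_id, day = s$day, iti_s = s$iti_s,
               jitter_max_s = s$jitter_max_s,
               pre_stim_timeout_window_s = s$pre_stim_timeout_window_s)
  }))
  # session-level parameters ride along on every row of that session
  df <- merge(df, meta, by = c("animal_id", "day"), sort = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sessions from a trials CSV
#'
#' Inverse of [write_sessions()]: rows are grouped into sessions by
#' `(animal_id, day)` and trials are restored in `trial_index` order, so a
#' file with shuffled rows reads back identically.
#'
#' @param path Input file path.
#' @return A list of [session()] objects (empty list for an empty file).
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop_lickroc(paste("no such file:", path), "parse_error")
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(list())
  if ("lick_times_s" %in% names(df)) {
    df$lick_times_s <- ifelse(is.na(df$lick_times_s), "",
                              as.character(df$lick_times_s))
  }
  missing <- setdiff(.required_cols, names(df))
  if (length(missing) > 0) {
    stop_lickroc(paste("missing column(s):", paste(missing, collapse = ", ")),
                 "parse_error")
  }
  for (col in c("contrast", "delay_s", "response_window_s")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop_lickroc(sprintf("non-numeric %s at data row %d", col, bad),
                   "parse_error")
    }
  }
  key <- paste(df$animal_id, df$day, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(sd) {
    sd <- sd[order(sd$trial_index), , drop = FALSE]
    trs <- lapply(seq_len(nrow(sd)), function(i) {
      licks <- sd$lick_times_s[i]
      lt <- if (is.na(licks) || !nzchar(licks)) numeric() else {
        v <- as.numeric(strsplit(licks, ";", fixed = TRUE)[[1]])
        if (anyNA(v)) {
          stop_lickroc(sprintf("non-numeric latency at data row %d", i),
                       "parse_error")
        }
        v
      }
      trial(sd$trial_index[i], sd$kind[i], sd$contrast[i],
            as.logical(sd$led_on[i]), sd$delay_s[i], sd$response_window_s[i],
            lt)
    })
    session(sd$animal_id[1], sd$day[1], sd$group[1], trs,
            iti_s = if ("iti_s" %in% names(sd)) sd$iti_s[1] else 3,
            jitter_max_s = if ("jitter_max_s" %in% names(sd)) sd$jitter_max_s[1] else 2,
            pre_stim_timeout_window_s =
              if ("pre_stim_timeout_window_s" %in% names(sd))
                sd$pre_stim_timeout_window_s[1] else 1.5)
  }) |> unname()
}
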