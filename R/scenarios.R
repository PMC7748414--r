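#' Scenario configuration
#'
#' Bundles the settings of an end-to-end synthetic experiment. Recognized
#' scenarios: `learning_14d` (two-week training cohorts per group, learning
#' curves + slope fits + criterion days + pairwise slope comparisons),
#' `extended_21d` (three-week training, showing delayed groups approaching
#' the intact plateau), `prepost_lesion` (train an intact cohort, then
#' continue its sessions under a lesion profile and compare performance
#' pre/post), `contrast_silencing` (expert-stage contrast sessions with
#' interleaved LED silencing; psychometric fits, modulation index and
#' threshold fold change), `training_duration_sweep` (the silencing fold
#' interpolated from its early- to late-training value; MI as a function of
#' training extent), and `sc_depth` (simulated collicular recordings across
#' depth; depth profile of silencing and a contrast-response fit).
#'
#' @param scenario One of the six scenario names above.
#' @param groups Character vector of profile names (see
#'   [default_profiles()]).
#' @param n_mice,n_days,n_trials Cohort dimensions.
#' @param seed Master seed.
#' @param output_dir Directory for the report bundle; `NULL` disables
#'   writing.
#' @param ... Scenario-specific overrides stored on the config.
#' @return Object of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario, groups = "intact", n_mice = 4,
                            n_days = 14, n_trials = 240, seed = 1,
                            output_dir = NULL, ...) {
  known <- c("learning_14d", "extended_21d", "prepost_lesion",
             "contrast_silencing", "training_duration_sweep", "sc_depth")
  if (!scenario %in% known) {
    stop_lickroc(paste0("unknown scenario '", scenario, "'"), "bad_config")
  }
  stopifnot(n_mice >= 1, n_days >= 1, n_trials >= 1)
  structure(c(list(scenario = scenario, groups = groups, n_mice = n_mice,
                   n_days = n_days, n_trials = n_trials,
                   seed = as.integer(seed), output_dir = output_dir),
              list(...)),
            class = "scenario_config")
}

#' Read a scenario configuration file
#'
#' YAML (preferred) or JSON with the same field names as
#' [scenario_config()].
#'
#' @param path Config file path.
#' @return A `"scenario_config"`.
#' @export
read_scenario_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  lst <- if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt) else
    yaml::yaml.load(txt)
  do.call(scenario_config, lst)
}

.group_curve_block <- function(profile, n_mice, n_days, n_trials, seed,
                               fit_range = c(1, 14)) {
  sess <- simulate_cohort(profile, n_mice, n_days, n_trials, seed = seed)
  curve <- build_curve(sess)
  fr <- c(fit_range[1], min(fit_range[2], max(curve$days)))
  fit <- fit_slope(curve$days, curve$aroc$mean, fr)
  per_animal_crit <- apply(curve$aroc$per_animal, 1, criterion_day,
                           days = curve$days)
  list(sessions = sess, curve = curve, fit = fit,
       criterion = list(population = criterion_day(curve$aroc$mean,
                                                   days = curve$days),
                        per_animal = per_animal_crit))
}

#' Run an end-to-end scenario
#'
#' Simulates the configured cohorts, runs the corresponding analyses, and
#' (when `output_dir` is set) writes a report bundle: `curves.csv` (tidy
#' day-wise metrics), `fits.json` and `summary.json`. The bundle records the
#' seed and the package version; identical configurations produce identical
#' bundles.
#'
#' @param config A [scenario_config()].
#' @return The report bundle (a list), invisibly containing all fitted
#'   objects plus a `summary` list of scalar results.
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  profiles <- default_profiles()
  bad <- setdiff(config$groups, names(profiles))
  if (length(bad) > 0) {
    stop_lickroc(paste("unknown group(s):", paste(bad, collapse = ", ")),
                 "bad_config")
  }
  message(sprintf("[lickroc] scenario=%s seed=%d groups=%s",
                  config$scenario, config$seed,
                  paste(config$groups, collapse = ",")))
  out <- switch(
    config$scenario,
    learning_14d = ,
    extended_21d = {
      n_days <- if (config$scenario == "extended_21d") max(config$n_days, 21)
        else config$n_days
      blocks <- lapply(config$groups, function(g) {
        .group_curve_block(profiles[[g]], config$n_mice, n_days,
                           config$n_trials, mix_seed(config$seed,
                                                     match(g, config$groups)))
      })
      names(blocks) <- config$groups
      comparisons <- list()
      if (length(blocks) >= 2) {
        prs <- utils::combn(config$groups, 2, simplify = FALSE)
        comparisons <- lapply(prs, function(p) {
          c(list(groups = p), compare_slopes(blocks[[p[1]]]$fit,
                                             blocks[[p[2]]]$fit))
        })
      }
      summary <- lapply(blocks, function(b) {
        nd <- length(b$curve$days)
        list(slope = b$fit$slope, se_slope = b$fit$se_slope, r2 = b$fit$r2,
             p_value = b$fit$p_value,
             final_day_aroc = b$curve$aroc$mean[nd],
             final_day_aroc_sem = b$curve$aroc$sem[nd],
             criterion_day = b$criterion$population)
      })
      list(blocks = blocks, comparisons = comparisons, summary = summary)
    },
    prepost_lesion = {
      pre_profile <- profiles[["intact"]]
      post_profile <- profiles[[if (length(config$groups)) config$groups[1]
                                else "VC-lesion"]]
      n_post <- config$n_post %||% 5
      pre <- simulate_cohort(pre_profile, config$n_mice, config$n_days,
                             config$n_trials, seed = mix_seed(config$seed, 1))
      # post-lesion sessions restart from the lesion profile's naive state
      post <- vector("list", 0)
      for (m in seq_len(config$n_mice)) {
        for (d in seq_len(n_post)) {
          post <- c(post, list(simulate_session(
            post_profile, d, n_trials = config$n_trials,
            seed = mix_seed(config$seed, 2, m, d),
            animal_id = sprintf("%s_m%02d", pre_profile$name, m))))
        }
      }
      pre_last <- Filter(function(s) s$day == config$n_days, pre)
      pre_ar <- vapply(pre_last, session_aroc, numeric(1))
      post_first <- Filter(function(s) s$day == 1, post)
      post_ar <- vapply(post_first, session_aroc, numeric(1))
      test <- rank_tests(pre_ar, post_ar, paired = TRUE)
      list(pre_curve = build_curve(pre), post_curve = build_curve(post),
           summary = list(pre_aroc = mean(pre_ar), post_aroc = mean(post_ar),
                          drop = mean(pre_ar) - mean(post_ar),
                          p_value = test$p_value))
    },
    contrast_silencing = {
      res <- lapply(config$groups, function(g) {
        .silencing_fits(profiles[[g]], config, fold = NULL,
                        seed = mix_seed(config$seed, match(g, config$groups)))
      })
      names(res) <- config$groups
      list(groups = res,
           summary = lapply(res, function(r) {
             list(threshold_control = r$fits$control$alpha,
                  threshold_silenced = r$fits$silenced$alpha,
                  modulation_index = r$mi, fold_change = r$fold)
           }))
    },
    training_duration_sweep = {
      g <- config$groups[1]
      prof <- profiles[[g]]
      scales <- config$training_scales %||% seq(0, 1, by = 0.25)
      sweep <- lapply(seq_along(scales), function(i) {
        s <- scales[i]
        fold <- prof$silencing_fold +
          (prof$silencing_fold_late - prof$silencing_fold) * s
        r <- .silencing_fits(prof, config, fold = fold,
                             seed = mix_seed(config$seed, i))
        list(training_scale = s, generating_fold = fold,
             modulation_index = r$mi, fold_change = r$fold)
      })
      list(sweep = sweep,
           summary = list(
             training_scale = scales,
             modulation_index = vapply(sweep, `[[`, numeric(1),
                                       "modulation_index")))
    },
    sc_depth = {
      depths <- config$depths_um %||% seq(100, 1500, by = 100)
      w <- config$cortical_weights %||%
        0.6 * exp(-((depths - 900) / 250)^2)  # cortical drive peaks in SI
      recs <- simulate_sc_activity(
        depths, training_scale = config$training_scale %||% 1,
        cortical_weight_by_depth = w,
        n_trials = config$n_trials_per_condition %||% 40,
        seed = config$seed)
      prof <- silencing_depth_profile(recs)
      # contrast response at the depth of maximal control response
      best <- which.max(prof$raw_control)
      er <- evoked_response(recs[[best]], led_on = FALSE)
      cfit <- fit_crf(er$contrast, er$response)
      list(records = recs, depth_profile = prof, crf_fit = cfit,
           summary = list(x50 = cfit$x50, r_max = cfit$r_max,
                          n_exp = cfit$n_exp,
                          min_silenced_ratio = min(prof$silenced)))
    })
  bundle <- c(list(scenario = config$scenario, seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("lickroc")),
                   config = unclass(config)), out)
  if (!is.null(config$output_dir)) .write_bundle(bundle, config)
  invisible(bundle)
}

# Expert-stage contrast sessions with interleaved silencing, per-condition
# psychometric fits, and the derived threshold statistics.
.silencing_fits <- function(profile, config, fold = NULL, seed = 1) {
  day <- config$psych_day %||% length(profile$days)
  n_sessions <- config$n_sessions %||% config$n_mice
  sess <- lapply(seq_len(n_sessions), function(m) {
    simulate_session(profile, day, n_trials = config$n_trials,
                     contrasts = c(4, 8, 16, 32, 64, 100),
                     led_fraction = 1 / 3, seed = mix_seed(seed, m),
                     animal_id = sprintf("%s_m%02d", profile$name, m),
                     silencing_fold = fold)
  })
  pc <- psychometric_curves(sess)
  list(sessions = sess, data = pc$data, fits = pc$fits,
       mi = modulation_index(pc$fits$silenced$alpha, pc$fits$control$alpha),
       fold = threshold_fold_change(pc$fits$silenced$alpha,
                                    pc$fits$control$alpha))
}

.write_bundle <- function(bundle, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- NULL
  if (!is.null(bundle$blocks)) {
    curves <- do.call(rbind, lapply(names(bundle$blocks), function(g) {
      df <- as.data.frame(bundle$blocks[[g]]$curve)
      df$group <- g
      df
    }))
  } else if (!is.null(bundle$groups)) {
    curves <- do.call(rbind, lapply(names(bundle$groups), function(g) {
      df <- bundle$groups[[g]]$data
      df$group <- g
      df
    }))
  } else if (!is.null(bundle$depth_profile)) {
    curves <- bundle$depth_profile
  }
  if (!is.null(curves)) {
    utils::write.csv(curves, file.path(config$output_dir, "curves.csv"),
                     row.names = FALSE)
  }
  fits <- bundle$summary
  jsonlite::write_json(fits, file.path(config$output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(
    list(scenario = bundle$scenario, seed = bundle$seed,
         package_version = bundle$package_version, summary = bundle$summary),
    file.path(config$output_dir, "summary.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(NULL)
}

#' Human-readable scenario summary table
#'
#' Flattens a [run_scenario()] bundle into one row per group x metric with
#' values formatted to three significant digits; missing metrics yield `NA`
#' cells with a warning.
#'
#' @param bundle A report bundle from [run_scenario()].
#' @return A data frame with columns `group`, `metric`, `value`.
#' @export
scenario_summary <- function(bundle) {
  if (is.null(bundle$summary) || length(bundle$summary) == 0) {
    stop_lickroc("empty bundle", "empty_input")
  }
  sm <- bundle$summary
  if (!is.list(sm[[1]])) sm <- list(all = sm)
  rows <- list()
  for (g in names(sm)) {
    for (m in names(sm[[g]])) {
      v <- sm[[g]][[m]]
      if (is.null(v) || length(v) == 0 || all(is.na(v))) {
        warning(sprintf("metric '%s' missing for '%s'", m, g))
        val <- NA_character_
      } else {
        val <- paste(signif(as.numeric(v), 3), collapse = ", ")
      }
      rows[[length(rows) + 1]] <- data.frame(group = g, metric = m,
                                             value = val)
    }
  }
  do.call(rbind, rows)
}
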