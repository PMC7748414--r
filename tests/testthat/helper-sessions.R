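# Shared fixtures and independent oracles, built in code.

stim_trial <- function(index, licks = numeric(), contrast = 100, ...) {
  trial(index, "stimulus", contrast = contrast, lick_times_s = licks, ...)
}

blank_trial <- function(index, licks = numeric(), ...) {
  trial(index, "blank", contrast = 0, lick_times_s = licks, ...)
}

# Session of n_stim stimulus trials with the given latencies (NA = no lick)
# followed by n_blank blanks with theirs.
fixed_session <- function(stim_lat, blank_lat, animal_id = "a1", day = 1,
                          group = "test") {
  k <- 0
  trs <- c(
    lapply(stim_lat, function(l) {
      k <<- k + 1
      stim_trial(k, if (is.na(l)) numeric() else l)
    }),
    lapply(blank_lat, function(l) {
      k <<- k + 1
      blank_trial(k, if (is.na(l)) numeric() else l)
    }))
  session(animal_id, day, group, trs)
}

# Random valid session for round-trip / counting properties.
random_session <- function(seed, n = 30, animal_id = "r1", day = 1) {
  set.seed(seed)
  trs <- lapply(seq_len(n), function(i) {
    kind <- sample(c("stimulus", "blank"), 1)
    licks <- sort(runif(rpois(1, 1.2), -3, 4))
    licks <- round(licks, 6)
    licks <- unique(licks)
    trial(i, kind, contrast = if (kind == "blank") 0 else
            sample(c(4, 32, 100), 1),
          led_on = runif(1) < 0.3, lick_times_s = licks)
  })
  session(animal_id, day, "rand", trs)
}

# Independent aROC oracle: exhaustive pairwise comparison (U statistic with
# half ties) on explicitly binned values.
pairwise_aroc <- function(stim, blank) {
  bin1 <- function(s) {
    nb <- round(s$window_s / s$bin_s)
    idx <- pmin(floor(s$values_s / s$bin_s), nb - 1)
    idx[s$values_s == s$censor_s] <- nb
    idx
  }
  bs <- bin1(stim); bb <- bin1(blank)
  tot <- 0
  for (x in bs) for (y in bb) tot <- tot + (x < y) + 0.5 * (x == y)
  tot / (length(bs) * length(bb))
}

# Closed-form OLS (normal equations) oracle.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = b[1], slope = b[2])
}

# Random censored latency sample for property tests.
random_latency_sample <- function(n, p_censor = 0.3) {
  v <- ifelse(runif(n) < p_censor, 4.1, round(runif(n, 0, 4), 3))
  latency_sample(v)
}
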