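#' @keywords internal
"_PACKAGE"

# Deterministic child seed for (master seed, stream indices).
# Simple multiplicative mixing kept below 2^31 so set.seed() accepts it on
# every platform; collisions across distinct index tuples are avoided by
# using distinct odd multipliers per level.
mix_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  mult <- c(1000003, 7919, 104729, 1299709)
  for (k in seq_along(idx)) {
    m <- mult[((k - 1L) %% length(mult)) + 1L]
    s <- (s * 31 + as.double(idx[k]) * m + 17) %% 2147483647
  }
  as.integer(s)
}

# Gamma random draws parameterized by mean and coefficient of variation,
# truncated to [lo, hi] by inverse-CDF sampling (no rejection loop).
rgamma_trunc <- function(n, mean, cv, lo = 0, hi = Inf) {
  stopifnot(mean > 0, cv > 0, hi > lo)
  shape <- 1 / cv^2
  rate <- shape / mean
  p_lo <- stats::pgamma(lo, shape, rate)
  p_hi <- stats::pgamma(hi, shape, rate)
  if (p_hi <= p_lo) {
    # whole window in an extreme tail; fall back to clamping
    return(rep(min(max(mean, lo), hi), n))
  }
  u <- stats::runif(n, p_lo, p_hi)
  stats::qgamma(u, shape, rate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_lickroc <- function(msg, class) {
  stop(structure(class = c(class, "lickroc_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
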