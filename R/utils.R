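# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
# All conditions also carry class "capnopred_error".
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "capnopred_error")))
}

abort_invalid <- function(msg) abort(msg, "capnopred_invalid_argument")
abort_state <- function(msg) abort(msg, "capnopred_invalid_state")

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampling of a normal distribution restricted to
#' `[lower, upper]`. With `sd = 0` all draws equal `mean` (clamped to the
#' bounds). Draws consume exactly `n` uniforms from the current RNG stream.
#'
#' @param n Number of draws.
#' @param mean,sd Mean and standard deviation of the parent normal.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort_invalid("sd must be >= 0")
  if (sd == 0) {
    stats::runif(n) # keep stream advancement consistent
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Mean of a normal truncated to [lower, upper] (closed form).
truncnorm_mean <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# Deterministic per-record sub-seed derived from a base seed; kept below
# 2^31 so it is a valid R integer seed.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483629)
}

# Small deterministic string hash (djb2) used to fingerprint configs in
# run manifests; not cryptographic.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^28
  sprintf("%07x", h)
}
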