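# Internal helpers shared across modules.

# Deterministic substream seed derived from a master seed and a component name.
# Keeps every derived seed in [0, 2^31 - 2] so set.seed() accepts it, and keeps
# intermediate products below 2^53 so double arithmetic stays exact.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Round half away from zero (report convention for partition coefficients;
# base round() rounds half to even).
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Multiplicative lognormal noise with mean 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stop_msikp <- function(msg, class) {
  abort(msg, class = c(class, "msikp_error"))
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_msikp(sprintf("`%s` must be a single finite number", name),
               "msikp_config_error")
  }
  bad_low <- if (strict_min) x <= min else x < min
  if (bad_low || x > max) {
    stop_msikp(sprintf("`%s` = %g is outside its allowed range", name, x),
               "msikp_config_error")
  }
  invisible(x)
}
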