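# Structured conditions: every validation failure carries a machine-readable
# class so callers (and tests) can dispatch on the error category rather than
# parse messages.
xylo_error <- function(message, class, ...) {
  structure(
    class = c(class, "xylo_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

# Lognormal parameterised by mean and coefficient of variation; cv = 0
# degenerates to the mean (used by the noise-free generator configuration).
rlnorm_mcv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Equivalent-circle diameter from a cross-sectional area (um^2 -> um).
equivalent_diameter <- function(area) 2 * sqrt(area / pi)

`%||%` <- function(a, b) if (is.null(a)) b else a
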