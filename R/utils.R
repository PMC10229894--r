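# Internal helpers shared across modules.

# round half away from zero (metric percentages are reported half-up,
# not banker's-rounded)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# per-column standardization; zero-SD columns get scale 1 so constant
# features pass through centered
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd <= 0] <- 1
  list(center = mu, scale = sd)
}

standardize_apply <- function(x, fit) {
  sweep(sweep(x, 2, fit$center, "-"), 2, fit$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
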