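#' @keywords internal
"_PACKAGE"

# Deterministic child seeds fanned out from one global seed.
# Keeps every derived seed a valid 32-bit integer.
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 7919 * k) %% .Machine$integer.max)
}

# Run expr with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Left-truncated normal draws via inverse-CDF so they compose with
# correlated standard-normal inputs (Gaussian copula margins).
rtrunc_norm <- function(z, mean, sd, lower) {
  if (sd == 0) {
    if (mean < lower) stop("degenerate truncated normal below its bound")
    return(rep(mean, length(z)))
  }
  p_lo <- stats::pnorm((lower - mean) / sd)
  u <- p_lo + stats::pnorm(z) * (1 - p_lo)
  mean + sd * stats::qnorm(u)
}

# Mean of a normal(mu, sd) left-truncated at `lower`.
trunc_norm_mean <- function(mu, sd, lower) {
  if (sd == 0) return(mu)
  a <- (lower - mu) / sd
  mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# Location mu such that normal(mu, sd) truncated at `lower` has mean `target`.
calibrate_trunc_mu <- function(target, sd, lower) {
  if (sd == 0) return(target)
  f <- function(mu) trunc_norm_mean(mu, sd, lower) - target
  stats::uniroot(f, lower = target - 6 * sd, upper = target + sd,
                 extendInt = "upX", tol = 1e-10)$root
}

`%||%` <- function(a, b) if (is.null(a)) b else a
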