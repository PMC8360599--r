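# Internal helpers shared across modules.

# Deterministic child seed for a named pipeline stage. A multiplicative
# hash spreads nearby master seeds far apart so that replicate runs with
# consecutive seeds do not produce correlated streams. Result is always a
# valid 32-bit integer.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (abs(as.double(seed)) * 2654435761 + h * 40503 + 17) %% 2147483629
  as.integer(x)
}

# Evaluate an expression under a local RNG state so package internals never
# disturb the caller's random stream.
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

# Truncated normal draws by inverse-CDF; exact and vectorised.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Null (intercept-only) binomial log-likelihood for n0 failures / n1 successes.
ll_null_binary <- function(n1, n0) {
  n <- n1 + n0
  if (n1 == 0L || n0 == 0L) return(0)
  n1 * log(n1 / n) + n0 * log(n0 / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary01 <- function(x) {
  u <- unique(x[!is.na(x)])
  length(u) <= 2L && all(u %in% c(0, 1))
}
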