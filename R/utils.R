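# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route through this so that user-level seeds are explicit and non-invasive.
with_preserved_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Draws from a Normal(mean, sd) truncated to (0, Inf) via inverse-CDF;
# degenerates to `mean` exactly when sd == 0.
rtruncnorm_pos <- function(n, mean, sd) {
  stopifnot(sd >= 0)
  if (sd == 0) {
    if (mean <= 0) stop("degenerate truncated normal with nonpositive mean")
    return(rep(mean, n))
  }
  lo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean, sd)
}

# Mean of a Normal(mean, sd) truncated to (0, Inf).
truncnorm_pos_mean <- function(mean, sd) {
  if (sd == 0) return(mean)
  alpha <- (0 - mean) / sd
  mean + sd * stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log density of a half-Student-t(df, 0, scale) evaluated at x > 0.
dhalf_t_log <- function(x, df, scale) {
  out <- rep(-Inf, length(x))
  ok <- x > 0
  out[ok] <- log(2) + stats::dt(x[ok] / scale, df = df, log = TRUE) - log(scale)
  out
}

# log density of a Normal(mean, sd) truncated to (0, Inf).
dtruncnorm_pos_log <- function(x, mean, sd) {
  out <- rep(-Inf, length(x))
  ok <- x > 0
  out[ok] <- stats::dnorm(x[ok], mean, sd, log = TRUE) -
    stats::pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE)
  out
}

# Bivariate normal log density with zero mean, standard deviations s1, s2 and
# correlation rho; x is a two-column matrix.
dbinorm0_log <- function(x, s1, s2, rho) {
  z1 <- x[, 1] / s1
  z2 <- x[, 2] / s2
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  -log(2 * pi) - log(s1) - log(s2) - 0.5 * log(1 - rho^2) - q / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
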