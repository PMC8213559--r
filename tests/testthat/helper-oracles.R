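# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Conjugate normal-normal model: y_i ~ N(mu, sigma^2) with known sigma and
# mu ~ N(mu0, tau0^2). Everything is available in closed form.
conjugate_model <- function(y, sigma = 1, mu0 = 0, tau0 = 2) {
  n <- length(y)
  ybar <- mean(y)
  S <- sum((y - ybar)^2)
  logml <- -n / 2 * log(2 * pi) - (n - 1) * log(sigma) -
    0.5 * log(sigma^2 + n * tau0^2) - S / (2 * sigma^2) -
    n * (ybar - mu0)^2 / (2 * (sigma^2 + n * tau0^2))
  tau_n2 <- 1 / (1 / tau0^2 + n / sigma^2)
  mu_n <- tau_n2 * (mu0 / tau0^2 + n * ybar / sigma^2)
  list(
    y = y, sigma = sigma, mu0 = mu0, tau0 = tau0,
    logml = logml, post_mean = mu_n, post_sd = sqrt(tau_n2),
    # log unnormalized posterior for a column-matrix of mu values
    log_posterior = function(eta) {
      mu <- as.matrix(eta)[, 1]
      vapply(mu, function(m) {
        sum(dnorm(y, m, sigma, log = TRUE)) + dnorm(m, mu0, tau0, log = TRUE)
      }, 0)
    },
    draw_posterior = function(S_draws) {
      matrix(rnorm(S_draws, mu_n, sqrt(tau_n2)), ncol = 1)
    },
    pointwise_loglik = function(mu_draws) {
      sapply(y, function(yi) dnorm(yi, mu_draws, sigma, log = TRUE))
    },
    # exact case-deletion log predictive density per observation
    exact_loo = function() {
      vapply(seq_len(n), function(i) {
        yi <- y[-i]
        t2 <- 1 / (1 / tau0^2 + (n - 1) / sigma^2)
        m <- t2 * (mu0 / tau0^2 + sum(yi) / sigma^2)
        dnorm(y[i], m, sqrt(sigma^2 + t2), log = TRUE)
      }, 0)
    }
  )
}

# Box's epsilon via the original summation formula (no contrast matrices).
box_epsilon_oracle <- function(S) {
  L <- nrow(S)
  rowm <- rowMeans(S)
  allm <- mean(S)
  diagm <- mean(diag(S))
  num <- L^2 * (diagm - allm)^2
  den <- (L - 1) * (sum(S^2) - 2 * L * sum(rowm^2) + L^2 * allm^2)
  num / den
}

# Within-subject one-way ANOVA via base aov (multi-stratum projection).
aov_within_oracle <- function(cells) {
  d <- data.frame(
    id = factor(cells$participant_id),
    stim = factor(cells$stimulus_id),
    y = cells$mean_response
  )
  fit <- stats::aov(y ~ stim + Error(id / stim), data = d)
  s <- summary(fit)
  tab <- s[["Error: id:stim"]][[1]]
  list(
    ss_effect = tab["stim", "Sum Sq"],
    ss_error = tab["Residuals", "Sum Sq"],
    f = tab["stim", "F value"]
  )
}

# Sample correlated multivariate normal rows given a covariance matrix.
rmvn_rows <- function(n, Sigma) {
  matrix(rnorm(n * nrow(Sigma)), n) %*% chol(Sigma)
}

make_cells <- function(Y, method = "standard") {
  N <- nrow(Y); B <- ncol(Y)
  tibble::tibble(
    participant_id = rep(seq_len(N), each = B),
    method = rep(method, length.out = N)[rep(seq_len(N), each = B)],
    stimulus_id = rep(seq_len(B), N),
    mean_response = as.vector(t(Y))
  )
}

# quick small-scale fitted models shared by comparison/ppc tests (memoized:
# several test files reuse the same pair)
.fit_pair_cache <- new.env(parent = emptyenv())
fit_small_pair <- function(seed = 7) {
  key <- paste0("seed", seed)
  if (!exists(key, envir = .fit_pair_cache)) {
    assign(key, fit_small_pair_impl(seed), envir = .fit_pair_cache)
  }
  get(key, envir = .fit_pair_cache)
}

fit_small_pair_impl <- function(seed = 7) {
  pop <- population_spec(mean_a = 0.44, sd_a = 0.18, noise_sd = 0.03,
                         n_participants = 8, seed = seed)
  ds <- simulate_ratings(draw_participants(pop), luminance_stimulus_table(),
                         "standard", pop)
  ds <- preprocess(ds, log = FALSE)$dataset
  list(
    power = suppressWarnings(
      fit_scaling_model(power_model_spec(), ds, chains = 2, warmup = 300,
                        draws = 1000, adapt = 300, seed = seed)
    ),
    linear = suppressWarnings(
      fit_scaling_model(linear_model_spec(), ds, chains = 2, warmup = 300,
                        draws = 1000, adapt = 300, seed = seed + 1)
    ),
    dataset = ds
  )
}
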