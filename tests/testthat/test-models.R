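test_that("likelihood log densities match direct normal-pdf evaluation", {
  # at the mean the log density is -log(sigma * sqrt(2 pi))
  expect_equal(power_log_density(y = 0.23 * 0.5^0.44, x = 0.5, b0j = 0.23,
                                 b1j = 0.44, sigma_e = 0.03),
               -log(0.03 * sqrt(2 * pi)))
  expect_equal(linear_log_density(y = 0.1 + 0.2 * 0.3, x = 0.3, beta0j = 0.1,
                                  beta1j = 0.2, sigma_e = 0.05),
               -log(0.05 * sqrt(2 * pi)))

  # posterior-mean parameter values of the standard luminance condition:
  # mean response at the reference is 0.23 * 0.1^0.44 = 0.0835
  mu <- 0.23 * 0.1^0.44
  expect_equal(mu, 0.0835, tolerance = 2e-4)
  expect_equal(power_log_density(0.1, 0.1, 0.23, 0.44, 0.03),
               dnorm(0.1, mu, 0.03, log = TRUE))

  # with unit exponent the power density reduces to the zero-intercept line
  xs <- c(0.05, 0.1, 0.4, 1)
  expect_equal(power_log_density(0.2, xs, 0.37, 1, 0.04),
               linear_log_density(0.2, xs, 0, 0.37, 0.04))

  # arbitrary toy numbers against a hand-rolled normal pdf
  y <- 0.17; x <- 0.32; b0 <- 0.29; b1 <- 0.61; s <- 0.045
  m <- b0 * x^b1
  expect_equal(power_log_density(y, x, b0, b1, s),
               -0.5 * log(2 * pi) - log(s) - (y - m)^2 / (2 * s^2))

  expect_error(power_log_density(0.1, 0.1, 0.2, 0.4, sigma_e = -1), "positive")
  expect_error(power_log_density(0.1, -0.1, 0.2, 0.4, 0.03), "positive")
})

test_that("log priors respect support boundaries and LKJ(1) flatness", {
  ps <- power_model_spec()
  ls <- linear_model_spec()
  base_p <- list(b0 = 0.2, b1 = 0.5, u0 = c(0.01, -0.01), u1 = c(0.1, -0.1),
                 sigma_u0 = 0.1, sigma_u1 = 0.2, sigma_e = 0.03)
  expect_true(is.finite(log_prior(ps, base_p)))
  expect_equal(log_prior(ps, modifyList(base_p, list(sigma_e = -0.1))), -Inf)
  expect_equal(log_prior(ps, modifyList(base_p, list(b1 = -0.2))), -Inf)

  base_l <- list(beta0 = 0.05, beta1 = 0.2, u = cbind(c(0.01, 0), c(0, 0.02)),
                 sigma_u0 = 0.05, sigma_u1 = 0.1, rho = 0.3, sigma_e = 0.04)
  expect_true(is.finite(log_prior(ls, base_l)))
  expect_equal(log_prior(ls, modifyList(base_l, list(rho = 1.4))), -Inf)

  # LKJ(1) on a 2x2 correlation is flat: prior ratio across rho values is 1
  # (holding the rho-dependent random-effect term fixed by zero effects)
  zero_u <- modifyList(base_l, list(u = matrix(0, 2, 2)))
  lp1 <- log_prior(ls, modifyList(zero_u, list(rho = -0.8)))
  lp2 <- log_prior(ls, modifyList(zero_u, list(rho = 0.5)))
  # remove the MVN normalization that legitimately depends on rho
  norm1 <- -2 * (log(2 * pi) + log(0.05) + log(0.1) + 0.5 * log(1 - 0.8^2))
  norm2 <- -2 * (log(2 * pi) + log(0.05) + log(0.1) + 0.5 * log(1 - 0.5^2))
  expect_equal(lp1 - norm1, lp2 - norm2, tolerance = 1e-12)

  # half-normal exponent prior: truncated-normal density, normalized
  p1 <- modifyList(base_p, list(b1 = 0.7))
  p2 <- modifyList(base_p, list(b1 = 1.3))
  expect_equal(log_prior(ps, p1) - log_prior(ps, p2),
               dnorm(0.7, 1, 0.5, log = TRUE) - dnorm(1.3, 1, 0.5, log = TRUE),
               tolerance = 1e-12)
})

test_that("JAGS prior marginals match the stated prior distributions", {
  # prior-only model: drop the likelihood loop, keep the hierarchy
  strip_likelihood <- function(code) {
    sub("for \\(i in 1:N\\) \\{[^}]*\\}", "", code)
  }
  draw_prior <- function(spec, monitors, n = 10000) {
    code <- strip_likelihood(spec$jags_code)
    jm <- rjags::jags.model(textConnection(code), data = list(J = 2),
                            inits = list(.RNG.name = "base::Mersenne-Twister",
                                         .RNG.seed = 99),
                            n.chains = 1, n.adapt = 200, quiet = TRUE)
    stats::update(jm, 500, progress.bar = "none")
    as.matrix(rjags::coda.samples(jm, monitors, n.iter = n * 5, thin = 5,
                                  progress.bar = "none"))
  }
  ks_dist <- function(x, cdf) {
    u <- sort(cdf(x))
    n <- length(u)
    max(pmax(abs(u - (seq_len(n) - 1) / n), abs(u - seq_len(n) / n)))
  }

  pm <- draw_prior(power_model_spec(), c("b0", "b1", "sigma_e"))
  # b0 ~ N(0, 5)
  expect_lt(ks_dist(pm[, "b0"], function(x) pnorm(x, 0, 5)), 0.02)
  # b1 ~ N(1, 0.5) truncated at zero
  cdf_b1 <- function(x) {
    (pnorm(x, 1, 0.5) - pnorm(0, 1, 0.5)) / (1 - pnorm(0, 1, 0.5))
  }
  expect_lt(ks_dist(pm[, "b1"], cdf_b1), 0.02)
  # sigma_e ~ half-t(3, 0, 2.5)
  cdf_ht <- function(x) 2 * pt(x / 2.5, 3) - 1
  expect_lt(ks_dist(pm[, "sigma_e"], cdf_ht), 0.02)

  lm_ <- draw_prior(linear_model_spec(), c("beta1", "rho", "sigma_u0"))
  expect_lt(ks_dist(lm_[, "beta1"], function(x) pnorm(x, 0, 1)), 0.02)
  expect_lt(ks_dist(lm_[, "rho"], function(x) punif(x, -1, 1)), 0.02)
  expect_lt(ks_dist(lm_[, "sigma_u0"], cdf_ht), 0.02)
})

test_that("fitting recovers known parameters from clean data", {
  lum <- luminance_stimulus_table()
  pop <- population_spec(mean_a = 0.5, sd_a = 0.05, mean_k = 1, sd_k = 0,
                         noise_sd = 0.005, n_participants = 8, seed = 17)
  ds <- preprocess(simulate_ratings(draw_participants(pop), lum,
                                    "standard", pop), log = FALSE)$dataset
  fit <- suppressWarnings(
    fit_scaling_model(power_model_spec(), ds, chains = 2, warmup = 400,
                      draws = 2000, adapt = 400, seed = 5)
  )
  sm <- posterior_summary(fit)
  b1 <- sm[sm$parameter == "b1", ]
  expect_lt(abs(b1$mean - 0.5), 2 * max(b1$sd, 0.05 / sqrt(8)))
  # the implied constant pins the reference rating: b0 = 0.1^(1 - a)
  b0 <- sm[sm$parameter == "b0", ]
  expect_lt(abs(b0$mean - 0.1^(1 - 0.5)), 4 * max(b0$sd, 0.01))
  # pointwise log likelihood has full dimensions and no gaps
  expect_equal(dim(fit$loglik), c(nrow(fit$draw_matrix), nrow(ds$trials)))
  expect_false(anyNA(fit$loglik))
  expect_true(all(c("b0", "b1", "sigma_u0", "sigma_u1", "sigma_e") %in%
                    names(fit$rhat)))
})

test_that("the same seed reproduces a fit exactly", {
  pair <- list(
    fit_small_pair(seed = 7)$power,
    local({
      pop <- population_spec(mean_a = 0.44, sd_a = 0.18, noise_sd = 0.03,
                             n_participants = 8, seed = 7)
      ds <- simulate_ratings(draw_participants(pop), luminance_stimulus_table(),
                             "standard", pop)
      ds <- preprocess(ds, log = FALSE)$dataset
      suppressWarnings(
        fit_scaling_model(power_model_spec(), ds, chains = 2, warmup = 300,
                          draws = 1000, adapt = 300, seed = 7)
      )
    })
  )
  expect_equal(pair[[1]]$draw_matrix, pair[[2]]$draw_matrix)
})

test_that("power and linear fits coincide on unit-exponent data", {
  lum <- luminance_stimulus_table()
  pop <- population_spec(mean_a = 1, sd_a = 0.05, sd_k = 0, noise_sd = 0.02,
                         n_participants = 8, seed = 23)
  ds <- preprocess(simulate_ratings(draw_participants(pop), lum,
                                    "standard", pop), log = FALSE)$dataset
  pfit <- suppressWarnings(
    fit_scaling_model(power_model_spec(), ds, chains = 2, warmup = 300,
                      draws = 1000, adapt = 300, seed = 2)
  )
  lfit <- suppressWarnings(
    fit_scaling_model(linear_model_spec(), ds, chains = 2, warmup = 300,
                      draws = 1000, adapt = 300, seed = 3)
  )
  mu_p <- colMeans(magscale:::fitted_means(pfit))
  mu_l <- colMeans(magscale:::fitted_means(lfit))
  ppsd <- sqrt(mean(pfit$draw_matrix[, "sigma_e"]^2))
  expect_lt(max(abs(mu_p - mu_l)), 2 * ppsd)
})

test_that("the unconstrained log posterior matches its constrained pieces", {
  fits <- fit_small_pair(seed = 7)
  for (fit in fits[c("power", "linear")]) {
    eta <- magscale:::unconstrained_draws(fit)
    lp <- magscale:::log_posterior_unconstrained(fit)
    vals <- lp(eta[1:5, , drop = FALSE])
    expect_true(all(is.finite(vals)))
    # manual recomputation for the first draw
    d <- fit$data
    m <- fit$draw_matrix[1, ]
    J <- d$J
    if (fit$spec$name == "power") {
      params <- list(b0 = m[["b0"]], b1 = m[["b1"]],
                     u0 = m[paste0("u0[", 1:J, "]")],
                     u1 = m[paste0("u1[", 1:J, "]")],
                     sigma_u0 = m[["sigma_u0"]], sigma_u1 = m[["sigma_u1"]],
                     sigma_e = m[["sigma_e"]])
      ll <- sum(power_log_density(d$y, d$x,
                                  (m[["b0"]] + params$u0)[d$pid],
                                  (m[["b1"]] + params$u1)[d$pid],
                                  m[["sigma_e"]]))
      jac <- log(m[["b1"]]) + log(m[["sigma_u0"]]) + log(m[["sigma_u1"]]) +
        log(m[["sigma_e"]])
    } else {
      params <- list(beta0 = m[["beta0"]], beta1 = m[["beta1"]],
                     u = cbind(m[paste0("u[", 1:J, ",1]")],
                               m[paste0("u[", 1:J, ",2]")]),
                     sigma_u0 = m[["sigma_u0"]], sigma_u1 = m[["sigma_u1"]],
                     rho = m[["rho"]], sigma_e = m[["sigma_e"]])
      ll <- sum(linear_log_density(d$y, d$x,
                                   (m[["beta0"]] + params$u[, 1])[d$pid],
                                   (m[["beta1"]] + params$u[, 2])[d$pid],
                                   m[["sigma_e"]]))
      jac <- log(m[["sigma_u0"]]) + log(m[["sigma_u1"]]) +
        log(m[["sigma_e"]]) + log(1 - m[["rho"]]^2)
    }
    expect_equal(vals[1], unname(ll + log_prior(fit$spec, params) + jac),
                 tolerance = 1e-8)
  }
})
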