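#' Hierarchical psychophysical model specifications
#'
#' Two competing hierarchical Bayesian models for normalized ratings
#' y (rating / 100) as a function of normalized stimulus intensity x,
#' with participant-level intercepts and slopes:
#'
#' * **power law**: y ~ Normal(b0j * x^b1j, sigma_e^2), b0j = b0 + u0j,
#'   b1j = b1 + u1j, with priors b0 ~ Normal(0, 5), b1 ~ half-Normal(1, 0.5)
#'   (a normal truncated to positive support), independent participant
#'   effects u0 ~ Normal(0, sigma_u0^2), u1 ~ Normal(0, sigma_u1^2), and
#'   half-Student-t(3, 0, 2.5) priors on all standard deviations.
#' * **linear**: y ~ Normal(beta0j + beta1j * x, sigma_e^2) with priors
#'   beta0 ~ Normal(0, 5), beta1 ~ Normal(0, 1), correlated participant
#'   effects (u0, u1) ~ MVN(0, Sigma) with Sigma built from sigma_u0,
#'   sigma_u1 and a correlation rho ~ LKJ(1) (uniform on (-1, 1) for a
#'   2 x 2 correlation matrix), and half-Student-t(3, 0, 2.5) scale priors.
#'
#' The second argument of the normal priors is a standard deviation.
#'
#' @return an object of class `model_spec` with elements `name`,
#'   `jags_code` and `parameters`.
#' @export
power_model_spec <- function() {
  code <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(b0j[pid[i]] * pow(x[i], b1j[pid[i]]), tau_e)
  }
  # centered hierarchical form: b0j = b0 + u0j with u0 ~ N(0, sigma_u0^2)
  for (j in 1:J) {
    b0j[j] ~ dnorm(b0, tau_u0)
    b1j[j] ~ dnorm(b1, tau_u1)
  }
  b0 ~ dnorm(0, 0.04)          # SD 5
  b1 ~ dnorm(1, 4) T(0,)       # half-Normal(1, 0.5)
  sigma_u0 ~ dt(0, 0.16, 3) T(0,)   # half-Student-t(3, 0, 2.5)
  sigma_u1 ~ dt(0, 0.16, 3) T(0,)
  sigma_e ~ dt(0, 0.16, 3) T(0,)
  tau_u0 <- pow(sigma_u0, -2)
  tau_u1 <- pow(sigma_u1, -2)
  tau_e <- pow(sigma_e, -2)
}"
  structure(
    list(name = "power", jags_code = code,
         monitors = c("b0", "b1", "b0j", "b1j",
                      "sigma_u0", "sigma_u1", "sigma_e"),
         parameters = c("b0", "b1", "u0", "u1",
                        "sigma_u0", "sigma_u1", "sigma_e")),
    class = "model_spec"
  )
}

#' @rdname power_model_spec
#' @export
linear_model_spec <- function() {
  code <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(bj[pid[i], 1] + bj[pid[i], 2] * x[i], tau_e)
  }
  # centered form: bj = (beta0, beta1) + u with (u0, u1) ~ MVN(0, Sigma)
  for (j in 1:J) {
    bj[j, 1:2] ~ dmnorm(mu2, Omega)
  }
  mu2[1] <- beta0
  mu2[2] <- beta1
  beta0 ~ dnorm(0, 0.04)       # SD 5
  beta1 ~ dnorm(0, 1)          # SD 1
  sigma_u0 ~ dt(0, 0.16, 3) T(0,)
  sigma_u1 ~ dt(0, 0.16, 3) T(0,)
  rho ~ dunif(-1, 1)           # LKJ(1) on a 2x2 correlation matrix
  sigma_e ~ dt(0, 0.16, 3) T(0,)
  Sigma[1, 1] <- pow(sigma_u0, 2)
  Sigma[2, 2] <- pow(sigma_u1, 2)
  Sigma[1, 2] <- sigma_u0 * sigma_u1 * rho
  Sigma[2, 1] <- Sigma[1, 2]
  Omega <- inverse(Sigma)
  tau_e <- pow(sigma_e, -2)
}"
  structure(
    list(name = "linear", jags_code = code,
         monitors = c("beta0", "beta1", "bj", "sigma_u0", "sigma_u1",
                      "rho", "sigma_e"),
         parameters = c("beta0", "beta1", "u", "sigma_u0", "sigma_u1",
                        "rho", "sigma_e")),
    class = "model_spec"
  )
}

#' Pointwise log densities of the two likelihoods
#'
#' Normal log density of an observation under the participant-level mean:
#' `power_log_density` uses mean b0j * x^b1j, `linear_log_density` uses
#' beta0j + beta1j * x. Vectorized over observations.
#'
#' @param y normalized response(s).
#' @param x normalized intensity(ies), positive for the power model.
#' @param b0j,b1j,beta0j,beta1j participant-level coefficients.
#' @param sigma_e residual SD, positive.
#' @return log density contribution(s).
#' @export
power_log_density <- function(y, x, b0j, b1j, sigma_e) {
  if (any(sigma_e <= 0)) stop("sigma_e must be positive")
  if (any(x <= 0)) stop("x must be positive")
  stats::dnorm(y, b0j * x^b1j, sigma_e, log = TRUE)
}

#' @rdname power_log_density
#' @export
linear_log_density <- function(y, x, beta0j, beta1j, sigma_e) {
  if (any(sigma_e <= 0)) stop("sigma_e must be positive")
  stats::dnorm(y, beta0j + beta1j * x, sigma_e, log = TRUE)
}

#' Joint log prior density of a model's parameters
#'
#' Sum of the (normalized) prior log densities stated in the model
#' specification, including the participant effects given the variance
#' components; -Inf outside support (negative scales, nonpositive power-law
#' exponent, |rho| >= 1).
#'
#' @param spec a `model_spec`.
#' @param params named list: for the power model `b0`, `b1`, `u0` (vector),
#'   `u1` (vector), `sigma_u0`, `sigma_u1`, `sigma_e`; for the linear model
#'   `beta0`, `beta1`, `u` (J x 2 matrix), `sigma_u0`, `sigma_u1`, `rho`,
#'   `sigma_e`.
#' @return the log prior density.
#' @export
log_prior <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  p <- params
  scales_ok <- p$sigma_u0 > 0 && p$sigma_u1 > 0 && p$sigma_e > 0
  if (!scales_ok) return(-Inf)
  lp <- dhalf_t_log(p$sigma_u0, 3, 2.5) + dhalf_t_log(p$sigma_u1, 3, 2.5) +
    dhalf_t_log(p$sigma_e, 3, 2.5)
  if (spec$name == "power") {
    if (p$b1 <= 0) return(-Inf)
    lp <- lp + stats::dnorm(p$b0, 0, 5, log = TRUE) +
      dtruncnorm_pos_log(p$b1, 1, 0.5) +
      sum(stats::dnorm(p$u0, 0, p$sigma_u0, log = TRUE)) +
      sum(stats::dnorm(p$u1, 0, p$sigma_u1, log = TRUE))
  } else if (spec$name == "linear") {
    if (abs(p$rho) >= 1) return(-Inf)
    lp <- lp + stats::dnorm(p$beta0, 0, 5, log = TRUE) +
      stats::dnorm(p$beta1, 0, 1, log = TRUE) +
      log(0.5) + # LKJ(1): uniform correlation on (-1, 1)
      sum(dbinorm0_log(p$u, p$sigma_u0, p$sigma_u1, p$rho))
  } else {
    stop("unknown model spec")
  }
  lp
}

# ---- data preparation -------------------------------------------------------

#' Model data from a preprocessed dataset
#'
#' Maps a `rating_dataset` (raw response scale, standard-format recoded) to
#' the model's normalized scales: y = response / 100, x = normalized
#' intensity, plus a dense participant index.
#'
#' @param dataset a `rating_dataset` on the raw (not log) response scale.
#' @return list with `y`, `x`, `pid`, `J`, `N`, `participants`.
#' @export
model_data <- function(dataset) {
  stopifnot(inherits(dataset, "rating_dataset"))
  if (isTRUE(dataset$provenance$log_scale)) {
    stop("model fitting uses raw-scale responses (rating / 100), not logs")
  }
  tr <- dataset$trials
  ids <- sort(unique(tr$participant_id))
  list(
    y = tr$response / 100,
    x = tr$intensity,
    pid = match(tr$participant_id, ids),
    J = length(ids),
    N = nrow(tr),
    participants = ids
  )
}

# ---- fitting ----------------------------------------------------------------

#' Fit a hierarchical scaling model by MCMC
#'
#' Draws from the posterior of a [power_model_spec()] or
#' [linear_model_spec()] with JAGS. Defaults mirror the study settings:
#' four chains, a burn-in of 2,000 iterations per chain and 20,000
#' post-warmup draws in total. Per-draw pointwise log likelihoods are
#' retained for every observation, and split-chain R-hat and effective
#' sample sizes are computed for all population-level parameters; a
#' convergence warning is raised when any population-level R-hat exceeds
#' 1.01. Runs with the same seed, data and settings are identical.
#'
#' @param spec a `model_spec`.
#' @param dataset a `rating_dataset` (raw response scale) or a list from
#'   [model_data()].
#' @param chains number of Markov chains.
#' @param warmup burn-in iterations per chain (after adaptation).
#' @param draws total post-warmup draws across chains.
#' @param adapt JAGS adaptation iterations.
#' @param seed integer seed controlling all chains' RNG streams.
#' @param quiet suppress JAGS progress output.
#' @return a `posterior_samples` object: `draws` (coda mcmc.list),
#'   `draw_matrix` (pooled draws x parameters), `loglik` (draws x
#'   observations), `rhat`, `ess`, `spec`, `data`, `settings`.
#' @export
fit_scaling_model <- function(spec, dataset, chains = 4, warmup = 2000,
                              draws = 20000, adapt = 1000, seed = 1,
                              quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  dat <- if (inherits(dataset, "rating_dataset")) model_data(dataset) else dataset
  stopifnot(all(c("y", "x", "pid", "J", "N") %in% names(dat)))
  if (any(dat$x <= 0)) stop("intensities must be positive")
  n_iter <- ceiling(draws / chains)

  jdata <- list(y = dat$y, x = dat$x, pid = dat$pid, N = dat$N, J = dat$J)

  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = as.integer(seed) * 1000L + ch
    )
    if (spec$name == "power") {
      ini$b1 <- 0.8 + 0.1 * ch
      ini$b0 <- 0.2
    } else {
      ini$beta0 <- 0.05
      ini$beta1 <- 0.1 + 0.05 * ch
    }
    ini
  })

  jm <- rjags::jags.model(textConnection(spec$jags_code), data = jdata,
                          inits = inits, n.chains = chains, n.adapt = adapt,
                          quiet = quiet)
  stats::update(jm, warmup, progress.bar = "none")
  samp_raw <- rjags::coda.samples(jm, spec$monitors, n.iter = n_iter,
                                  progress.bar = "none")

  # re-express the centered participant coefficients as deviations u from the
  # population means (a unit-Jacobian reparameterization)
  samp <- coda::as.mcmc.list(lapply(samp_raw, function(ch) {
    coda::mcmc(deviation_draws(spec, as.matrix(ch), dat$J),
               start = stats::start(ch), thin = coda::thin(ch))
  }))
  draw_matrix <- as.matrix(samp)
  pop_only <- grep("^(u0|u1|u)\\[", colnames(draw_matrix),
                   value = TRUE, invert = TRUE)

  rhat <- tryCatch({
    gd <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
    stats::setNames(gd$psrf[, 1], rownames(gd$psrf))
  }, error = function(e) stats::setNames(rep(NA_real_, ncol(draw_matrix)),
                                         colnames(draw_matrix)))
  ess <- coda::effectiveSize(samp)

  if (chains > 1 && any(rhat[pop_only] > 1.01, na.rm = TRUE)) {
    warning("convergence warning: R-hat > 1.01 for ",
            paste(names(which(rhat[pop_only] > 1.01)), collapse = ", "),
            call. = FALSE)
  }

  loglik <- pointwise_loglik(spec, draw_matrix, dat)

  structure(
    list(
      draws = samp, draw_matrix = draw_matrix, loglik = loglik,
      rhat = rhat, ess = ess, spec = spec, data = dat,
      settings = list(chains = chains, warmup = warmup, draws = nrow(draw_matrix),
                      adapt = adapt, seed = seed)
    ),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples> ", x$spec$name, " model: ",
      nrow(x$draw_matrix), " draws x ", ncol(x$draw_matrix), " parameters, ",
      x$data$N, " observations, ", x$data$J, " participants\n", sep = "")
  print(utils::head(posterior_summary(x), 8))
  invisible(x)
}

#' Posterior summary table
#'
#' Means, SDs, central 95% credible intervals, R-hat and effective sample
#' size per parameter, mirroring the reporting format of hierarchical-model
#' tables (population constant/exponent, variance components).
#'
#' @param samples a `posterior_samples` object.
#' @return a tibble with one row per parameter.
#' @export
posterior_summary <- function(samples) {
  m <- samples$draw_matrix
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975)))
  tibble::tibble(
    parameter = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = qs[, 1],
    q97.5 = qs[, 2],
    rhat = unname(samples$rhat[colnames(m)]),
    ess = unname(samples$ess[colnames(m)])
  )
}

# map monitored centered coefficients (b0j / bj) to population parameters
# plus deviations (u0, u1 / u) in a fixed column order
deviation_draws <- function(spec, m, J) {
  if (spec$name == "power") {
    u0 <- m[, paste0("b0j[", seq_len(J), "]"), drop = FALSE] - m[, "b0"]
    u1 <- m[, paste0("b1j[", seq_len(J), "]"), drop = FALSE] - m[, "b1"]
    colnames(u0) <- paste0("u0[", seq_len(J), "]")
    colnames(u1) <- paste0("u1[", seq_len(J), "]")
    cbind(m[, c("b0", "b1"), drop = FALSE], u0, u1,
          m[, c("sigma_u0", "sigma_u1", "sigma_e"), drop = FALSE])
  } else {
    u0 <- m[, paste0("bj[", seq_len(J), ",1]"), drop = FALSE] - m[, "beta0"]
    u1 <- m[, paste0("bj[", seq_len(J), ",2]"), drop = FALSE] - m[, "beta1"]
    colnames(u0) <- paste0("u[", seq_len(J), ",1]")
    colnames(u1) <- paste0("u[", seq_len(J), ",2]")
    cbind(m[, c("beta0", "beta1"), drop = FALSE], u0, u1,
          m[, c("sigma_u0", "sigma_u1", "rho", "sigma_e"), drop = FALSE])
  }
}

# draws x observations matrix of pointwise log likelihoods
pointwise_loglik <- function(spec, draw_matrix, dat) {
  S <- nrow(draw_matrix)
  if (spec$name == "power") {
    b0 <- draw_matrix[, "b0"] + draw_matrix[, paste0("u0[", dat$pid, "]"), drop = FALSE]
    b1 <- draw_matrix[, "b1"] + draw_matrix[, paste0("u1[", dat$pid, "]"), drop = FALSE]
    mu <- b0 * exp(sweep(b1, 2, log(dat$x), `*`)) # b0j * x^b1j per draw
    out <- stats::dnorm(matrix(dat$y, S, dat$N, byrow = TRUE), mu,
                        draw_matrix[, "sigma_e"], log = TRUE)
  } else {
    be0 <- draw_matrix[, "beta0"] + draw_matrix[, paste0("u[", dat$pid, ",1]"), drop = FALSE]
    be1 <- draw_matrix[, "beta1"] + draw_matrix[, paste0("u[", dat$pid, ",2]"), drop = FALSE]
    mu <- be0 + sweep(be1, 2, dat$x, `*`)
    out <- stats::dnorm(matrix(dat$y, S, dat$N, byrow = TRUE), mu,
                        draw_matrix[, "sigma_e"], log = TRUE)
  }
  out
}

# participant-level fitted means per draw (draws x observations)
fitted_means <- function(samples) {
  dat <- samples$data
  m <- samples$draw_matrix
  if (samples$spec$name == "power") {
    b0 <- m[, "b0"] + m[, paste0("u0[", dat$pid, "]"), drop = FALSE]
    b1 <- m[, "b1"] + m[, paste0("u1[", dat$pid, "]"), drop = FALSE]
    b0 * exp(sweep(b1, 2, log(dat$x), `*`))
  } else {
    be0 <- m[, "beta0"] + m[, paste0("u[", dat$pid, ",1]"), drop = FALSE]
    be1 <- m[, "beta1"] + m[, paste0("u[", dat$pid, ",2]"), drop = FALSE]
    be0 + sweep(be1, 2, dat$x, `*`)
  }
}

# ---- unconstrained parameterization (bridge sampling support) ---------------

# order of the unconstrained vector:
# power:  b0, log b1, u0[1:J], u1[1:J], log sigma_u0, log sigma_u1, log sigma_e
# linear: beta0, beta1, u0[1:J], u1[1:J], log sigma_u0, log sigma_u1,
#         atanh rho, log sigma_e
unconstrained_draws <- function(samples) {
  m <- samples$draw_matrix
  J <- samples$data$J
  if (samples$spec$name == "power") {
    cbind(
      m[, "b0"], log(m[, "b1"]),
      m[, paste0("u0[", seq_len(J), "]"), drop = FALSE],
      m[, paste0("u1[", seq_len(J), "]"), drop = FALSE],
      log(m[, "sigma_u0"]), log(m[, "sigma_u1"]), log(m[, "sigma_e"])
    )
  } else {
    cbind(
      m[, "beta0"], m[, "beta1"],
      m[, paste0("u[", seq_len(J), ",1]"), drop = FALSE],
      m[, paste0("u[", seq_len(J), ",2]"), drop = FALSE],
      log(m[, "sigma_u0"]), log(m[, "sigma_u1"]),
      atanh(m[, "rho"]), log(m[, "sigma_e"])
    )
  }
}

# log unnormalized posterior (likelihood x prior) on the unconstrained scale,
# including the log Jacobian of the transforms; eta is a matrix (rows =
# evaluation points). Fully vectorized over rows.
log_posterior_unconstrained <- function(samples) {
  spec <- samples$spec
  dat <- samples$data
  J <- dat$J
  Y <- NULL # observation matrix built lazily per batch size
  force(spec); force(dat)
  function(eta) {
    if (is.null(dim(eta))) eta <- matrix(eta, nrow = 1)
    S <- nrow(eta)
    Ym <- matrix(dat$y, S, dat$N, byrow = TRUE)
    if (spec$name == "power") {
      b0 <- eta[, 1]; lb1 <- eta[, 2]; b1 <- exp(lb1)
      u0 <- eta[, 3:(2 + J), drop = FALSE]
      u1 <- eta[, (3 + J):(2 + 2 * J), drop = FALSE]
      ls0 <- eta[, 2 * J + 3]; ls1 <- eta[, 2 * J + 4]; lse <- eta[, 2 * J + 5]
      s_u0 <- exp(ls0); s_u1 <- exp(ls1); s_e <- exp(lse)
      mu <- (b0 + u0[, dat$pid, drop = FALSE]) *
        exp(sweep(b1 + u1[, dat$pid, drop = FALSE], 2, log(dat$x), `*`))
      ll <- rowSums(stats::dnorm(Ym, mu, s_e, log = TRUE))
      lp <- stats::dnorm(b0, 0, 5, log = TRUE) +
        dtruncnorm_pos_log(b1, 1, 0.5) +
        rowSums(stats::dnorm(u0, 0, s_u0, log = TRUE)) +
        rowSums(stats::dnorm(u1, 0, s_u1, log = TRUE)) +
        dhalf_t_log(s_u0, 3, 2.5) + dhalf_t_log(s_u1, 3, 2.5) +
        dhalf_t_log(s_e, 3, 2.5)
      jac <- lb1 + ls0 + ls1 + lse
    } else {
      b0 <- eta[, 1]; b1 <- eta[, 2]
      u0 <- eta[, 3:(2 + J), drop = FALSE]
      u1 <- eta[, (3 + J):(2 + 2 * J), drop = FALSE]
      ls0 <- eta[, 2 * J + 3]; ls1 <- eta[, 2 * J + 4]
      zr <- eta[, 2 * J + 5]; lse <- eta[, 2 * J + 6]
      s_u0 <- exp(ls0); s_u1 <- exp(ls1); rho <- tanh(zr); s_e <- exp(lse)
      mu <- (b0 + u0[, dat$pid, drop = FALSE]) +
        (b1 + u1[, dat$pid, drop = FALSE]) *
        matrix(dat$x, S, dat$N, byrow = TRUE)
      ll <- rowSums(stats::dnorm(Ym, mu, s_e, log = TRUE))
      z1 <- u0 / s_u0
      z2 <- u1 / s_u1
      quad <- rowSums(z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
      lmvn <- -J * (log(2 * pi) + log(s_u0) + log(s_u1) +
                      0.5 * log(1 - rho^2)) - quad / 2
      lp <- stats::dnorm(b0, 0, 5, log = TRUE) +
        stats::dnorm(b1, 0, 1, log = TRUE) +
        log(0.5) + lmvn +
        dhalf_t_log(s_u0, 3, 2.5) + dhalf_t_log(s_u1, 3, 2.5) +
        dhalf_t_log(s_e, 3, 2.5)
      jac <- ls0 + ls1 + lse + log(1 - rho^2)
    }
    ll + lp + jac
  }
}
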