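lum <- luminance_stimulus_table()

test_that("participant draws honour degenerate spread and the seed contract", {
  pop0 <- population_spec(mean_k = 1.2, sd_k = 0, mean_a = 0.5, sd_a = 0,
                          n_participants = 7, seed = 3)
  p0 <- draw_participants(pop0)
  expect_equal(p0$k, rep(1.2, 7))
  expect_equal(p0$a, rep(0.5, 7))

  pop <- population_spec(sd_k = 0.3, sd_a = 0.2, n_participants = 50, seed = 11)
  expect_identical(draw_participants(pop), draw_participants(pop))
  pop2 <- population_spec(sd_k = 0.3, sd_a = 0.2, n_participants = 50, seed = 12)
  expect_false(identical(draw_participants(pop), draw_participants(pop2)))
})

test_that("exponent draws match truncated-normal moments at large n", {
  pop <- population_spec(mean_a = 0.5, sd_a = 0.1, n_participants = 10000,
                         seed = 21)
  a <- draw_participants(pop)$a
  # closed-form mean of N(0.5, 0.1^2) truncated to (0, Inf)
  alpha <- -0.5 / 0.1
  mu_trunc <- 0.5 + 0.1 * dnorm(alpha) / (1 - pnorm(alpha))
  se <- 0.1 / sqrt(10000)
  expect_lt(abs(mean(a) - mu_trunc), 3 * se)
  expect_true(all(a > 0))
})

test_that("noiseless ratings obey the response-format algebra", {
  pop <- population_spec(mean_k = 1, sd_k = 0.4, mean_a = 0.44, sd_a = 0.2,
                         noise_sd = 0, n_participants = 5, seed = 5)
  parts <- draw_participants(pop)
  std <- simulate_ratings(parts, lum, "standard", pop)
  rev <- simulate_ratings(parts, lum, "reversal", pop)
  uni <- simulate_ratings(parts, lum, "unidirectional", pop)

  # reversal is the reciprocal of standard, trial for trial
  expect_equal(rev$trials$response, 100 / std$trials$response,
               tolerance = 1e-12)
  # unidirectional ratings never drop below the modulus
  expect_true(all(uni$trials$response >= 10))
  # ... and stay at or above it even under response noise
  popn <- population_spec(mean_a = 0.55, sd_a = 0.3, noise_sd = 0.05,
                          n_participants = 20, seed = 77)
  noisy <- simulate_ratings(draw_participants(popn), lum,
                            "unidirectional", popn)
  expect_true(all(noisy$trials$response >= 10))
  # back-transforming below-reference unidirectional trials recovers standard
  below <- uni$trials$intensity < 0.1
  expect_equal(100 / uni$trials$response[below], std$trials$response[below],
               tolerance = 1e-12)
  # direction matches the objective relation when no errors are injected
  expect_equal(uni$trials$direction, ifelse(uni$trials$latent_f >= 1,
                                            "higher", "lower"))
})

test_that("a unit-exponent observer rates the brightest stimulus 100", {
  pop <- population_spec(mean_k = 1, sd_k = 0, mean_a = 1, sd_a = 0,
                         noise_sd = 0, n_participants = 1, seed = 1)
  ds <- simulate_ratings(draw_participants(pop), lum, "standard", pop)
  brightest <- ds$trials$response[ds$trials$stimulus_id == 9]
  expect_equal(brightest, rep(100, 5), tolerance = 1e-12)
  # intensity equal to the reference would be rated exactly 10: nearest check
  # via latent ratio at the reference intensity
  expect_equal(10 * (0.1 / 0.1)^1, 10)
})

test_that("noiseless log ratings are linear in log intensity with slope a", {
  pop <- population_spec(mean_a = 0.37, sd_a = 0.15, noise_sd = 0,
                         n_participants = 6, seed = 9)
  parts <- draw_participants(pop)
  ds <- simulate_ratings(parts, lum, "standard", pop)
  for (j in parts$participant_id) {
    tr <- ds$trials[ds$trials$participant_id == j, ]
    fit <- lm(log(response) ~ log(intensity), data = tr)
    expect_equal(unname(coef(fit)[2]), parts$a[parts$participant_id == j],
                 tolerance = 1e-9)
  }
})

test_that("trial bookkeeping matches the 8 x 5 design", {
  pop <- study_population(2, "standard", seed = 2)
  ds <- simulate_ratings(draw_participants(pop), lum, "standard", pop)
  counts <- table(ds$trials$participant_id)
  expect_true(all(counts == 40))
  expect_false(any(ds$trials$stimulus_id == lum$reference_id))
  expect_error(simulate_ratings(draw_participants(pop), lum, "sideways", pop),
               "unknown method")
})

test_that("generated datasets write byte-identical CSVs under one spec", {
  pop <- population_spec(n_participants = 4, seed = 33)
  gen <- function() {
    ds <- simulate_ratings(draw_participants(pop), lum, "unidirectional", pop)
    path <- tempfile(fileext = ".csv")
    write_ratings_csv(ds, path)
    on.exit(unlink(path))
    readLines(path)
  }
  expect_identical(gen(), gen())
})

test_that("ratings CSV round-trips and validates its schema", {
  pop <- population_spec(n_participants = 3, seed = 14)
  ds <- simulate_ratings(draw_participants(pop), lum, "unidirectional", pop)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(ds, path)
  back <- read_ratings_csv(path, lum)
  expect_equal(back$trials$response, ds$trials$response)
  expect_equal(back$trials$direction, ds$trials$direction)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(suppressWarnings(read_ratings_csv(bad, lum)))
})

test_that("anchoring bias blends below-reference ratings as specified", {
  pop <- population_spec(mean_a = 0.5, sd_a = 0.2, noise_sd = 0,
                         n_participants = 4, seed = 8)
  parts <- draw_participants(pop)
  ds <- simulate_ratings(parts, lum, "standard", pop)

  # lambda = 1 is the identity
  expect_equal(apply_anchoring_bias(ds, 1)$trials$response,
               ds$trials$response)

  # lambda = 0 with f = 1/2 gives the pure difference response 10 - 1 = 9
  one <- ds
  one$trials <- one$trials[1, ]
  one$trials$latent_f <- 0.5
  one$trials$response <- 10 * 0.5
  expect_equal(apply_anchoring_bias(one, 0)$trials$response, 9)

  # above-reference trials are untouched for any lambda
  biased <- apply_anchoring_bias(ds, 0.3)
  above <- ds$trials$latent_f >= 1
  expect_equal(biased$trials$response[above], ds$trials$response[above])
  # partial bias lies between unbiased (lambda = 1) and full bias (lambda = 0)
  full <- apply_anchoring_bias(ds, 0)
  below <- ds$trials$latent_f < 1
  lo <- pmin(ds$trials$response[below], full$trials$response[below])
  hi <- pmax(ds$trials$response[below], full$trials$response[below])
  expect_true(all(biased$trials$response[below] >= lo - 1e-12))
  expect_true(all(biased$trials$response[below] <= hi + 1e-12))
  # the biased rating is still monotone in the latent ratio
  one_part <- biased$trials[below & biased$trials$participant_id == 1, ]
  one_part <- one_part[order(one_part$latent_f), ]
  expect_true(all(diff(one_part$response) >= -1e-12))
  expect_error(apply_anchoring_bias(ds, 1.2), "lambda")
})

test_that("the linear generator produces linear population data", {
  ds <- simulate_linear_ratings(lum, n_participants = 40, noise_sd = 0,
                                sd_intercept = 0, sd_slope = 0,
                                mean_intercept = 0.05, mean_slope = 0.3,
                                seed = 4)
  fit <- lm(I(response / 100) ~ intensity, data = ds$trials)
  expect_equal(unname(coef(fit)), c(0.05, 0.3), tolerance = 1e-9)
})
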