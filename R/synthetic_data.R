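#' Population specification for synthetic magnitude-estimation experiments
#'
#' Describes the participant population from which synthetic raters are
#' drawn. Each participant j perceives intensity I through a personal power
#' law psi_j(I) = k_j * I^(a_j); k and a are drawn from normal distributions
#' truncated at zero. Because ratings are ratios to the reference stimulus
#' (the modulus), the proportionality constant k cancels from every rating
#' and only the exponent a shapes the response curve; k is retained so the
#' perceptual model is stated in full.
#'
#' @param mean_k,sd_k population mean and SD of the proportionality constant.
#' @param mean_a,sd_a population mean and SD of the power-law exponent.
#' @param noise_sd residual SD of the response on the normalized (rating/100)
#'   scale, matching the fitted models' likelihood.
#' @param n_participants number of participants.
#' @param n_reps repetitions per test stimulus (5 in all three studies,
#'   giving 8 x 5 = 40 trials per condition).
#' @param bias_lambda anchoring-bias mixing weight in \[0, 1\]; 1 = unbiased
#'   ratio responding (see [apply_anchoring_bias()]).
#' @param bias_c slope of the difference-thinker response (default 1).
#' @param direction_error_rate probability that the binary direction
#'   judgment (unidirectional / binary-standard formats) is flipped.
#' @param seed integer RNG seed; identical specs generate identical data.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(mean_k = 1, sd_k = 0.3,
                            mean_a = 0.44, sd_a = 0.18,
                            noise_sd = 0.03,
                            n_participants = 16, n_reps = 5,
                            bias_lambda = 1, bias_c = 1,
                            direction_error_rate = 0,
                            seed = 1) {
  stopifnot(
    mean_k > 0, sd_k >= 0, mean_a > 0, sd_a >= 0, noise_sd >= 0,
    n_participants >= 1, n_reps >= 1,
    bias_lambda >= 0, bias_lambda <= 1, bias_c >= 0,
    direction_error_rate >= 0, direction_error_rate <= 1
  )
  structure(
    list(
      mean_k = mean_k, sd_k = sd_k, mean_a = mean_a, sd_a = sd_a,
      noise_sd = noise_sd, n_participants = as.integer(n_participants),
      n_reps = as.integer(n_reps), bias_lambda = bias_lambda,
      bias_c = bias_c, direction_error_rate = direction_error_rate,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' Study-condition population specifications
#'
#' Returns the generator settings emulating one arm of the three studies.
#' Exponent means/SDs and residual SDs follow the fitted hierarchical
#' power-law posteriors per condition; direction-error rates reproduce the
#' reported erroneous-trial percentages. Study 1 used 20 participants in a
#' fully within-subject design, Study 2 compared 16 (standard) with 18
#' (unidirectional) participants between subjects plus an additional
#' binary-standard sample of 19, Study 3 used 18 per arm.
#'
#' @param study 1, 2 or 3.
#' @param method response format of the arm: `"standard"`, `"reversal"`,
#'   `"unidirectional"` or `"binary_standard"`.
#' @param seed RNG seed stored in the spec.
#' @return a [population_spec].
#' @export
study_population <- function(study, method = "standard", seed = 1) {
  study <- as.integer(study)
  if (!study %in% 1:3) stop("study must be 1, 2 or 3")
  ok <- switch(as.character(study),
    "1" = c("standard", "reversal"),
    "2" = c("standard", "unidirectional", "binary_standard"),
    "3" = c("standard", "unidirectional")
  )
  if (!method %in% ok) {
    stop("method ", method, " not part of study ", study)
  }
  if (study == 1L) {
    population_spec(mean_a = 0.44, sd_a = 0.18, noise_sd = 0.03,
                    n_participants = 20, seed = seed)
  } else if (study == 2L) {
    switch(method,
      standard = population_spec(mean_a = 0.44, sd_a = 0.18, noise_sd = 0.03,
                                 n_participants = 16, seed = seed),
      unidirectional = population_spec(mean_a = 0.55, sd_a = 0.30,
                                       noise_sd = 0.05, n_participants = 18,
                                       direction_error_rate = 0.0014,
                                       seed = seed),
      binary_standard = population_spec(mean_a = 0.42, sd_a = 0.18,
                                        noise_sd = 0.03, n_participants = 19,
                                        direction_error_rate = 0.0014,
                                        seed = seed)
    )
  } else {
    switch(method,
      standard = population_spec(mean_a = 1.99, sd_a = 1.01, noise_sd = 0.04,
                                 n_participants = 18, seed = seed),
      unidirectional = population_spec(mean_a = 1.73, sd_a = 0.91,
                                       noise_sd = 0.04, n_participants = 18,
                                       direction_error_rate = 0.0222,
                                       seed = seed)
    )
  }
}

#' Draw per-participant psychometric functions
#'
#' Samples `n_participants` pairs (k, a) from normal distributions truncated
#' at zero with the population means and SDs of `pop`. With zero SDs every
#' participant gets exactly the population mean.
#'
#' @param pop a [population_spec].
#' @return a tibble with columns `participant_id`, `k`, `a`.
#' @export
draw_participants <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  with_preserved_seed(pop$seed, {
    tibble::tibble(
      participant_id = seq_len(pop$n_participants),
      k = rtruncnorm_pos(pop$n_participants, pop$mean_k, pop$sd_k),
      a = rtruncnorm_pos(pop$n_participants, pop$mean_a, pop$sd_a)
    )
  })
}

rating_methods <- c("standard", "reversal", "unidirectional", "binary_standard")

new_rating_dataset <- function(trials, stimulus_set, provenance) {
  structure(
    list(trials = tibble::as_tibble(trials), stimulus_set = stimulus_set,
         provenance = provenance),
    class = "rating_dataset"
  )
}

#' @export
print.rating_dataset <- function(x, ...) {
  cat("<rating_dataset> ", nrow(x$trials), " trials, ",
      length(unique(x$trials$participant_id)), " participants, methods: ",
      paste(unique(x$trials$method), collapse = ", "), "\n", sep = "")
  print(utils::head(x$trials))
  invisible(x)
}

#' Simulate trial-level magnitude-estimation ratings
#'
#' Generates one condition of a synthetic experiment. Each participant rates
#' every test stimulus `n_reps` times. The noiseless latent perceived ratio
#' is f_j(s) = psi_j(I_s) / psi_j(I_ref); the response format maps it to a
#' rating anchored at the modulus 10:
#' standard 10 f, reversal 10 / f, unidirectional 10 max(f, 1/f) with a
#' binary direction judgment ("higher"/"lower" intensity than the
#' reference), binary_standard a standard rating preceded by the direction
#' judgment. Normal noise with SD `pop$noise_sd` is added on the normalized
#' rating/100 scale and the rating is truncated at zero.
#'
#' @param participants tibble from [draw_participants()].
#' @param stimulus_set a [stimulus_set].
#' @param method one of `"standard"`, `"reversal"`, `"unidirectional"`,
#'   `"binary_standard"`.
#' @param pop the [population_spec] (noise, repetitions, seed, error rate).
#' @return a `rating_dataset`: trial tibble (columns `participant_id`,
#'   `method`, `stimulus_id`, `intensity`, `response`, `direction`,
#'   `trial_index`, plus the generator-internal `latent_f`), the stimulus
#'   set, and the generating parameters as provenance.
#' @export
simulate_ratings <- function(participants, stimulus_set, method, pop) {
  stopifnot(inherits(stimulus_set, "stimulus_set"),
            inherits(pop, "population_spec"))
  if (!method %in% rating_methods) {
    stop("unknown method: ", method)
  }
  tests <- test_stimuli(stimulus_set)
  i_ref <- reference_intensity(stimulus_set)
  modulus <- stimulus_set$reference_rating

  grid <- tidyr::expand_grid(
    participant_id = participants$participant_id,
    stimulus_id = rep(tests$stimulus_id, times = pop$n_reps)
  )
  grid <- dplyr::left_join(grid, participants, by = "participant_id")
  grid <- dplyr::left_join(
    grid, stimulus_set$stimuli[, c("stimulus_id", "intensity")],
    by = "stimulus_id"
  )
  # k cancels in the ratio; written out in full for clarity.
  f <- (grid$k * grid$intensity^grid$a) / (grid$k * i_ref^grid$a)

  base <- switch(method,
    standard = modulus * f,
    binary_standard = modulus * f,
    reversal = modulus / f,
    unidirectional = modulus * pmax(f, 1 / f)
  )

  # seed offset keeps trial noise independent of the participant draws
  trials <- with_preserved_seed(pop$seed + 1L, {
    eps <- stats::rnorm(length(f), 0, pop$noise_sd)
    # the unidirectional format only admits ratings at or above the modulus;
    # the other formats admit any nonnegative rating
    floor_rating <- if (method == "unidirectional") modulus else 0
    response <- pmax(floor_rating / 100, base / 100 + eps) * 100
    direction <- rep(NA_character_, length(f))
    if (method %in% c("unidirectional", "binary_standard")) {
      direction <- ifelse(f >= 1, "higher", "lower")
      if (pop$direction_error_rate > 0) {
        flip <- stats::runif(length(f)) < pop$direction_error_rate
        direction[flip] <- ifelse(direction[flip] == "higher",
                                  "lower", "higher")
      }
    }
    tibble::tibble(
      participant_id = grid$participant_id,
      method = method,
      stimulus_id = grid$stimulus_id,
      intensity = grid$intensity,
      response = response,
      direction = direction,
      trial_index = stats::ave(seq_along(f), grid$participant_id,
                               FUN = seq_along),
      latent_f = f
    )
  })

  ds <- new_rating_dataset(trials, stimulus_set,
                           provenance = c(unclass(pop), list(method = method)))
  if (method == "standard" && pop$bias_lambda < 1) {
    ds <- apply_anchoring_bias(ds, pop$bias_lambda, pop$bias_c)
  }
  ds
}

#' Apply an anchoring ("difference-thinking") bias to standard-format ratings
#'
#' Operationalizes the hypothesis that some raters judge below-reference
#' stimuli by perceived differences rather than ratios. For trials whose
#' latent perceived ratio f is below 1, the noiseless rating 10 f is blended
#' with a difference-responder's rating max(0, 10 - c (1/f - 1)):
#' biased = lambda (10 f) + (1 - lambda) max(0, 10 - c (1/f - 1)),
#' and the trial's original noise deviation is carried over. lambda = 1
#' returns the input unchanged; above-reference trials are never touched.
#' The transform is monotone in f. lambda and c are simulator knobs, not
#' estimates of any empirical quantity.
#'
#' @param dataset a standard-format `rating_dataset` produced by
#'   [simulate_ratings()] (the latent ratio column is required).
#' @param lambda mixing weight in \[0, 1\].
#' @param c_bias difference-responder slope (default 1 rating unit per unit
#'   of 1/f).
#' @return the biased `rating_dataset`.
#' @export
apply_anchoring_bias <- function(dataset, lambda, c_bias = 1) {
  stopifnot(inherits(dataset, "rating_dataset"))
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  tr <- dataset$trials
  if (!all(tr$method == "standard")) {
    stop("anchoring bias applies to standard-format datasets only")
  }
  if (is.null(tr$latent_f)) {
    stop("dataset lacks the generator's latent ratio column")
  }
  modulus <- dataset$stimulus_set$reference_rating
  below <- tr$latent_f < 1
  unbiased <- modulus * tr$latent_f[below]
  diff_resp <- pmax(0, modulus - c_bias * (1 / tr$latent_f[below] - 1))
  noise_dev <- tr$response[below] - unbiased
  tr$response[below] <- pmax(
    0, lambda * unbiased + (1 - lambda) * diff_resp + noise_dev
  )
  dataset$trials <- tr
  dataset$provenance$bias_lambda <- lambda
  dataset$provenance$bias_c <- c_bias
  dataset
}

#' Simulate ratings from a linear response population
#'
#' Counterpart generator to [simulate_ratings()] for a world in which the
#' normalized response is linear in normalized intensity rather than a
#' power function: y = beta0_j + beta1_j x + noise, with participant
#' intercepts and slopes drawn from normal distributions (slopes truncated
#' at zero) and the rating = 100 y truncated at zero. Used to calibrate
#' model selection: data from this generator should be preferred by the
#' hierarchical linear model. Defaults follow the linear-model posterior of
#' the unidirectional luminance arm (intercept 0.05, slope 0.28, between-
#' participant SDs 0.02 and 0.17, residual SD 0.05).
#'
#' @param stimulus_set a [stimulus_set].
#' @param n_participants,n_reps design size (defaults 18 participants,
#'   5 repetitions).
#' @param mean_intercept,sd_intercept population intercept distribution on
#'   the normalized response scale.
#' @param mean_slope,sd_slope population slope distribution (truncated at 0).
#' @param noise_sd residual SD on the normalized response scale.
#' @param seed integer RNG seed.
#' @return a `rating_dataset` labelled with method `"standard"`.
#' @export
simulate_linear_ratings <- function(stimulus_set, n_participants = 18,
                                    n_reps = 5,
                                    mean_intercept = 0.05,
                                    sd_intercept = 0.02,
                                    mean_slope = 0.28, sd_slope = 0.17,
                                    noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(stimulus_set, "stimulus_set"))
  tests <- test_stimuli(stimulus_set)
  with_preserved_seed(seed, {
    beta0 <- stats::rnorm(n_participants, mean_intercept, sd_intercept)
    beta1 <- rtruncnorm_pos(n_participants, mean_slope, sd_slope)
    grid <- tidyr::expand_grid(
      participant_id = seq_len(n_participants),
      stimulus_id = rep(tests$stimulus_id, times = n_reps)
    )
    grid <- dplyr::left_join(
      grid, stimulus_set$stimuli[, c("stimulus_id", "intensity")],
      by = "stimulus_id"
    )
    y <- beta0[grid$participant_id] + beta1[grid$participant_id] * grid$intensity +
      stats::rnorm(nrow(grid), 0, noise_sd)
    trials <- tibble::tibble(
      participant_id = grid$participant_id,
      method = "standard",
      stimulus_id = grid$stimulus_id,
      intensity = grid$intensity,
      response = pmax(0, y) * 100,
      direction = NA_character_,
      trial_index = stats::ave(seq_len(nrow(grid)), grid$participant_id,
                               FUN = seq_along),
      latent_f = NA_real_
    )
    new_rating_dataset(
      trials, stimulus_set,
      provenance = list(generator = "linear", mean_intercept = mean_intercept,
                        sd_intercept = sd_intercept, mean_slope = mean_slope,
                        sd_slope = sd_slope, noise_sd = noise_sd,
                        n_participants = n_participants, n_reps = n_reps,
                        seed = seed)
    )
  })
}

#' Bind several condition arms into one dataset
#'
#' @param ... `rating_dataset` objects sharing one stimulus set.
#' @return a combined `rating_dataset`.
#' @export
bind_ratings <- function(...) {
  arms <- list(...)
  stopifnot(length(arms) >= 1, all(vapply(arms, inherits, TRUE, "rating_dataset")))
  new_rating_dataset(
    dplyr::bind_rows(lapply(arms, `[[`, "trials")),
    arms[[1]]$stimulus_set,
    provenance = lapply(arms, `[[`, "provenance")
  )
}

ratings_csv_columns <- c("participant_id", "method", "stimulus_id",
                         "intensity", "response", "direction", "trial_index")

#' Write / read trial-level ratings as CSV
#'
#' The on-disk schema is `participant_id, method, stimulus_id, intensity,
#' response, direction, trial_index`; a missing direction is an empty field.
#' Identical generator specifications produce byte-identical files.
#'
#' @param dataset a `rating_dataset`.
#' @param path file path.
#' @param stimulus_set stimulus set to attach on reading.
#' @return `read_ratings_csv` returns a `rating_dataset`;
#'   `write_ratings_csv` returns `path` invisibly.
#' @export
write_ratings_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "rating_dataset"))
  readr::write_csv(dataset$trials[, ratings_csv_columns], path, na = "")
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path, stimulus_set) {
  tr <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_integer(),
      method = readr::col_character(),
      stimulus_id = readr::col_integer(),
      intensity = readr::col_double(),
      response = readr::col_double(),
      direction = readr::col_character(),
      trial_index = readr::col_integer()
    )
  )
  if (!identical(names(tr), ratings_csv_columns)) {
    stop("ratings CSV must have columns: ",
         paste(ratings_csv_columns, collapse = ", "))
  }
  bad <- !tr$stimulus_id %in% stimulus_set$stimuli$stimulus_id
  if (any(bad)) stop("unknown stimulus_id in ratings CSV")
  if (any(tr$stimulus_id == stimulus_set$reference_id)) {
    stop("reference stimulus must not appear as a test stimulus")
  }
  new_rating_dataset(tr, stimulus_set, provenance = list(source = path))
}
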