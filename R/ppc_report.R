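#' Posterior predictive replicates
#'
#' Draws `n_rep` replicate response vectors from a fitted model: for each
#' replicate one posterior draw is selected and responses are simulated
#' from the model's normal likelihood at the observed design points
#' (participant and stimulus structure preserved). Comparing the observed
#' response distribution with the replicate distributions is the package's
#' posterior predictive check.
#'
#' @param samples a `posterior_samples` object.
#' @param n_rep number of replicate datasets (default 10).
#' @param seed RNG seed.
#' @return a `ppc_replicates` object: `y` (observed, normalized scale),
#'   `y_rep` (`n_rep` x N matrix), `stimulus` (intensity per observation),
#'   `model`, `draw_ids`.
#' @export
posterior_predictive <- function(samples, n_rep = 10, seed = 1) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (n_rep < 1) stop("n_rep must be at least 1")
  S <- nrow(samples$draw_matrix)
  mu <- fitted_means(samples)
  sig <- samples$draw_matrix[, "sigma_e"]
  with_preserved_seed(seed, {
    ids <- sample.int(S, n_rep, replace = n_rep > S)
    y_rep <- t(vapply(ids, function(s) {
      stats::rnorm(samples$data$N, mu[s, ], sig[s])
    }, numeric(samples$data$N)))
    structure(
      list(y = samples$data$y, y_rep = y_rep,
           stimulus = samples$data$x, model = samples$spec$name,
           draw_ids = ids),
      class = "ppc_replicates"
    )
  })
}

#' @export
print.ppc_replicates <- function(x, ...) {
  cat("<ppc_replicates> ", x$model, " model: ", nrow(x$y_rep),
      " replicates of ", length(x$y), " observations\n", sep = "")
  cat(sprintf("  observed mean %.4f; replicate means %.4f to %.4f\n",
              mean(x$y), min(rowMeans(x$y_rep)), max(rowMeans(x$y_rep))))
  invisible(x)
}

#' Density overlay of observed vs replicate responses
#'
#' Kernel density curves of the observed responses and each replicate,
#' pooled over stimuli as in the usual predictive-check display. The
#' bandwidth is fixed to Silverman's rule evaluated on the observed data so
#' that output is deterministic given the replicates.
#'
#' @param x a `ppc_replicates` object.
#' @param ... unused.
#' @return a ggplot object (requires ggplot2).
#' @export
plot.ppc_replicates <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  bw <- stats::bw.nrd0(x$y)
  dens <- function(v, id, type) {
    d <- stats::density(v, bw = bw)
    tibble::tibble(response = d$x, density = d$y, id = id, type = type)
  }
  dd <- dplyr::bind_rows(
    dens(x$y, "observed", "y"),
    dplyr::bind_rows(lapply(seq_len(nrow(x$y_rep)), function(i) {
      dens(x$y_rep[i, ], paste0("rep", i), "y_rep")
    }))
  )
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$response, y = .data$density,
                                   group = .data$id,
                                   colour = .data$type,
                                   linewidth = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(y = "#08306b", y_rep = "#9ecae1")) +
    ggplot2::scale_linewidth_manual(values = c(y = 1, y_rep = 0.4),
                                    guide = "none") +
    ggplot2::labs(x = "normalized response", y = "density",
                  colour = NULL, title = paste(x$model, "model")) +
    ggplot2::theme_minimal()
}

#' Pipeline configuration
#'
#' Bundles everything needed to run one study's analysis chain end to end:
#' which study design to emulate (or a CSV of real data), the response
#' formats to analyse, the sampler settings, and explicit seeds.
#'
#' @param study 1, 2 or 3.
#' @param methods response-format arms to analyse; defaults to the study's
#'   own arms.
#' @param input `NULL` to simulate from the study's generator conditions, or
#'   a path to a ratings CSV.
#' @param chains,warmup,draws,adapt sampler settings per
#'   [fit_scaling_model()].
#' @param n_bridge_reps bridge-sampling repetitions.
#' @param n_rep_ppc posterior-predictive replicates.
#' @param seed master integer seed; stage seeds are derived from it.
#' @param out_dir optional directory for report artifacts (JSON/CSV).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(study = 2, methods = NULL, input = NULL,
                            chains = 4, warmup = 2000, draws = 20000,
                            adapt = 1000, n_bridge_reps = 10, n_rep_ppc = 10,
                            seed = 1, out_dir = NULL) {
  study <- as.integer(study)
  if (!study %in% 1:3) stop("unknown study label: must be 1, 2 or 3")
  default_methods <- switch(as.character(study),
    "1" = c("standard", "reversal"),
    "2" = c("standard", "unidirectional"),
    "3" = c("standard", "unidirectional")
  )
  methods <- methods %||% default_methods
  cfg <- structure(
    list(study = study, methods = methods, input = input, chains = chains,
         warmup = warmup, draws = draws, adapt = adapt,
         n_bridge_reps = n_bridge_reps, n_rep_ppc = n_rep_ppc,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> ANOVA -> fit power and
#' linear models per arm -> bridge-sampling model comparison -> posterior
#' predictive checks, and optionally writes all artifacts to
#' `config$out_dir`. Fully reproducible: re-running the same configuration
#' reproduces every number.
#'
#' @param config a [pipeline_config()].
#' @return a report list: `config`, `datasets`, `preprocess_reports`,
#'   `anova`, and per arm `fits`, `comparison`, `ppc`, `summaries`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stim <- if (config$study == 3) red_stimulus_table() else luminance_stimulus_table()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- data -----------------------------------------------------------------
  arms <- stage("data", {
    if (is.null(config$input)) {
      lapply(stats::setNames(config$methods, config$methods), function(m) {
        pop <- study_population(config$study, m,
                                seed = config$seed + match(m, config$methods))
        simulate_ratings(draw_participants(pop), stim, m, pop)
      })
    } else {
      full <- read_ratings_csv(config$input, stim)
      lapply(stats::setNames(config$methods, config$methods), function(m) {
        out <- full
        out$trials <- out$trials[out$trials$method == m, ]
        if (nrow(out$trials) == 0) stop("no trials for method ", m)
        out
      })
    }
  })

  # in the between-subject studies participant ids must not collide across arms
  if (config$study != 1 && is.null(config$input)) {
    offset <- 0L
    for (m in names(arms)) {
      arms[[m]]$trials$participant_id <- arms[[m]]$trials$participant_id + offset
      offset <- offset + max(arms[[m]]$trials$participant_id)
    }
  }

  # --- preprocessing --------------------------------------------------------
  pre <- stage("preprocess", lapply(arms, preprocess))
  cleaned_log <- lapply(pre, `[[`, "dataset")
  reports <- lapply(pre, `[[`, "report")
  cleaned_raw <- lapply(arms, function(a) {
    p <- preprocess(a, log = FALSE)
    p$dataset
  })

  # --- ANOVA ----------------------------------------------------------------
  anova_res <- stage("anova", {
    all_cells <- cell_means(bind_ratings_list(cleaned_log, stim))
    mixed_anova(all_cells,
                between = if (config$study == 1) NULL else "method")
  })

  # --- model fitting and comparison -----------------------------------------
  per_arm <- stage("models", {
    lapply(stats::setNames(names(arms), names(arms)), function(m) {
      ds <- cleaned_raw[[m]]
      pfit <- fit_scaling_model(power_model_spec(), ds,
                                chains = config$chains, warmup = config$warmup,
                                draws = config$draws, adapt = config$adapt,
                                seed = config$seed + 100L)
      lfit <- fit_scaling_model(linear_model_spec(), ds,
                                chains = config$chains, warmup = config$warmup,
                                draws = config$draws, adapt = config$adapt,
                                seed = config$seed + 200L)
      cmp <- compare_models(pfit, lfit, n_reps = config$n_bridge_reps,
                            seed = config$seed + 300L)
      list(
        power = pfit, linear = lfit, comparison = cmp,
        ppc = list(
          power = posterior_predictive(pfit, config$n_rep_ppc,
                                       seed = config$seed + 400L),
          linear = posterior_predictive(lfit, config$n_rep_ppc,
                                        seed = config$seed + 401L)
        )
      )
    })
  })

  report <- list(
    config = config,
    datasets = arms,
    preprocess_reports = reports,
    anova = anova_res,
    arms = per_arm
  )
  if (!is.null(config$out_dir)) write_pipeline_report(report)
  report
}

bind_ratings_list <- function(lst, stim) {
  combined <- do.call(bind_ratings, unname(lst))
  combined$stimulus_set <- stim
  combined
}

write_pipeline_report <- function(report) {
  dir.create(report$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- report$config$out_dir
  meta <- list(config_hash = report$config$hash, seed = report$config$seed)
  anova_to_json(report$anova, file.path(out, "anova.json"))
  for (m in names(report$arms)) {
    arm <- report$arms[[m]]
    readr::write_csv(posterior_summary(arm$power),
                     file.path(out, paste0(m, "_power_posterior.csv")))
    readr::write_csv(posterior_summary(arm$linear),
                     file.path(out, paste0(m, "_linear_posterior.csv")))
    cmp <- arm$comparison
    meta[[m]] <- list(
      log_bf_power_vs_linear = cmp$log_bf$mean,
      log_bf_sd = cmp$log_bf$sd,
      logml = list(power = cmp$power$logml$mean, linear = cmp$linear$logml$mean),
      waic = list(power = cmp$power$waic$estimate,
                  linear = cmp$linear$waic$estimate),
      looic = list(power = cmp$power$loo$estimate,
                   linear = cmp$linear$loo$estimate)
    )
  }
  jsonlite::write_json(meta, file.path(out, "comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
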