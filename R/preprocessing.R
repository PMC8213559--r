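#' Trial-level preprocessing of magnitude-estimation ratings
#'
#' The analysis pipeline applies, in this order: zero-flooring (so the later
#' reciprocal recoding and log transform are defined), exclusion of
#' direction-erroneous trials, back-transformation of reversal and
#' below-reference unidirectional ratings onto the standard scale via
#' r' = 10 / r x 10 = 100 / r, and the natural-log transform.
#'
#' @name preprocessing
NULL

new_preprocess_report <- function(n_in, n_out, n_zero = 0L, n_err = 0L,
                                  floor_value = NA_real_) {
  structure(
    list(
      n_trials_in = n_in, n_trials_out = n_out,
      n_zero_recoded = n_zero,
      fraction_zero_recoded = if (n_in > 0) n_zero / n_in else 0,
      n_erroneous_excluded = n_err,
      fraction_erroneous_excluded = if (n_in > 0) n_err / n_in else 0,
      floor_value = floor_value
    ),
    class = "preprocess_report"
  )
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n",
      "  trials in/out: ", x$n_trials_in, " / ", x$n_trials_out, "\n",
      "  zeros recoded: ", x$n_zero_recoded,
      sprintf(" (%.2f%%)", 100 * x$fraction_zero_recoded),
      if (!is.na(x$floor_value)) paste0(" to ", x$floor_value), "\n",
      "  erroneous excluded: ", x$n_erroneous_excluded,
      sprintf(" (%.2f%%)", 100 * x$fraction_erroneous_excluded), "\n",
      sep = "")
  invisible(x)
}

#' Reciprocal recoding of a rating
#'
#' Maps a rating r to r' = 10 / r x 10 = 100 / r, the transformation that
#' brings reversal-format ratings (and below-reference unidirectional
#' ratings) onto the standard scale. An estimate of 20 ("twice as intense")
#' becomes 5 ("half as intense"); the modulus 10 is the fixed point. The
#' map is an involution: applying it twice returns the input.
#'
#' @param r positive rating(s); zeros must be floored first.
#' @return the recoded rating(s).
#' @export
recode_reciprocal <- function(r) {
  if (any(r <= 0)) stop("recode_reciprocal requires strictly positive ratings")
  100 / r
}

#' Floor zero ratings
#'
#' Replaces every exactly-zero response by a small floor (default 0.001) so
#' that reciprocal recoding and the log transform are defined.
#'
#' @param dataset a `rating_dataset`.
#' @param floor replacement value for zero responses.
#' @return list with elements `dataset` and `report` (a `preprocess_report`).
#' @export
floor_zeros <- function(dataset, floor = 0.001) {
  stopifnot(inherits(dataset, "rating_dataset"), floor > 0)
  r <- dataset$trials$response
  if (any(r < 0)) stop("negative responses are invalid")
  zero <- r == 0
  dataset$trials$response[zero] <- floor
  list(
    dataset = dataset,
    report = new_preprocess_report(length(r), length(r),
                                   n_zero = sum(zero), floor_value = floor)
  )
}

#' Flag and exclude direction-erroneous trials
#'
#' For response formats with a binary direction judgment (unidirectional and
#' binary-standard), a trial is erroneous when the stated direction
#' disagrees with the objective relation of the test stimulus' intensity to
#' the reference intensity ("higher" on an objectively less intense
#' stimulus, or vice versa). Erroneous trials are removed; other formats
#' pass through untouched.
#'
#' @param dataset a `rating_dataset`.
#' @param stimulus_set stimulus set providing the objective intensities
#'   (defaults to the dataset's own).
#' @return list with elements `dataset` and `report`.
#' @export
flag_erroneous_direction <- function(dataset,
                                     stimulus_set = dataset$stimulus_set) {
  stopifnot(inherits(dataset, "rating_dataset"))
  tr <- dataset$trials
  needs <- tr$method %in% c("unidirectional", "binary_standard")
  if (any(needs & is.na(tr$direction))) {
    stop("direction missing on trials of a method that requires it")
  }
  i_ref <- reference_intensity(stimulus_set)
  objective <- ifelse(tr$intensity > i_ref, "higher", "lower")
  erroneous <- needs & tr$direction != objective
  dataset$trials <- tr[!erroneous, ]
  list(
    dataset = dataset,
    report = new_preprocess_report(nrow(tr), nrow(tr) - sum(erroneous),
                                   n_err = sum(erroneous))
  )
}

#' Recode all ratings onto the standard scale
#'
#' Reversal-format trials are reciprocal-recoded throughout; unidirectional
#' trials are recoded only where the test stimulus is objectively below the
#' reference (the format reports magnitudes >= 10 in both directions);
#' standard and binary-standard trials are unchanged.
#'
#' @param dataset a `rating_dataset`.
#' @param stimulus_set stimulus set providing the reference intensity.
#' @return the recoded `rating_dataset`.
#' @export
to_standard_scale <- function(dataset, stimulus_set = dataset$stimulus_set) {
  stopifnot(inherits(dataset, "rating_dataset"))
  tr <- dataset$trials
  i_ref <- reference_intensity(stimulus_set)
  flip <- tr$method == "reversal" |
    (tr$method == "unidirectional" & tr$intensity < i_ref)
  tr$response[flip] <- recode_reciprocal(tr$response[flip])
  dataset$trials <- tr
  dataset
}

#' Natural-log transform of the responses
#'
#' @param dataset a `rating_dataset` with strictly positive responses.
#' @return the dataset with `response` replaced by its natural logarithm
#'   (and a `log_scale` provenance marker).
#' @export
log_responses <- function(dataset) {
  stopifnot(inherits(dataset, "rating_dataset"))
  if (any(dataset$trials$response <= 0)) {
    stop("log transform requires strictly positive responses; floor zeros first")
  }
  dataset$trials$response <- log(dataset$trials$response)
  dataset$provenance$log_scale <- TRUE
  dataset
}

#' Full preprocessing chain
#'
#' Runs floor-zeros, erroneous-trial exclusion and standard-scale recoding
#' in the pipeline's fixed order, optionally followed by the log transform.
#'
#' @param dataset a `rating_dataset`.
#' @param floor zero floor (default 0.001).
#' @param log take natural logs at the end (default TRUE).
#' @return list with elements `dataset` and `report`.
#' @export
preprocess <- function(dataset, floor = 0.001, log = TRUE) {
  fz <- floor_zeros(dataset, floor)
  fe <- flag_erroneous_direction(fz$dataset)
  out <- to_standard_scale(fe$dataset)
  if (log) out <- log_responses(out)
  report <- new_preprocess_report(
    fz$report$n_trials_in, fe$report$n_trials_out,
    n_zero = fz$report$n_zero_recoded,
    n_err = fe$report$n_erroneous_excluded,
    floor_value = floor
  )
  list(dataset = out, report = report)
}

#' Per-stimulus geometric-mean ratings
#'
#' The study's summary quantity "mean rating calculated from the mean log
#' rating": exp of the mean log response per method and stimulus, computed
#' from raw-scale responses.
#'
#' @param dataset a `rating_dataset` on the raw (not log) response scale.
#' @return a tibble with columns `method`, `stimulus_id`, `geometric_mean`.
#' @export
stimulus_mean_ratings <- function(dataset) {
  stopifnot(inherits(dataset, "rating_dataset"))
  if (isTRUE(dataset$provenance$log_scale)) {
    stop("expected raw-scale responses")
  }
  if (any(dataset$trials$response <= 0)) {
    stop("geometric means require strictly positive responses")
  }
  dataset$trials |>
    dplyr::group_by(.data$method, .data$stimulus_id) |>
    dplyr::summarise(geometric_mean = exp(mean(log(.data$response))),
                     .groups = "drop")
}
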