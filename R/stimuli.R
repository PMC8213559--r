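#' Stimulus sets for magnitude-estimation experiments
#'
#' A `stimulus_set` describes the physical intensities of the eight test
#' stimuli and the single reference stimulus (the modulus, rated 10) of one
#' experiment: achromatic luminance patches for the brightness studies and
#' red patches of varying colorimetric saturation for the redness study.
#'
#' Intensities used for modelling are normalized to a 0--1 scale: luminance
#' as a fraction of the maximum presented luminance (100 cd/m2, so the
#' reference sits at 0.1) and red saturation as the nominal saturation
#' fraction (0.15--0.85, reference 0.50). The printed physical values are
#' retained in the `physical` column.
#'
#' @param dimension_label either `"luminance"` or `"red_saturation"`.
#' @param stimuli a data frame with columns `stimulus_id` (integer),
#'   `label` (character), `physical` (printed physical magnitude) and
#'   `intensity` (normalized magnitude used for modelling).
#' @param reference_id the `stimulus_id` of the reference stimulus.
#' @param reference_rating the modulus assigned to the reference (default 10).
#'
#' @return an object of class `stimulus_set` with elements `dimension_label`,
#'   `stimuli` (tibble), `reference_id`, `reference_rating`, `n_above`,
#'   `n_below`.
#' @export
stimulus_set <- function(dimension_label, stimuli, reference_id,
                         reference_rating = 10) {
  stopifnot(is.character(dimension_label), length(dimension_label) == 1L)
  stimuli <- tibble::as_tibble(stimuli)
  req <- c("stimulus_id", "label", "physical", "intensity")
  if (!all(req %in% names(stimuli))) {
    stop("stimuli must have columns: ", paste(req, collapse = ", "))
  }
  stimuli <- dplyr::arrange(stimuli, .data$stimulus_id)
  if (anyDuplicated(stimuli$stimulus_id)) stop("duplicated stimulus_id")
  if (any(stimuli$intensity <= 0)) stop("intensities must be strictly positive")
  if (any(diff(stimuli$intensity) <= 0)) {
    stop("intensities must be strictly increasing by stimulus_id")
  }
  if (!reference_id %in% stimuli$stimulus_id) {
    stop("reference_id not present in stimuli")
  }
  ref_int <- stimuli$intensity[stimuli$stimulus_id == reference_id]
  test <- stimuli[stimuli$stimulus_id != reference_id, ]
  if (ref_int <= min(test$intensity) || ref_int >= max(test$intensity)) {
    stop("reference intensity must lie strictly between min and max test intensity")
  }
  structure(
    list(
      dimension_label = dimension_label,
      stimuli = stimuli,
      reference_id = reference_id,
      reference_rating = reference_rating,
      n_above = sum(test$intensity > ref_int),
      n_below = sum(test$intensity < ref_int)
    ),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set> ", x$dimension_label, ": ",
      nrow(x$stimuli), " stimuli (reference id ", x$reference_id,
      ", modulus ", x$reference_rating, ")\n", sep = "")
  print(x$stimuli)
  invisible(x)
}

reference_intensity <- function(set) {
  set$stimuli$intensity[set$stimuli$stimulus_id == set$reference_id]
}

test_stimuli <- function(set) {
  set$stimuli[set$stimuli$stimulus_id != set$reference_id, ]
}

#' Luminance stimulus set of the brightness studies
#'
#' Nine achromatic luminances (CIE xyY, 10 degree 1964 observer, D65 white
#' point): eight test stimuli from 1.0 to 100.0 cd/m2 plus the 10.0 cd/m2
#' reference (stimulus 5), four test stimuli brighter and four darker than
#' the reference. Values are read from the packaged colorimetric table.
#'
#' @return a [stimulus_set] with `dimension_label = "luminance"`; normalized
#'   intensity is luminance / 100 (fraction of the maximum, reference 0.1).
#' @export
luminance_stimulus_table <- function() {
  tab <- read_table1_csv(system.file("extdata", "table1_luminance.csv",
                                     package = "magscale", mustWork = TRUE))
  stimulus_set(
    dimension_label = "luminance",
    stimuli = tibble::tibble(
      stimulus_id = tab$stimulus,
      label = as.character(tab$stimulus),
      physical = tab$Y,
      intensity = tab$Y / 100
    ),
    reference_id = 5L
  )
}

#' Red-saturation stimulus set of the redness study
#'
#' Nine red patches of equal lightness and hue but varying colorimetric
#' saturation: eight test stimuli with nominal saturations 15--85 % plus the
#' nominal 50 % reference. Measured CIE LCh saturation values S are stored as
#' the `physical` magnitude; the nominal saturation fraction drives
#' simulation and model fitting.
#'
#' @return a [stimulus_set] with `dimension_label = "red_saturation"`.
#' @export
red_stimulus_table <- function() {
  tab <- read_table3_csv(system.file("extdata", "table3_red_saturation.csv",
                                     package = "magscale", mustWork = TRUE))
  nominal <- as.numeric(sub("^Red ([0-9]+)%$", "\\1", tab$stimulus)) / 100
  stimulus_set(
    dimension_label = "red_saturation",
    stimuli = tibble::tibble(
      stimulus_id = seq_len(nrow(tab)),
      label = tab$stimulus,
      physical = tab$S,
      intensity = nominal
    ),
    reference_id = which(nominal == 0.50)
  )
}

#' Colorimetric records of the red stimuli
#'
#' The full colorimetric table for the red-saturation study: CIE XYZ
#' tristimulus values (Y in cd/m2), CIE LCh lightness `L_star`, hue angle
#' `h_star` (degrees) and saturation percentage `S`, plus the chroma
#' `C_star` recovered from S and L* by inverting [saturation_from_chroma()].
#'
#' @return a tibble, one row per stimulus.
#' @export
red_colorimetric_records <- function() {
  tab <- read_table3_csv(system.file("extdata", "table3_red_saturation.csv",
                                     package = "magscale", mustWork = TRUE))
  s <- tab$S / 100
  tab$C_star <- tab$L_star * s / sqrt(1 - s^2)
  tibble::as_tibble(tab)
}

#' CIE LCh saturation from chroma and lightness
#'
#' Computes the saturation percentage of a colour from its CIE LCh chroma
#' C* and lightness L*: S = C* / sqrt(C*^2 + L*^2) x 100. Monotone
#' increasing in chroma at fixed lightness and invariant to a common
#' rescaling of both arguments.
#'
#' @param C_star chroma, >= 0.
#' @param L_star lightness, >= 0. `C_star` and `L_star` must not both be zero.
#' @return saturation in percent, in \[0, 100\].
#' @export
saturation_from_chroma <- function(C_star, L_star) {
  if (any(C_star < 0) || any(L_star < 0)) {
    stop("C_star and L_star must be nonnegative")
  }
  if (any(C_star == 0 & L_star == 0)) {
    stop("saturation undefined when chroma and lightness are both zero")
  }
  C_star / sqrt(C_star^2 + L_star^2) * 100
}

# -- fixture CSV readers (headers validated exactly) --------------------------

read_table1_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  expected <- c("stimulus", "x", "y", "Y")
  if (!identical(names(tab), expected)) {
    stop("luminance table must have columns: ", paste(expected, collapse = ", "))
  }
  tab
}

read_table3_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  expected <- c("stimulus", "X", "Y", "Z", "L_star", "h_star", "S")
  if (!identical(names(tab), expected)) {
    stop("red-saturation table must have columns: ",
         paste(expected, collapse = ", "))
  }
  tab
}

#' Write / read a stimulus set as CSV
#'
#' Serializes a [stimulus_set] to a plain CSV (columns `dimension`,
#' `stimulus_id`, `label`, `physical`, `intensity`, `is_reference`,
#' `reference_rating`) and reads it back; the round trip is exact.
#'
#' @param set a [stimulus_set].
#' @param path file path.
#' @return `read_stimulus_set` returns a [stimulus_set];
#'   `write_stimulus_set` returns `path` invisibly.
#' @export
write_stimulus_set <- function(set, path) {
  stopifnot(inherits(set, "stimulus_set"))
  out <- set$stimuli
  out$dimension <- set$dimension_label
  out$is_reference <- out$stimulus_id == set$reference_id
  out$reference_rating <- set$reference_rating
  out <- out[, c("dimension", "stimulus_id", "label", "physical",
                 "intensity", "is_reference", "reference_rating")]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  expected <- c("dimension", "stimulus_id", "label", "physical",
                "intensity", "is_reference", "reference_rating")
  if (!identical(names(tab), expected)) {
    stop("stimulus-set CSV must have columns: ", paste(expected, collapse = ", "))
  }
  stimulus_set(
    dimension_label = tab$dimension[1],
    stimuli = tibble::tibble(
      stimulus_id = as.integer(tab$stimulus_id),
      label = as.character(tab$label),
      physical = tab$physical,
      intensity = tab$intensity
    ),
    reference_id = as.integer(tab$stimulus_id[tab$is_reference]),
    reference_rating = tab$reference_rating[1]
  )
}
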