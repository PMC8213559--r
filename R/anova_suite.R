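#' Participant-by-stimulus cell means
#'
#' Averages the repeated trials of each participant x method x stimulus cell
#' (5 repetitions by design), the unit entering the repeated-measures
#' ANOVAs. The dataset must be preprocessed (log responses).
#'
#' @param dataset a `rating_dataset`, normally log-scale.
#' @return a tibble `participant_id`, `method`, `stimulus_id`, `mean_response`,
#'   complete in `stimulus_id` for every participant x method.
#' @export
cell_means <- function(dataset) {
  stopifnot(inherits(dataset, "rating_dataset"))
  cells <- dataset$trials |>
    dplyr::group_by(.data$participant_id, .data$method, .data$stimulus_id) |>
    dplyr::summarise(mean_response = mean(.data$response), .groups = "drop")
  n_stim <- length(unique(cells$stimulus_id))
  counts <- cells |>
    dplyr::count(.data$participant_id, .data$method)
  if (any(counts$n != n_stim)) {
    stop("missing cells: every participant x method needs all stimulus levels")
  }
  cells
}

# orthonormal contrast matrix, (L-1) x L, rows orthonormal and orthogonal to
# the unit vector
orthonormal_contrasts <- function(L) {
  t(qr.Q(qr(stats::contr.helmert(L)))) * -1
}

#' Greenhouse-Geisser epsilon
#'
#' Box's sphericity estimate computed from the covariance matrix of the L
#' within-subject cell scores: with A the covariance of orthonormalized
#' contrast scores, epsilon = tr(A)^2 / ((L-1) tr(A^2)). Equals 1 exactly
#' for L = 2 and under compound symmetry; bounded below by 1/(L-1).
#'
#' @param sigma L x L covariance matrix of the within-subject cells (L >= 2).
#' @return the epsilon estimate.
#' @export
gg_epsilon <- function(sigma) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma)) stop("covariance matrix must be square")
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma)))) {
    stop("covariance matrix must be symmetric")
  }
  L <- nrow(sigma)
  if (L < 2) stop("need at least two within-subject levels")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) stop("covariance matrix must be PSD")
  C <- orthonormal_contrasts(L)
  A <- C %*% sigma %*% t(C)
  sum(diag(A))^2 / ((L - 1) * sum(A * A))
}

effect_row <- function(effect, ss, df1, ss_err, df2, epsilon, denom_extra) {
  ms <- ss / df1
  ms_err <- ss_err / df2
  f <- ms / ms_err
  tibble::tibble(
    effect = effect, ss = ss, df1 = df1, ss_error = ss_err, df2 = df2,
    f = f, epsilon = epsilon,
    df1_gg = epsilon * df1, df2_gg = epsilon * df2,
    p_gg = stats::pf(f, epsilon * df1, epsilon * df2, lower.tail = FALSE),
    eta_g_sq = ss / (ss + denom_extra)
  )
}

#' Repeated-measures / mixed ANOVA with Greenhouse-Geisser correction
#'
#' Runs the 2 x 8 (method x stimulus) ANOVA of the studies on a balanced
#' cell-means table: fully within-subject when both factors vary within
#' participants (the reversal study), mixed with method between subjects
#' (the unidirectional studies; group sizes may differ), or a one-way
#' within-subject ANOVA when only one method is present. All effects are
#' reported with uncorrected and Greenhouse-Geisser-corrected degrees of
#' freedom, the GG-corrected p value, and generalized eta squared
#' (SS_effect / (SS_effect + sum of all subject-related error SS),
#' the convention for designs with measured factors).
#'
#' Sums of squares are computed by projection onto orthonormalized
#' within-subject contrasts; for unequal between-group sizes the
#' within-subject main effect tests the unweighted mean of group profiles
#' (Type-III convention).
#'
#' @param cells a cell-means tibble from [cell_means()].
#' @param between `NULL` for fully within designs, or `"method"` to treat
#'   method as a between-subjects factor.
#' @return an `anova_result`: a tibble with one row per effect (`effect`,
#'   `ss`, `df1`, `ss_error`, `df2`, `f`, `epsilon`, `df1_gg`, `df2_gg`,
#'   `p_gg`, `eta_g_sq`) with the full sums-of-squares ledger as an
#'   attribute.
#' @export
mixed_anova <- function(cells, between = NULL) {
  stopifnot(is.data.frame(cells),
            all(c("participant_id", "method", "stimulus_id",
                  "mean_response") %in% names(cells)))
  methods <- sort(unique(cells$method))
  stim <- sort(unique(cells$stimulus_id))
  A <- length(methods)
  B <- length(stim)
  wide <- cells |>
    dplyr::arrange(.data$participant_id, .data$method, .data$stimulus_id)

  if (!is.null(between)) {
    if (!identical(between, "method")) stop("between factor must be 'method'")
    if (A < 2) stop("between-subjects design needs at least two methods")
    res <- anova_mixed_between_within(wide, methods, stim)
  } else if (A == 2) {
    res <- anova_two_within(wide, methods, stim)
  } else if (A == 1) {
    res <- anova_one_within(wide, stim)
  } else {
    stop("within-subject method factor must have one or two levels")
  }
  res
}

# scores per subject on an orthonormal contrast basis; y is the N x P cell
# matrix in a fixed cell order, M is k x P with orthonormal rows
contrast_scores <- function(y, M) y %*% t(M)

cells_matrix <- function(wide) {
  m <- matrix(wide$mean_response, nrow = length(unique(wide$participant_id)),
              byrow = TRUE)
  rownames(m) <- unique(wide$participant_id)
  m
}

anova_one_within <- function(wide, stim) {
  B <- length(stim)
  Y <- cells_matrix(wide)
  N <- nrow(Y)
  if (N < 2) stop("need at least two participants")
  CB <- orthonormal_contrasts(B)
  Z <- contrast_scores(Y, CB)
  ss_eff <- N * sum(colMeans(Z)^2)
  ss_err <- sum(sweep(Z, 2, colMeans(Z))^2)
  ss_subj <- B * sum((rowMeans(Y) - mean(Y))^2)
  eps <- gg_epsilon_scores(Z)
  out <- effect_row("stimulus", ss_eff, B - 1, ss_err, (N - 1) * (B - 1),
                    eps, ss_subj + ss_err)
  new_anova_result(out, list(ss_subjects = ss_subj))
}

anova_two_within <- function(wide, methods, stim) {
  A <- length(methods)
  B <- length(stim)
  per <- dplyr::count(wide, .data$participant_id)
  if (any(per$n != A * B)) {
    stop("fully within design: every participant needs all method x stimulus cells")
  }
  Y <- cells_matrix(wide) # N x (A*B), cells ordered method-major
  N <- nrow(Y)
  if (N < 2) stop("need at least two participants")
  CA <- orthonormal_contrasts(A)
  CB <- orthonormal_contrasts(B)
  oneA <- matrix(1 / sqrt(A), 1, A)
  oneB <- matrix(1 / sqrt(B), 1, B)
  M <- list(
    method = CA %x% oneB,
    stimulus = oneA %x% CB,
    `method:stimulus` = CA %x% CB
  )
  ss_subj <- A * B * sum((rowMeans(Y) - mean(Y))^2)
  comp <- lapply(M, function(m) {
    Z <- contrast_scores(Y, m)
    list(
      ss = N * sum(colMeans(Z)^2),
      ss_err = sum(sweep(Z, 2, colMeans(Z))^2),
      df1 = nrow(m),
      eps = gg_epsilon_scores(Z)
    )
  })
  denom_err <- ss_subj + sum(vapply(comp, `[[`, 0, "ss_err"))
  rows <- dplyr::bind_rows(lapply(names(comp), function(nm) {
    cc <- comp[[nm]]
    effect_row(nm, cc$ss, cc$df1, cc$ss_err, (N - 1) * cc$df1, cc$eps,
               denom_err)
  }))
  new_anova_result(rows, list(ss_subjects = ss_subj))
}

anova_mixed_between_within <- function(wide, methods, stim) {
  B <- length(stim)
  # one method per participant
  per <- unique(wide[, c("participant_id", "method")])
  if (anyDuplicated(per$participant_id)) {
    stop("between-subjects design: each participant must have exactly one method")
  }
  Y <- matrix(wide$mean_response, ncol = B, byrow = TRUE)
  group <- factor(per$method, levels = methods)
  N <- nrow(Y)
  g <- nlevels(group)
  n_g <- as.vector(table(group))
  if (any(n_g < 2)) stop("need at least two participants per group")

  subj_mean <- rowMeans(Y)
  grp_mean <- tapply(subj_mean, group, mean)
  grand_w <- mean(subj_mean)
  ss_method <- B * sum(n_g * (grp_mean - grand_w)^2)
  ss_subj_err <- B * sum((subj_mean - grp_mean[group])^2)

  CB <- orthonormal_contrasts(B)
  Z <- contrast_scores(Y, CB) # N x (B-1)
  zbar_g <- apply(Z, 2, function(z) tapply(z, group, mean)) # g x (B-1)
  # within main effect: unweighted mean of group profiles (Type III)
  mu_u <- colMeans(zbar_g)
  n_eff <- g^2 / sum(1 / n_g)
  ss_stim <- n_eff * sum(mu_u^2)
  zbar_w <- colMeans(Z)
  ss_inter <- sum(vapply(seq_len(ncol(Z)), function(k) {
    sum(n_g * (zbar_g[, k] - zbar_w[k])^2)
  }, 0))
  resid <- Z - zbar_g[as.integer(group), , drop = FALSE]
  ss_werr <- sum(resid^2)
  eps <- gg_epsilon_scores_pooled(resid, N - g)

  denom_err <- ss_subj_err + ss_werr
  rows <- dplyr::bind_rows(
    effect_row("method", ss_method, g - 1, ss_subj_err, N - g, 1,
               denom_err),
    effect_row("stimulus", ss_stim, B - 1, ss_werr, (N - g) * (B - 1),
               eps, denom_err),
    effect_row("method:stimulus", ss_inter, (g - 1) * (B - 1), ss_werr,
               (N - g) * (B - 1), eps, denom_err)
  )
  new_anova_result(rows, list(ss_subjects_error = ss_subj_err))
}

# epsilon from subject-level contrast scores (orthonormal basis): covariance
# of the scores already equals C Sigma C'
gg_epsilon_scores <- function(Z) {
  if (ncol(Z) == 1) return(1)
  A <- stats::cov(Z)
  sum(diag(A))^2 / (ncol(Z) * sum(A * A))
}

gg_epsilon_scores_pooled <- function(resid, df) {
  if (ncol(resid) == 1) return(1)
  A <- crossprod(resid) / df
  sum(diag(A))^2 / (ncol(resid) * sum(A * A))
}

new_anova_result <- function(rows, ledger) {
  structure(rows, ledger = ledger, class = c("anova_result", class(rows)))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA (Greenhouse-Geisser corrected)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s F(%.2f, %.2f) = %.2f, p = %.4g, eta_g^2 = %.3f\n",
                x$effect[i], x$df1_gg[i], x$df2_gg[i], x$f[i], x$p_gg[i],
                x$eta_g_sq[i]))
  }
  invisible(x)
}

#' Serialize an ANOVA result as JSON
#'
#' @param result an `anova_result`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string or (invisibly) `path`.
#' @export
anova_to_json <- function(result, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(result), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
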