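#' Variance filter (selection step i)
#'
#' Discards features that carry almost the same value for all observations,
#' keeping exactly the columns whose sample variance is strictly greater
#' than `thresh`.
#'
#' @param X Numeric matrix (training rows only).
#' @param thresh Variance threshold, default 0.03.
#' @return Integer vector of surviving column indices.
#' @export
variance_filter <- function(X, thresh = 0.03) {
  stopifnot(nrow(X) >= 2)
  v <- apply(X, 2, stats::var)
  which(v > thresh)
}

#' Correlation-with-target filter (selection step ii)
#'
#' Keeps features whose absolute Pearson correlation with the class label is
#' at least `thresh` (the complement — absolute correlation below 10% — is
#' discarded). A zero-variance feature reaching this step has correlation
#' defined as 0 and is removed.
#'
#' @param X Numeric matrix (training rows only).
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param thresh Absolute-correlation threshold, default 0.10.
#' @return Integer vector of surviving column indices.
#' @export
correlation_filter <- function(X, y, thresh = 0.10) {
  stopifnot(length(unique(y)) == 2)
  sds <- apply(X, 2, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- drop(stats::cor(X[, ok, drop = FALSE], y))
  }
  which(abs(r) >= thresh)
}

#' Capped lasso selection (selection step iii)
#'
#' Fits an L1-penalized linear model of the label on the standardized
#' features over a decreasing regularization path (geometric grid from the
#' data-derived maximum penalty) and returns the non-zero-coefficient set of
#' the smallest penalty whose active set has at most `max_nf` members. Among
#' penalties sharing that identical active set, the largest (most
#' regularized) is reported. The returned set can be empty when no penalty
#' on the path admits a small enough active set.
#'
#' @param X Numeric matrix, standardized on the training rows.
#' @param y Labels in `{-1, +1}` (fit as a numeric response).
#' @param max_nf Cap on the number of selected features.
#' @param path_length Number of penalties on the path, default 100.
#' @return List with `selected` (integer column indices) and `weights`
#'   (their lasso coefficients).
#' @export
lasso_cap <- function(X, y, max_nf, path_length = 100) {
  stopifnot(max_nf >= 1, nrow(X) == length(y))
  if (ncol(X) == 0) stop("no features reached the lasso step (over-aggressive filtering)")
  if (ncol(X) == 1) {
    # glmnet requires >= 2 columns; a single candidate either correlates or not
    b <- stats::coef(stats::lm(y ~ X[, 1]))[2]
    return(list(selected = 1L, weights = unname(b)))
  }
  fit <- glmnet::glmnet(X, as.numeric(y), family = "gaussian",
                        standardize = FALSE, nlambda = path_length)
  beta <- as.matrix(fit$beta)
  nnz <- colSums(beta != 0)
  cand <- which(nnz <= max_nf)
  if (length(cand) == 0) {
    return(list(selected = integer(0), weights = numeric(0)))
  }
  idx <- max(cand)  # smallest penalty obeying the cap
  active <- which(beta[, idx] != 0)
  # prefer the most regularized penalty with this identical active set
  while (idx > 1 && identical(which(beta[, idx - 1] != 0), active)) {
    idx <- idx - 1L
  }
  list(selected = as.integer(active), weights = unname(beta[active, idx]))
}

#' Three-step feature-selection cascade on a training partition
#'
#' Applies, strictly on the supplied training rows, (i) the variance filter,
#' (ii) the correlation-with-target filter and (iii) capped lasso selection
#' on standardized survivors. Standardization parameters are estimated on
#' the training rows only. Radiomics columns are by default standardized
#' before the variance filter so that the single variance threshold operates
#' on a scale comparable with the SNV-normalized spectral features
#' (`prestandardize_rad = FALSE` filters raw radiomics values instead).
#'
#' If the lasso returns an empty set, the top-`max_nf` step-ii survivors
#' ranked by absolute correlation are used instead, with a warning.
#'
#' @param X Numeric matrix of training rows.
#' @param y Training labels in `{-1, +1}`.
#' @param max_nf Cap on selected features.
#' @param var_thresh,corr_thresh Filter thresholds (defaults 0.03, 0.10).
#' @param modality Optional per-column modality tags (for radiomics
#'   pre-standardization).
#' @param prestandardize_rad Standardize `Rad` columns before the variance
#'   filter; default `TRUE`.
#' @param path_length Lasso path length.
#' @return A `selection_result`: list with `survivors_step1`,
#'   `survivors_step2`, `selected` (ordered global column indices), `weights`,
#'   `max_nf` and `fallback` flag. Invariants: nested index sets and
#'   `length(selected) <= max_nf`.
#' @export
select_features <- function(X, y, max_nf = 10, var_thresh = 0.03,
                            corr_thresh = 0.10, modality = NULL,
                            prestandardize_rad = TRUE, path_length = 100) {
  stopifnot(nrow(X) == length(y))
  Xv <- X
  if (prestandardize_rad && !is.null(modality)) {
    rad <- which(modality == "Rad")
    if (length(rad) > 0) {
      par <- standardize_fit(X[, rad, drop = FALSE])
      Xv[, rad] <- standardize_apply(X[, rad, drop = FALSE], par)
    }
  }
  s1 <- variance_filter(Xv, var_thresh)
  if (length(s1) == 0) stop("variance filter removed every feature")
  s2_local <- correlation_filter(X[, s1, drop = FALSE], y, corr_thresh)
  s2 <- s1[s2_local]
  if (length(s2) == 0) stop("correlation filter removed every feature")
  par <- standardize_fit(X[, s2, drop = FALSE])
  Xs <- standardize_apply(X[, s2, drop = FALSE], par)
  las <- lasso_cap(Xs, y, max_nf, path_length)
  fallback <- FALSE
  if (length(las$selected) == 0) {
    warning("lasso selected no features; falling back to top correlated step-ii survivors")
    fallback <- TRUE
    r <- abs(drop(stats::cor(Xs, y)))
    ord <- order(r, decreasing = TRUE)[seq_len(min(max_nf, length(s2)))]
    las <- list(selected = sort(ord), weights = rep(NA_real_, length(ord)))
  }
  selected <- s2[las$selected]
  structure(list(survivors_step1 = s1, survivors_step2 = s2,
                 selected = selected, weights = las$weights,
                 max_nf = max_nf, fallback = fallback),
            class = "selection_result")
}
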