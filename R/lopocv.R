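#' Leave-one-patient-out cross-validation with per-fold feature selection
#'
#' One fold per patient: the held-out patient's sites are scored by a model
#' trained on all remaining patients. Within each fold, feature selection
#' (the three-step cascade), standardization and Platt calibration are all
#' estimated on the training rows exclusively, so no information from the
#' held-out patient can leak into the model that scores it. Held-out
#' posterior probabilities are pooled across folds.
#'
#' @param ft A [feature_table()].
#' @param labels Numeric vector in `{-1, +1}` aligned with the table's rows.
#' @param cost Cost matrix, default [default_cost_matrix()].
#' @param max_nf Cap on selected features per fold, default 10.
#' @param C_reg SVM regularization constant, default 1.
#' @param fixed_features Optional character vector of feature names: bypass
#'   selection and train every fold on exactly these columns.
#' @param var_thresh,corr_thresh,prestandardize_rad Cascade parameters, see
#'   [select_features()].
#' @return An object of class `cv_result`: list with pooled `scores` (named
#'   by site), `labels`, `patient_id`, `fold_selections` (feature names per
#'   fold), `fold_weights`, `n_features` and `sv_ratios` per fold,
#'   `mean_n_features`, `mean_sv_ratio`.
#' @export
lopocv <- function(ft, labels, cost = default_cost_matrix(), max_nf = 10,
                   C_reg = 1, fixed_features = NULL, var_thresh = 0.03,
                   corr_thresh = 0.10, prestandardize_rad = TRUE) {
  stopifnot(inherits(ft, "feature_table"), length(labels) == nrow(ft$X),
            all(labels %in% c(-1, 1)))
  patients <- unique(ft$patient_id)
  if (length(patients) < 2) stop("LOPOCV needs at least two patients")
  if (length(unique(labels)) < 2) stop("both classes must be present overall")
  if (!is.null(fixed_features)) {
    missing <- setdiff(fixed_features, colnames(ft$X))
    if (length(missing) > 0) {
      stop("fixed features absent from the table: ", paste(missing, collapse = ", "))
    }
  }
  scores <- rep(NA_real_, nrow(ft$X))
  names(scores) <- ft$site_id
  fold_selections <- vector("list", length(patients))
  fold_weights <- vector("list", length(patients))
  n_features <- numeric(length(patients))
  sv_ratios <- numeric(length(patients))
  names(fold_selections) <- patients
  for (k in seq_along(patients)) {
    p <- patients[k]
    test <- ft$patient_id == p
    train <- !test
    y_tr <- labels[train]
    if (length(unique(y_tr)) < 2) {
      stop(sprintf("training fold for held-out patient %s has a single class", p))
    }
    X_tr <- ft$X[train, , drop = FALSE]
    if (is.null(fixed_features)) {
      sel <- select_features(X_tr, y_tr, max_nf = max_nf,
                             var_thresh = var_thresh,
                             corr_thresh = corr_thresh,
                             modality = ft$modality,
                             prestandardize_rad = prestandardize_rad)
      cols <- sel$selected
    } else {
      cols <- match(fixed_features, colnames(ft$X))
    }
    par <- standardize_fit(X_tr[, cols, drop = FALSE])
    Xs_tr <- standardize_apply(X_tr[, cols, drop = FALSE], par)
    model <- train_cost_svm(Xs_tr, y_tr, cost = cost, C_reg = C_reg)
    calib <- calibrate_posterior(model, Xs_tr, y_tr)
    Xs_te <- standardize_apply(ft$X[test, cols, drop = FALSE], par)
    scores[test] <- posterior(calib, decision_values(model, Xs_te))
    fold_selections[[k]] <- colnames(ft$X)[cols]
    fold_weights[[k]] <- stats::setNames(model$w, colnames(ft$X)[cols])
    n_features[k] <- length(cols)
    sv_ratios[k] <- sv_ratio(model)
  }
  stopifnot(!anyNA(scores))
  structure(list(scores = scores, labels = labels, patient_id = ft$patient_id,
                 fold_selections = fold_selections,
                 fold_weights = fold_weights,
                 n_features = n_features, sv_ratios = sv_ratios,
                 mean_n_features = mean(n_features),
                 mean_sv_ratio = mean(sv_ratios)),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: %d sites, %d folds, mean %.1f features/fold, mean SV ratio %.2f\n",
    length(x$scores), length(x$fold_selections), x$mean_n_features,
    x$mean_sv_ratio))
  invisible(x)
}
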