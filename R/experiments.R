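#' Assign classification labels from histology
#'
#' The three prediction tasks:
#' * `gg_gt1` — clinically significant cancer: +1 iff ISUP grade group > 1.
#' * `gg_ge1` — any cancer: +1 iff grade group >= 1, -1 for benign.
#' * `high_grade` — as `gg_ge1`, but tumor sites with a high-grade
#'   percentage below `hg_cutoff` are excluded (`NA`); benign sites are
#'   always retained.
#'
#' @param histology A histology table (see [validate_histology()]).
#' @param scheme Labeling scheme name.
#' @param hg_cutoff High-grade percentage cutoff, default 20.
#' @return Numeric vector: `+1`, `-1`, or `NA` for excluded sites.
#' @export
assign_labels <- function(histology, scheme = c("gg_gt1", "gg_ge1", "high_grade"),
                          hg_cutoff = 20) {
  scheme <- match.arg(scheme)
  validate_histology(histology)
  gg <- histology$isup_gg
  lab <- switch(scheme,
    gg_gt1 = ifelse(gg > 1, 1, -1),
    gg_ge1 = ifelse(gg >= 1, 1, -1),
    high_grade = {
      tumor <- gg >= 1
      if (any(tumor & is.na(histology$hg_percent))) {
        stop("tumor site with missing high-grade percentage under the high_grade scheme")
      }
      out <- ifelse(tumor, 1, -1)
      out[tumor & histology$hg_percent < hg_cutoff] <- NA
      out
    })
  lab
}

#' ROC curve, AUC and closest-to-corner operating point
#'
#' Sweeps every unique score as a threshold (predict +1 when the score is at
#' least the threshold), computes the (FPR, TPR) curve and the trapezoidal
#' AUC, and reports the operating point closest in Euclidean distance to the
#' ideal (0, 1) corner. Threshold ties in corner distance are broken toward
#' higher sensitivity. Accuracy, sensitivity and specificity at the optimal
#' point are plain (unweighted) proportions.
#'
#' @param scores Numeric scores (posterior probabilities).
#' @param labels Labels in `{-1, +1}`; both classes required.
#' @return An object of class `roc_summary`: list with `fpr`, `tpr`,
#'   `thresholds`, `auc`, `optimal_threshold`, `accuracy`, `sensitivity`,
#'   `specificity`, `optimal_fpr`, `optimal_tpr`.
#' @export
roc_summary <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == -1) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  d2 <- fpr^2 + (1 - tpr)^2
  best <- which(d2 == min(d2))
  best <- best[which.max(tpr[best])]  # tie toward sensitivity
  t_opt <- thr[best]
  pred <- ifelse(scores >= t_opt, 1, -1)
  structure(list(
    fpr = fpr, tpr = tpr, thresholds = thr, auc = auc,
    optimal_threshold = t_opt,
    optimal_fpr = fpr[best], optimal_tpr = tpr[best],
    accuracy = mean(pred == labels),
    sensitivity = sum(pred == 1 & labels == 1) / n_pos,
    specificity = sum(pred == -1 & labels == -1) / n_neg),
    class = "roc_summary")
}

#' Feature-combination experiment
#'
#' Runs one full LOPOCV per feature-set combination (spectral regions and/or
#' radiomics), each restricted to that combination's columns, and reports
#' the pooled-posterior ROC metrics alongside the mean number of selected
#' features and mean support-vector ratio per combination.
#'
#' @param ft Full [feature_table()] with modality tags.
#' @param labels Labels in `{-1, +1}` aligned with rows.
#' @param combos Character vector of combination names.
#' @param max_nf Per-fold feature cap, default 10.
#' @param ... Passed to [lopocv()].
#' @return List with `report` (one data.frame row per combination: features,
#'   mean_n_features, auc, accuracy, sensitivity, specificity, sv_ratio) and
#'   `cv` (the per-combination `cv_result`s).
#' @export
feature_combination_experiment <- function(ft, labels,
    combos = c("FP", "HW", "Rad", "FP+HW", "FP+Rad", "FP+HW+Rad", "HW+Rad"),
    max_nf = 10, ...) {
  cvs <- list()
  rows <- lapply(combos, function(cb) {
    sub <- subset_combo(ft, cb)
    cv <- lopocv(sub, labels, max_nf = max_nf, ...)
    cvs[[cb]] <<- cv
    roc <- roc_summary(cv$scores, labels)
    data.frame(features = cb, mean_n_features = cv$mean_n_features,
               auc = roc$auc, accuracy = roc$accuracy,
               sensitivity = roc$sensitivity, specificity = roc$specificity,
               sv_ratio = cv$mean_sv_ratio, stringsAsFactors = FALSE)
  })
  list(report = do.call(rbind, rows), cv = cvs)
}

#' Feature-count sweep
#'
#' Re-runs LOPOCV on one combination while increasing the feature-selection
#' cap, tracking the realized mean number of selected features and the
#' pooled-ROC metrics at each grid point.
#'
#' @param ft Full [feature_table()].
#' @param labels Labels in `{-1, +1}`.
#' @param combo Combination to sweep, default `"FP+Rad"`.
#' @param max_nf_values Grid of caps, default `2:18`.
#' @param ... Passed to [lopocv()].
#' @return List with `curve` (data.frame: max_nf, mean_n_features, auc,
#'   accuracy, sensitivity, specificity) and `selections` (per grid point,
#'   the per-fold selected feature names).
#' @export
max_nf_sweep <- function(ft, labels, combo = "FP+Rad", max_nf_values = 2:18,
                         ...) {
  sub <- subset_combo(ft, combo)
  selections <- list()
  rows <- lapply(max_nf_values, function(nf) {
    cv <- lopocv(sub, labels, max_nf = nf, ...)
    selections[[as.character(nf)]] <<- cv$fold_selections
    roc <- roc_summary(cv$scores, labels)
    data.frame(max_nf = nf, mean_n_features = cv$mean_n_features,
               auc = roc$auc, accuracy = roc$accuracy,
               sensitivity = roc$sensitivity, specificity = roc$specificity)
  })
  list(curve = do.call(rbind, rows), selections = selections)
}

#' Consensus features across cross-validation folds
#'
#' Features selected in strictly more than `min_count` folds — the
#' most-frequently-selected set.
#'
#' @param fold_selections List of character vectors (one per fold).
#' @param min_count Strict lower bound on the selection count, default 10.
#' @return data.frame with columns `feature` and `count`, ordered by
#'   decreasing count.
#' @export
consensus_features <- function(fold_selections, min_count = 10) {
  stopifnot(length(fold_selections) >= 1)
  counts <- table(unlist(fold_selections))
  keep <- counts[counts > min_count]
  out <- data.frame(feature = names(keep), count = as.integer(keep),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$feature), , drop = FALSE]
}

#' Prediction-task experiment with a fixed feature set
#'
#' For each labeling scheme: relabel the cohort, drop excluded sites, run
#' LOPOCV with selection bypassed (every fold trains on exactly the supplied
#' features), and report class counts plus pooled-ROC metrics at the optimal
#' operating point.
#'
#' @param ft Full [feature_table()].
#' @param histology Histology table aligned with the feature table's sites.
#' @param features Character vector of feature names to train on.
#' @param schemes Labeling schemes to evaluate.
#' @param hg_cutoff High-grade percentage cutoff for the `high_grade` scheme.
#' @param ... Passed to [lopocv()].
#' @return List with `report` (one row per scheme: scheme, n_sites, n_pos,
#'   n_neg, auc, accuracy, sensitivity, specificity) and `cv`.
#' @export
prediction_task_experiment <- function(ft, histology, features,
    schemes = c("gg_gt1", "gg_ge1", "high_grade"), hg_cutoff = 20, ...) {
  stopifnot(length(features) >= 1)
  stopifnot(identical(as.character(histology$site_id), ft$site_id))
  cvs <- list()
  rows <- lapply(schemes, function(sc) {
    lab <- assign_labels(histology, sc, hg_cutoff)
    keep <- !is.na(lab)
    if (length(unique(lab[keep])) < 2) {
      stop("labeling scheme ", sc, " leaves a single class")
    }
    sub <- feature_table(ft$X[keep, , drop = FALSE], ft$modality,
                         ft$site_id[keep], ft$patient_id[keep])
    cv <- lopocv(sub, lab[keep], fixed_features = features, ...)
    cvs[[sc]] <<- cv
    roc <- roc_summary(cv$scores, lab[keep])
    data.frame(scheme = sc, n_sites = sum(keep), n_pos = sum(lab[keep] == 1),
               n_neg = sum(lab[keep] == -1), auc = roc$auc,
               accuracy = roc$accuracy, sensitivity = roc$sensitivity,
               specificity = roc$specificity, stringsAsFactors = FALSE)
  })
  list(report = do.call(rbind, rows), cv = cvs)
}
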