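#' Construct a sites-by-features table
#'
#' Container aligning the feature matrix with per-site and per-patient
#' identifiers and a modality tag per feature (`"FP"`, `"HW"` or `"Rad"`).
#'
#' @param X Numeric matrix, sites in rows, features in columns; column names
#'   must be unique and non-missing.
#' @param modality Character vector tagging each column.
#' @param site_id,patient_id Character vectors aligned with rows.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(X, modality, site_id, patient_id) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stop("feature columns must carry unique names")
  }
  stopifnot(length(modality) == ncol(X),
            length(site_id) == nrow(X),
            length(patient_id) == nrow(X))
  if (any(!is.finite(X))) stop("feature table must not contain missing values")
  stopifnot(all(modality %in% c("FP", "HW", "Rad")))
  rownames(X) <- site_id
  structure(list(X = X, modality = as.character(modality),
                 site_id = as.character(site_id),
                 patient_id = as.character(patient_id)),
            class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d sites x %d features (FP %d, HW %d, Rad %d)\n",
              nrow(x$X), ncol(x$X), sum(x$modality == "FP"),
              sum(x$modality == "HW"), sum(x$modality == "Rad")))
  invisible(x)
}

#' Column-bind feature tables over the same sites
#'
#' @param ... `feature_table` objects with identical site/patient alignment.
#' @return A combined `feature_table`.
#' @export
combine_feature_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  for (t in tabs[-1]) {
    if (!identical(t$site_id, tabs[[1]]$site_id)) {
      stop("feature tables are not aligned on the same sites")
    }
  }
  feature_table(do.call(cbind, lapply(tabs, `[[`, "X")),
                unlist(lapply(tabs, `[[`, "modality")),
                tabs[[1]]$site_id, tabs[[1]]$patient_id)
}

#' Restrict a feature table to a modality combination
#'
#' @param ft A [feature_table()].
#' @param combo Combination name: one of `"FP"`, `"HW"`, `"Rad"`, `"FP+HW"`,
#'   `"FP+Rad"`, `"FP+HW+Rad"`, `"HW+Rad"`.
#' @return A `feature_table` with only the requested modalities' columns.
#' @export
subset_combo <- function(ft, combo) {
  parts <- strsplit(combo, "+", fixed = TRUE)[[1]]
  if (!all(parts %in% c("FP", "HW", "Rad")) || length(parts) == 0) {
    stop("unknown feature combination: ", combo)
  }
  keep <- ft$modality %in% parts
  if (!any(keep)) stop("combination selects no columns: ", combo)
  feature_table(ft$X[, keep, drop = FALSE], ft$modality[keep],
                ft$site_id, ft$patient_id)
}
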