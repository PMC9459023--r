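#' Write / read the site table
#'
#' Tab-separated, UTF-8, '.' decimal separator; a benign site's missing
#' high-grade percentage is encoded as an empty field. Gleason/grade-group
#' consistency is validated on read with the offending row named.
#'
#' @param sites data.frame with columns patient_id, site_id, x, y, z,
#'   gs_primary, gs_secondary, isup_gg, hg_percent.
#' @param path Output/input file path.
#' @return `read_site_table` returns the validated data.frame.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  sites <- utils::read.delim(path, sep = "\t", na.strings = "",
                             stringsAsFactors = FALSE)
  required <- c("patient_id", "site_id", "x", "y", "z",
                "gs_primary", "gs_secondary", "isup_gg", "hg_percent")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    stop("site table at ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  validate_histology(sites)
  sites
}

#' Write / read replicate spectra as CSV
#'
#' First column is the axis (pixel or Raman shift), remaining columns one
#' replicate each.
#'
#' @param acq A [raman_acquisition_set()].
#' @param path File path.
#' @param region Region tag used when reading.
#' @return `read_spectra_csv` returns a `raman_acq`.
#' @export
write_spectra_csv <- function(acq, path) {
  stopifnot(inherits(acq, "raman_acq"))
  df <- data.frame(axis = acq$pixel_axis, t(acq$replicates))
  names(df) <- c("axis", sprintf("rep%03d", seq_len(nrow(acq$replicates))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, region = c("FP", "HW")) {
  region <- match.arg(region)
  df <- utils::read.csv(path)
  raman_acquisition_set(t(as.matrix(df[, -1, drop = FALSE])), region,
                        df[[1]])
}

#' Write / read an MRI volume as NIfTI-1
#'
#' Voxel spacing and origin are carried in the header (qform); the modality
#' comes from the filename tag (`*_T2.nii`, `*_ADC.nii`, `*_b2000.nii`) or
#' can be passed explicitly.
#'
#' @param vol An [mri_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param modality Modality override when reading.
#' @return `read_volume` returns an `mri_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mri_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, modality = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) {
    stop("expected a 3-D volume, got ", length(dim(img)), "-D: ", path)
  }
  if (is.null(modality)) {
    tag <- regmatches(basename(path),
                      regexpr("(T2|ADC|b2000)", basename(path)))
    if (length(tag) == 0) {
      stop("cannot infer modality from filename: ", basename(path))
    }
    modality <- tag
  }
  x <- RNifti::xform(img)
  # NIfTI stores pixdim/offsets as float32; round back to sub-nm precision
  mri_volume(as.array(img), round(RNifti::pixdim(img)[1:3], 6),
             round(x[1:3, 4], 6), modality)
}

#' Write / read a registration transform as JSON
#'
#' Stored as a row-major 4x4 matrix.
#'
#' @param mat 4x4 affine matrix.
#' @param path File path.
#' @return `read_transform` returns the 4x4 matrix.
#' @export
write_transform <- function(mat, path) {
  stopifnot(all(dim(mat) == c(4, 4)))
  jsonlite::write_json(list(mri_to_trus = as.vector(t(mat))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  matrix(obj$mri_to_trus, 4, 4, byrow = TRUE)
}

#' Write / read a feature table as TSV
#'
#' Two header rows — feature names, then modality tags — followed by one row
#' per site with `site_id` and `patient_id` leading columns.
#'
#' @param ft A [feature_table()].
#' @param path File path.
#' @return `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("site_id", "patient_id", colnames(ft$X)),
                   collapse = "\t"), con)
  writeLines(paste(c("id", "id", ft$modality), collapse = "\t"), con)
  body <- cbind(ft$site_id, ft$patient_id,
                format(ft$X, digits = 15, trim = TRUE, scientific = TRUE))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  header <- readLines(path, n = 2)
  names <- strsplit(header[1], "\t", fixed = TRUE)[[1]]
  tags <- strsplit(header[2], "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(path, skip = 2, header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- names
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  colnames(X) <- names[-(1:2)]
  feature_table(X, tags[-(1:2)], df$site_id, df$patient_id)
}

#' Write a cross-validation result as JSON
#'
#' Serializes the pooled per-site posteriors, per-fold selected features and
#' weights, and the fold summaries.
#'
#' @param cv A [lopocv()] result.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  obj <- list(scores = as.list(cv$scores),
              labels = cv$labels,
              fold_selections = cv$fold_selections,
              fold_weights = lapply(cv$fold_weights, as.list),
              n_features = cv$n_features,
              sv_ratios = cv$sv_ratios,
              mean_n_features = cv$mean_n_features,
              mean_sv_ratio = cv$mean_sv_ratio)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' YAML with a versioned schema; unknown keys are rejected so typos fail
#' loudly rather than silently falling back to defaults.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version)) stop("run config must declare schema_version")
  known <- c("schema_version", "seed", "scheme", "combo", "max_nf",
             "var_thresh", "corr_thresh", "cost_fn", "cost_fp", "n_patients",
             "lesion_contrast", "out_dir", "radius_mm", "bin_width")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(seed = 1L, scheme = "gg_gt1", combo = "FP+Rad",
                   max_nf = 10, var_thresh = 0.03, corr_thresh = 0.10,
                   cost_fn = 2, cost_fp = 1, n_patients = 18,
                   lesion_contrast = 0.35, out_dir = ".", radius_mm = 5,
                   bin_width = 25)
  utils::modifyList(defaults, cfg[setdiff(names(cfg), "schema_version")])
}

#' Run the end-to-end pipeline from a configuration
#'
#' Simulate a cohort, preprocess the spectra, extract radiomics, assign
#' labels under the configured scheme and run LOPOCV on the configured
#' feature combination; writes the site table, feature table, CV result and
#' a report TSV under `out_dir` and returns the report row.
#'
#' @param config A list from [load_run_config()] (or compatible).
#' @return data.frame with the run's pooled-ROC metrics.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sc <- synthetic_config(n_patients = config$n_patients,
                         lesion_contrast = config$lesion_contrast,
                         seed = config$seed)
  cohort <- generate_cohort(sc)
  ft <- cohort_feature_table(cohort)
  labels <- assign_labels(cohort$sites, config$scheme)
  keep <- !is.na(labels)
  sub <- feature_table(ft$X[keep, , drop = FALSE], ft$modality,
                       ft$site_id[keep], ft$patient_id[keep])
  cost <- matrix(c(0, config$cost_fn, config$cost_fp, 0), 2)
  cv <- lopocv(subset_combo(sub, config$combo), labels[keep], cost = cost,
               max_nf = config$max_nf, var_thresh = config$var_thresh,
               corr_thresh = config$corr_thresh)
  roc <- roc_summary(cv$scores, labels[keep])
  report <- data.frame(scheme = config$scheme, combo = config$combo,
                       n_sites = sum(keep),
                       mean_n_features = cv$mean_n_features,
                       auc = roc$auc, accuracy = roc$accuracy,
                       sensitivity = roc$sensitivity,
                       specificity = roc$specificity,
                       sv_ratio = cv$mean_sv_ratio)
  write_site_table(cohort$sites, file.path(config$out_dir, "sites.tsv"))
  write_cv_result(cv, file.path(config$out_dir, "cv_result.json"))
  utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report
}
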