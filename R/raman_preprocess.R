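#' Construct a Raman acquisition set
#'
#' Bundles the replicate raw spectra recorded at one inspected site for one
#' spectral region (fingerprint or high wavenumber).
#'
#' @param replicates Numeric matrix, one row per replicate acquisition.
#' @param region `"FP"` or `"HW"`.
#' @param pixel_axis Monotone numeric axis (pixel index or provisional
#'   Raman shift in cm-1); length must match `ncol(replicates)`.
#' @return An object of class `raman_acq`.
#' @export
raman_acquisition_set <- function(replicates, region = c("FP", "HW"),
                                  pixel_axis = seq_len(ncol(replicates))) {
  region <- match.arg(region)
  replicates <- as.matrix(replicates)
  if (nrow(replicates) < 1) stop("acquisition set needs at least one replicate")
  if (length(pixel_axis) != ncol(replicates)) {
    stop("pixel_axis length must equal the number of spectral samples")
  }
  if (any(!is.finite(replicates))) stop("replicate intensities must be finite")
  if (any(diff(pixel_axis) <= 0)) stop("pixel_axis must be strictly increasing")
  structure(list(region = region, pixel_axis = as.numeric(pixel_axis),
                 replicates = replicates),
            class = "raman_acq")
}

# Within-spectrum spike detection on running-median residuals: flags samples
# whose robust z-score exceeds the threshold, but only in runs of at most 3
# consecutive samples — cosmic rays are 1-3 samples wide, whereas a genuine
# Raman peak exceeds the residual threshold over a broader support.
narrow_spike_flags <- function(resid, z_thresh, max_width = 3L) {
  # running-median residuals are exactly zero over locally monotone
  # stretches, so the scale is estimated from the non-zero residuals
  # (falling back to the SD when even those are degenerate)
  nz <- resid[resid != 0]
  if (length(nz) == 0) return(logical(length(resid)))
  s <- stats::mad(nz)
  if (s == 0) s <- stats::sd(resid)
  if (!is.finite(s) || s == 0) return(logical(length(resid)))
  flag <- abs(resid) > z_thresh * s
  if (!any(flag)) return(flag)
  r <- rle(flag)
  r$values[r$values & r$lengths > max_width] <- FALSE
  inverse.rle(r)
}

#' Remove cosmic-ray spikes from replicate spectra
#'
#' Cosmic rays appear as narrow, high-amplitude positive spikes in individual
#' replicates. With three or more replicates, detection is performed across
#' the replicate stack: at each spectral sample the replicate values are
#' compared to their cross-replicate median, and values whose robust z-score
#' (median absolute deviation scaled by 1.4826) exceeds `z_thresh` are
#' replaced by that median. When the MAD is zero (replicates in exact
#' agreement) only values that deviate at all are replaced, so an identical
#' stack passes through untouched. With fewer than three replicates the
#' function falls back to within-spectrum detection against a running
#' median, with a warning.
#'
#' @param acq A [raman_acquisition_set()].
#' @param z_thresh Robust z-score threshold; default 5.
#' @return The acquisition set with flagged values replaced.
#' @export
remove_cosmic_rays <- function(acq, z_thresh = 5) {
  stopifnot(inherits(acq, "raman_acq"), z_thresh > 0)
  reps <- acq$replicates
  if (nrow(reps) >= 3) {
    med <- col_medians(reps)
    dev <- abs(sweep(reps, 2, med, "-"))
    mad <- 1.4826 * col_medians(dev)
    # dev > z*MAD; a zero MAD flags any non-zero deviation (and flags
    # nothing when all replicates agree)
    flag <- sweep(dev, 2, mad * z_thresh, ">") & dev > 0
    if (any(flag)) {
      reps[flag] <- med[col(reps)[flag]]
    }
  } else {
    warning("fewer than 3 replicates: falling back to within-spectrum spike detection")
    for (r in seq_len(nrow(reps))) {
      x <- reps[r, ]
      smooth <- stats::runmed(x, k = 5, endrule = "median")
      bad <- narrow_spike_flags(x - smooth, z_thresh)
      reps[r, bad] <- smooth[bad]
    }
  }
  acq$replicates <- reps
  acq
}

#' Average replicate spectra
#'
#' @param acq A [raman_acquisition_set()].
#' @return Numeric vector: the arithmetic mean spectrum over replicates.
#' @export
average_replicates <- function(acq) {
  stopifnot(inherits(acq, "raman_acq"))
  if (nrow(acq$replicates) < 1) stop("empty acquisition set")
  colMeans(acq$replicates)
}

#' Subtract the autofluorescence baseline
#'
#' Tissue autofluorescence contributes a broad, smooth background that can be
#' an order of magnitude larger than the Raman peaks. It is estimated by
#' iterative modified polynomial fitting: an order-`poly_order` polynomial is
#' fit by least squares, the working signal is replaced by the elementwise
#' minimum of itself and the fit, and the fit is repeated until the maximum
#' change in the baseline falls below `tol` times the signal scale or
#' `max_iter` is reached. Peaks are progressively excluded from the fit while
#' the smooth background is retained.
#'
#' @param spectrum Numeric vector (typically the replicate-averaged spectrum).
#' @param poly_order Polynomial order, default 5.
#' @param max_iter Iteration cap, default 100.
#' @param tol Relative convergence tolerance on the baseline, default 1e-6.
#' @return The baseline-subtracted spectrum, with attributes `baseline`,
#'   `iterations` and `converged`. Non-convergence returns the last iterate
#'   with `converged = FALSE`.
#' @export
subtract_autofluorescence <- function(spectrum, poly_order = 5,
                                      max_iter = 100, tol = 1e-6) {
  n <- length(spectrum)
  if (n < poly_order + 2) stop("spectrum too short for the requested polynomial order")
  scale <- max(abs(spectrum), 1e-12)
  u <- seq(-1, 1, length.out = n)
  basis <- stats::poly(u, degree = poly_order, raw = FALSE)
  design <- cbind(1, basis)
  qrd <- qr(design)
  work <- spectrum
  fit_prev <- rep(0, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    fit <- drop(qr.fitted(qrd, work))
    work <- pmin(work, fit)
    if (max(abs(fit - fit_prev)) < tol * scale) {
      converged <- TRUE
      fit_prev <- fit
      break
    }
    fit_prev <- fit
  }
  out <- spectrum - fit_prev
  attr(out, "baseline") <- fit_prev
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

#' Standard normal variate normalization
#'
#' Centers a spectrum to zero mean and scales it to unit sample standard
#' deviation (divisor n-1), removing multiplicative intensity differences
#' between acquisitions.
#'
#' @param spectrum Numeric vector.
#' @return The normalized spectrum (mean 0, sample SD 1).
#' @export
snv_normalize <- function(spectrum) {
  spectrum <- as.numeric(spectrum)
  s <- stats::sd(spectrum)
  if (!is.finite(s) || s == 0) {
    stop("degenerate acquisition: spectrum has zero variance, cannot SNV-normalize")
  }
  (spectrum - mean(spectrum)) / s
}

#' Assign a Raman-shift axis to spectrometer pixels
#'
#' Applies a strictly monotone calibration map elementwise to the pixel axis,
#' yielding Raman shifts in cm-1.
#'
#' @param pixel_axis Numeric vector of pixel positions.
#' @param calibration A function mapping pixel position to Raman shift, or
#'   `NULL` for the identity (the pixel axis already holds shifts).
#' @return Strictly increasing numeric vector of Raman shifts.
#' @export
assign_shift_axis <- function(pixel_axis, calibration = NULL) {
  if (is.null(calibration)) return(as.numeric(pixel_axis))
  shift <- vapply(pixel_axis, calibration, numeric(1))
  if (any(diff(shift) <= 0)) {
    stop("calibration map is not strictly monotone over the pixel range")
  }
  shift
}

#' Preprocess one site's replicate spectra into a single Raman spectrum
#'
#' Full per-site, per-region processing chain: cosmic-ray rejection on the
#' replicate stack, replicate averaging, autofluorescence baseline removal,
#' SNV normalization and Raman-shift axis assignment. The
#' `order = "average_first"` variant averages the replicates before removing
#' spikes from the averaged spectrum (within-spectrum detection).
#'
#' @param acq A [raman_acquisition_set()].
#' @param z_thresh Spike-rejection threshold, see [remove_cosmic_rays()].
#' @param poly_order,max_iter,tol Baseline parameters, see
#'   [subtract_autofluorescence()].
#' @param calibration Optional pixel-to-shift calibration map.
#' @param order `"spikes_first"` (default; replicate-stack detection) or
#'   `"average_first"`.
#' @return An object of class `processed_spectrum`: list with `region`,
#'   `shift` (cm-1, strictly increasing) and `intensity` (SNV-normalized).
#' @export
preprocess_site <- function(acq, z_thresh = 5, poly_order = 5, max_iter = 100,
                            tol = 1e-6, calibration = NULL,
                            order = c("spikes_first", "average_first")) {
  order <- match.arg(order)
  stopifnot(inherits(acq, "raman_acq"))
  if (order == "spikes_first") {
    mean_spec <- average_replicates(remove_cosmic_rays(acq, z_thresh))
  } else {
    mean_spec <- average_replicates(acq)
    smooth <- stats::runmed(mean_spec, k = 5, endrule = "median")
    bad <- narrow_spike_flags(mean_spec - smooth, z_thresh)
    mean_spec[bad] <- smooth[bad]
  }
  corrected <- subtract_autofluorescence(mean_spec, poly_order, max_iter, tol)
  intensity <- snv_normalize(as.numeric(corrected))
  shift <- assign_shift_axis(acq$pixel_axis, calibration)
  structure(list(region = acq$region, shift = shift, intensity = intensity),
            class = "processed_spectrum")
}
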