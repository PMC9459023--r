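#' Construct an MRI volume
#'
#' A single modality's 3-D intensity grid with physical voxel spacing and
#' origin. Volumes are axis-aligned; world coordinates (mm) relate to 1-based
#' voxel indices by `world = origin + (index - 1) * spacing`.
#'
#' @param data 3-D numeric array of intensities.
#' @param spacing_mm Positive 3-vector of voxel spacing in mm.
#' @param origin_mm 3-vector, world position of voxel (1,1,1), default zeros.
#' @param modality `"T2"`, `"ADC"` or `"b2000"`.
#' @return An object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0),
                       modality = c("T2", "ADC", "b2000")) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3) stop("volume must be a 3-D array")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0)) {
    stop("spacing must be a positive 3-vector")
  }
  if (any(!is.finite(data))) stop("volume intensities must be finite")
  structure(list(modality = modality, data = data,
                 spacing = as.numeric(spacing_mm),
                 origin = as.numeric(origin_mm)),
            class = "mri_volume")
}

#' Map an intraoperative (TRUS-frame) point into MRI coordinates
#'
#' The registration transform maps MRI to TRUS coordinates; inspected-site
#' coordinates recorded in the TRUS frame are carried back into the MRI frame
#' by applying the inverse transform.
#'
#' @param point_mm 3-vector, TRUS-frame position in mm.
#' @param mri_to_trus 4x4 affine matrix (homogeneous, mm to mm).
#' @return 3-vector, the MRI-frame position in mm.
#' @export
map_trus_to_mri <- function(point_mm, mri_to_trus) {
  stopifnot(length(point_mm) == 3, all(dim(mri_to_trus) == c(4, 4)))
  inv <- tryCatch(solve(mri_to_trus),
                  error = function(e) stop("registration transform is singular"))
  drop(inv %*% c(point_mm, 1))[1:3]
}

#' Extract a spherical region of interest from a volume
#'
#' Includes exactly the voxels whose physical centers lie within
#' `radius_mm` (Euclidean distance in mm; anisotropic spacing respected) of
#' the given center.
#'
#' @param vol An [mri_volume()].
#' @param center_mm 3-vector, ROI center in the volume's world frame (mm).
#' @param radius_mm Sphere radius in mm, default 5.
#' @return List with `indices` (n x 3 integer matrix of voxel indices),
#'   `intensities` and `voxel_volume_mm3`.
#' @export
spherical_roi <- function(vol, center_mm, radius_mm = 5) {
  stopifnot(inherits(vol, "mri_volume"), radius_mm > 0, length(center_mm) == 3)
  dims <- dim(vol$data)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (dims - 1) * vol$spacing + vol$spacing / 2
  if (any(center_mm < lo) || any(center_mm > hi)) {
    stop(sprintf("ROI center outside the %s volume extent", vol$modality))
  }
  rng <- lapply(1:3, function(a) {
    idx <- seq_len(dims[a])
    pos <- vol$origin[a] + (idx - 1) * vol$spacing[a]
    idx[abs(pos - center_mm[a]) <= radius_mm]
  })
  if (any(lengths(rng) == 0)) {
    stop(sprintf("empty ROI in the %s volume", vol$modality))
  }
  grid <- as.matrix(expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]]))
  pos <- sweep(sweep(grid - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
  d2 <- rowSums(sweep(pos, 2, center_mm, "-")^2)
  keep <- d2 <= radius_mm^2
  if (!any(keep)) stop(sprintf("empty ROI in the %s volume", vol$modality))
  idx <- grid[keep, , drop = FALSE]
  list(indices = idx,
       intensities = vol$data[idx],
       voxel_volume_mm3 = prod(vol$spacing))
}

#' Discretize ROI intensities into contiguous grey levels
#'
#' Fixed-bin-width discretization anchored at the ROI minimum:
#' `level = floor((x - min(x)) / bin_width) + 1`. Levels are contiguous from 1.
#'
#' @param x Numeric intensities.
#' @param bin_width Positive bin width in intensity units, default 25.
#' @return List with integer `levels` and `n_levels`.
#' @export
discretize <- function(x, bin_width = 25) {
  stopifnot(bin_width > 0, length(x) > 0)
  lev <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  list(levels = lev, n_levels = max(lev))
}

#' First-order radiomics features
#'
#' The eight intensity-distribution statistics: Energy (sum of squared
#' intensities), Total energy (Energy times voxel volume), Entropy (bits,
#' over the fixed-bin-width discretization), Mean, Median, Standard deviation
#' (population, divisor n), Mean absolute deviation and Uniformity (sum of
#' squared bin probabilities).
#'
#' @param roi A [spherical_roi()] result.
#' @param bin_width Discretization bin width shared with the GLCM features.
#' @return Named numeric vector of length 8.
#' @export
first_order_features <- function(roi, bin_width = 25) {
  x <- roi$intensities
  n <- length(x)
  if (n == 0) stop("empty ROI")
  disc <- discretize(x, bin_width)
  p <- tabulate(disc$levels, nbins = disc$n_levels) / n
  p <- p[p > 0]
  mu <- mean(x)
  c(Energy = sum(x^2),
    TotalEnergy = roi$voxel_volume_mm3 * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Mean = mu,
    Median = stats::median(x),
    StandardDeviation = sqrt(mean((x - mu)^2)),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Uniformity = sum(p^2))
}

#' The 13 unique 3-D GLCM offsets at distance 1
#'
#' @return 13 x 3 integer matrix of voxel offsets (one per direction pair).
#' @export
glcm_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
}

#' Grey-level co-occurrence matrices of a masked level grid
#'
#' For each spatial offset, counts in-mask voxel pairs `(v, v + d)` by their
#' level pair, symmetrizes (`P + t(P)`) and normalizes to sum 1. Directions
#' with no valid pair are dropped; an error is raised if none remain.
#'
#' @param levels_arr 3-D integer array of grey levels with `NA` outside the
#'   ROI mask.
#' @param n_levels Number of grey levels.
#' @param directions Integer matrix of offsets, default [glcm_directions()].
#' @return List of normalized symmetric co-occurrence matrices.
#' @export
glcm_matrix <- function(levels_arr, n_levels, directions = glcm_directions()) {
  dims <- dim(levels_arr)
  stopifnot(length(dims) == 3, n_levels >= 1)
  out <- list()
  for (d in seq_len(nrow(directions))) {
    off <- directions[d, ]
    src <- lapply(1:3, function(a) {
      i <- seq_len(dims[a])
      i[i + off[a] >= 1 & i + off[a] <= dims[a]]
    })
    if (any(lengths(src) == 0)) next
    a <- levels_arr[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- levels_arr[src[[1]] + off[1], src[[2]] + off[2], src[[3]] + off[3],
                    drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    P <- matrix(0, n_levels, n_levels)
    tab <- table(factor(a[ok], levels = seq_len(n_levels)),
                 factor(b[ok], levels = seq_len(n_levels)))
    P <- matrix(as.numeric(tab), n_levels, n_levels)
    P <- P + t(P)
    out[[length(out) + 1L]] <- P / sum(P)
  }
  if (length(out) == 0) stop("no valid voxel pairs in any GLCM direction")
  out
}

# The eight texture features of one normalized co-occurrence matrix.
glcm_features_single <- function(P) {
  L <- nrow(P)
  i <- row(P); j <- col(P)
  pi_m <- rowSums(P); pj_m <- colSums(P)
  li <- seq_len(L)
  mu_i <- sum(li * pi_m); mu_j <- sum(li * pj_m)
  sd_i <- sqrt(sum((li - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((li - mu_j)^2 * pj_m))
  corr <- if (sd_i * sd_j == 0) 1 else (sum(i * j * P) - mu_i * mu_j) / (sd_i * sd_j)
  k <- abs(i - j)
  p_diff <- vapply(0:(L - 1), function(d) sum(P[k == d]), numeric(1))
  p_diff <- p_diff[p_diff > 0]
  pk <- P[P > 0]
  c(Autocorrelation = sum(i * j * P),
    ClusterShade = sum((i + j - mu_i - mu_j)^3 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    Id = sum(P / (1 + k)),
    DifferenceEntropy = -sum(p_diff * log2(p_diff)),
    JointEntropy = -sum(pk * log2(pk)),
    JointEnergy = sum(P^2))
}

#' GLCM texture features averaged over directions
#'
#' Computes Autocorrelation, Cluster shade, Contrast, Correlation, Inverse
#' difference (Id), Difference entropy, Joint entropy and Joint energy for
#' each direction's co-occurrence matrix and averages over directions.
#' Correlation of a single-level matrix is defined as 1.
#'
#' @param P_list List of normalized co-occurrence matrices
#'   (from [glcm_matrix()]).
#' @return Named numeric vector of length 8.
#' @export
glcm_features <- function(P_list) {
  stopifnot(length(P_list) >= 1)
  feats <- vapply(P_list, glcm_features_single, numeric(8))
  rowMeans(feats)
}

#' Table of the 48 radiomics feature identifiers
#'
#' Identifier-to-feature layout: r1-r16 on T2, r17-r32 on ADC, r33-r48 on
#' b2000, with the eight first-order features preceding the eight GLCM
#' features within each modality (so e.g. r17 is Energy on ADC and r46 is
#' Difference entropy on b2000).
#'
#' @return data.frame with columns `id`, `group`, `name`, `modality`.
#' @export
radiomics_feature_info <- function() {
  fo <- c("Energy", "TotalEnergy", "Entropy", "Mean", "Median",
          "StandardDeviation", "MeanAbsoluteDeviation", "Uniformity")
  gl <- c("Autocorrelation", "ClusterShade", "Contrast", "Correlation",
          "Id", "DifferenceEntropy", "JointEntropy", "JointEnergy")
  data.frame(
    id = paste0("r", 1:48),
    group = rep(rep(c("first_order", "glcm"), each = 8), times = 3),
    name = rep(c(fo, gl), times = 3),
    modality = rep(c("T2", "ADC", "b2000"), each = 16),
    stringsAsFactors = FALSE)
}

# Build the masked level array spanning the ROI's bounding box.
roi_level_array <- function(roi, bin_width) {
  disc <- discretize(roi$intensities, bin_width)
  lo <- apply(roi$indices, 2, min)
  hi <- apply(roi$indices, 2, max)
  arr <- array(NA_integer_, dim = hi - lo + 1)
  arr[cbind(roi$indices[, 1] - lo[1] + 1,
            roi$indices[, 2] - lo[2] + 1,
            roi$indices[, 3] - lo[3] + 1)] <- disc$levels
  list(arr = arr, n_levels = disc$n_levels)
}

#' Full radiomics vector for one inspected site
#'
#' Maps the site's TRUS coordinate into the MRI frame, draws a spherical ROI
#' in each of the three volumes and computes the 48 features keyed r1-r48
#' (see [radiomics_feature_info()] for the layout).
#'
#' @param trus_coords_mm 3-vector, the site position in the TRUS frame.
#' @param volumes Named list with elements `T2`, `ADC`, `b2000`
#'   ([mri_volume()] objects).
#' @param mri_to_trus 4x4 registration matrix (MRI to TRUS).
#' @param radius_mm ROI radius, default 5 mm.
#' @param bin_width Discretization bin width, default 25.
#' @return Named numeric vector `r1` ... `r48`.
#' @export
radiomics_vector <- function(trus_coords_mm, volumes, mri_to_trus,
                             radius_mm = 5, bin_width = 25) {
  stopifnot(all(c("T2", "ADC", "b2000") %in% names(volumes)))
  mri_pt <- map_trus_to_mri(trus_coords_mm, mri_to_trus)
  vals <- lapply(c("T2", "ADC", "b2000"), function(mod) {
    vol <- volumes[[mod]]
    roi <- tryCatch(spherical_roi(vol, mri_pt, radius_mm),
                    error = function(e) stop(sprintf(
                      "radiomics failed on %s: %s", mod, conditionMessage(e))))
    fo <- first_order_features(roi, bin_width)
    la <- roi_level_array(roi, bin_width)
    P <- glcm_matrix(la$arr, la$n_levels)
    c(fo, glcm_features(P))
  })
  out <- unlist(vals)
  names(out) <- paste0("r", 1:48)
  out
}
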