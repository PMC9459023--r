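#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a fully synthetic study cohort:
#' patients carrying a spherical lesion, inspected sites with replicate Raman
#' acquisitions in two spectral regions, three co-registered MRI volumes per
#' patient, a TRUS-frame registration transform and a histology record per
#' site. Defaults emulate an 18-patient cohort with 47-odd sites, a
#' benign/GG1/GG2/GG3/GG4 mix of 23:3:10:8:3, 50-100 replicates per site,
#' fingerprint and high-wavenumber grids of 1801 and 2801 samples, five
#' discriminative fingerprint bands (around 994, 1007, 1334, 1766 and
#' 1772 cm-1, stronger in benign tissue), and a lesion that lowers ADC
#' intensity and partially decorrelates the b2000 texture.
#'
#' @param n_patients Number of patients.
#' @param sites_per_patient_range Min/max inspected sites per patient.
#' @param sites_per_patient_weights Sampling weights over that range
#'   (favoring 2, matching a median of 2).
#' @param n_replicates_range Min/max replicate spectra per site and region.
#' @param fp_axis,hw_axis Raman-shift grids (cm-1); lengths fixed at 1801
#'   and 2801.
#' @param peak_bands data.frame with columns `center`, `width` (Gaussian SD,
#'   cm-1), `amp_benign`, `amp_tumor`.
#' @param band_jitter_sd SD of the per-site log-normal band-amplitude jitter.
#' @param baseline_params List: `coefs` (polynomial coefficients on a
#'   0-1-normalized axis) and `amplitude` (autofluorescence scale, much
#'   larger than the peak amplitudes).
#' @param noise_sd Additive white-noise SD per replicate sample.
#' @param cosmic_ray_rate Probability that a replicate carries a spike.
#' @param cosmic_ray_amplitude Spike amplitude (intensity units).
#' @param lesion_contrast Fractional ADC intensity drop inside the lesion;
#'   also scales the lesion's b2000 texture decorrelation, so
#'   `lesion_contrast = 0` removes every image-side class effect.
#' @param lesion_radius_mm Lesion sphere radius.
#' @param texture_params Named spatial correlation lengths (mm) of the
#'   per-modality noise fields.
#' @param mri_params Per-modality base intensity and noise SD; for b2000
#'   also `lesion_intensity` (hyperintensity, times `lesion_contrast`) and
#'   `lesion_decorrelation` (texture-decorrelation strength, times
#'   `lesion_contrast`).
#' @param lesion_effect_jitter Log-normal SDs of the per-patient lesion
#'   effect multipliers for the ADC and b2000 effects.
#' @param class_mix Target site fractions for benign/GG1/GG2/GG3/GG4;
#'   must sum to 1.
#' @param hg_low_fraction Target fraction of tumor sites with a high-grade
#'   percentage below 20.
#' @param seed Integer seed; the cohort is a pure function of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    n_patients = 18,
    sites_per_patient_range = c(2, 5),
    sites_per_patient_weights = c(0.55, 0.20, 0.15, 0.10),
    n_replicates_range = c(50, 100),
    fp_axis = seq(400, 1800, length.out = 1801),
    hw_axis = seq(2050, 3450, length.out = 2801),
    peak_bands = default_peak_bands(),
    band_jitter_sd = 0.10,
    baseline_params = list(coefs = c(1, 1.5, -0.8, 0.2, 0.4, -0.3),
                           amplitude = 60),
    noise_sd = 0.08,
    cosmic_ray_rate = 0.1,
    cosmic_ray_amplitude = 30,
    lesion_contrast = 0.35,
    lesion_radius_mm = 10,
    texture_params = c(T2 = 2, ADC = 3, b2000 = 4),
    mri_params = list(T2 = list(base = 500, noise_sd = 60),
                      ADC = list(base = 1400, noise_sd = 100),
                      b2000 = list(base = 150, noise_sd = 25,
                                   lesion_intensity = 0,
                                   lesion_decorrelation = 3.5)),
    lesion_effect_jitter = c(ADC = 0.35, b2000 = 0.25),
    class_mix = c(benign = 23, gg1 = 3, gg2 = 10, gg3 = 8, gg4 = 3) / 47,
    hg_low_fraction = 0.25,
    seed = 1L) {
  if (length(fp_axis) != 1801) stop("fp_axis must have exactly 1801 samples")
  if (length(hw_axis) != 2801) stop("hw_axis must have exactly 2801 samples")
  if (any(diff(fp_axis) <= 0) || any(diff(hw_axis) <= 0)) {
    stop("spectral axes must be strictly increasing")
  }
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    stop("class_mix must be non-negative and sum to 1")
  }
  for (r in c(cosmic_ray_rate, hg_low_fraction)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (lesion_contrast < 0 || lesion_contrast > 1) {
    stop("lesion_contrast must lie in [0, 1]")
  }
  stopifnot(n_patients >= 2, noise_sd >= 0,
            sites_per_patient_range[1] >= 1,
            sites_per_patient_range[2] >= sites_per_patient_range[1],
            n_replicates_range[1] >= 1,
            all(c("center", "width", "amp_benign", "amp_tumor") %in%
                  names(peak_bands)))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Default synthetic Raman band structure
#'
#' Five discriminative fingerprint bands (centers 994, 1007, 1334, 1766 and
#' 1772 cm-1) whose amplitudes are roughly halved in tumor tissue —
#' phenylalanine-, collagen/nucleic-acid- and lipid/protein-associated bands
#' that are more prominent in benign prostate — plus class-neutral
#' fingerprint and high-wavenumber (CH-stretch) structure.
#'
#' @return data.frame with columns `center`, `width`, `amp_benign`,
#'   `amp_tumor`.
#' @export
default_peak_bands <- function() {
  data.frame(
    center = c(994, 1007, 1334, 1766, 1772,
               855, 936, 1095, 1265, 1445, 1555, 1660,
               2850, 2885, 2930, 3060),
    width = c(3.5, 3.5, 6, 2.5, 2.5,
              8, 8, 9, 10, 12, 10, 12,
              15, 15, 20, 25),
    amp_benign = c(0.9, 1.3, 1.4, 0.8, 0.8,
                   1.2, 1.0, 1.2, 1.4, 2.2, 1.0, 2.0,
                   0.9, 1.0, 1.5, 0.5),
    amp_tumor = c(0.54, 0.78, 0.84, 0.48, 0.48,
                  1.2, 1.0, 1.2, 1.4, 2.2, 1.0, 2.0,
                  0.9, 1.0, 1.5, 0.5))
}

# ---- internal geometry constants of the synthetic patient ----
# MRI frame: axis-aligned volumes with origin 0; prostate modeled as a ball.
synth_geometry <- function() {
  list(t2_dim = c(48L, 48L, 48L), t2_spacing = c(1, 1, 1),
       adc_dim = c(27L, 27L, 13L), adc_spacing = c(1.8, 1.8, 4),
       b2000_dim = c(19L, 19L, 10L), b2000_spacing = c(2.6, 2.6, 5),
       prostate_center = c(23.5, 23.5, 23.5), prostate_radius = 16,
       lesion_offset_max = 7)
}

# Separable Gaussian smoothing with circular boundary, one sigma per axis
# (in voxels). Used to give the MRI noise fields a spatial correlation length.
gauss_smooth3 <- function(arr, sigma_vox) {
  dims <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    hw <- max(1L, ceiling(2.5 * s))
    kern <- stats::dnorm(seq(-hw, hw), sd = s)
    kern <- kern / sum(kern)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = dims[axis])
    f <- stats::filter(m, kern, method = "convolution", sides = 2,
                       circular = TRUE)
    a <- array(as.numeric(f), dim = dims[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

# Correlated unit-variance noise field.
correlated_noise <- function(dims, spacing, corr_length_mm) {
  white <- array(stats::rnorm(prod(dims)), dim = dims)
  sm <- gauss_smooth3(white, corr_length_mm / spacing)
  sm / stats::sd(sm)
}

# Voxel-center world coordinates along one axis.
axis_positions <- function(n, spacing) (seq_len(n) - 1) * spacing

lesion_mask <- function(dims, spacing, center, radius) {
  dx <- axis_positions(dims[1], spacing[1]) - center[1]
  dy <- axis_positions(dims[2], spacing[2]) - center[2]
  dz <- axis_positions(dims[3], spacing[3]) - center[3]
  d2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
  d2 <= radius^2
}

#' Simulate one patient's co-registered MRI triplet
#'
#' Builds T2 (1 x 1 x 1 mm), ADC (1.8 x 1.8 x 4 mm) and b2000
#' (2.6 x 2.6 x 5 mm) volumes sharing one world frame, with spatially
#' correlated noise per modality. Inside the patient's lesion sphere the ADC
#' intensity is reduced by the configured fractional contrast, and the b2000
#' intensity and voxel-scale heterogeneity are increased proportionally to
#' the same contrast (diffusion restriction in tumor). T2 carries no class
#' effect.
#'
#' @param lesion List with `center` (MRI mm) and `radius`.
#' @param config A [synthetic_config()].
#' @param stream Integer seed for this patient's imaging stream.
#' @return Named list of three [mri_volume()] objects: `T2`, `ADC`, `b2000`.
#' @export
simulate_mri_triplet <- function(lesion, config, stream) {
  g <- synth_geometry()
  tp <- config$texture_params
  mp <- config$mri_params
  # per-patient effect multipliers (set by generate_cohort); default 1
  adc_mult <- lesion$adc_mult %||% 1
  b2000_mult <- lesion$b2000_mult %||% 1
  lc <- config$lesion_contrast
  with_seed(stream, {
    vols <- list()
    specs <- list(T2 = list(g$t2_dim, g$t2_spacing),
                  ADC = list(g$adc_dim, g$adc_spacing),
                  b2000 = list(g$b2000_dim, g$b2000_spacing))
    for (mod in names(specs)) {
      dims <- specs[[mod]][[1]]; sp <- specs[[mod]][[2]]
      noise <- correlated_noise(dims, sp, tp[[mod]])
      mask <- lesion_mask(dims, sp, lesion$center, lesion$radius)
      base <- mp[[mod]]$base
      img <- base + mp[[mod]]$noise_sd * noise
      if (mod == "ADC") {
        img <- img - base * min(lc * adc_mult, 0.85) * mask
      } else if (mod == "b2000") {
        # texture effect: partially decorrelate the field inside the lesion
        # at equal marginal variance, so first-order statistics are untouched
        # while neighbor co-occurrence (GLCM) changes
        a <- min(1, lc * b2000_mult * (mp$b2000$lesion_decorrelation %||% 0))
        if (a > 0) {
          white <- array(stats::rnorm(prod(dims)), dims)
          img <- img + mp[[mod]]$noise_sd * mask *
            ((sqrt(1 - a^2) - 1) * noise + a * white)
        }
        img <- img + (mp$b2000$lesion_intensity %||% 0) * lc * b2000_mult * mask
      }
      vols[[mod]] <- mri_volume(img, sp, c(0, 0, 0), mod)
    }
    vols
  })
}

# Evaluate the autofluorescence polynomial baseline on a shift axis.
baseline_curve <- function(axis, baseline_params) {
  u <- (axis - min(axis)) / (max(axis) - min(axis))
  coefs <- baseline_params$coefs
  val <- Reduce(`+`, lapply(seq_along(coefs),
                            function(k) coefs[k] * u^(k - 1)))
  baseline_params$amplitude * val
}

#' Simulate one site's replicate Raman acquisitions
#'
#' Each replicate is the site's noiseless spectrum — an autofluorescence
#' polynomial baseline plus Gaussian peaks with class-dependent,
#' site-jittered amplitudes — plus white noise, with cosmic-ray spikes
#' (1-3 samples wide, positive) injected independently per replicate at the
#' configured rate. The replicate count is drawn uniformly from the
#' configured range.
#'
#' @param tumor Logical: is this a tumor site (grade group >= 1)?
#' @param region `"FP"` or `"HW"`.
#' @param config A [synthetic_config()].
#' @param stream Integer seed for this site/region stream.
#' @return A [raman_acquisition_set()]; attribute `truth` carries the
#'   noiseless spectrum.
#' @export
simulate_acquisition_set <- function(tumor, region = c("FP", "HW"), config,
                                     stream) {
  region <- match.arg(region)
  axis <- if (region == "FP") config$fp_axis else config$hw_axis
  bands <- config$peak_bands
  with_seed(stream, {
    amp <- if (tumor) bands$amp_tumor else bands$amp_benign
    amp <- amp * exp(stats::rnorm(nrow(bands), 0, config$band_jitter_sd))
    base_scale <- stats::runif(1, 0.7, 1.3)
    truth <- base_scale * baseline_curve(axis, config$baseline_params)
    for (b in seq_len(nrow(bands))) {
      truth <- truth + amp[b] *
        exp(-(axis - bands$center[b])^2 / (2 * bands$width[b]^2))
    }
    n_rep <- if (config$n_replicates_range[1] == config$n_replicates_range[2]) {
      config$n_replicates_range[1]
    } else {
      sample(config$n_replicates_range[1]:config$n_replicates_range[2], 1)
    }
    n <- length(axis)
    reps <- matrix(rep(truth, each = n_rep), nrow = n_rep)
    if (config$noise_sd > 0) {
      reps <- reps + matrix(stats::rnorm(n_rep * n, 0, config$noise_sd),
                            nrow = n_rep)
    }
    if (config$cosmic_ray_rate > 0) {
      hit <- stats::runif(n_rep) < config$cosmic_ray_rate
      for (r in which(hit)) {
        pos <- sample.int(n, 1)
        width <- sample.int(3, 1)
        idx <- pos:min(n, pos + width - 1)
        reps[r, idx] <- reps[r, idx] +
          config$cosmic_ray_amplitude * stats::runif(1, 0.8, 1.2)
      }
    }
    acq <- raman_acquisition_set(reps, region, axis)
    attr(acq, "truth") <- truth
    acq
  })
}

# Largest-remainder allocation of S sites to the class-mix fractions.
allocate_classes <- function(n_sites, class_mix) {
  target <- class_mix * n_sites
  counts <- floor(target)
  rem <- n_sites - sum(counts)
  if (rem > 0) {
    extra <- order(target - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

# Sample a point uniformly inside a ball.
runif_ball <- function(center, radius) {
  repeat {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(center + p)
  }
}

# Histology record for one site of a given class (1 = benign, 2..5 = GG1..4).
sample_histology <- function(class_idx, gg2_low_prob) {
  pairs <- list(c(0L, 0L), c(3L, 3L), c(3L, 4L), c(4L, 3L), c(4L, 4L))
  pair <- pairs[[class_idx]]
  hg <- switch(class_idx,
               NA_real_,
               stats::runif(1, 0, 15),
               if (stats::runif(1) < gg2_low_prob) stats::runif(1, 5, 19.5)
               else stats::runif(1, 21, 49),
               stats::runif(1, 55, 85),
               stats::runif(1, 85, 100))
  data.frame(gs_primary = pair[1], gs_secondary = pair[2],
             isup_gg = isup_grade_group(pair[1], pair[2]), hg_percent = hg)
}

# Rigid MRI -> TRUS transform: small rotation about z plus a translation.
sample_transform <- function() {
  theta <- stats::runif(1, -5, 5) * pi / 180
  R <- diag(4)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  R[1:3, 4] <- stats::runif(3, -20, 20)
  R
}

#' Generate a complete synthetic cohort
#'
#' Produces patients, inspected sites with TRUS coordinates and histology,
#' replicate Raman acquisition sets (both spectral regions), a co-registered
#' MRI triplet and a registration transform per patient. The realized class
#' counts follow the configured mix to within largest-remainder rounding
#' (at most one site per class). Tumor sites are placed inside the patient's
#' lesion sphere (with margin so the radiomics ROI stays in the lesion);
#' benign sites are placed in the prostate away from the lesion. The output
#' is a pure function of the config (including its seed); random streams are
#' hierarchical per cohort/patient/site.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `ram_cohort`: list with `config`, `sites`
#'   (data.frame: patient_id, site_id, x, y, z TRUS mm + histology columns),
#'   `raman` (per site: `FP` and `HW` acquisition sets), `volumes` and
#'   `transforms` (per patient), `lesions` (per patient: center, radius).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- synth_geometry()
  plan <- with_seed(derive_seed(config$seed, 1), {
    rng <- config$sites_per_patient_range
    sizes <- rng[1]:rng[2]
    w <- config$sites_per_patient_weights
    if (length(w) != length(sizes)) w <- rep(1, length(sizes))
    n_sites_pp <- sample(sizes, config$n_patients, replace = TRUE, prob = w)
    total <- sum(n_sites_pp)
    counts <- allocate_classes(total, config$class_mix)
    classes <- sample(rep(seq_along(counts), counts))  # 1=benign, 2..5=GG1..4
    n_tumor <- sum(classes > 1)
    n_gg1 <- sum(classes == 2); n_gg2 <- sum(classes == 3)
    gg2_low_prob <- if (n_gg2 > 0) {
      min(1, max(0, (config$hg_low_fraction * n_tumor - n_gg1) / n_gg2))
    } else 0
    list(n_sites_pp = n_sites_pp, classes = classes,
         gg2_low_prob = gg2_low_prob)
  })
  patient_ids <- sprintf("P%02d", seq_len(config$n_patients))
  sites_list <- list()
  raman <- list()
  volumes <- list()
  transforms <- list()
  lesions <- list()
  site_counter <- 0L
  class_cursor <- 0L
  for (k in seq_len(config$n_patients)) {
    pid <- patient_ids[k]
    n_s <- plan$n_sites_pp[k]
    cls <- plan$classes[class_cursor + seq_len(n_s)]
    class_cursor <- class_cursor + n_s
    pat <- with_seed(derive_seed(config$seed, 2, k), {
      lesion <- list(center = runif_ball(g$prostate_center,
                                         g$lesion_offset_max),
                     radius = config$lesion_radius_mm,
                     # lesions differ between patients in how strongly they
                     # restrict diffusion; independent jitter per modality
                     # keeps the two imaging effects complementary
                     adc_mult = exp(stats::rnorm(1, 0,
                       config$lesion_effect_jitter[["ADC"]])),
                     b2000_mult = exp(stats::rnorm(1, 0,
                       config$lesion_effect_jitter[["b2000"]])))
      trans <- sample_transform()
      coords <- lapply(cls, function(cl) {
        if (cl > 1) {
          runif_ball(lesion$center, max(lesion$radius - 5, 2))
        } else {
          # benign: in the prostate, ROI clear of the lesion
          for (try in 1:200) {
            p <- runif_ball(g$prostate_center, g$prostate_radius)
            if (sqrt(sum((p - lesion$center)^2)) >= lesion$radius + 6) break
          }
          p
        }
      })
      hist <- do.call(rbind, lapply(cls, sample_histology,
                                    gg2_low_prob = plan$gg2_low_prob))
      list(lesion = lesion, trans = trans, coords = coords, hist = hist)
    })
    volumes[[pid]] <- simulate_mri_triplet(pat$lesion, config,
                                           derive_seed(config$seed, 3, k))
    transforms[[pid]] <- pat$trans
    lesions[[pid]] <- pat$lesion
    for (s in seq_len(n_s)) {
      site_counter <- site_counter + 1L
      sid <- sprintf("S%03d", site_counter)
      trus <- drop(pat$trans %*% c(pat$coords[[s]], 1))[1:3]
      sites_list[[site_counter]] <- cbind(
        data.frame(patient_id = pid, site_id = sid,
                   x = trus[1], y = trus[2], z = trus[3],
                   stringsAsFactors = FALSE),
        pat$hist[s, , drop = FALSE])
      tumor <- cls[s] > 1
      raman[[sid]] <- list(
        FP = simulate_acquisition_set(tumor, "FP", config,
                                      derive_seed(config$seed, 4, k, s, 1)),
        HW = simulate_acquisition_set(tumor, "HW", config,
                                      derive_seed(config$seed, 4, k, s, 2)))
    }
  }
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  validate_histology(sites)
  structure(list(config = config, sites = sites, raman = raman,
                 volumes = volumes, transforms = transforms,
                 lesions = lesions),
            class = "ram_cohort")
}

#' @exportS3Method base::print
print.ram_cohort <- function(x, ...) {
  cat(sprintf("ram_cohort: %d patients, %d sites (%d tumor)\n",
              length(x$volumes), nrow(x$sites), sum(x$sites$isup_gg > 0)))
  invisible(x)
}

#' Preprocess every site's Raman acquisitions into spectral feature tables
#'
#' Runs [preprocess_site()] on each site and region and assembles the
#' SNV-normalized intensities into one feature table per region, with
#' columns named by Raman shift (e.g. `FP_1007.00`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param ... Passed to [preprocess_site()].
#' @return List with `FP` and `HW` [feature_table()] objects.
#' @export
preprocess_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "ram_cohort"))
  out <- lapply(c("FP", "HW"), function(region) {
    rows <- lapply(cohort$sites$site_id, function(sid) {
      preprocess_site(cohort$raman[[sid]][[region]], ...)$intensity
    })
    X <- do.call(rbind, rows)
    axis <- cohort$raman[[cohort$sites$site_id[1]]][[region]]$pixel_axis
    colnames(X) <- sprintf("%s_%.2f", region, axis)
    feature_table(X, rep(region, ncol(X)),
                  cohort$sites$site_id, cohort$sites$patient_id)
  })
  names(out) <- c("FP", "HW")
  out
}

#' Compute the radiomics feature table of a cohort
#'
#' Maps every site into its patient's MRI volumes and computes the 48-entry
#' radiomics vector (see [radiomics_vector()]).
#'
#' @param cohort A [generate_cohort()] result.
#' @param radius_mm,bin_width Passed to [radiomics_vector()].
#' @return A [feature_table()] with columns `r1` ... `r48`.
#' @export
radiomics_cohort <- function(cohort, radius_mm = 5, bin_width = 25) {
  stopifnot(inherits(cohort, "ram_cohort"))
  rows <- lapply(seq_len(nrow(cohort$sites)), function(i) {
    pid <- cohort$sites$patient_id[i]
    radiomics_vector(c(cohort$sites$x[i], cohort$sites$y[i], cohort$sites$z[i]),
                     cohort$volumes[[pid]], cohort$transforms[[pid]],
                     radius_mm, bin_width)
  })
  X <- do.call(rbind, rows)
  feature_table(X, rep("Rad", 48), cohort$sites$site_id,
                cohort$sites$patient_id)
}

#' Full multimodal feature table of a cohort
#'
#' Convenience wrapper: preprocesses both spectral regions, computes the
#' radiomics table and column-binds all three (4650 features under the
#' default grids: 1801 FP + 2801 HW + 48 Rad).
#'
#' @param cohort A [generate_cohort()] result.
#' @param ... Passed to [preprocess_cohort()].
#' @return A combined [feature_table()].
#' @export
cohort_feature_table <- function(cohort, ...) {
  spec <- preprocess_cohort(cohort, ...)
  rad <- radiomics_cohort(cohort)
  combine_feature_tables(spec$FP, spec$HW, rad)
}

#' Count recovered planted effects in a consensus feature list
#'
#' The generator plants its class signal in the discriminative spectral bands
#' (rows of `peak_bands` with unequal class amplitudes) plus two imaging
#' effects: the lesion's ADC intensity drop (carried by the ADC first-order
#' features, r17-r24) and its b2000 texture heterogeneity (carried by the
#' b2000 GLCM features, r41-r48). A spectral band counts as recovered when a
#' consensus feature lies within `window` band widths of its center; each
#' imaging effect counts when any consensus feature falls in its feature
#' group.
#'
#' @param consensus A [consensus_features()] data.frame.
#' @param config The [synthetic_config()] the cohort was generated with.
#' @param window Band half-width multiplier, default 2.
#' @return List with `n_planted`, `n_recovered` and a logical `recovered`
#'   vector named by planted effect.
#' @export
planted_recovery <- function(consensus, config, window = 2) {
  bands <- config$peak_bands
  disc <- bands[bands$amp_benign != bands$amp_tumor, , drop = FALSE]
  feats <- consensus$feature
  spectral <- grepl("^(FP|HW)_", feats)
  shifts <- suppressWarnings(as.numeric(sub("^(FP|HW)_", "", feats[spectral])))
  hits <- vapply(seq_len(nrow(disc)), function(b) {
    any(abs(shifts - disc$center[b]) <= window * disc$width[b])
  }, logical(1))
  names(hits) <- sprintf("band_%g", disc$center)
  info <- radiomics_feature_info()
  adc_fo <- info$id[info$modality == "ADC" & info$group == "first_order"]
  b2000_glcm <- info$id[info$modality == "b2000" & info$group == "glcm"]
  img <- c(adc_intensity = any(feats %in% adc_fo),
           b2000_texture = any(feats %in% b2000_glcm))
  rec <- c(hits, img)
  list(n_planted = length(rec), n_recovered = sum(rec), recovered = rec)
}
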