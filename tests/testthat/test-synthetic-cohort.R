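test_that("configuration validation rejects malformed inputs", {
  expect_error(synthetic_config(fp_axis = 1:100), "1801")
  expect_error(synthetic_config(hw_axis = seq(3450, 2050, length.out = 2801)),
               "increasing|2801")
  expect_error(synthetic_config(class_mix = c(0.5, 0.2, 0.1, 0.1, 0.2)),
               "sum to 1")
  expect_error(synthetic_config(cosmic_ray_rate = 1.5), "rates")
  expect_error(synthetic_config(lesion_contrast = -0.1), "lesion_contrast")
})

test_that("identical seeds give bitwise-identical cohorts", {
  a <- generate_cohort(tiny_config(seed = 5))
  b <- generate_cohort(tiny_config(seed = 5))
  expect_identical(a$sites, b$sites)
  expect_identical(a$raman, b$raman)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$transforms, b$transforms)
  c <- generate_cohort(tiny_config(seed = 6))
  expect_false(identical(a$sites, c$sites))
})

test_that("acquisition sets follow the configured replicate and noise model", {
  cfg <- tiny_config()
  # zero noise, zero cosmic rays: replicates identical and equal to truth
  cfg0 <- tiny_config(noise_sd = 0, cosmic_ray_rate = 0)
  acq <- simulate_acquisition_set(FALSE, "FP", cfg0, stream = 11)
  expect_true(all(acq$replicates == rep(attr(acq, "truth"),
                                        each = nrow(acq$replicates))))
  expect_true(nrow(acq$replicates) >= 8 && nrow(acq$replicates) <= 12)
  expect_length(acq$pixel_axis, 1801)

  # rate 1: every replicate carries a spike well above the noise floor
  cfg1 <- tiny_config(cosmic_ray_rate = 1)
  acq1 <- simulate_acquisition_set(TRUE, "FP", cfg1, stream = 3)
  excess <- acq1$replicates - rep(attr(acq1, "truth"),
                                  each = nrow(acq1$replicates))
  expect_true(all(apply(excess, 1, max) >= 5 * cfg1$noise_sd))
})

test_that("volumes carry the acquisition geometry and cover every site", {
  coh <- generate_cohort(tiny_config(seed = 2))
  vols <- coh$volumes[[1]]
  expect_equal(vols$T2$spacing, c(1, 1, 1))
  expect_equal(vols$ADC$spacing, c(1.8, 1.8, 4))
  expect_equal(vols$b2000$spacing, c(2.6, 2.6, 5))
  # every site maps inside all three volumes: the full radiomics table exists
  ft <- radiomics_cohort(coh)
  expect_equal(nrow(ft$X), nrow(coh$sites))
  expect_true(all(is.finite(ft$X)))
})

test_that("realized class counts follow the requested mix to within rounding", {
  for (s in 1:5) {
    coh <- generate_cohort(tiny_config(seed = s))
    n <- nrow(coh$sites)
    got <- c(sum(coh$sites$isup_gg == 0), sum(coh$sites$isup_gg == 1),
             sum(coh$sites$isup_gg == 2), sum(coh$sites$isup_gg == 3),
             sum(coh$sites$isup_gg == 4))
    want <- tiny_config()$class_mix * n
    expect_true(all(abs(got - want) <= 1))
  }
})

test_that("a benign-dominant band makes the mean benign spectrum higher there", {
  # single discriminative band at 1007 with benign amplitude above tumor
  bands <- data.frame(center = c(1007, 1445), width = c(4, 12),
                      amp_benign = c(1.5, 1.5), amp_tumor = c(0.5, 1.5))
  cfg <- tiny_config(seed = 3, peak_bands = bands, n_patients = 8)
  coh <- generate_cohort(cfg)
  fp <- preprocess_cohort(coh)$FP
  at <- which.min(abs(cfg$fp_axis - 1007))
  tumor <- coh$sites$isup_gg > 0
  expect_gt(mean(fp$X[!tumor, at]), mean(fp$X[tumor, at]))
})

test_that("with all class effects disabled the classes are indistinguishable", {
  # equal band amplitudes and zero lesion contrast: a two-sample KS test on a
  # peak spectral feature and an ADC feature should fail to reject the null
  # in nearly all seeded repeats (alpha = 0.01)
  bands <- default_peak_bands()
  bands$amp_tumor <- bands$amp_benign
  reject <- replicate(40, NA)
  for (s in seq_len(40)) {
    cfg <- tiny_config(seed = 100 + s, peak_bands = bands,
                       lesion_contrast = 0, n_patients = 5,
                       n_replicates_range = c(5, 6))
    coh <- generate_cohort(cfg)
    tumor <- coh$sites$isup_gg > 0
    if (sum(tumor) < 2 || sum(!tumor) < 2) next
    fp <- preprocess_cohort(coh)$FP
    at <- which.min(abs(cfg$fp_axis - 1007))
    rad <- radiomics_cohort(coh)
    p1 <- suppressWarnings(ks.test(fp$X[tumor, at], fp$X[!tumor, at])$p.value)
    p2 <- suppressWarnings(ks.test(rad$X[tumor, "r20"],
                                   rad$X[!tumor, "r20"])$p.value)
    reject[s] <- (p1 < 0.01) || (p2 < 0.01)
  }
  expect_gte(mean(!reject, na.rm = TRUE), 0.9)
})

test_that("zero lesion contrast leaves ADC flat across the lesion boundary", {
  diffs <- vapply(1:30, function(s) {
    cfg <- tiny_config(seed = 200 + s, lesion_contrast = 0)
    lesion <- list(center = c(23.5, 23.5, 23.5), radius = 10)
    vols <- simulate_mri_triplet(lesion, cfg, stream = 300 + s)
    adc <- vols$ADC
    dims <- dim(adc$data)
    pos <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * adc$spacing[a])
    d2 <- outer(outer((pos[[1]] - 23.5)^2, (pos[[2]] - 23.5)^2, "+"),
                (pos[[3]] - 23.5)^2, "+")
    mean(adc$data[d2 <= 100]) - mean(adc$data[d2 > 100])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})

test_that("larger band contrast raises fingerprint-only cross-validated AUC", {
  # three gap levels, a few seeds each; mean AUC must increase monotonically
  gaps <- c(0, 0.5, 1)
  mean_auc <- vapply(gaps, function(g) {
    aucs <- vapply(1:5, function(s) {
      bands <- default_peak_bands()
      bands$amp_tumor <- bands$amp_benign -
        g * (bands$amp_benign - bands$amp_tumor)
      cfg <- tiny_config(seed = 400 + s, peak_bands = bands, n_patients = 8,
                         sites_per_patient_range = c(2, 4),
                         sites_per_patient_weights = c(0.4, 0.3, 0.3))
      coh <- generate_cohort(cfg)
      labs <- assign_labels(coh$sites, "gg_gt1")
      fp <- preprocess_cohort(coh)$FP
      cv <- lopocv(fp, labs, max_nf = 5)
      roc_summary(cv$scores, labs)$auc
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) > 0))
})
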