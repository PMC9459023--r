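test_that("replicate averaging is the arithmetic mean", {
  acq <- raman_acquisition_set(rbind(c(1, 2), c(3, 4)), "FP", c(1, 2))
  expect_equal(average_replicates(acq), c(2, 3))
  one <- raman_acquisition_set(matrix(c(5, 6, 7), 1), "FP", 1:3)
  expect_equal(average_replicates(one), c(5, 6, 7))
})

test_that("averaging n i.i.d. noise replicates shrinks the SD like 1/sqrt(n)", {
  # sample SD of the mean over 200 seeds vs sigma/sqrt(50), within 30%
  sigma <- 2
  means <- withr::with_seed(99, replicate(200, {
    acq <- raman_acquisition_set(matrix(rnorm(50 * 4, 0, sigma), 50), "FP", 1:4)
    average_replicates(acq)[1]
  }))
  expect_lt(abs(sd(means) - sigma / sqrt(50)) / (sigma / sqrt(50)), 0.3)
})

test_that("cross-replicate spike removal repairs spikes and leaves clean data alone", {
  clean <- toy_acquisition(n_rep = 50)
  expect_equal(remove_cosmic_rays(clean)$replicates, clean$replicates)

  spiked <- clean
  spiked$replicates[7, 100] <- spiked$replicates[7, 100] + 1000
  fixed <- remove_cosmic_rays(spiked, z_thresh = 5)
  expect_lt(max(abs(average_replicates(fixed) - average_replicates(clean))),
            1e-6)

  # identical stack passes through untouched despite zero MAD
  same <- raman_acquisition_set(matrix(1, 5, 10), "FP", 1:10)
  expect_equal(remove_cosmic_rays(same)$replicates, same$replicates)
})

test_that("single-replicate spike removal falls back with a warning", {
  acq <- toy_acquisition(n_rep = 1)
  acq$replicates[1, 50] <- acq$replicates[1, 50] + 500
  expect_warning(out <- remove_cosmic_rays(acq), "fewer than 3")
  expect_lt(abs(out$replicates[1, 50] - toy_acquisition(n_rep = 1)$replicates[1, 50]), 1)
})

test_that("iterative polynomial baseline removal recovers a pure polynomial", {
  u <- seq(0, 1, length.out = 500)
  poly_only <- 100 * (1 + 2 * u - 3 * u^2 + u^5)
  out <- subtract_autofluorescence(poly_only, poly_order = 5)
  expect_lt(max(abs(out)), 1e-6 * max(abs(poly_only)))
  expect_true(attr(out, "converged"))
  # zero in, zero out
  expect_lt(max(abs(subtract_autofluorescence(rep(0, 100)))), 1e-12)
})

test_that("baseline removal preserves an injected peak within 5%", {
  u <- seq(0, 1, length.out = 1000)
  baseline <- 200 * (1 + u - 0.5 * u^2)
  peak <- 5 * exp(-(u - 0.5)^2 / (2 * 0.01^2))
  out <- subtract_autofluorescence(baseline + peak, poly_order = 5)
  expect_lt(abs(max(out) - 5) / 5, 0.05)
})

test_that("SNV normalization matches its definition and invariances", {
  expect_equal(snv_normalize(c(1, 2, 3)), c(-1, 0, 1))
  x <- withr::with_seed(1, rnorm(500, 10, 3))
  z <- snv_normalize(x)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sd(z) - 1), 1e-9)
  # affine invariance and idempotence
  expect_equal(snv_normalize(3.7 * x + 11), z, tolerance = 1e-12)
  expect_equal(snv_normalize(z), z, tolerance = 1e-9)
  expect_error(snv_normalize(rep(2, 10)), "degenerate")
})

test_that("shift-axis assignment applies a monotone calibration", {
  expect_equal(assign_shift_axis(1:5), 1:5)
  out <- assign_shift_axis(1:1801, function(p) 0.5 * p + 400)
  expect_length(out, 1801)
  expect_true(all(diff(out) > 0))
  expect_error(assign_shift_axis(1:10, function(p) -p), "monotone")
})

test_that("the preprocessing chain yields a valid normalized spectrum", {
  acq <- toy_acquisition(n_rep = 20, noise_sd = 0.05)
  ps <- preprocess_site(acq)
  expect_s3_class(ps, "processed_spectrum")
  expect_length(ps$intensity, 200)
  expect_lt(abs(mean(ps$intensity)), 1e-9)
  expect_lt(abs(sd(ps$intensity) - 1), 1e-9)
  expect_true(all(diff(ps$shift) > 0))
  # determinism: identical replicates give identical outputs
  expect_identical(preprocess_site(acq)$intensity, ps$intensity)
})

test_that("a spike-laden site preprocesses to the spike-free result", {
  clean <- toy_acquisition(n_rep = 50)
  spiked <- clean
  for (r in c(3, 9, 21)) {
    spiked$replicates[r, 40 + 5 * r] <-
      spiked$replicates[r, 40 + 5 * r] + 800
  }
  out_clean <- preprocess_site(clean)
  out_spiked <- preprocess_site(spiked)
  expect_lt(max(abs(out_clean$intensity - out_spiked$intensity)), 1e-3)
})

test_that("swapping spike removal and averaging is immaterial on clean data", {
  # bounded (uniform) noise keeps every robust z-score far below threshold,
  # so neither detection order flags anything and the outputs coincide
  acq <- toy_acquisition(n_rep = 50, peak_width = 30)
  acq$replicates <- acq$replicates +
    withr::with_seed(7, matrix(runif(50 * 200, -0.05, 0.05), 50))
  a <- preprocess_site(acq, order = "spikes_first")
  b <- preprocess_site(acq, order = "average_first")
  expect_lt(max(abs(a$intensity - b$intensity)), 1e-9)
})
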