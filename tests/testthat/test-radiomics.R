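make_volume <- function(dims = c(12, 12, 12), spacing = c(1, 1, 1),
                        origin = c(0, 0, 0), seed = 1, modality = "T2") {
  withr::with_seed(seed,
    mri_volume(array(rnorm(prod(dims), 100, 20), dims), spacing, origin,
               modality))
}

test_that("TRUS-to-MRI mapping inverts the registration transform", {
  p <- c(10, -4, 7)
  expect_equal(map_trus_to_mri(p, diag(4)), p)
  tr <- diag(4); tr[1:3, 4] <- c(5, -2, 1)
  expect_equal(map_trus_to_mri(p, tr), p - c(5, -2, 1))
  A <- withr::with_seed(3, {
    A <- diag(4)
    A[1:3, 1:3] <- matrix(rnorm(9), 3) + 3 * diag(3)
    A[1:3, 4] <- rnorm(3)
    A
  })
  q <- drop(A %*% c(p, 1))[1:3]
  expect_equal(map_trus_to_mri(q, A), p, tolerance = 1e-9)
  expect_error(map_trus_to_mri(p, matrix(0, 4, 4)), "singular")
})

test_that("spherical ROI voxel counts match brute-force lattice enumeration", {
  # unit spacing, radius 5, centered on a voxel: lattice points with
  # x^2+y^2+z^2 <= 25
  brute <- sum(outer(outer((-5:5)^2, (-5:5)^2, "+"), (-5:5)^2, "+") <= 25)
  expect_equal(brute, 515L)
  vol <- make_volume(c(15, 15, 15))
  roi <- spherical_roi(vol, c(7, 7, 7), 5)
  expect_equal(nrow(roi$indices), 515L)
  expect_equal(roi$voxel_volume_mm3, 1)

  # anisotropic ADC-like grid
  vol2 <- make_volume(c(15, 15, 7), spacing = c(1.8, 1.8, 4), modality = "ADC")
  center <- c(7 * 1.8, 7 * 1.8, 3 * 4)
  roi2 <- spherical_roi(vol2, center, 5)
  grid <- expand.grid(i = 0:14, j = 0:14, k = 0:6)
  d2 <- (grid$i * 1.8 - center[1])^2 + (grid$j * 1.8 - center[2])^2 +
    (grid$k * 4 - center[3])^2
  expect_equal(nrow(roi2$indices), sum(d2 <= 25))
  expect_equal(roi2$voxel_volume_mm3, 1.8 * 1.8 * 4)

  # tiny radius keeps exactly the central voxel
  expect_equal(nrow(spherical_roi(vol, c(7, 7, 7), 0.4)$indices), 1L)
  expect_error(spherical_roi(vol, c(200, 7, 7), 5), "extent")
})

test_that("discretization is min-anchored with contiguous levels", {
  expect_equal(discretize(rep(7, 5), 25)$levels, rep(1L, 5))
  expect_equal(discretize(rep(7, 5), 25)$n_levels, 1L)
  expect_equal(discretize(c(0, 25, 50), 25)$levels, c(1L, 2L, 3L))
  x <- withr::with_seed(2, runif(50, 0, 200))
  expect_equal(discretize(x + 1234, 25)$levels, discretize(x, 25)$levels)
})

test_that("first-order features match hand arithmetic and degenerate cases", {
  roi <- list(intensities = c(1, 2, 2, 3), voxel_volume_mm3 = 2)
  f <- first_order_features(roi, bin_width = 1)
  expect_equal(unname(f["Energy"]), 18)
  expect_equal(unname(f["TotalEnergy"]), 36)
  expect_equal(unname(f["Mean"]), 2)
  expect_equal(unname(f["Median"]), 2)
  expect_equal(unname(f["MeanAbsoluteDeviation"]), 0.5)

  cst <- list(intensities = rep(4, 10), voxel_volume_mm3 = 1)
  fc <- first_order_features(cst)
  expect_equal(unname(fc[c("Entropy", "Uniformity", "StandardDeviation",
                           "MeanAbsoluteDeviation")]), c(0, 1, 0, 0))

  two <- list(intensities = c(0, 0, 25, 25), voxel_volume_mm3 = 1)
  ft <- first_order_features(two, bin_width = 25)
  expect_equal(unname(ft["Entropy"]), 1)
  expect_equal(unname(ft["Uniformity"]), 0.5)
})

test_that("GLCM matrices match hand counts and the brute-force oracle", {
  # 1-D strip 1,2,1,2 along x
  strip <- array(NA_integer_, c(4, 1, 1))
  strip[, 1, 1] <- c(1L, 2L, 1L, 2L)
  P <- glcm_matrix(strip, 2, directions = rbind(c(1, 0, 0)))
  expect_equal(P[[1]], matrix(c(0, 0.5, 0.5, 0), 2))
  f <- glcm_features(P)
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["JointEnergy"]), 0.5)
  expect_equal(unname(f["JointEntropy"]), 1)

  # constant 2x2x1 block: all mass at (1,1) in every direction
  cst <- array(1L, c(2, 2, 1))
  for (Pd in glcm_matrix(cst, 1)) expect_equal(sum(Pd), 1)
  fc <- glcm_features(glcm_matrix(cst, 1))
  expect_equal(unname(fc[c("Contrast", "JointEnergy", "JointEntropy",
                           "ClusterShade", "Id")]), c(0, 1, 0, 0, 1))

  # random grids against the double-loop oracle, all 13 directions
  dirs <- glcm_directions()
  for (seed in 1:5) {
    arr <- withr::with_seed(seed, {
      a <- array(sample.int(4, 64, replace = TRUE), c(4, 4, 4))
      a[sample(64, 10)] <- NA  # irregular mask
      a
    })
    got <- glcm_matrix(arr, 4)
    expected <- Filter(Negate(is.null),
                       lapply(seq_len(nrow(dirs)),
                              function(d) brute_glcm(arr, 4, dirs[d, ])))
    expect_equal(length(got), length(expected))
    for (d in seq_along(got)) {
      expect_equal(got[[d]], expected[[d]], tolerance = 1e-12)
      expect_equal(sum(got[[d]]), 1, tolerance = 1e-12)
      expect_equal(glcm_features(got[d]), brute_glcm_features(expected[[d]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("the 48-entry radiomics vector follows the identifier layout", {
  info <- radiomics_feature_info()
  expect_equal(nrow(info), 48L)
  expect_equal(info$id, paste0("r", 1:48))
  expect_equal(info$name[info$id == "r17"], "Energy")
  expect_equal(info$modality[info$id == "r17"], "ADC")
  expect_equal(info$name[info$id == "r46"], "DifferenceEntropy")
  expect_equal(info$modality[info$id == "r46"], "b2000")

  vols <- list(T2 = make_volume(c(20, 20, 20), seed = 1),
               ADC = make_volume(c(12, 12, 6), c(1.8, 1.8, 4), seed = 2,
                                 modality = "ADC"),
               b2000 = make_volume(c(9, 9, 5), c(2.6, 2.6, 5), seed = 3,
                                   modality = "b2000"))
  pt <- c(10, 10, 10)
  rv <- radiomics_vector(pt, vols, diag(4))
  expect_length(rv, 48L)
  expect_named(rv, paste0("r", 1:48))
  expect_true(all(is.finite(rv)))

  # r17 equals first-order Energy on the ADC ROI alone; r46 equals GLCM
  # difference entropy on the b2000 ROI alone
  adc_roi <- spherical_roi(vols$ADC, pt, 5)
  expect_equal(unname(rv["r17"]),
               unname(first_order_features(adc_roi)["Energy"]))
  expect_equal(unname(rv["r1"]),
               unname(first_order_features(spherical_roi(vols$T2, pt, 5))["Energy"]))

  # geometry invariance: shifting origins and the site together
  shift <- c(13, -8, 21)
  vols2 <- lapply(vols, function(v) {
    mri_volume(v$data, v$spacing, v$origin + shift, v$modality)
  })
  rv2 <- radiomics_vector(pt + shift, vols2, diag(4))
  expect_equal(rv2, rv, tolerance = 1e-12)

  # failure names the offending modality
  expect_error(radiomics_vector(c(60, 10, 10), vols, diag(4)), "ADC|T2|b2000")
})
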