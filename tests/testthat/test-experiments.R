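test_that("label assignment reproduces the pilot cohort's task bookkeeping", {
  h <- reference_histology()
  gt1 <- assign_labels(h, "gg_gt1")
  expect_equal(sum(gt1 == 1), 21L)
  expect_equal(sum(gt1 == -1), 26L)
  ge1 <- assign_labels(h, "gg_ge1")
  expect_equal(sum(ge1 == 1), 24L)
  expect_equal(sum(ge1 == -1), 23L)
  hg <- assign_labels(h, "high_grade")
  expect_equal(sum(!is.na(hg)), 41L)
  expect_equal(sum(hg == 1, na.rm = TRUE), 18L)
  expect_equal(sum(hg == -1, na.rm = TRUE), 23L)
  # benign sites are always retained; schemes other than high_grade cover all
  expect_false(anyNA(gt1))
  expect_false(anyNA(ge1))
  expect_true(all(hg[h$isup_gg == 0] == -1))
  # a tumor site without HG% is an error under high_grade only
  h2 <- h
  h2$hg_percent[h2$isup_gg == 2][1] <- NA
  expect_error(assign_labels(h2, "high_grade"), "missing high-grade")
  expect_silent(assign_labels(h2, "gg_gt1"))
})

test_that("ROC summary handles perfect, inverted and random scores", {
  r <- roc_summary(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1))
  expect_equal(r$auc, 1)
  expect_equal(c(r$optimal_fpr, r$optimal_tpr), c(0, 1))
  expect_equal(c(r$accuracy, r$sensitivity, r$specificity), c(1, 1, 1))

  expect_equal(roc_summary(c(0.4, 0.6), c(1, -1))$auc, 0)
  expect_error(roc_summary(c(0.5, 0.6), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random instances", {
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, {
      scores <- round(runif(20), 2)  # rounding forces ties
      labels <- sample(c(-1, 1), 20, replace = TRUE, prob = c(0.5, 0.5))
      if (length(unique(labels)) < 2) labels[1:2] <- c(-1, 1)
      list(scores = scores, labels = labels)
    })
    expect_equal(roc_summary(dat$scores, dat$labels)$auc,
                 brute_auc(dat$scores, dat$labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  dat <- withr::with_seed(33, list(s = runif(60),
                                   y = rep(c(-1, 1), 30)))
  ours <- roc_summary(dat$s, dat$y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(dat$y, dat$s, levels = c(-1, 1),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("ROC curve is monotone and the optimal point lies on it", {
  dat <- withr::with_seed(14, list(s = runif(40), y = rep(c(-1, 1), 20)))
  r <- roc_summary(dat$s, dat$y)
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  i <- which(r$thresholds == r$optimal_threshold)
  expect_equal(c(r$fpr[i], r$tpr[i]), c(r$optimal_fpr, r$optimal_tpr))
})

test_that("consensus counting uses a strict threshold", {
  sels <- c(rep(list(c("a", "b")), 10), rep(list(c("b")), 8))
  cons <- consensus_features(sels, min_count = 10)
  expect_false("a" %in% cons$feature)  # exactly 10 is excluded
  expect_true("b" %in% cons$feature)
  expect_equal(cons$count[cons$feature == "b"], 18L)
})

test_that("the combination experiment reports one capped row per feature set", {
  fix <- toy_feature_table(n_pat = 8, k_info = 4, k_noise = 8, effect = 2.5,
                           modality = c(rep("FP", 2), rep("HW", 2),
                                        rep("Rad", 8)))
  res <- feature_combination_experiment(fix$ft, fix$labels, max_nf = 4)
  expect_equal(nrow(res$report), 7L)
  expect_setequal(res$report$features,
                  c("FP", "HW", "Rad", "FP+HW", "FP+Rad", "FP+HW+Rad",
                    "HW+Rad"))
  expect_true(all(res$report$mean_n_features <= 4))
  expect_true(all(res$report$auc >= 0 & res$report$auc <= 1))
  expect_error(subset_combo(fix$ft, "PET"), "unknown")
})

test_that("the cap sweep covers its grid with realized counts under the cap", {
  fix <- toy_feature_table(n_pat = 8, k_info = 3, k_noise = 10, effect = 2.5)
  sw <- max_nf_sweep(fix$ft, fix$labels, combo = "FP", max_nf_values = 2:6)
  expect_equal(nrow(sw$curve), 5L)
  expect_true(all(sw$curve$mean_n_features <= sw$curve$max_nf))
  expect_equal(length(sw$selections), 5L)
  # full study grid has 17 points
  expect_length(2:18, 17L)
})

test_that("prediction tasks relabel, exclude, and bypass selection", {
  h <- reference_histology()
  ft <- withr::with_seed(40, {
    n <- nrow(h)
    gg1 <- assign_labels(h, "gg_ge1")
    X <- matrix(rnorm(n * 6), n)
    X[, 1:2] <- X[, 1:2] + 2.5 * (gg1 == 1)
    colnames(X) <- paste0("f", 1:6)
    feature_table(X, rep("FP", 6), h$site_id, h$patient_id)
  })
  res <- prediction_task_experiment(ft, h, features = c("f1", "f2"))
  expect_equal(res$report$scheme, c("gg_gt1", "gg_ge1", "high_grade"))
  expect_equal(res$report$n_sites, c(47L, 47L, 41L))
  expect_equal(res$report$n_pos, c(21L, 24L, 18L))
  expect_equal(res$report$n_neg, c(26L, 23L, 23L))
  # high_grade drops exactly 6 sites relative to gg_ge1
  expect_equal(res$report$n_sites[2] - res$report$n_sites[3], 6L)
  for (cv in res$cv) {
    for (sel in cv$fold_selections) expect_identical(sel, c("f1", "f2"))
  }
})
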