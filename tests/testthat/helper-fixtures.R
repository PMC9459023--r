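# Shared fixture builders. All fixtures are generated in code at test time.

# A scaled-down cohort configuration for fast end-to-end tests: fewer
# patients and replicates than the study-scale defaults, same structure.
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_patients = 6,
         sites_per_patient_range = c(2, 3),
         sites_per_patient_weights = c(0.6, 0.4),
         n_replicates_range = c(8, 12),
         seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

# Deterministic acquisition set: smooth baseline + one Gaussian peak.
toy_acquisition <- function(n_rep = 5, n = 200, noise_sd = 0, seed = 42,
                            peak_width = 15) {
  axis <- seq(800, 1200, length.out = n)
  truth <- 50 + 0.02 * (axis - 800) +
    2 * exp(-(axis - 1000)^2 / (2 * peak_width^2))
  reps <- matrix(rep(truth, each = n_rep), nrow = n_rep)
  if (noise_sd > 0) {
    reps <- reps + withr::with_seed(seed,
      matrix(stats::rnorm(n_rep * n, 0, noise_sd), nrow = n_rep))
  }
  raman_acquisition_set(reps, "FP", axis)
}

# Small labeled feature table: n_pat patients x 2 sites, k_info informative
# columns (class-shifted), k_noise pure-noise columns, with modality tags.
toy_feature_table <- function(n_pat = 8, k_info = 3, k_noise = 12,
                              effect = 3, seed = 1,
                              modality = NULL) {
  withr::with_seed(seed, {
    n <- n_pat * 2
    patient <- rep(sprintf("P%02d", seq_len(n_pat)), each = 2)
    site <- sprintf("S%03d", seq_len(n))
    y <- rep(c(-1, 1), n_pat)
    X <- matrix(stats::rnorm(n * (k_info + k_noise)), n)
    X[, seq_len(k_info)] <- X[, seq_len(k_info)] + effect * (y == 1)
    colnames(X) <- sprintf("f%02d", seq_len(ncol(X)))
    if (is.null(modality)) modality <- rep("FP", ncol(X))
    list(ft = feature_table(X, modality, site, patient), labels = y)
  })
}

# Brute-force GLCM of a masked 3-D level array: literal double loop over all
# voxel pairs for one offset. Independent oracle for glcm_matrix().
brute_glcm <- function(levels_arr, n_levels, off) {
  dims <- dim(levels_arr)
  P <- matrix(0, n_levels, n_levels)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      i2 <- i + off[1]; j2 <- j + off[2]; k2 <- k + off[3]
      if (i2 < 1 || i2 > dims[1] || j2 < 1 || j2 > dims[2] ||
          k2 < 1 || k2 > dims[3]) next
      a <- levels_arr[i, j, k]; b <- levels_arr[i2, j2, k2]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
    }
  }
  P <- P + t(P)
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

# Literal-formula GLCM features of one normalized matrix; independent of the
# package implementation.
brute_glcm_features <- function(P) {
  L <- nrow(P)
  s <- 0; ac <- 0; con <- 0; id <- 0; je <- 0; jen <- 0
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mu_i <- sum(seq_len(L) * pi_m); mu_j <- sum(seq_len(L) * pj_m)
  sd_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_m))
  sd_j <- sqrt(sum((seq_len(L) - mu_j)^2 * pj_m))
  cs <- 0; cross <- 0
  pd <- numeric(L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    p <- P[i, j]
    ac <- ac + i * j * p
    cs <- cs + (i + j - mu_i - mu_j)^3 * p
    con <- con + (i - j)^2 * p
    cross <- cross + i * j * p
    id <- id + p / (1 + abs(i - j))
    if (p > 0) jen <- jen - p * log2(p)
    je <- je + p^2
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p
  }
  de <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  corr <- if (sd_i * sd_j == 0) 1 else (cross - mu_i * mu_j) / (sd_i * sd_j)
  c(Autocorrelation = ac, ClusterShade = cs, Contrast = con,
    Correlation = corr, Id = id, DifferenceEntropy = de,
    JointEntropy = jen, JointEnergy = je)
}

# Pairwise-concordance AUC (Mann-Whitney, ties counted half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == -1]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Weighted-hinge SVM objective for a linear model.
svm_objective <- function(w, b, X, y, wts, C_reg = 1) {
  margins <- y * (X %*% w + b)
  0.5 * sum(w^2) + C_reg * sum(wts * pmax(0, 1 - margins))
}
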