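#' Map a Gleason pattern pair to its ISUP grade group
#'
#' Benign tissue (both patterns 0) maps to grade group 0. Tumor patterns
#' follow the ISUP convention: 3+3 -> 1, 3+4 -> 2, 4+3 -> 3, Gleason sum 8
#' -> 4, sums 9-10 -> 5.
#'
#' @param primary,secondary Gleason patterns; 0 (benign) or 3-5. Vectorized.
#' @return Integer grade group(s) in 0-5.
#' @export
isup_grade_group <- function(primary, secondary) {
  stopifnot(length(primary) == length(secondary))
  ok <- (primary == 0 & secondary == 0) |
    (primary %in% 3:5 & secondary %in% 3:5)
  if (any(!ok)) {
    stop("invalid Gleason pattern pair: patterns must both be 0 (benign) or both in 3-5")
  }
  total <- primary + secondary
  gg <- integer(length(primary))
  tumor <- primary > 0
  gg[tumor & total <= 6] <- 1L
  gg[tumor & total == 7 & primary == 3] <- 2L
  gg[tumor & total == 7 & primary == 4] <- 3L
  gg[tumor & total == 8] <- 4L
  gg[tumor & total >= 9] <- 5L
  gg
}

#' Validate a histology table
#'
#' Checks the per-site ground-truth table: Gleason pair vs ISUP grade-group
#' consistency, high-grade percentage in range, and that benign sites carry
#' no high-grade percentage.
#'
#' @param histology data.frame with columns `patient_id`, `site_id`,
#'   `gs_primary`, `gs_secondary`, `isup_gg`, `hg_percent` (NA for benign).
#' @return The table, invisibly, if valid; otherwise an error naming the row.
#' @export
validate_histology <- function(histology) {
  required <- c("patient_id", "site_id", "gs_primary", "gs_secondary",
                "isup_gg", "hg_percent")
  missing <- setdiff(required, names(histology))
  if (length(missing) > 0) {
    stop("histology table is missing column(s): ", paste(missing, collapse = ", "))
  }
  expected <- isup_grade_group(histology$gs_primary, histology$gs_secondary)
  bad <- which(expected != histology$isup_gg)
  if (length(bad) > 0) {
    stop(sprintf(
      "row %d: ISUP grade group %d inconsistent with Gleason %d+%d (expected %d)",
      bad[1], histology$isup_gg[bad[1]], histology$gs_primary[bad[1]],
      histology$gs_secondary[bad[1]], expected[bad[1]]))
  }
  hg <- histology$hg_percent
  bad_hg <- which(!is.na(hg) & (hg < 0 | hg > 100))
  if (length(bad_hg) > 0) {
    stop(sprintf("row %d: hg_percent %g outside [0, 100]", bad_hg[1], hg[bad_hg[1]]))
  }
  invisible(histology)
}

#' Bundled reference histology distribution
#'
#' The site-level ground-truth distribution of the 18-patient pilot cohort
#' this pipeline is designed around: 47 inspected sites — 23 benign, 3 grade
#' group 1 (Gleason 3+3), 10 grade group 2 (3+4), 8 grade group 3 (4+3) and
#' 3 grade group 4 (4+4) — with all three GG1 sites and three of the ten GG2
#' sites below 20% high-grade pattern. Patients hold between 2 and 5 sites
#' (median 2). Useful as the fixed input for label-assignment bookkeeping and
#' as the default class structure of the synthetic cohort.
#'
#' @return A validated histology data.frame with 47 rows.
#' @export
reference_histology <- function() {
  sites_per_patient <- c(rep(2L, 11), rep(3L, 4), 4L, 4L, 5L)
  stopifnot(sum(sites_per_patient) == 47L)
  # class code per site: 0 benign, 1..4 = GG1..GG4; interleaved across patients
  classes <- c(0L, 1L, 0L, 2L, 0L, 3L, 0L, 2L, 0L, 4L, 0L, 2L, 0L, 3L, 0L, 2L,
               0L, 1L, 0L, 3L, 0L, 2L, 0L, 2L, 3L, 0L, 2L, 4L, 0L, 3L, 2L, 0L,
               3L, 1L, 0L, 2L, 3L, 0L, 0L, 4L, 2L, 0L, 0L, 3L, 0L, 0L, 0L)
  stopifnot(length(classes) == 47L,
            sum(classes == 0L) == 23L, sum(classes == 1L) == 3L,
            sum(classes == 2L) == 10L, sum(classes == 3L) == 8L,
            sum(classes == 4L) == 3L)
  gs_pairs <- list(`0` = c(0L, 0L), `1` = c(3L, 3L), `2` = c(3L, 4L),
                   `3` = c(4L, 3L), `4` = c(4L, 4L))
  # HG%: GG1 below 20 by construction; first 3 of the 10 GG2 sites below 20.
  hg_by_class <- list(`0` = NA_real_, `1` = 10, `3` = 70, `4` = 90)
  gg2_hg <- c(10, 12, 15, rep(40, 7))
  patient_id <- rep(sprintf("P%02d", seq_along(sites_per_patient)),
                    times = sites_per_patient)
  gg2_seen <- 0L
  rows <- lapply(seq_along(classes), function(i) {
    cl <- classes[i]
    pair <- gs_pairs[[as.character(cl)]]
    hg <- if (cl == 2L) {
      gg2_seen <<- gg2_seen + 1L
      gg2_hg[gg2_seen]
    } else {
      hg_by_class[[as.character(cl)]]
    }
    data.frame(gs_primary = pair[1], gs_secondary = pair[2],
               isup_gg = isup_grade_group(pair[1], pair[2]),
               hg_percent = hg)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(patient_id = patient_id,
                          site_id = sprintf("S%02d", seq_len(47L)),
                          stringsAsFactors = FALSE),
               out)
  validate_histology(out)
  out
}
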