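---
title: "Multimodal Raman + mpMRI-radiomics classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal Raman + mpMRI-radiomics classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

During transperineal prostate interventions (biopsy, HDR brachytherapy), a
fibre-optic Raman probe can interrogate tissue *in situ* at pre-identified
sites, while preoperative multiparametric MRI (T2-weighted, ADC, b2000)
carries complementary macroscopic information about the same locations.
This package implements the full analysis chain that turns those two data
streams into a per-site classifier of clinically significant prostate
cancer:

1. **Raman preprocessing** — replicate raw spectra at each site are reduced
   to one normalized spectrum per spectral region (fingerprint, FP, 1801
   samples; high wavenumber, HW, 2801 samples).
2. **Radiomics extraction** — each site's intraoperative (TRUS-frame)
   coordinate is mapped into the MRI frame through the inverse registration
   transform, and 8 first-order + 8 grey-level co-occurrence (GLCM)
   features are computed per sequence in a 5-mm spherical ROI
   (48 features, identifiers r1–r48).
3. **Per-fold feature selection** — a variance filter, a
   correlation-with-label filter and a capped lasso, applied inside each
   cross-validation training set only.
4. **Cost-sensitive linear SVM** with Platt-calibrated posteriors, under
   leave-one-patient-out cross-validation (LOPOCV), evaluated on the pooled
   held-out posteriors via ROC and the closest-to-(0,1)-corner operating
   point.

The clinical data of the motivating study are not public, so the package
ships a seeded synthetic-cohort generator whose statistical structure
mimics the study, and the three experiment drivers under `analysis/` run
the complete program on that cohort.

# Spectral preprocessing

Per site and region the chain is: cosmic-ray rejection → replicate
averaging → autofluorescence baseline removal → standard normal variate
(SNV) normalization → Raman-shift axis assignment.

**Cosmic-ray rejection.** Spikes are narrow, high-amplitude and replicate
specific, so detection across the replicate stack is far more powerful than
within a single spectrum: at each spectral sample, replicate values whose
robust z-score against the cross-replicate median (MAD scaled by 1.4826)
exceeds `z_thresh = 5` are replaced by that median. When the MAD is zero,
only values that deviate at all are replaced, so identical stacks pass
through bitwise-unchanged. A summary description of such pipelines often
lists averaging before artifact removal; both orders are provided
(`order = "average_first"` uses within-spectrum detection on the averaged
spectrum), and on spike-free data they agree to numerical precision.

**Baseline removal.** Tissue autofluorescence is a smooth background an
order of magnitude above the Raman peaks. It is estimated by iterative
modified polynomial fitting (order 5, tolerance 1e-6, at most 100
iterations): refit an ordinary least-squares polynomial to the elementwise
minimum of the signal and the current fit until the baseline stabilizes.
Peaks are progressively excluded while the smooth background is retained; a
pure polynomial input yields a numerically zero residual, and injected peak
heights are preserved to within a few percent.

**SNV.** Each spectrum is centered and scaled to unit sample standard
deviation (divisor n−1, fixed for reproducibility). SNV removes
multiplicative intensity differences between acquisitions; it also couples
features — a spectrum-wide loss of peak mass in one class re-scales every
other band — which is why the synthetic generator keeps most spectral
variance in class-neutral bands (see below).

# Radiomics

Volumes are axis-aligned grids with physical spacing and origin; world and
voxel coordinates are related by `world = origin + (index − 1) · spacing`.
The ROI is the set of voxels whose centers lie within 5 mm (Euclidean, in
mm, anisotropy respected) of the mapped site position; with 1-mm isotropic
spacing and a lattice-aligned center this is exactly 515 voxels.

First-order features are Energy, Total energy (Energy × voxel volume),
Entropy, Mean, Median, population SD, mean absolute deviation and
Uniformity. Entropy and Uniformity share one fixed-bin-width
discretization (`bin_width = 25` intensity units, min-anchored) with the
GLCM, giving a single consistent probabilistic base. GLCM matrices are
built at distance 1 over the 13 unique 3-D directions, symmetrized and
normalized per direction; the eight texture features (Autocorrelation,
Cluster shade, Contrast, Correlation, Inverse difference, Difference
entropy, Joint entropy, Joint energy) are averaged over directions — the
standard aggregation of the common extraction platforms. Correlation of a
single-level matrix is defined as 1. The identifier layout is fixed:
r1–r16 T2, r17–r32 ADC, r33–r48 b2000, first-order before GLCM within each
sequence (r17 = ADC Energy, r46 = b2000 Difference entropy).

The voxel-membership rule is center-in-sphere — the simplest unambiguous
rule. Published ROI voxel-count ranges for comparable acquisitions differ
slightly from what any single inclusion rule produces on an ideal grid, so
no attempt is made to reproduce exact voxel counts.

# Feature selection

Applied strictly per training partition, never on held-out patients:

* **Step i, variance:** keep features with sample variance > 0.03. The
  threshold is meaningful on the SNV scale; raw radiomics features live on
  wildly different native scales (ADC Energy ~1e7), so radiomics columns
  are standardized (training statistics) before this filter by default
  (`prestandardize_rad = FALSE` restores the literal raw-variance reading).
* **Step ii, correlation:** keep features with |Pearson r| against the
  ±1 label ≥ 0.10 (the discard rule is "< 10%", so the boundary is
  retained). Under the null at n = 47 this filter passes a feature about
  half the time — it trims silent features, it is not a test.
* **Step iii, capped lasso:** an L1-penalized linear model of the label on
  the standardized survivors over a 100-point geometric penalty path from
  the data-derived maximum. The selected set is the active set of the
  smallest penalty whose active-set size is ≤ `max_nf`; among penalties
  with that identical active set the most regularized is reported. The
  path solver is glmnet; the cap/active-set logic is this package's.

An empty lasso selection falls back to the top-`max_nf` step-ii survivors
by |r|, with a warning, so per-fold training stays well defined.

# Classifier

The SVM minimizes `½‖w‖² + C Σᵢ cᵢ hinge(yᵢ(w·xᵢ + b))` with a linear
kernel, where `cᵢ` is the misclassification cost of example i's true class.
The default cost matrix `[[0,1],[2,0]]` doubles the penalty of a false
negative (missed tumor), which shifts the boundary toward sensitivity —
realized as class-weighted hinge loss, the standard equivalence for 2×2
zero-diagonal cost matrices (solver: libsvm via e1071; deterministic).
`C = 1` by default with no inner tuning loop. Posteriors come from Platt
scaling fit on the training decision values with the conventional
regularized targets, so perfectly separated folds do not diverge.

LOPOCV holds out all sites of one patient per fold; selection,
standardization and calibration are re-estimated per fold on training rows
only. Held-out posteriors are pooled across folds and the ROC is computed
on the pool (matching an evaluation that plots one curve from all
validation posteriors); the operating point minimizes Euclidean distance
to (0,1), ties broken toward higher sensitivity, and accuracy at that
point is the plain unweighted proportion (the cost matrix affects training
only).

# Labeling schemes

From the per-site histology (Gleason pair, ISUP grade group, high-grade
percentage): `gg_gt1` labels GG > 1 positive; `gg_ge1` labels any tumor
positive; `high_grade` is `gg_ge1` with tumor sites under 20% high-grade
pattern excluded (benign sites always retained). On the bundled
47-site reference distribution (23 benign / 3 GG1 / 10 GG2 / 8 GG3 /
3 GG4, six tumor sites under 20% HG) these give 21/26, 24/23 and 41 sites
with 18 positives respectively.

# The synthetic cohort

The generator emulates the study conditions: 18 patients, 2–5 sites each
(weights favoring 2, matching a median of 2), class mix 23:3:10:8:3,
50–100 replicate spectra per site and region, FP/HW grids of 1801/2801
samples (FP 400–1800 cm⁻¹ so that all planted bands lie on the grid,
HW 2050–3450 cm⁻¹; endpoints configurable, counts fixed).

**Spectra.** Each site's noiseless spectrum is a 5th-order polynomial
autofluorescence baseline (amplitude 60, ~40× the peak scale, per-site
scale jitter ±30%) plus Gaussian bands. Five fingerprint bands — 994,
1007, 1334, 1766 and 1772 cm⁻¹, matching protein-, collagen/nucleic-acid-
and lipid-associated bands reported as more prominent in benign prostate —
carry class contrast (tumor amplitude ~60% of benign); seven fingerprint
and four high-wavenumber bands are class-neutral and deliberately carry
most of the spectral variance, so that SNV rescaling is nearly
class-independent and the planted contrast stays at the planted centers.
Band amplitudes get independent per-site log-normal jitter (SD 0.12);
replicates add white noise (SD 0.08) and cosmic-ray spikes (rate 0.1,
amplitude 30, 1–3 samples).

**Imaging.** T2 (1×1×1 mm), ADC (1.8×1.8×4 mm) and b2000 (2.6×2.6×5 mm)
volumes share a world frame with spatially correlated noise (Gaussian
kernels, correlation lengths 2/3/4 mm). Each patient carries one spherical
lesion (radius 10 mm); tumor sites sample its interior with enough margin
that the 5-mm ROI stays inside, benign sites sample the prostate away from
the lesion. Two planted imaging effects mirror the intended radiomics
signal: the lesion lowers ADC intensity by `lesion_contrast` (default
0.35 — a typical tumor ADC drop), driving the ADC first-order features;
and it partially decorrelates the b2000 noise field *at equal marginal
variance* (mixing weight `min(1, 2.5 · lesion_contrast · patient
multiplier)`), driving the b2000 GLCM features while leaving b2000
first-order statistics untouched. Both effects carry independent
per-patient log-normal multipliers (SD 0.5 and 0.25), for two reasons:
real lesions differ in diffusion restriction, and without them the two
imaging effects would be perfectly collinear functions of the same lesion
mask, letting the selection keep one and discard the other. Setting
`lesion_contrast = 0` and equal band amplitudes removes every class effect,
a property the tests verify with two-sample KS tests.

**Histology.** ISUP grade groups follow the Gleason pair; high-grade
percentages are drawn per grade group (GG1 always < 20%, a configurable
fraction of GG2 below 20%, GG3/GG4 high), targeting an overall quarter of
tumor sites below the 20% cutoff, as in the reference distribution.

**Random streams** are hierarchical (cohort → patient → site → replicate),
so one site's draw never perturbs another's, and every output is a pure
function of the configuration including its seed.

**Calibration of the defaults.** The generator's effect sizes were chosen
so that the planted structure behaves like the study's data: pooled LOPOCV
AUC on FP+Rad around 0.85–0.95, roughly 8–10 features selected per fold at
cap 10, and a consensus list (features selected in >10 of 18 folds) that
is dominated by the seven planted effects. Two design lessons are baked
in: signal-to-noise must be comparable across the seven planted groups
(a single dominant group absorbs the selection), and effects must not be
collinear (per-band and per-patient jitters provide the independent
variation that makes all groups jointly necessary). These values were
fixed before the acceptance checks were finalized and are not tuned per
seed.

**What the generator does not emulate:** anatomically realistic prostate
or lesion geometry, ultrasound imaging, registration error, EM-tracking
noise, scanner-specific intensity distributions, spectral
instrument-response functions, or inter-patient spectral batch effects.
Passing tests on this cohort therefore demonstrate that the pipeline's
machinery is correct and leakage-free and that it can recover planted
multimodal structure at study-like sample sizes — not that the clinical
performance figures of any real cohort would be reproduced.

# Numerical choices and degenerate inputs

* SNV of a constant spectrum and single-class training folds raise errors
  naming the offending object; zero-MAD replicate stacks pass through.
* The baseline fit returns its last iterate flagged `converged = FALSE`
  rather than failing at the iteration cap.
* GLCM directions without valid voxel pairs are dropped from the average;
  a fully empty direction set is an error.
* Lasso active-set ties (identical sets along the path) resolve to the
  most regularized penalty; exact-duplicate columns (e.g. Energy vs Total
  energy within one modality) may enter together, as they are
  indistinguishable after standardization.
* ROC threshold ties equidistant from the corner resolve toward higher
  sensitivity, consistent with the false-negative-averse cost design.
* The SVM solver runs at a convergence tolerance of 1e-6 (rather than
  libsvm's looser default) so the primal objective matches a brute-force
  oracle within 1e-3 on small instances and results are deterministic.
* Problem sizes in the test-suite property checks (small cohorts, reduced
  replicate counts) were chosen to exercise the same code paths at a
  fraction of the study-scale cost; the `analysis/` drivers and the
  acceptance script run the full study-scale configuration.

# Known limitations

* The pipeline accepts the MRI↔TRUS transform as input; no registration is
  performed.
* Only axis-aligned volumes are supported (origin + spacing geometry, no
  oblique direction matrices).
* No nonlinear kernels, no hyperparameter search, no alternative
  calibration (isotonic) or selectors (mRMR, RFE) — deliberately outside
  scope.
* Consensus recovery is evaluated at band-group granularity (a consensus
  feature within 4 band-widths of a planted center attributes to that
  band); adjacent selected shifts can attribute to two overlapping bands,
  exactly as overlapping spectral lines do in practice.
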