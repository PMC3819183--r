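---
title: "Methods: spatial covariance analysis of perfusion volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial covariance analysis of perfusion volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssmpca)
```

This vignette documents the statistical model, the numerical conventions,
and the design decisions behind `ssmpca`, in the spirit of a methods
section a maintainer can audit.

## The scaled-subprofile model

The data are N co-registered, nonnegative 3D perfusion volumes on a shared
voxel grid, a binary brain mask with V in-mask voxels, and a per-subject
clinical table. The model treats each subject's log intensity at an
in-mask voxel as

$$\log Y_{iv} = \mu_v + g_i + \sum_k s_{ik}\, w_{kv} + \varepsilon_{iv},$$

with a shared group profile $\mu$, a subject global offset $g_i$ (which
absorbs any multiplicative scanner factor), K covariant spatial patterns
$w_k$ with subject expression scores $s_{ik}$, and voxel noise. Double
centering of the log data — subject (row) means first, then voxel (column)
means of the row-centered matrix — removes $\mu$ and $g$ *exactly*, so the
residual matrix contains only pattern structure plus noise. Both orders of
centering give the same matrix; the row-first order is fixed so the stored
intermediates (subject offsets, group profile) are reproducible.

The thin SVD $R = USV^\top$ supplies the eigenimages (right singular
vectors, unit norm and exactly mean zero because both margins of $R$ are
zero), the subject scaling factors $s_{ik}=U_{ik}S_k$, and variance
fractions $S_k^2/\sum_j S_j^2$. Only components explaining more than 10%
of the residual variance (strict inequality) are analyzed further.

Conventions the decomposition fixes, because the SVD does not:

- **Sign.** Each component is oriented so the skewness of its weight
  vector is nonnegative; for numerically symmetric weights
  (|skewness| < 1e-12) the largest-magnitude weight is made positive.
  Deterministic and data-driven; the clinical interpretation is unaffected
  since correlations change sign with the component.
- **Scale.** Weights are unit-norm; all magnitude is carried by the SSF.
  Z maps are therefore scale-free and SSFs are directly comparable to
  generative scores.
- **Z-scoring.** Population (1/n) standard deviation over in-mask voxels,
  so the Z map is bit-for-bit reproducible; the default threshold 1.64 is
  the upper-0.05 standard normal quantile rounded to two decimals.
- **Degeneracies.** Fewer than 3 subjects is an error; an exactly zero
  residual matrix yields zero components and the pipeline exits early with
  status `"no-components"`; singular values below
  `max(dim) * eps * S[1]` are treated as numerically zero.

## Preprocessing

The pipeline smooths first, then intensity-normalizes.
Smoothing uses a separable Gaussian kernel with per-axis
$\sigma_\text{vox} = \mathrm{FWHM}/(\sqrt{8\ln 2}\,\cdot\,\text{voxel
size})$, truncated at $4\sigma$, with nearest-edge replication at the
boundaries. Replication preserves constant volumes exactly and conserves
the integral of interior blobs; wrap-around modes would leak intensity
across the volume. Oblique affines are rejected rather than silently
approximated — a rotated grid would need a rotated kernel, and both the
synthetic generator and typical template-space data are axis-aligned.

Global normalization divides each subject by its own in-mask mean, so
every subject's in-mask mean is exactly 1; voxels outside the mask never
enter any statistic. The step is idempotent and makes the whole pipeline
invariant to per-subject positive rescaling (the log of a constant factor
is removed with the row mean in any case; normalization additionally fixes
the displayed intensities). Vectorization uses the canonical voxel order —
ascending linear array index, first axis fastest — shared by every map and
matrix in the package.

## Bootstrap stability and clusters

The bootstrap resamples subjects with replacement (a replicate with fewer
than three distinct subjects is redrawn and not counted), recomputes the
log transform and the double centering *within* the replicate (the group
profile changes with the resample; reusing the original profile would be a
different procedure), and re-decomposes. The replicate component with the
largest |Pearson correlation| to the target pattern is selected;
below the matching threshold (default 0.5) the replicate is rejected and
counted, otherwise the matched weights are sign-aligned and accumulated.
The per-voxel statistic is the mean over accepted replicates divided by
the sample standard deviation over accepted replicates — an inverse
coefficient of variation Z, the convention of the covariance-analysis
software family this pipeline follows. Voxels whose replicate weights are
constant to within 1e-6 of the weight RMS (a zero-noise cohort reproduces
the pattern exactly, up to SVD round-off) are flagged `stable` rather than
given an arbitrarily large Z, and count as suprathreshold on the side of
their mean.

**Calibration of the stability Z.** At a voxel carrying no pattern signal
the statistic is approximately self-normalized,
$z \approx \sum_i s_i \varepsilon_{iv} \big/ \sqrt{\sum_i s_i^2
\varepsilon_{iv}^2}$, whose tails at N = 40 are heavier than standard
normal: direct null simulation puts the exceedance of 1.64 at roughly
10–14%, not 5%. The acceptance suite therefore measures background
specificity at ~89% on the reference synthetic cohort, below the 95% a
normal reference would promise, while blob-core voxels are flagged with
very large margins. This is a property of the mean/sd statistic itself at
this sample size, not of the implementation; users who need calibrated
voxel-level error rates should treat the 1.64 cut on the stability Z as a
descriptive screen, in the same way the cluster size filter is.

Cluster extraction labels connected components of the thresholded map
under face (6-neighbour) connectivity by default — the most conservative
standard choice; 18- and 26-neighbour variants are available. Components
below the minimum size (default ten voxels) are dropped; clusters are
sorted by size, then peak |Z|, then canonical peak index, and peaks are
reported in mm through the affine (zero-based voxel convention). No
parametric cluster-level p-values are computed: significance is the
voxel-level stability threshold plus the extent filter, the conservative
reading when a cluster table is described only as thresholded and
size-filtered.

## Clinical statistics

- Pearson correlations report r, t and a two-sided p from Student t with
  n − 2 df. Reaction times are natural-log transformed before parametric
  analysis (the base is a convention; correlations are unaffected).
- Partial correlation residualizes both variables on the covariates plus
  intercept by least squares and correlates the residuals, with
  n − 2 − c df; with one covariate this equals the classical closed form
  to 1e-12, which the tests verify as a dual-route check.
- Confounder screening flags a candidate at p < 0.10 against **both** the
  imaging and the clinical variable — the classical confounder definition;
  a switch (`rule = "either"`) implements the looser either-variable
  reading, since usage varies in the applied literature. Binary candidates are correlated as 0/1
  (point-biserial). Under independence the both-test rule flags ~1% of
  null candidates (0.10²), which the calibration test measures.
- Stepwise regression keeps the imaging predictor forced in — matching the
  purpose of assessing whether covariates alter *its* effect — with
  forward entry at p < 0.05 and backward removal at p ≥ 0.10, the common
  statistics-package defaults, iterated to a fixed point.
- Group comparisons use the pooled-variance Student t (not Welch), χ²
  tests use no continuity correction, the Shapiro–Wilk screen only logs
  warnings and never branches the analysis, and all p-values are
  two-sided with α = 0.05 for the mediation flag.
- Mediation: an exposure–outcome association is "mediated" when the
  marginal correlation is significant and the partial correlation
  controlling for the mediator is not. When the outcome is an exact linear
  function of the mediator the residual variance is zero; this
  complete-mediation limit is reported as r_partial = 0, p = 1 rather than
  an error.

No multiple-testing correction is applied across the clinical panel;
associations are reported descriptively, one model per variable.

## The synthetic cohort

`simulate_cohort()` draws, from a single generator seeded once per run:
subject global offsets (log sd 0.15), per-pattern scores, a medication
indicator that shifts the second pattern's score downward, voxel
log-noise, and a uniform per-subject scanner scale factor (0.8–1.25,
present deliberately to exercise the normalization-invariance of the
decomposition). In-mask intensity is
$c_i \exp(\mu_v + g_i + \sum_k s_{ik} p_{kv} + \varepsilon_{iv})$ with a
fixed, smooth, center-weighted group profile. The fluctuation outcome is
linear in the second pattern's score with Gaussian noise and **no direct
medication term** — full mediation by construction; a config flag
(`clinical_direct_beta`) adds a direct effect for negative-control
experiments. Identical configs and seeds give bit-identical cohorts.

Patterns are sums of isotropic Gaussian bumps, mean-removed,
Gram–Schmidt-orthogonalized and unit-normed, so the embedded set is
exactly orthonormal and PCA's orthogonality assumption is satisfied by
construction — recovery is then a sharp property rather than an
approximation. Two further design points matter:

- **Score-variance separation.** The default score sds are 3.5 and 1.6.
  Perturbation analysis says sampling rotates estimated components within
  a pair by an angle of order (sample score cross-covariance)/(variance
  gap); at N = 40 closely spaced variances would make recovery of the
  individual patterns unstable even at low noise, which is a property of
  PCA, not of the implementation. The defaults keep the rotation angle
  small while both components stay well above the 10% retention cut.
- **Volume-balanced bumps.** Within each pattern the bump amplitudes
  satisfy $\sum_b a_b r_b^3 = 0$, so the bump sum integrates to ~0 and
  mean removal leaves no diffuse offset. Without this, every "background"
  voxel carries a small constant true weight (a mean-zero pattern with
  localized positive mass must go negative somewhere), and background
  specificity would measure the generator's offset rather than the
  bootstrap's behaviour.

The default cohort is 40 subjects on a 27 × 23 × 19 grid of 4 mm voxels
with an ellipsoidal mask of ≈ 4,000 voxels, log-noise sd 0.05, medication
probability 0.5 and score shift 3, outcome slope 3 with outcome noise 7.5
(chosen for a score–outcome correlation of about 0.6, a strong but
realistic clinical association adopted as the modelling target). `clinical_noise_for_rho()`
computes the noise level for any target correlation.

What the generator does **not** emulate: SPECT physics (attenuation,
scatter, collimator blur beyond a single Gaussian), misregistration,
non-Gaussian or spatially correlated noise, non-ellipsoidal anatomy, and
atrophy-like structured confounds. Passing recovery tests therefore show
the estimator chain is correct under its stated model, not that real
perfusion data meet that model.

## Problem sizes used by the test suite

Unit tests run on ~670-voxel masks with 8–20 subjects; the reference
recovery and bootstrap checks use the full default cohort (40 subjects,
≈ 4,000 voxels, 200 bootstrap replicates); mediation properties aggregate
100 simulated cohorts of 40 subjects on the small grid; calibration
checks use 2,000 null simulations. These sizes were chosen so the whole
suite exercises the study-scale path while remaining quick to run
routinely.

## Known limitations

- The stability Z is not null-calibrated at small N (see above); its
  threshold is a screen, not a per-voxel test.
- Holdout projection (`project_subject`) uses the training group profile;
  scores for subjects scanned under a different protocol are only as
  comparable as the profiles are.
- The stepwise procedure inherits the usual caveats of stepwise selection
  (post-selection inference is not corrected).
- Real-data inputs are assumed co-registered; no registration is
  performed or checked beyond grid/affine equality.
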