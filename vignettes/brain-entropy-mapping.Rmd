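---
title: "Brain entropy mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain entropy mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benmap)
```

## What the package computes

`benmap` implements the analysis stream used in patient-versus-control
resting-state fMRI studies of brain entropy (BEN): voxel-wise sample entropy
of the preprocessed BOLD signal, an amplitude-of-low-frequency-fluctuation
(ALFF) comparison metric, a mass-univariate group comparison with
Monte-Carlo cluster-extent correction, and ROI-level regressions of regional
entropy against clinical and microstructural measures with leave-one-out
cross-validated (LOOCV) prediction. A synthetic cohort generator with fully
recorded ground truth exercises every stage.

## Sample entropy

For a series $x = [x_1, \dots, x_N]$, templates $u_i = [x_i, \dots,
x_{i+m-1}]$ are compared under the Chebyshev (maximum coordinate) distance.
With tolerance $r$ equal to `r_frac` times the series' sample standard
deviation,

$$\mathrm{SampEn}(m, r, N) = -\ln\frac{A}{B},$$

where $B$ counts ordered template pairs $(i, j)$, $i \ne j$, within $r$ at
length $m$, and $A$ the same pairs at length $m+1$. Template starts are
restricted to $i \le N - m$ so every $m$-template has an $(m+1)$-point
extension; self-matches are excluded. Lower values mean more regular, more
predictable dynamics. Defaults are $m = 3$ and $r = 0.6 \times$ SD, the
values commonly used for BEN mapping of 3 T BOLD data.

Two normalization conventions are available. The default (`standard`) is
the matched-pair ratio above. The alternative (`literal`) applies the
asymmetric averaging factors $(N-m)(N-m+1)$ to the $m$-count and
$(N-m)(N-m-1)$ to the $(m+1)$-count that some toolbox descriptions print.
These factors are internally inconsistent: on an input where *every*
template pair matches at both lengths they give
$-\ln[(N-m+1)/(N-m-1)] < 0$, i.e. negative entropy for the most regular
possible signal, where the standard form correctly gives 0. We therefore
treat the printed form as a transcription error and keep it only as an
explicit option for comparability.

Degenerate cases are flagged, never silently numeric: a constant series
(zero SD, so $r = 0$) and series with no template matches at either length
return `NA` and are counted in the map's quality report.

### Implementation

Pair counting is exact, not approximate. The compiled kernel enumerates
pairs by lag $d = j - i$: the template match at $(i, i+d)$ is a run of $m$
consecutive pointwise indicators $|x_t - x_{t+d}| < r$, so each lag reduces
to a single branch-free run-length scan, and four lags are interleaved to
break the sequential dependency. The suite verifies the kernel against an
independent brute-force double-loop oracle on hundreds of random series:
counts must agree exactly and the log to $10^{-12}$.

## Preprocessing

The stream follows the common DPARSF-style ordering:

| step | operation | default |
|------|-----------|---------|
| 1 | discard initial volumes | `discard_k = 10` |
| 2 | spatial Gaussian smoothing | `fwhm_mm = 6` (3 mm voxels) |
| 3 | voxel-wise linear detrend | always |
| 4 | ideal band-pass | 0.01–0.08 Hz |
| 5 | nuisance regression | 6 motion + WM + CSF signals |

Smoothing precedes the temporal steps by default (`smooth_first = TRUE`),
matching that ordering; the reverse order is available. The band-pass is an
ideal (brick-wall) DFT filter — bins strictly outside the band are zeroed,
the DC bin is removed whenever the low edge is positive — which reproduces
the REST/DPARSF convention; a zero-phase Butterworth is provided as an
option. WM and CSF regressors are the mean signal inside the one-voxel-eroded
probability-above-0.9 tissue masks of the series being cleaned (with a
fall-back to the uneroded mask when a thin compartment would vanish, which
matters on coarse test grids).

Motion QC excludes a subject when the mean over time of the absolute value
of any translation parameter exceeds 2 mm or of any rotation parameter
exceeds 2 degrees. The source description of this rule mixes "greater than
2 mm" with "less than 2.0 degrees" in one sentence; we implement the
standard either/or exclusion reading. "Mean head motion" is the mean
absolute parameter value per axis; mean framewise displacement is the main
alternative reading and can be built from the same tables.

The ALFF input is the detrended, nuisance-corrected but *not* band-passed
series: band selection happens inside the ALFF spectral sum itself
($\mathrm{ALFF} = \sqrt{\sum_{f \in \text{band}} |X(f)|^2}$ over
positive-frequency bins of the unnormalized forward DFT, so a unit sine on
an in-band bin gives $N/2$). Band-passing first would zero the out-of-band
content ALFF is defined against.

### Numerical conventions

* Smoothing uses a separable, unit-sum, circularly wrapped Gaussian kernel
  truncated at $4\sigma$, with $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$
  per axis in voxel units. Circular wrapping preserves total image mass
  exactly; all images in this package have identically zero background, so
  the wrap-around has no practical effect.
* Map-level smoothing of BEN/ALFF maps is mask-normalized: values are
  weighted by an indicator that excludes background and undefined voxels,
  so the mask boundary does not bleed zeros into the map.
* "Fisher's z-transform" of a BEN map is interpreted as in-mask z-scoring
  (subtract in-mask mean, divide by in-mask SD). The literal
  $\mathrm{artanh}$ reading is implemented behind `mode = "artanh"` but is
  refused with an explicit error whenever any in-mask value lies outside
  $(-1, 1)$ — which raw SampEn values typically do, making z-scoring the
  only interpretation that runs on real maps.
* Voxel indices are 0-based internally; all reported coordinates are world
  mm through the image affine.

## Group inference

Per voxel, an OLS fit of the standardized maps on intercept + group
indicator (patient = 1) + age + sex + education; the group t statistic with
$n - p$ degrees of freedom equals the classical pooled-variance two-sample
t-test when no covariates are present (verified voxel-wise in the suite).

Cluster-extent correction follows the AlphaSim recipe: simulate `n_iter`
(default 1000) smooth Gaussian fields on the analysis mask — white noise
smoothed to the applied map FWHM and re-standardized in-mask — threshold
two-sided at the voxel p (default 0.01), record the maximum cluster extent
under the chosen connectivity (default 26-neighbor, the common
DPARSF/AlphaSim setting), and report the smallest extent whose exceedance
probability is at most alpha (default 0.05). The null smoothness defaults
to the known applied smoothing because on synthetic data the truth is
known; residual-based smoothness estimation is the natural extension for
real data, where the entropy map also inherits smoothness from the
image-space smoothing and the default is therefore mildly liberal.
Suprathreshold voxels are clustered separately by t sign, clusters with
extent at least `min_extent` (default 50 voxels; at 3 mm isotropic, 50
voxels = 1350 mm$^3$) are tabulated with their peak |t| voxel in world mm.

The family-wise error calibration test regenerates whole null datasets
(68 smoothed-noise maps, the full GLM, the full cluster pipeline) and
checks that the rate of any surviving cluster lies in the 95% binomial
window around 0.05. The t-field/z-field discrepancy (the Monte-Carlo null
is Gaussian; the data map is Student t with 63 df) is within that window at
these smoothness levels.

## ROI associations and LOOCV

Cluster-mean entropy is regressed against clinical scores (EDSS, MFIS-5,
PASAT) and ROI-mean MD with single-predictor OLS, patients only by default.
`beta_std` is reported as the sign-carrying Pearson correlation, so
$\beta^2 = R^2$ holds identically — this is precisely the internal
consistency relation the published (R$^2$, $\beta$) pairs satisfy.
Bonferroni correction is applied over the family of all (ROI × measure)
tests in one invocation, and the family definition is recorded in the
output rather than guessed.

LOOCV prediction refits the simple regression on each leave-one-out sample,
predicts the held-out score, and reports the Pearson correlation between
predictions and observations with a two-sided t p-value on $n - 2$ df; this
convention reproduces published LOOCV (R$^2$, p) pairs (e.g. $R^2 = 0.116
\rightarrow p = 0.048$ at $n = 34$).

**A calibration warning that the package makes explicit.** Under a null
slope the held-out prediction is essentially the leave-one-out training
mean, $(S - y_i)/(n-1)$, which is *exactly anticorrelated* with the
held-out value. The null distribution of the LOOCV correlation is therefore
centred well below zero (simulation at $n = 34$: mean $r \approx -0.35$),
and the two-sided t-test on it rejects far more than 5% of the time under
the null. The correlation-as-accuracy index is a descriptive measure, not a
calibrated test; its p-value should not be read as family-wise evidence.
The suite asserts the anticorrelation property, and the acceptance report
includes the measured null rejection rate rather than pretending it is
0.05. The companion shrinkage property — a planted in-sample $R^2$ of 0.15
shrinks to a much smaller LOOCV $R^2$ — does hold and is asserted.

## The synthetic cohort

The generator emulates a two-group study matched to the cohort the pipeline
targets: 34 patients and 34 controls, 240 timepoints at TR = 2 s, 3 mm
isotropic voxels, sex ratio 13M/21F per group, ages uniform on 20–58,
education approximately normal (12 ± 3 years). The grid is desk-scale
(24 × 24 × 16); the brain is a centred ellipsoid covering about 60% of the
grid with concentric "WM core / GM shell / CSF rim" compartments, which is
enough to exercise nuisance extraction, BPF and masked statistics without
any registration machinery.

Entropy is controlled through the mixing weight $w$ of
$x = (1 - w)\,s_{AR} + w\,e$, with $s_{AR}$ a unit-variance AR(1) process
($\phi = 0.9$) and $e$ unit white noise: sample entropy is monotonically
increasing in $w$ (asserted over a $w$ grid in the suite), giving an
interpretable knob with no claim to hemodynamic realism. Defaults plant one
entropy-increase ROI ("SMA", $w$ 0.85 vs 0.5) and one entropy-decrease ROI
("pHIPP", 0.15 vs 0.5) of 75 voxels each — sized like the smaller published
clusters, and large enough to survive a 50-voxel extent filter after 6 mm
smoothing. Per-subject ROI weights jitter around the group value
(SD 0.05), and clinical scores are linear in these per-subject entropy
offsets plus Gaussian noise, scaled so the planted score–entropy $R^2$ is
about 0.3 with EDSS-like (median ≈ 2, range 0–4) and MFIS-5-like ranges;
PASAT is left unlinked (slope 0) since no entropy association is claimed
for it. MD maps are a baseline (8 × 10⁻⁴ mm²/s) plus a coupling times the
same offsets inside designated ROIs plus noise. Motion tables are small
random walks; a configurable fraction of subjects (default 0) receive a
planted QC violation.

Everything planted is stored in a ground-truth record (group weights,
per-subject weights and offsets, link slopes, MD couplings, seeds), so
recovery tests never re-read the images. A fixed seed makes the cohort —
including the lazily materialised 4D images — byte-identical across runs.

What the generator does *not* emulate: scanner physics, slice timing,
realistic head motion in image space, spatial normalization error,
physiological noise spectra, or between-voxel heterogeneity of the
hemodynamic response. Passing tests therefore demonstrate that the
*pipeline* recovers what was planted under its own assumptions, not that
the method is validated on real MS data.

### Series length matters more than it looks

A finding from validating the pipeline on planted effects: after the
brick-wall band-pass a series of length $T$ retains only about $2 \times$
(number of in-band DFT bins) real degrees of freedom — 64 at $T = 230$,
TR 2 s, 0.01–0.08 Hz. Nuisance regression then projects out up to 9 more
directions, and because head-motion random walks and tissue means are
low-frequency-weighted, the projection whitens strongly autocorrelated
voxels more than white ones. At 240 timepoints the planted entropy
contrast survives comfortably; at 120 timepoints or fewer it is largely
erased by this interaction. The generator's 240-timepoint default is
therefore load-bearing, and tests that need the planted contrast always
simulate full-length series. For real studies this is an argument for
longer acquisitions when entropy mapping is combined with aggressive
nuisance regression.

## Problem sizes used by the tests and the acceptance report

Chosen to keep a full run on a single desktop CPU comfortable: the
planted-effect recovery criterion runs the full default cohort (34 + 34,
24 × 24 × 16 × 240) across 20 seeds in the test suite (about 40 s per
cohort) and 12 seeds in the acceptance script; the family-wise error
calibration uses a reduced 14 × 14 × 10 grid with 400 simulated null
datasets; LOOCV calibration/shrinkage use 200 and 100 replicates at
n = 34. The Monte-Carlo extent threshold always uses the full 1000
iterations. Operator-level tests use toy grids.

## Known limitations

* Spatial normalization, slice-timing and rigid realignment are out of
  scope; inputs must already be on a common grid.
* The Monte-Carlo null assumes stationary Gaussian smoothness set by the
  applied kernel; residual-based smoothness estimation is not implemented.
* Anatomical labels for cluster tables are caller-supplied; no atlas is
  bundled.
* Entropy maps from very short series (N below roughly 100) are noisy at
  m = 3; the generator's 240-timepoint default sidesteps this, but real
  short acquisitions deserve caution.
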