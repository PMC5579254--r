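---
title: "Vascular control of BOLD signal variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular control of BOLD signal variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldvar)
```

# The scientific question

Younger adults tend to show larger moment-to-moment fluctuations of the
BOLD signal (SD_BOLD) than older adults in many cortical regions. Because
the BOLD signal is a vascular signal, an obvious worry is that this age
difference merely reflects age differences in vascular physiology —
baseline cerebral blood flow (CBF), cerebrovascular reactivity (CVR), or
the maximum attainable BOLD change (M, the signal's dynamic range) — rather
than anything neural. `boldvar` implements the analysis chain that puts
this to a test: estimate SD_BOLD from fixation blocks of a dual-echo
BOLD/pCASL acquisition, estimate CBF, CVR and M from the same session (the
latter two via a hypercapnic breathing challenge), locate the regions where
young exceed old in SD_BOLD with a Task partial least squares (PLS) model,
and ask whether the age effect on the region-level SD_BOLD score survives
statistical control for the vascular measures.

Real cohort data of this kind are not publicly deposited, so the package
ships a synthetic-cohort generator with known ground truth. Every stage of
the analysis is exercised — and, crucially, *validated* — against planted
parameters rather than against irreproducible numbers.

# Signal model and preprocessing

A dual-echo pCASL acquisition yields, per frame, a short-echo (TE 10 ms,
flow-weighted) and a long-echo (TE 30 ms, BOLD-weighted) volume, with
arterial labeling alternating tag/control across frames. Two linear
operations separate the two physiological signals:

* **Surround subtraction** (`surround_subtract`): frame i minus the mean of
  its neighbours, sign-corrected per frame, isolates the tag/control
  difference (perfusion) while cancelling the smooth BOLD carrier.
* **Surround addition** (`surround_add`): frame i averaged with the mean of
  its neighbours cancels the tag/control alternation and keeps the BOLD
  carrier.

Endpoints use their single available neighbour. On a pure linear trend the
three-point average is exact in the interior; on realistic autocorrelated
fluctuations the averaging attenuates high-frequency variance by a fixed
factor, which is irrelevant downstream because every comparison is across
subjects or groups under the same operator.

Temporal high-pass filtering uses a zero-phase order-5 Butterworth filter
(`signal::filtfilt`) at 0.01 Hz; only the cutoff is prescribed by the
protocol, the filter family is our numerical choice, and the filter removes
the temporal mean (the pipeline restores each voxel's mean before
normalization, where it is needed as the scaling reference). Spatial
smoothing is a separable Gaussian with FWHM 8 mm (sigma = FWHM/2.3548),
renormalized at volume edges so constants are preserved exactly.

## Component-based denoising

ICA-style denoising is implemented as *classification* of given components,
not component estimation (estimating components from seconds of synthetic
data would test nothing). `classify_component` operationalizes the
criteria used in manual denoising practice: time-series spikes (robust
|z| >= 6, median/MAD so the spike cannot mask itself), high-frequency power
(>= 75% of periodogram power above 0.13 Hz), low-frequency drift (>= 50% of
power below the high-pass cutoff), speckled spatial scatter (>= 25% of the
brain covered with < 5% of suprathreshold voxels in clusters of >= 10), and
white-matter/CSF or edge dominance (>= 50% of suprathreshold voxels inside
the respective mask). Spatial "activation" is robust-z >= 2 of the map over
the brain mask; cluster connectivity is 26-neighbourhood; both are our
documented choices where practice varies. A keep-on-ambiguity rule retains
any flagged component whose suprathreshold map is >= 60% grey matter with a
dominant (>= 10 voxel) cluster, mirroring the conservative habit of keeping
components that mix apparent signal with noise. Rejected components are
removed by *partial* regression (`regress_out_components`): all components
are fit jointly and only the rejected contributions subtracted, so variance
shared with kept components survives.

# SD_BOLD

Fixation blocks are normalized in two steps (`normalize_blocks`): scale all
fixation data so the grand mean over brain voxels and block frames is 100,
then subtract each voxel's block mean per block and concatenate the blocks.
SD_BOLD is the per-voxel sample SD (n − 1) of the concatenated series
(`compute_sdbold`). Block-mean removal makes the statistic insensitive to
slow drifts between discontinuous blocks; the grand-mean scaling makes it
scale-free. A split-half check (`split_half_reliability`) correlates the
SD map from concatenated first half-blocks with that from second
half-blocks; odd-length blocks drop their final frame.

# Vascular parameters

The hypercapnia run (end-tidal PCO2 stepped 40 → 45 mmHg, PO2 held at
100 mmHg) is modelled per voxel by a GLM with an HRF-convolved boxcar
(difference-of-gammas HRF peaking at 6 s with a 16-s undershoot at ratio
1/6), an intercept, and Legendre drift polynomials up to cubic order
(`fit_block_glm`). Fractional change = effect / constant. Then:

* **CVR** = percent BOLD change / ΔPCO2 (%BOLD/mmHg, `compute_cvr`).
* **CBF** from the baseline tag/control difference via the
  single-compartment pCASL closed form (`quantify_cbf`), with the baseline
  EPI signal as M0 surrogate corrected for incomplete T1 recovery over the
  TR (T1_gm = 1.4 s), partition coefficient 0.9, labeling efficiency 0.80,
  blood T1 1.49 s, post-labeling delay 0.9 s, tag duration 1.5 s.
* **M** from the generalized calibration model (`compute_m`). The venous
  oxygen saturation inputs come from the Severinghaus dissociation curve
  plus the Fick principle under iso-metabolic hypercapnia with baseline OEF
  0.30 (`estimate_svo2`); these "series of equations" are not printed in
  full anywhere authoritative, so all three ingredients are explicit,
  documented and swappable.

Two denominator forms are provided for M. The form printed in the source
literature, `1 − (CBF/CBF0)^α − (dHb ratio)^β`, is negative for
physiological hypercapnia values (both subtracted terms are near 1);
`compute_m` implements it verbatim as the default and flags
non-physiological results. The standard deoxyhemoglobin-ratio form
`1 − (CBF/CBF0)^(α−β) (dHb ratio)^β` is positive for the same inputs; the
*pipeline* uses it by default (`analysis_config(gcm_form = "dhb_ratio")`)
because the downstream distributional treatment log-transforms M, which is
undefined for negative values. α = 0.18 and β = 1.5 throughout.

ROI-level CVR and M average the *time series* over the ROI first and then
apply the GLM and the calibration equations once. Averaging voxelwise
fractional-change ratios instead is numerically fragile (each voxel ratio
is heavy-tailed); averaging before the ratio is the stable order and
matches the ROI-averaged usage of these quantities.

# Task PLS

With one condition and two groups, the group-by-voxel matrix of group mean
SD_BOLD values, centered by removing the per-voxel grand mean across
groups, is decomposed by SVD (`task_pls`); exactly one latent variable is
estimable and its voxel pattern is proportional to the per-voxel group mean
difference. Inference:

* **Permutation test**: group labels shuffled without restriction;
  p = (#{permuted S1 >= observed} + 1)/(n_perm + 1).
* **Bootstrap ratios**: subjects resampled with replacement within group;
  the scaled salience pattern V1·S1 is recomputed, sign-aligned to the
  original by correlation (sufficient for a single LV), and
  BSR = original salience / SD of bootstrap saliences. We bootstrap the
  scaled pattern rather than the unit-norm V because the unit-norm
  constraint mixes every voxel's uncertainty into every other voxel's
  denominator; the scaled pattern behaves like a per-voxel mean difference
  and its BSR is well calibrated under the null (verified by test).
* **Thresholding** at |BSR| >= 2.70 (beyond the two-sided 99% normal
  critical value 2.576) defines the young-higher region used for brain
  scores and vascular ROI extraction; clusters are 26-connected components.

Brain scores are the dot product of the LV's voxel saliences with a
subject's SD_BOLD vector, restricted to the thresholded region.

# Regression suite

The cohort table (brain score, ROI CBF/CVR/M, group, sex, coupling r's)
passes through, in order: single-pass univariate outlier removal at
±2.5 SD (single pass, so a gross outlier can inflate the SD enough to mask
itself — this mirrors common practice and is tested as such); a
Kolmogorov–Smirnov normality gate that log-transforms right-skewed
failures (CVR and M in practice); and an iterative Mahalanobis filter
(df = 4) that removes the worst case while its D² exceeds the χ² quantile
at probability 1 − 1/(2n), capped at ~5% of cases — a quantile rule
standing in for the visual Q-Q judgement it operationalizes. Models 1–4
regress the brain score on age group plus one or all vascular predictors;
Models 5–6 regress per-subject within-subject coupling correlations
(SD–CBF, SD–CVR across voxels) on age group. Each model reports b,
percentile bootstrap 95% CI (1000 case resamples), SE, t, p, zero-order,
partial and semi-partial correlations, VIF, and Levene's test of outcome
variance across groups. Group is coded young = 1, old = 0. The
sex-composition χ² is Pearson's without continuity correction.

# The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults *are* the study conditions: 28 young (20 M/8 F)
and 43 old (11 M/32 F) subjects; five 60-s fixation blocks (TR 3 s,
alternating with task blocks, 300 s of fixation total); a hypercapnia run
stepping PCO2 from 40 to 45 mmHg with PO2 at 100 mmHg; grey-matter CBF
60/45 ml/100g/min (young/old), CVR 0.35/0.25 %BOLD/mmHg, M 0.08/0.06.
Where the source is silent we chose once: between-subject SDs (CBF 10,
CVR 0.08, M 0.018) and a latent-factor loading of 0.65 for the three
vascular indicators, set so the model VIFs land in the realistic 1.1–2
band; BOLD fluctuations are AR(1) with φ = 0.3 at TR 3 s; planted SD_BOLD
is 2.0/1.2 (young/old) in a contiguous ≥30-voxel effect region against a
background of 1.0, values chosen for testability since fluctuation
magnitudes in native units are not standardized; the grid is 12×12×6
voxels at 4 mm so grid-scale criteria (25% scatter coverage, 10-voxel
clusters) are meaningful while tests run in seconds.

The generator plants each voxel's sample SD exactly (the AR(1) process is
rescaled to unit sample SD), encodes CBF by inverting the pCASL closed
form so quantification is exact by construction, scales echo-1 BOLD
fluctuations by TE1/TE2 ≈ 1/3, and builds the hypercapnia response with
the same HRF the GLM fits. Planted M is floored at 1.1 × ΔBOLD/BOLD0
because M is the asymptote of the BOLD response and the calibration
inversion has no solution below it.

Coupling between a subject's SD_BOLD level and the vascular factor has
three modes. `independent` draws them independently — a direct age effect.
`fully_mediated` makes the SD level an affine function of the *absolute*
latent vascular level (same mapping in both groups), so the group SD
difference exists only because the groups differ vascularly.
`partial` interpolates with `coupling_rho`. This is the lever that makes
the headline claim testable: vascular control in Model 4 should leave the
age effect intact under `independent` and erase it under `fully_mediated`
— and does (see `analysis/04_headline_logic.R`).

What the generator does **not** emulate: anatomy and registration, motion,
cardiac/respiratory physiology, multi-delay ASL kinetics, and spatial
autocorrelation of noise. Passing tests therefore demonstrate the
*statistical machinery* is correct and calibrated, not that the pipeline
is robust to every artifact of real acquisitions.

# Numerical choices and degenerate inputs

* Sample SDs use n − 1 everywhere.
* Block frame membership is half-open ([onset, onset + duration)), so no
  frame belongs to two blocks.
* Tag parity is specified in 0-based acquisition numbering ("even" = first,
  third, ... acquired frames are tags).
* Drift polynomials are orthogonalized; effect and constant terms are
  invariant to this.
* `transform_to_gaussian` refuses non-positive values rather than fudging
  them; the pipeline logs and skips the transform in that case.
* Degenerate bootstrap resamples (a group collapsing to one unique
  subject) are redrawn and counted.
* An empty thresholded region aborts ROI-dependent stages with a warning
  rather than an error.
* Problem sizes in the shipped experiments (20+20 subjects, 200
  permutations/bootstraps for recovery; 100 simulated cohorts for the
  mediation contrast; 200 null simulations for calibration) were chosen as
  the smallest sizes at which the quantities of interest are estimated
  with comfortable margin.

# Known limitations

* The printed calibration denominator and the exact venous-saturation
  equations could not be fully pinned to the source; both are implemented
  with explicit, swappable choices and the discrepancy is documented above.
* Voxelwise M maps are deliberately not produced (reliable M needs ROI
  averaging at this SNR).
* The ICA criteria for motion ringing and susceptibility artifacts are
  inherently qualitative; the edge-mask operationalization is an
  approximation.
* Registration to a standard space is out of scope; all maps live in the
  acquisition grid.
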