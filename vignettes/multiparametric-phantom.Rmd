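---
title: "Methods: multiparametric MR quantification on a glioma digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric MR quantification on a glioma digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpmri)
```

## What the package models

The package reproduces the quantitative-MRI arm of a preclinical study of
sexual dimorphism in a C6 glioma rat model: four experimental groups
(male/female × tumour/sham, n = 8), each characterized in two tumour
regions (core and contrast-enhancing periphery) by MTR, MD and FA, and
over the whole tumour by relative CBV, CBF and MTT from DSC bolus
tracking. Group differences are expressed as the relative change of the
tumour group against its same-sex sham group and tested with unpaired
two-tailed Welch t tests. Since no image data are deposited with such
studies, the package ships a digital phantom whose ground truth *is* the
study's absolute group tables, so that the full pipeline can be exercised
and verified end to end.

## The phantom

**Geometry.** The map grid matches the MTR/DTI acquisitions: 128 × 128
pixels at 273 µm in-plane, five 1.5-mm axial slices. The DSC grid is the
coarser perfusion readout (80 × 64 at 437 × 547 µm). Brain is an
in-plane ellipse (semi-axes 8 × 11 mm) spanning all slices — an elliptic
cylinder rather than an ellipsoid, which guarantees the lesion fits
inside the mask on every slice. The tumour is a 2.78-mm-radius sphere in
the right hemisphere; rasterized on the map grid it encloses ≈ 88 mm³,
inside the 75–100 mm³ window at which the study triggered its full MR
protocol. Its outer 2-voxel (0.546 mm) shell is the "periphery" ROI and
the interior the "core"; a contralateral 1.6-mm sphere distant from the
lesion is the perfusion reference region. All masks are rasterized from
the same continuous shapes, so the lesion occupies the same physical
location in every modality.

**Ground-truth values.** Truth maps are piecewise constant: tumour
groups carry their core/periphery table values on the lesion and their
same-sex sham values on the background brain; sham groups carry their
own (lesion-free) regional values. Because the sham rows of the two
regional tables differ slightly (analogous but distinct healthy areas),
sham "core" and "periphery" truth differ by < 2% — regional baseline,
not lesion contrast. An optional smooth multiplicative perturbation
(`spatial_sd`) breaks the piecewise constancy when heterogeneous maps
are wanted; it defaults to 0 so that ROI means equal table cells
exactly.

**Between-subject variability.** The study prints SEMs at n = 8, so the
between-subject SD defaults to SEM·√8 per cell. Subject-level region
means are drawn Normal(group mean, SD); rendered subjects then get their
own truth maps. FA draws are clamped to [0, 0.99] and MD to > 0 to keep
truth physically admissible (at the table's SDs the clamp is never
active in practice).

**Noise model.** Magnitude MR images receive Rician noise — the
magnitude of a complex Gaussian pair — with SNR defined as noiseless
reference signal over the Gaussian channel σ. This is the standard
magnitude-MRI noise physics; the source study does not state a noise
model. DSC signals receive plain Gaussian noise (optional), as the
first-pass drop rides on a high-intensity baseline.

**Diffusion truth.** The tensor field is axially symmetric: given a
voxel's (MD, FA), the prolate spectrum is
λ⊥ = MD − d, λ∥ = MD + 2d with d = MD·FA/√(3 − 2FA²), which inverts the
MD/FA closed forms exactly and is non-negative for all FA ∈ [0, 1). The
principal axis defaults to z everywhere (MD and FA are rotation
invariant, so orientation is immaterial to every quantity the study
reports); per-voxel random orientations are available and exercised in
the tests. The direction set is not listed in the source study; the
package's documented default is the six (±1,±1,0)/√2-family directions
plus (1,1,1)/√3 at b = 300 and 1400 s/mm², which is full-rank for the
tensor fit, and any user scheme file is accepted.

**Perfusion truth.** Each voxel carries gamma-variate parameters with
fixed shape α = 2 and arrival t0 = 10 s (the injection time). Raw
reference tissue gets CBV = 1 a.u. and MTT = 3 s (a plausible tissue
transit); the tumour gets those scaled by the group's *relative* CBV and
MTT, so normalization to the reference ROI reproduces the tabulated
relative values identically. β = MTT/(α+1) and K = CBV/(β^{α+1}Γ(α+1))
follow. The concentration-to-signal proportionality is arbitrary (no
absolute calibration exists without an arterial input function); the
simulator applies a scale of 100 so first-pass signal drops have
realistic magnitude, and the scale cancels exactly under reference
normalization.

A deliberate consequence of the central-volume relation CBF = CBV/MTT is
that the three relative perfusion quantities cannot be set
independently: the published CBF row is not consistent with the
published CBV and MTT rows (its sham cells duplicate the CBV ones —
likely a table artifact), so the phantom treats CBV and MTT as primary
and derives CBF. Round-trip checks therefore compare CBF against
CBV/MTT.

## Quantification

**MTR.** `(S0 − S_MT)/S0 × 100` per voxel. Voxels with S0 below
max(ε, 10⁻³ × robust brain-median) are flagged invalid rather than
zeroed — a division guard the source analysis never needed to state.
Negative MTR under noise is kept unclipped so ROI means stay unbiased.

**Tensor fit.** Plain (unweighted) least squares on log-signals, all
shells in one joint fit — matching a pixel-by-pixel fit with no stated
weighting; WLS would change noise propagation but not the noiseless
result. Voxels with any non-positive signal are flagged invalid (the log
is undefined; substituting an epsilon would bias the tensor low).
Negative eigenvalues, possible under noise, are clamped to zero before
the FA evaluation and counted. Two FA conventions exist in the
literature of this analysis: the package implements the standard
normalized form (√(3/2)·‖λ − MD‖/‖λ‖, bounded by 1, consistent with the
healthy-tissue FA ≈ 0.31–0.35 the tables report) and exposes the
unnormalized printed variant behind `printed_form = TRUE` for
comparison only. The eigenvalue-sum form of MD is treated as having a
typographical duplication in its source (λ2 repeated for λ3).

**DSC.** Concentration is −ln(S/S_base)/TE with S_base the mean of the
frames ending one frame before the 10-s injection (1-frame guard, the
study states no explicit baseline rule). The gamma-variate fit
initializes t0 from the last sub-5%-of-peak sample before the peak,
seeds K, α, β by a log-linearized regression, and refines all four
parameters by Levenberg–Marquardt with bounded iterations; the fit
window ends at 1.5× the first-rise-to-return-below-20%-of-peak span, a
standard recirculation trim (configurable, and inert on the phantom's
recirculation-free curves). Non-convergent, flat or peakless voxels are
flagged, never raised. CBV and MTT come from the closed forms
K β^{α+1}Γ(α+1) and β(α+1); MTT is defined relative to t0 (tissue
transit, a pure (α, β) property) because the arbitrary-unit MTT
convention of the original maps is unrecoverable. Perfusion is analysed
over the whole tumour only — at the DSC resolution a core/periphery
split is not meaningful — and fitting is typically restricted to the
tumour and reference ROIs.

**Group statistics.** The percent-change statistic offers two
aggregation modes because the published percent changes are not all
consistent with the ratio of the published group means (e.g. male core
MTR: −29.45 published vs −29.01 from the table): `group-mean` (default)
applies the formula to the two group means with delta-method SEM
propagation; `per-subject` averages each glioma subject's ratio against
the sham mean. Neither is asserted to be "the" original computation.
Welch's t is computed from (mean, SEM, n) triplets — the form the study
prints — with raw-value mode funnelling through the identical formula;
no multiple-testing correction is applied, as none was in the source
analysis. Stars follow the figure-legend convention (*, **, ***, ****
at 0.05, 0.01, 0.001, 0.0001). Degenerate zero-variance comparisons
(noiseless cohorts) are reported as flagged NAs in the tables rather
than errors.

**RER.** The circadian generator produces 30-min bins under a 12-h
light/dark schedule: per-phase means (sham day 0.88, night 0.98 —
nocturnal feeding raises RER at night) with tumour groups offset by the
study's reported percent changes (day −4.85% male / −1.22% female,
night −4.11% / −1.99%), a within-phase sinusoidal ripple with exactly
zero mean over complete 12-h blocks, a subject-level offset and per-bin
noise. The reported values are read as percent changes (absolute RER is
0.7–1.0, so values near −5 cannot be raw RER). The sex-specific
between-subject SDs (0.0033 male, 0.0013 female RER units) are
calibrated so the simulated percent-change SEMs at n = 5 match the
reported ±0.24 and ±0.09; recording length multiples of 12 h keep the
phase means exact under the binning.

## Numerical choices and problem sizes

Noiseless round trips are exact by construction: MTR inverts its
definition algebraically, the log-linear tensor fit is exact on ≥ 7
noiseless volumes, and the gamma-variate fit recovers noiseless
parameters to ≲ 10⁻⁶ relative, so table cells come back at machine
precision. Trapezoidal and analytic CBV/MTT agree within 0.5% at the
250-ms sampling. Determinism is by explicit seeding everywhere, with
per-subject seeds drawn once from the master seed; the caller's RNG
stream is saved and restored.

The shipped analyses use: noiseless pipeline at n = 2 per group (with
zero SD, all subjects equal the group mean, so n only exercises the
plumbing); the noisy demonstration at the study's n = 8 with SNR 40;
RER at the study's n = 5 and 60 h. The acceptance script averages the
RER recovery over 20 replicate cohorts because a single n = 5 draw has
sampling error comparable to the female effect itself; the replicate
mean estimates the generator-plus-estimator expectation with small
Monte-Carlo error. Property checks run 1,000 random positive
semi-definite tensors, a 10,000-replicate null calibration of the Welch
test at n = 8, and a 40,000-draw permutation cross-check.

## What passing tests do and do not show

The phantom is piecewise constant with spherical lesions, uniform
coil sensitivity, no partial-volume mixing, no motion, eddy-current or
susceptibility artefacts, no arterial input function and no
recirculation; its noise is spatially white. Passing round trips
therefore validate the *estimators* — the algebra, fits and statistics —
not robustness to the many nuisances of in vivo data. MR spectroscopy
concentrations, GFAP/Evans-blue and HPLC endpoints enter only as printed
summary statistics through the generic percent-change and Welch
machinery; Bloch-equation MT simulation, anatomical atlases, AIF
deconvolution and leakage correction are out of scope by design.
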