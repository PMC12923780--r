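---
title: "Methods: the DTI-ALPS pipeline and its synthetic testbed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS pipeline and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphalps)
```

## The measurement model

The ALPS index summarises how strongly water diffuses along the
perivascular direction relative to directions perpendicular to the local
fiber systems. The geometric premise, taken at an axial slice through the
body of the lateral ventricles, is that three orthogonal directions carry
distinct tissue structures: projection fibers along z, association fibers
along y, and medullary veins — and with them the perivascular space —
along x. In the projection-fiber region, Dxx is then diffusivity
perpendicular to the fiber but *along* the perivascular axis, and Dyy is
perpendicular to both; in the association-fiber region the same roles are
played by Dxx and Dzz. The index is the ratio of ROI-mean diffusivities

$$\mathrm{ALPS} = \frac{(D_{xx}^{proj} + D_{xx}^{assoc})/2}
                       {(D_{yy}^{proj} + D_{zz}^{assoc})/2}.$$

Two assumptions are inherited from this construction and should be kept in
mind when interpreting results: the fiber systems must actually be aligned
with the coordinate axes (in practice guaranteed by spatial normalisation,
which is out of scope here — users of real data must supply maps already in
an axis-aligned space), and a single Gaussian tensor must be an adequate
local model at the acquisition's b-value.

### Tensor estimation

Per voxel, the monoexponential model \(S = S_0 e^{-b\,g^\top D g}\) is
linear in \(\log S\), so the six tensor components and \(\log S_0\) are
estimated by ordinary least squares against the design with rows
\([1, -bg_x^2, -bg_y^2, -bg_z^2, -2bg_xg_y, -2bg_xg_z, -2bg_yg_z]\).
OLS on the log-signal was chosen over weighted or nonlinear variants
because it is exact on noiseless data, transparent, and adequate at the
moderate diffusion weighting the pipeline defaults to; one-pass
signal-weighted LS is available via `weighted = TRUE` for users who want
noise-floor bias partially compensated. Brain masking follows the
conventional background-noise rule: the mean signal in regions outside the
parenchyma (by default the eight 10%-per-dimension corner blocks of the
grid) defines a noise floor, and voxels whose mean b = 0 signal exceeds
`k` times that floor are retained. `k = 3` by default; it is a
configuration knob, not a physically forced value.

### Numerical choices

* Signals that are zero or negative inside the mask (possible under
  magnitude noise) are clamped to half the noise floor — or
  `1e-6 * max(S)` when the floor is 0 — before the logarithm.
* Negative fitted diagonal diffusivities are *kept* in the maps and only
  counted in `n_negative_diag`: clipping would bias ROI means upward,
  whereas the flag lets users audit affected fits.
* Masked-out voxels carry `NA`, never 0, so they cannot silently enter ROI
  means.
* ROI means are computed over ROI ∩ mask; an ROI entirely outside the mask
  is an error naming the ROI. When left/right ROI pairs are supplied the
  two hemisphere means are combined with *equal weight*, regardless of
  voxel counts, so an asymmetric mask cannot tilt the index. Whether
  bilateral or unilateral ROIs are more faithful to common practice is
  genuinely open; single-mask mode is the default.
* A non-positive ALPS denominator is an error (physically invalid fit),
  not an `NaN` propagated downstream.
* The eigenvector completion in `tensor_from_eigensystem()` breaks ties
  deterministically (the canonical basis vector least aligned with the
  principal axis, in x, y, z order), so phantom construction is exactly
  reproducible.

## The synthetic testbed

### Gradient schemes

Published direction tables for the 30-direction acquisition are not part
of the package; directions are instead generated by seeded electrostatic
repulsion with antipodal symmetry, which converges to near-uniform designs
(for n = 6 it recovers the classic icosahedral arrangement). Tensor
least-squares is rotation-robust for near-uniform designs, so the exact
table does not matter for any quantity the package reports; determinism
under the seed matters and is tested.

### Phantoms

`phantom_spec()` describes a 40 × 40 × 10 voxel grid at 1.7 mm isotropic
resolution (matching the acquisition's slice thickness) with axis-aligned
box regions: projection fibers (principal axis z), association fibers
(principal axis y), an optional subcortical strip (principal axis x,
included for geometric fidelity but unused by the index), and signal-free
background. Default eigenvalues are the diabetic-group ROI means of the
reference cohort — projection (Dzz, Dxx, Dyy) = (0.93, 0.72, 0.61) and
association (Dyy, Dxx, Dzz) = (0.99, 0.69, 0.50) × 10⁻³ mm²/s. A
`perivascular_x_boost` adds Dxx in both fiber regions to emulate stronger
perivascular-direction flow; the index is strictly increasing in it. ROI
shape and size are artifact choices — the source methodology does not
specify them — and since the regions are homogeneous, the extraction ROIs
default to the region boxes themselves.

Noise is Rician by default (magnitude reconstruction: two quadrature
Gaussian channels, then the modulus), with S0 = 1000 and σ = S0/30 — an
SNR of 30, typical of clinical DTI at this resolution. Gaussian
(zero-clamped, preserving signal positivity) and noiseless modes exist for
oracle tests. With zero true signal the Rician model reduces exactly to a
Rayleigh distribution, which supplies the closed-form mean σ√(π/2) used to
validate the background-noise estimator.

### Cohorts

`cohort_spec()` encodes the study conditions: 78 diabetic and 106 control
subjects, group distributions for all twelve ROI diffusivity components
and the ALPS index, demographic and clinical covariates (age, balanced
sex, BMI, HbA1c, diabetes duration for the patient group only, PSQI, ESS,
MoCA, OSA prevalence 17.9% vs 0). Physical quantities are drawn from
normals truncated at zero by redraw; questionnaire scores are rounded and
clamped to instrument ranges (PSQI 0–21, ESS 0–24, MoCA 0–30), which
perturbs their moments slightly and intentionally.

One modelling decision deserves emphasis. The reference values are
internally redundant: the ratio of group-mean diffusivities is 1.2703
(patients) and 1.3302 (controls), while the reported group ALPS means are
1.296 and 1.35 — consistent with the cohort value being a mean of
per-subject ratios, whose expectation exceeds the ratio of means for a
random denominator. The generator therefore draws a subject-level
`alps_target` directly from the stated ALPS distributions (this column
drives the group-level power and calibration analyses) and draws the
diffusivity targets independently from their own distributions (these are
what each subject's phantom physically realises). The pipeline-recovered
per-subject index is consequently centred on the ratio-of-means value, not
on `alps_target`; both are reported, and no attempt is made to force the
two into agreement, because the discrepancy is a property of the source
summary statistics, not of the implementation.

### What the generator does and does not emulate

The phantoms reproduce the acquisition geometry (b = 0/800 s/mm², 30
directions, 1.7 mm voxels), single-tensor anisotropy with the correct
principal axes, magnitude noise, and group-level diffusivity
distributions. They do **not** contain partial-volume mixtures, crossing
fibers, spatially varying tensors within a region, eddy/motion/
susceptibility artifacts, or anatomically realistic ROI placement — so
passing tests demonstrate correctness of the *computation* (signal model
inversion, masking, extraction, statistics), not robustness to the
confounds of real acquisitions.

## The statistical layer

* **Cohen's d** uses the average-variance denominator
  \(\sqrt{(s_1^2+s_2^2)/2}\). This form, rather than the n-weighted pooled
  SD, reproduces every published effect size in the reference tables from
  their printed means and SDs (the n-weighted form gives 1.67 rather than
  1.81 for the glycated-haemoglobin row), so it is numerically forced.
  **f = |d|/2** per the same convention.
* **t-tests** are Student equal-variance by default (the row clinical
  packages report first), Welch by flag. **Chi-square** is Pearson without
  continuity correction.
* **ANCOVA** is OLS of the outcome on a group indicator plus covariates,
  the group effect tested by its partial t — exactly the equal-variance
  t-test when the covariate set is empty (a tested identity). Covariate
  coding: sex male = 1/female = 0; MoCA < 26 → 1; ESS ≥ 11 → 1; OSA
  presence → 1. Collinear designs are an error naming the aliased columns.
* **Bonferroni** is `min(1, p·m)` with the family defaulting to the 13
  diffusivity/ALPS comparisons; `m` is configurable because the family
  size is an analysis choice.
* **Partial correlation** regresses both variables on the covariates and
  correlates residuals, with df reduced by the covariate count; with no
  covariates it *is* the Pearson routine, bit for bit.
* Missing values are deleted pairwise per analysis, never listwise across
  a table — clinical tables routinely have per-variable n.

## Problem sizes and test design

The test suite runs phantoms on 12 × 12 × 6 to 40 × 40 × 10 grids,
cohort-moment checks at n = 10,000 per group, power estimation over 200
replicated cohorts at the study sizes against a normal-approximation
oracle, and type-I calibration over 1,000 null cohorts — sizes chosen so
the whole suite completes in well under a minute while keeping Monte Carlo
error far below the tolerances being asserted. Where ~100 moment checks
are made simultaneously, the per-comparison bound is 4 standard errors to
keep the family-wise false-alarm rate below 1%; single-quantity checks use
3.

## Known limitations

* Real-data use requires pre-normalised, axis-aligned diffusivity maps and
  user-supplied ROI coordinates; no registration or automatic ROI
  placement is provided.
* The log-linear fit is not bias-corrected for the Rician noise floor;
  at SNR 30 and b = 800 this bias is small relative to the group
  differences of interest, but it exists.
* The simulator is single-shell, single-tensor; it cannot probe
  sensitivity of the index to crossing fibers or free-water
  contamination.
* The index itself is an indirect proxy for glymphatic function;
  microstructural change can move it without any change in perivascular
  flow. The package quantifies the computation, not the physiology.
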