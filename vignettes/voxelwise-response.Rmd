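---
title: "Voxel-wise longitudinal DCE-MRI response analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise longitudinal DCE-MRI response analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcetrack)
```

This vignette is the package's own account of the models it implements,
the conventions it fixes where the underlying definitions leave room, and
what its synthetic validation does and does not demonstrate about clinical
data.

## The measurement model

A DCE-MRI visit is three T1-weighted volumes: pre-contrast at `t0` and two
post-contrast frames at `t1` and `t2` (defaults 0, 2.5 and 7.5 minutes,
the timing of the two-post-contrast protocol this analysis targets). Two
visits are compared: pre-treatment and early-treatment. A displacement
field `u(x)` on the pre-treatment grid defines the transform
`T(x) = x + u(x)` into early-treatment coordinates; displacements are
stored in millimetres and all spatial derivatives are computed in world
units, so anisotropic voxels are handled correctly.

### Deformation features

At each voxel the transform gradient `∇T = I + ∇u` is computed by central
differences (one-sided on boundary faces, which are flagged). The
principal stretches `λ1 ≥ λ2 ≥ λ3` are taken as the *singular values* of
`∇T`, computed as square roots of the closed-form eigenvalues of the
symmetric matrix `∇T(∇T)ᵀ` (the trigonometric solution, vectorised over
voxels; the test suite checks it against per-voxel SVD to 1e-8). The
singular-value choice is deliberate: the volume-ratio identity
`J = λ1·λ2·λ3 = det(∇T)` only holds for singular values — raw eigenvalues
of `∇T(∇T)ᵀ` would square it. The raw-eigenvalue variant remains available
(`principal_stretches(..., stretch_mode = "squared")`) for comparison.

Degenerate-case conventions, chosen so map support always equals the
tumour mask (stable denominators downstream):

- ADI divides by `λ2` and `λ3`; both are clamped below at 1e-8 and clamped
  voxels are flagged rather than dropped.
- SRI's ratio `λ3(λ1−λ2) / (λ2(λ2−λ3))` has two degenerate regimes: a
  vanishing denominator with positive numerator is the rod-like limit and
  scores exactly 1; a fully isotropic voxel (`λ1 = λ2 = λ3`) scores 0 by
  convention and carries an `isotropic` flag. Ties between stretches are
  common in synthetic fields, so all inequalities are treated as
  non-strict.

### Kinetic features and response maps

Per voxel, with relative enhancement `(I(t) − I(t0))/I(t0)`:

- `PE` is the maximum over the two post-contrast frames; the peak time
  `t_PE` breaks ties toward the earlier frame and is a sentinel (`NA`)
  when no positive enhancement exists.
- `WIS = PE/(t_PE − t0)` requires a positive peak; otherwise 0. The
  alternative literal gate (`t_PE ≠ 0`, vacuous under this timing) is kept
  behind `wis_condition = "literal"`.
- `WOS = (I(t2) − I(t1))/(t2 − t_PE)` with a zero branch when the peak is
  at `t2`, exactly as the index is defined. Because mixing `t_PE` into
  this denominator is arguably an idiosyncrasy, a conventional
  `(t2 − t1)` denominator is available (`wos_denominator`).
- `SER = (I(t2) − I(t0))/(I(t1) − I(t0))`, guarded to 0 (and flagged)
  when the first-frame uptake is below `1e-3 · I(t0)`; the definition
  supplies no guard, and unguarded near-zero denominators would dominate
  tumour means.
- Voxels with nonpositive baseline are flagged and zeroed, never
  propagated as NaN.

The response map of feature `F` is `PRM(x) = J(x)·F_early(T(x)) − F_pre(x)`
on FTV₁, with `F_early` sampled by trilinear interpolation (nearest would
introduce half-voxel bias in smooth regions; the interpolation choice is
not dictated by the definition). Voxels mapped outside the early image are
flagged invalid and excluded from summaries.

### Functional tumour volume

`segment_ftv()` applies the signal-enhancement-ratio recipe: PE above a
threshold, SER inside an interval, then the largest 26-connected component.
The defaults (`pe_min = 0.7`, SER in `(0, ∞)`) are working placeholders —
the published operating points belong to a clinical calibration this
package does not reproduce — and both are configurable. Volumes are
reported in cm³.

### Heterogeneity indices

Jacobian and PRM maps collapse to the fraction of voxels strictly above
the "no change" value (1 for the Jacobian — an increase means expansion —
and 0 for PRMs; classic PRM dead-bands are available via `prm_deadband`
but default to 0, matching the plain "positive value" rule). ADI and SRI
collapse to histogram entropy, `Σ P(i) log2 P(i)` over equal-width bins of
the per-tumour observed range. Two conventions exist because the index as
printed omits the customary minus sign and its accompanying prose (low at
uniform histograms) is consistent with the sign-kept form; the default is
therefore `"as_printed"` (values in `[−log2 n_bins, 0]`), with `"shannon"`
available. Downstream models are indifferent up to coefficient sign. The
bin count is not specified anywhere for continuous maps; 32 equal-width
bins is the default (`entropy_bins`), a compromise between resolution and
stability at typical tumour sizes (10³–10⁴ voxels).

## Registration

The registration cost is
`E = Σ ms(x, T(x)) · (1/3) · ‖A₁(x) − A₂(T(x))‖² · voxel_volume`:
attribute matching weighted by mutual saliency. The cited attribute and
saliency constructions are not specified in detail, so this package fixes
concrete, simple stand-ins that preserve the cost's structure:

- **Attributes**: per scale (default 2 mm), Gaussian-smoothed intensity,
  its gradient magnitude and its Laplacian, each standardised to zero
  mean/unit variance over the mask. Components whose standard deviation is
  negligible at the image's intensity scale standardise to zero rather
  than amplifying machine-precision ripple.
- **Mutual saliency**: `s_core / (s_core + s_ring + 1e-6)`, where
  `s_core` is the mean attribute similarity (1 − normalised squared
  distance) in a 1-voxel neighbourhood of `T(x)` and `s_ring` the same
  over a 2–4 voxel shell. Distinctive matches score near 1, uniform
  texture near 0.5, correspondences entirely outside the moving image 0.

`register_baseline()` minimises the cost plus a diffusion penalty
`α‖∇u‖²` over a 3-level multi-resolution pyramid. The solver is operator
splitting: each iteration takes a data-force step (capped at
`step_voxel = 0.4` voxels) and then applies the diffusion as a Gaussian
smoothing of the field (`σ = 2·sqrt(2α)` voxels). We chose splitting over
explicit Laplacian gradient steps after observing that explicit coupling
propagates displacement into homogeneous regions too slowly to recover
even a uniform translation accurately; splitting is the standard solver
for this energy and recovers a 2-voxel translation to 0.37 voxels mean
endpoint error inside the tumour on the 48³ validation phantom. Saliency
weights are refreshed once per level. The exact objective is still
tracked every iteration and the best-scoring field is returned, so the
result never scores worse than the identity; a returned field whose
discrete Jacobian is nonpositive on more than 1% of mask voxels, or that
failed to improve on the identity, is flagged rather than silently
accepted (mirroring the need to exclude registration failures in
practice). Defaults `α = 0.1` and 100 iterations/level are configuration,
not doctrine — nothing in the underlying description pins them.

Accuracy is assessed where it is identifiable: endpoint error is averaged
over the tumour, because in constant background the data cannot determine
the field and any evaluation there measures the regulariser, not the
registration.

## Pre-processing

- **Bias correction** is a simplified smooth-field scheme with the N3
  contract (remove a smooth multiplicative field), not the N3 algorithm:
  iteratively accumulate the Gaussian-smoothed (default 24 mm) residual
  log-intensity into the field until updates fall below 1e-4. The field
  is rescaled so the corrected image keeps the mask-mean intensity
  exactly; this pins the field's mean to 1 to first order and makes
  downstream relative-enhancement features insensitive to the correction's
  global scale.
- **Histogram matching** is monotone piecewise-linear quantile mapping
  (default 256 knots) over a configurable mask, defaulting to the whole
  volume since the region used originally is unstated. A constant moving
  image maps to the reference median — any monotone convention works;
  this one is stable.
- **Resampling** uses voxel-centre alignment, preserves the physical
  extent, clamps out-of-extent samples to edge values, and offers linear
  and nearest modes (masks stay binary under nearest).

## The phantom and cohort generator

The phantom is an ellipsoidal tumour (default semi-axes 10×8×7 mm) with a
sigmoid boundary of configurable width (default 1.5 mm — crisp edges make
interpolation-error tests noisy), embedded in uniform background, with
per-class three-timepoint curves. The forward deformation is an affine map
about the tumour centre plus Gaussian bumps; the generator analytically
verifies `det ∇T > 0` at every grid voxel and rejects folding specs. The
early visit is synthesised by evaluating the tissue model at `T⁻¹(y)`
(fixed-point inversion, tolerance 1e-3 voxel, ≤ 50 iterations; analytic
inverse when the map is purely affine) with the early-visit curves, then
degrading *both* visits with independent smooth multiplicative bias fields
(smoothed white noise, log-amplitude default 0.05, 24 mm scale) and
additive Gaussian noise (default sd 1 against a baseline of 100). Truth
returned alongside: the displacement field, analytic per-voxel stretches,
the analytic Jacobian, the tumour mask, and the intended per-voxel change
of each kinetic feature. Defaults describe a mildly responding tumour
(0.92 linear contraction ≈ 0.78 volume ratio, one 1.5 mm bump,
post-contrast enhancement reduced ~10%).

The cohort generator draws covariates resembling a neoadjuvant breast
cancer trial population — age N(48, 9²), a binary race indicator
(white-or-Hispanic vs other, prevalence 0.8), three hormone-receptor
classes (HR+/HER2−, HER2+, triple-negative; probabilities 0.4/0.3/0.3) —
and imaging features from a parametric generator with plausible marginals
(Beta-distributed fractions, negative gamma-shaped entropies, log-normal
volume ratio, centred relative changes). Outcomes follow known models on
z-scored features: pCR is Bernoulli with baseline prevalence 0.30 (the
recorded-outcome prevalence the package's defaults emulate), RFS is
exponential with baseline rate 0.12/year and uniform administrative
censoring on `[0, h]`, where `h` is solved numerically so the expected
censored fraction equals `censor_rate` (default 0.70, matching a cohort
with roughly 30% events over a few years). `censor_rate = 1` degenerates
to pure administrative censoring. Because censoring is independent of the
linear predictor, Cox refits recover the generating coefficients (the
suite demonstrates a log-hazard of 0.693 recovered within 2 SE at
n = 400).

What the phantom does *not* emulate: MR physics (coils, k-space
artifacts), multi-site scanner variation, irregular tumour morphology,
infiltrative boundaries, and correlated feature distributions across
patients. Passing tests therefore demonstrate correctness of the
computations and recoverability under the stated models — not clinical
performance.

## The modeling protocol

Continuous covariates are z-scored before fitting, so reported odds and
hazard ratios are per standardised unit; `race` enters as 0/1 and hormone
status as an ordinal 1–3 score in listing order (HR+/HER2−, HER2+,
triple-negative), because the protocol reports a single ratio for it; a
two-dummy coding is available (`hormone_coding = "dummy"`). Rows missing
pCR are excluded from pCR analyses only.

`cv_select()` runs stratified 5-fold cross-validation (stratified on the
outcome or event indicator; a Cox training fold without events triggers a
fresh stratified draw, counted in the report). Ranking uses apparent
training-fold performance of baseline + candidate — resubstitution, as the
protocol describes, with no inner CV — with ties broken by lower training
AIC and then alphabetically (a documented rule makes the report invariant
to candidate order). The nested best-subset sequence (top-1, top-2, …) is
scored by training AIC; the winner is evaluated once on the held-out fold;
per-fold metrics are averaged. Everything is a pure function of
(table, seed).

`consensus_refit()` keeps features selected in ≥ 80% of folds (4 of 5),
refits baseline and augmented models on the full analyzed table, and
compares them by the likelihood-ratio test with df = number of added
features. Note the calibration caveat: LRT p-values are uniform under the
null for a *fixed* added set (the suite verifies this over 1000
replicates, KS p = 0.52), not after data-driven selection — the protocol's
p-values inherit the usual post-selection optimism.

`performance()` uses the rank (Mann–Whitney) AUC with midrank ties and
Harrell's C over usable pairs (shorter observed time must be an event;
score ties count ½); both are verified against brute-force pair
enumeration. `risk_stratify()` dichotomises the Cox linear predictor at
the cohort median (ties to low risk), compares groups by Kaplan–Meier
curves and the two-sided log-rank test, and reports the low/high ratio of
KM survival at the median follow-up time.

## Problem sizes and numerical tolerances

The validation suite uses 48³ phantoms for registration recovery (the
scale at which the tumour spans enough voxels for multi-resolution
matching while a full run takes ~20 s), 16³–40³ phantoms elsewhere,
n = 400 cohorts for selection/recovery checks, and 1000 replicates for
null-calibration checks (log-rank rejection 5.2% against a 5% ± 2% band;
LRT uniformity KS p > 0.01). Key tolerances: closed-form stretches vs SVD
1e-8; analytic map values at interior voxels 1e-6; volume consistency
(mean Jacobian × |FTV₁| vs the integrated partial-volume indicator of the
inverse-warped mask) 2%, reflecting one layer of boundary discretisation;
translation recovery 0.5 voxel and smooth-bump recovery 1 voxel of mean
in-tumour endpoint error.

## Known limitations

- The registration is a desk-scale baseline: single-channel attributes,
  one smoothing scale by default, no topology guarantees beyond the
  flagged Jacobian gate, and no validation against clinical deformations.
- FTV thresholds are placeholders, not the published clinical operating
  point; absolute volumes and volume ratios depend on them.
- The entropy index depends on the bin count and the per-tumour range;
  comparisons across tumours of very different sizes inherit histogram
  noise.
- The aggregate change `Δ_f` divides by the early-visit mean and is
  flagged undefined when that mean is near zero — a structural fragility
  of the definition, not of the implementation.
- Post-selection inference: cross-validated metrics are honest, but
  consensus-model p-values and the LRT are conditional on selection.
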