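---
title: "Eigenbrain decomposition and clinical decoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenbrain decomposition and clinical decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigenbrains)
```

This vignette documents the model implemented by `eigenbrains`, the
assumptions behind it, the tunable parameters, the synthetic cohort
generator used for validation, and the numerical and design choices that
were genuinely open.

## The model

### Preprocessing

Input is a cohort of co-registered 3D uptake volumes on a common template
grid (spatial normalization is assumed done upstream), a brain mask, and a
reference-region mask. Each scan is

1. **intensity normalized**: divided by its mean uptake over the reference
   region (the pons for FDG), yielding a dimensionless uptake ratio whose
   reference mean is exactly 1. The operation is invariant to global
   rescaling of the scan, which is what makes scanner- and dose-dependent
   global intensity irrelevant downstream. A reference mean below
   `1e-8` of the scan's global mean indicates a corrupt scan and raises an
   error rather than propagating huge ratios.
2. **smoothed** with a separable Gaussian kernel specified by its
   full-width at half-maximum (default 6 mm; `sigma = fwhm / (2*sqrt(2*log 2))`,
   converted to voxel units per axis). Boundaries are handled by mirror
   reflection, chosen so that a constant image is an exact fixed point —
   which in turn makes the smoothing contracts exactly testable. `fwhm = 0`
   is the identity.
3. **masked**: within-brain-mask voxels are extracted in a fixed,
   recorded lexicographic (column-major) order. Masking happens *after*
   smoothing; for the multiplicative normalization the
   normalization/smoothing order is immaterial away from boundaries, and
   this order matches the conventional pipeline description
   (normalize, smooth, then analyse within a mask).

A fingerprint of the mask and voxel ordering travels with the cohort
matrix, and projection of new scans refuses data extracted under a
different mask.

### Decomposition (BPR)

With `X` the subjects × voxels matrix, voxel columns are standardized to
mean 0, SD 1 (columns with SD below `1e-10` of the largest voxel SD carry
no between-subject information and are excluded, with indices recorded),
then subject rows are centred. On the processed matrix `Z` the n × n
matrix `Z Zᵀ` is eigen-decomposed and voxel-space eigenvectors are
reconstructed as `vᵢ = Zᵀ uᵢ / σᵢ` — the classical eigenfaces route, which
makes the computation O(n²p) instead of O(p³) (p is typically 10⁴–10⁵,
n ≈ 10²). Weights are `W = U diag(σ)`; the scale convention is
inconsequential for decoding because the regression layer re-standardizes
each weight column.

Two subtleties of this double standardization matter for interpretation:

- after voxel-wise standardization every retained voxel has unit
  between-subject variance, so a component's eigenvalue reflects *how many
  voxels* covary along it at least as much as the raw amplitude of its
  weights;
- subject-wise centring restricts the analysis to the zero-row-mean
  subspace, so eigenbrains code *relative* preservation versus reduction
  of uptake — they are inherently two-signed images.

**Component selection** defaults to the smallest k whose cumulative
variance fraction reaches 0.50, the conventional threshold for this
analysis; a fixed `k` can be given instead (e.g. `k = 8`).

**Sign convention.** Each eigenbrain and its weight column may be jointly
negated without changing anything observable. `fix_signs()` makes the
largest-magnitude voxel loading of each component positive; the output is
invariant to arbitrary sign flips of the input, idempotent, and leaves the
reconstruction `W vᵀ` untouched. All reported quantities are therefore
reproducible across platforms, but the orientation of any given component
remains a convention: a planted (or biological) association can surface
with either sign on its component.

**Numerical rank.** Components with `σ < 1e-7 σ_max` are treated as null.
The floor is set by the route: eigenvalues of `Z Zᵀ` carry relative error
of order machine epsilon, so singular values are only resolved to about
`sqrt(eps) ≈ 1.5e-8` of the largest; a threshold below that floor would
never fire, one much above it would mask genuine small components.

**Projection.** A new scan is mapped into an existing space by applying
the stored voxel means/SDs (dropping voxels excluded at training),
subtracting the scan's own mean over retained voxels, and taking dot
products with the eigenbrains. Projecting a training participant
reproduces that participant's stored weights to floating-point accuracy.

### Decoding

For each clinical variable, all k weights enter one regression jointly:

- continuous variables: OLS of the standardized outcome on standardized
  weights; coefficients are SD-per-SD effects; omnibus test is the overall
  F-test; R² and adjusted R² are reported;
- binary variables: maximum-likelihood logistic regression; `exp(β)` is
  the odds ratio per SD of weight; per-coefficient tests are Wald, the
  omnibus test is the likelihood-ratio test against the intercept-only
  model. The modelled level defaults to the alphabetically last level and
  is recorded. Complete separation is detected (fitted probabilities
  numerically at 0/1) and flagged on the result instead of silently
  returning diverged estimates — transparency was preferred over
  penalized fits, whose shrinkage would silently change reported odds
  ratios.

Missing data are handled by listwise deletion per variable, so each row of
the result reports its own n. The omnibus p-values of all variables form a
single Benjamini–Hochberg family (`fdr_bh()`, a validated wrapper over the
standard step-up adjustment); per-coefficient p-values are deliberately
reported unadjusted, with a significance marker at α = 0.05, since they
describe structure within a variable rather than independent hypotheses.
Standardization of the weights inside the fit makes all reported
quantities invariant to positive rescaling of the weights and
sign-equivariant under component flips.

### Cohort description utilities

`prevalence()` (percent present of documented, half-up to one decimal —
note base R's `round()` rounds half to even, hence the explicit half-up
rule used by printed clinical tables), `sex_ratio()`, `median_iqr()`
(type-7 quantiles, i.e. linear interpolation at positions `(n−1)q + 1`;
the convention is not universal, so it is fixed and documented),
`moans_to_z()` (`z = (scaled − 10)/3` for normative scaled scores with
mean 10, SD 3), `code_timed_floor()` (non-completed timed tests coded at
the z = −3 floor), and `suvr_classify()` (strict cut-offs: amyloid > 1.42,
tau > 1.23).

## The synthetic cohort generator

Since real clinical PET cohorts cannot be redistributed, validation rests
on a phantom generator with full ground truth.

**Geometry.** Default grid 32 × 38 × 32 at 4 mm voxels; an ellipsoidal
brain mask (semi-axes 40% of each dimension, ≈ 10,500 voxels) and a small
inferior box of constant uptake acting as the reference region, disjoint
from the brain mask. The scale keeps a full simulate–decompose cycle well
under a second, so hundred-replicate studies run in tens of seconds.

**Patterns.** Each planted pattern is a center–surround blob: a hard ball
minus a co-centred 1.4× surround scaled to make the pattern sum to zero in
the mask, both smoothed (8 mm FWHM) and jointly orthonormalized by
Gram–Schmidt (two passes, for 1e-10-level orthogonality). Built-in
placements: left occipito-parieto-temporal, its exact right mirror,
medial-temporal/limbic, medial-occipital, plus medial-frontal and
superior-parietal for configurations with more components. Zero-sum,
compact shapes are deliberate: the pipeline's subject centring confines
recoverable structure to the zero-mean subspace, so one-signed blobs (or a
shared diffuse background) would plant energy the decomposition cannot
represent cleanly, coupling components through the global mode.

**Identifiability by spatial extent.** Default blob radii decrease with
component order (28, 21, 14.5, 10 mm) in line with the strictly decreasing
weight SDs (3, 2.5, 2, 1.5). This is load-bearing: because voxel-wise
standardization equalizes every voxel's variance, the eigen-spectrum's
gaps are governed by each pattern's spatial extent rather than by the
weight SDs, and with near-equal extents adjacent eigenvalues come within a
few percent of each other — at which point n = 100 sampling noise freely
mixes neighbouring eigenvectors (mixing angle ≈ ρ√(λᵢλⱼ)/(λᵢ−λⱼ) with
sample correlation ρ ~ 1/√n). Extent ratios chosen here keep adjacent
eigenvalue ratios near 0.5, making both the component order and the
per-component recovery stable across seeds. A consequence worth knowing:
an exactly mirrored left/right pair of *equal* extent is resolvable as a
pair (its 2D subspace is stable) but not component-by-component; the
mirrored-pair construction is therefore exercised with equal radii where
only the pair structure is asserted.

**Images.** Subject i's volume is `baseline × (1 − Σⱼ w_ij P_j)` inside
the brain mask — hypometabolism is multiplicative on baseline, keeping
uptake positive and reference scaling realistic — plus independent
Gaussian voxel noise (default SD: 10% of the RMS planted signal over the
mask). The reference region is noiseless baseline, so reference
normalization is exact by construction. Values driven negative by extreme
weights are clipped at zero with a warning. Weights are drawn
independently per pattern; everything is bit-reproducible given the seed.

**Clinical links.** Continuous variables are linear in the standardized
weights plus Gaussian noise; binary variables follow a logistic link.
Defaults mirror the motivating application: age of onset rising with the
limbic pattern and falling with the occipital one (effects ±3 years per
SD, residual SD 2), aphasia odds rising with the left-lateralized pattern
(log-odds 0.9 per SD, i.e. OR ≈ 2.46). Link magnitudes were chosen once to
produce standardized coefficients of the size seen in clinical decoding
tables (|β| ≈ 0.3–0.6, ORs ≈ 2–3) and are fully config-exposed.

**What the phantom does not emulate** — and hence what passing tests do
not establish about real data: scanner physics (PSF, attenuation, partial
volume), spatially correlated noise (available as an option in spirit but
off by default; real PET noise is smooth), atrophy and registration error,
non-orthogonal or graded biological patterns, covariate structure
(age/sex confounding), and informative missingness in clinical tables.
Recovery results on the phantom demonstrate correctness of the machinery,
not clinical validity of any particular decomposition.

## Validation design and problem sizes

The test-suite checks at study-scale conditions use: 50 random matrices
(n ≤ 10, p ≤ 100) against a direct `svd()` oracle (singular values to
1e-9 relative, leading subspaces to 1e-6 rad); one n = 100 phantom cohort
for per-component pattern recovery (|r| > 0.9 against the planted
patterns in native uptake space) and 100 seeded replicates for
variance-order agreement (≥ 95%); n = 2000 for odds-ratio recovery and
1000 replicates at n = 200 for the omnibus type-I error (required within
0.03–0.07 at α = 0.05); 1000 random p-vectors against a brute-force
Benjamini–Hochberg step-up oracle (agreement to 1e-12). A noiseless
two-pattern cohort must be recovered exactly (principal angles < 1e-6);
the comparison there maps the planted patterns through the same
voxel-standardization and centring the decomposition applies, because that
is the space in which the decomposition operates — the map is diagonal and
invertible on retained voxels, so no information is lost in the
comparison.

## Known limitations

- Eigen-decomposition is unregularized PCA-type estimation: with few
  subjects, components whose eigenvalues are close are unstable as
  individuals (only their span is stable). Variance-fraction gaps should
  be inspected (`plot(fit)`) before interpreting single components.
- Reported p-values are conditional on the decomposition; weights are
  treated as fixed regressors, as is standard for this analysis style, so
  decoding inference does not propagate decomposition uncertainty.
- Logistic fits with small n and k = 8 predictors can separate; such
  results are flagged, not fixed — consider fewer components or exact
  methods in that regime.
- The package assumes co-registered inputs; no registration, partial
  volume correction or atrophy modelling is provided.
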