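---
title: "Methods: radiomics prognostic signatures in radprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics prognostic signatures in radprog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`radprog` builds and validates linear radiomics signatures for
progression-free survival (PFS) from segmented, co-registered 3D MRI
tumor volumes. This vignette documents the models and conventions the
package commits to, the tunable parameters, the synthetic cohort the
tests rely on, and the design decisions taken where the underlying
methodology left choices open.

## The prognostic model

Each patient contributes two scalar volumes (a T2-weighted-like and a
contrast-enhanced T1-weighted-like sequence) and one binary tumor mask.
The pipeline computes a fixed catalog of 970 features (485 per
sequence), z-scores them with discovery-set statistics, selects a sparse
subset by L1-penalized Cox partial-likelihood regression, and scores
patients with the linear Rad-score

$$\mathrm{RS}_i = c + \sum_k \beta_k z_{ik},$$

where $z_{ik}$ are normalized feature values, $\beta_k$ the non-zero
lasso-Cox coefficients and $c$ a centering constant. Patients with
$\mathrm{RS} \ge$ the discovery-set median are labelled high risk.
Validation fits multivariate Cox proportional-hazards models with the
clinical covariates alone (model 1) and with the Rad-score added
(model 2), separately on the discovery and validation sets, plus
Kaplan–Meier curves and log-rank tests within clinical subgroups.

A Cox model has no native intercept: $c$ is defined as the negative mean
of the linear predictor on the fitting set (plus a configurable offset,
default 0), so fitted Rad-scores are centred at 0. The published
signature shipped in `published_radscore_model()` instead uses its
reported constant (−7.995) and cutoff (−6.863) verbatim.

## Image variants

* **LoG filtering** (`apply_log_filter`). The 2D negated
  Laplacian-of-Gaussian kernel
  $K(x,y) = -\tfrac{1}{\pi\sigma^4}\bigl(1 - \tfrac{x^2+y^2}{2\sigma^2}\bigr)
  e^{-(x^2+y^2)/(2\sigma^2)}$
  is sampled on a radius-$\lceil 3.5\sigma\rceil$ grid (minimum 2),
  shifted to sum exactly to zero, and applied slice-wise in the axial
  plane with symmetric boundary extension. σ is measured in pixels;
  σ = 0 means no filtration. Applying the filter in 2D per slice (rather
  than in 3D) follows the printed 2D kernel; axial anisotropy of typical
  acquisitions (thick slices) also argues for in-plane filtering.
* **Wavelets** (`wavelet_decompositions`). A single-level undecimated
  (stationary) separable transform with Coiflet-1 analysis filters and
  symmetric extension produces 8 subbands (LLL…HHH, letters ordered
  x, y, z) of the same shape as the input, which makes the decomposition
  shift-consistent. The basis was not dictated by the methodology being
  reproduced; Coiflet-1 is the common choice in the radiomics literature
  this design follows, and the filter pair's orthonormal
  perfect-reconstruction identities are asserted in the tests.
* **Variant order**: original, LoG by ascending σ (default
  {1.0, 1.5, 2.0, 2.5}), wavelet subbands in lexicographic L-before-H
  order — 13 variants, indexed 1..13. The mapping from variant index to
  filter is a convention of this catalog; the source feature names only
  constrain the count, not the mapping.

## Feature catalog and conventions

Per sequence: 11 shape + 19 first-order features on the original image,
and (24 GLCM + 11 GLRLM) × 13 variants = 485; both sequences give 970.
These counts are asserted at catalog build time. Conventions:

* **Discretization**: equal-width binning of the in-mask intensity range
  into 32 levels (configurable); a constant region maps to level 1. The
  bin count is a common radiomics default; the methodology reproduced
  here did not state one.
* **GLCM**: co-occurrences at distance 1 voxel over all 13 unique 3D
  directions, merged (summed) into one matrix before symmetrization and
  normalization; merging was chosen over per-direction averaging for
  determinism and simplicity. Entropies use base 2. Degenerate cases:
  `correlation` is 1 when a marginal SD is 0; `IMC1` is 0 when
  `max(HX, HY)` is 0. `homogeneity1` is $\sum p(i,j)/(1+|i-j|)$ (the
  absolute-difference reading of "homogeneity 1").
* **GLRLM**: maximal runs of equal level along each of the 13 directions
  (out-of-mask voxels break runs), matrices summed over directions. Run
  percentage divides by (in-mask voxels × directions).
* **First order**: population moments; non-excess kurtosis; histogram
  entropy/uniformity on 32 equal-width bins; `robust_mad` over the
  10th–90th percentile values; sample-SD z-scores (matching `scale()` in
  the environment the original analysis used).
* **Shape**: volume is voxel count × voxel volume. Surface area uses a
  smoothed-indicator (coarea) estimator — the binary mask is smoothed
  with a small Gaussian (0.55 mm) and the gradient magnitude integrated —
  which compensates the voxel staircase; on digitized balls of radius
  6–10 voxels it reproduces the analytic area to within a few percent,
  and the derived sphericity of a radius-10 ball lies in [0.9, 1.0].
  Axis lengths are $4\sqrt{\lambda}$ of the coordinate covariance
  eigenvalues; the maximum 3D diameter is the largest pairwise distance
  between boundary voxel centres.

Features on filtered variants legitimately depend on out-of-mask voxels
near the tumor boundary (the filters read a neighbourhood); features of
the unfiltered variant depend on in-mask voxels only, and the tests pin
that down.

## Selection and validation choices

* The selector is penalized **Cox** regression (the outcome is
  time-to-event with censoring); the penalty is chosen by 10-fold
  cross-validated partial-likelihood deviance with a seeded fold
  assignment, at `lambda.min` by default (`lambda.1se` by option).
  Zero-variance features are flagged during normalization and excluded
  from selection rather than silently dropped.
* Normalization statistics, the signature, and the median cutoff are
  estimated on the discovery set only and applied frozen to the
  validation set; the pipeline's stage order enforces that validation
  outcomes are never read before the model is frozen.
* Cox models use Efron tie handling (lower bias; Breslow available),
  Wald 95% intervals, and report every covariate by default — backward
  AIC step-down is available by flag but off, so the model 1 / model 2
  tables stay directly comparable. The Rad-score enters model 2 as the
  continuous score by default, dichotomized by flag.
* Validation-set models are refit (not frozen coefficients), matching a
  per-set assessment design. On very small validation sets the full
  clinical model can be inestimable (monotone separation); the pipeline
  records the diagnostic for that model and keeps the others.

## The synthetic cohort

`generate_cohort()` emulates the data structure the pipeline expects, at
a deliberately reduced scale (default 28 × 28 × 14 voxel grids at
1 × 1 × 4 mm; n = 100 with a seeded 70/30 discovery/validation split,
round-half-up). Each tumor is an ellipsoid mask (jittered centre,
semi-axes about a third of the grid) shared by both sequences.

Intratumoral texture is a Gaussian random field with three components:
a shared band whose correlation length shrinks (2.6 → 0.5 voxels) and
whose weight grows as the patient's latent heterogeneity $h \sim U(0,1)$
rises, plus independent fine (σ = 0.7) and coarse (σ = 3.2) bands with
per-sequence random amplitudes. The shared band makes co-occurrence
features respond monotonically to $h$ (e.g. GLCM homogeneity falls
strictly from $h=0$ to $h=1$ at a fixed seed); the independent bands
give different filter scales and sequences partially independent
variation, which is what makes the planted prognostic signal
*attributable*: with a single latent, all texture features would be
mutually collinear and no selection method could identify five specific
columns among 970.

Survival follows a proportional-hazards design by inverse-transform
sampling: event times are exponential with rate
$h_0\exp(\mathrm{lp}_i)$, $h_0 = 0.012$ events/month, where
$\mathrm{lp}_i$ sums the z-scored *realized* values of five planted
catalog features weighted by ±1 per SD — co-occurrence cluster shade on
two wavelet subbands, first-order kurtosis, and co-occurrence maximum
probability on two filtered variants. These five were chosen because
their functional forms are distinct enough that no other catalog feature
nearly duplicates them (maximum inter-feature correlation ≈ 0.85, mutual
correlations ≤ 0.35 under the generator), making five-feature recovery a
well-posed identification problem; the two maximum-probability features
also load on $h$ (correlation ≈ −0.4), so higher heterogeneity shortens
survival. Effect magnitude 1 per SD corresponds to a per-SD hazard ratio
of e ≈ 2.7, of the order of published radiomics signature effects.
Follow-up ends by uniform dropout over the upper three quarters of an
80-month window, giving roughly half the cohort an observed progression.
Clinical covariates (age, sex, overall stage, hemoglobin, platelets) are
drawn independently of the hazard, mirroring a setting where the
clinical factors carry no prognostic signal; their marginals are set so
cohort medians fall within the reported discovery-set interquartile
ranges (the reported discovery and validation platelet distributions are
mutually inconsistent with any single sampling distribution, so the
discovery set anchors the defaults). Every output is a pure function of
the configuration and its seed.

What the generator does **not** emulate: MRI physics (bias fields, coil
inhomogeneity, partial-volume effects), registration error, irregular
tumor shapes, inter-feature correlation structure of real tumors, or
informative censoring. Passing tests therefore demonstrate the
correctness and internal consistency of the pipeline — not clinical
performance on real images.

```{r}
library(radprog)
cohort <- generate_cohort(cohort_config())
features <- extract_cohort_features(cohort)
disc <- cohort$clinical$split == "discovery"
norm <- zscore_normalize(features[disc, ])
model <- fit_lasso_cox(norm$table,
                       cohort$clinical$pfs_months[disc],
                       cohort$clinical$event[disc],
                       exclude = norm$stats$key[norm$stats$zero_variance])
```

## Statistical behaviour at the reference scale

At the reference conditions (n = 100, 70/30 split, effects ±1 per SD,
fixed seed) the test suite verifies that cross-validated lasso-Cox
recovers all five planted features with non-zero coefficients, that the
fitted Rad-score separates Kaplan–Meier curves (log-rank p < 0.05), and
that in model 2 the Rad-score hazard ratio exceeds 1 with a confidence
interval excluding 1 while every clinical covariate interval includes 1.
Recovery of *every* planted feature in *every* random cohort is not
guaranteed at ~50 events against 970 candidates — it is a statistical
property, asserted at the reference seed. The latent→survival rank
association among uncensored patients is likewise weak by construction
(event selection favours high linear predictors, compressing the latent
range), and is asserted at the reference seed alongside the structural
positive correlation between the latent and the planted linear
predictor.

Problem sizes used by the suite were chosen to keep a full run at a few
minutes on one core: unit oracles run on ≤5³ grids, smoke runs on 40
patients with 18 × 18 × 14 grids, calibration checks on 1000 simulated
two-group tables, and the reference cohort (the expensive fixture) is
built once and shared across test files.

## Known limitations

* The feature definitions follow the documented catalog, not a
  standardization-initiative certification; values can differ from other
  radiomics implementations in binning, aggregation, or boundary
  handling.
* The LoG filter is 2D axial by design; fully 3D filtering would give
  different variant features.
* The published-model constants apply to features normalized with the
  original study's (unavailable) statistics; applying them to new data
  requires a comparable normalization and is provided for arithmetic
  fidelity, not clinical reuse.
* Interaction terms between features are out of scope throughout.
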