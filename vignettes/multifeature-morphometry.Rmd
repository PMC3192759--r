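---
title: "Multi-feature structural MRI morphometry on synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-feature structural MRI morphometry on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(admri)
```

## What this package computes

Structural MRI carries several partly independent signatures of
Alzheimer's-type neurodegeneration: the hippocampus loses volume, the
cortical ribbon thins, tissue contracts regionally, and the overall
appearance of medial temporal structures drifts along the disease
continuum. `admri` implements a classification pipeline that extracts
one feature family per signature and asks whether combining the four
families separates clinical groups (healthy controls HC, stable and
progressive mild cognitive impairment S-MCI / P-MCI, and AD) better
than any single family:

* **HV** — bilateral hippocampal volume from multi-atlas segmentation:
  atlases are selected from a pool by image similarity in a region
  around the hippocampi, each selected atlas is non-rigidly registered
  to the query, the warped binary masks are averaged into a spatial
  prior, and a Gaussian-mixture EM refines the boundary under that
  prior. The feature is the label volume in mm³.
* **CTH** — statistical-ROI cortical thickness: the inner (WM/GM) and
  outer (GM/CSF) boundaries are linked by streamlines of the Laplace
  equation solved over the grey-matter ribbon; thickness is the
  Euclidean distance between linked endpoints (the t-link definition),
  smoothed on the surface graph with a heat kernel. Node-wise group
  t-tests pick nodes that are significantly thinner in the
  more-affected group, and each parcel containing such nodes
  contributes its mean thickness as one feature — so the number of CTH
  features depends on the contrast.
* **TBM** — multi-template tensor-based morphometry: each of a
  stratified library of template images is registered to the subject;
  the Jacobian determinant of each transform (J < 1 = local tissue
  loss relative to the template) is normalized into the space of a
  mean anatomical reference by resampling through the
  reference-to-template transform and multiplying by that transform's
  own Jacobian (chain rule). Voxelwise group t-maps define, per
  parcel, the "atrophic" voxels (significant and lower in the
  more-affected group), and the feature is the −log10(p)-weighted mean
  Jacobian over those voxels, averaged across templates. With the
  default 84-parcel partition this yields 84 features.
* **MBL** — manifold-based learning: z-scored intensity patches from a
  region around the hippocampi and amygdala feed a symmetrized k-NN
  similarity graph with Gaussian weights; Laplacian eigenmaps (solve
  `L y = λ D y`, drop the constant eigenvector) gives 20 unsupervised
  embedding coordinates per subject.

Raw features are harmonized before classification: a per-feature
linear age/sex model is fitted on healthy controls only and its
prediction subtracted from every subject, so normal covariate
variation is removed without touching disease effects; missing values
(cortical thickness fails on a configurable fraction of subjects) are
filled with training-set means; and forward–backward stepwise
regression (entry p < 0.05, removal p > 0.10) selects features inside
each training fold. Classification uses LDA with uninformative priors
(0.5/0.5) or an RBF-kernel SVM (libSVM via e1071), scored as CCR /
sensitivity / specificity on the percent scale, with 95% confidence
intervals taken as empirical percentiles of the run-level CCR
distribution.

## Evaluation protocols

`run_dataset1()` implements the three-part cross-validation: the
cohort is split into three equal parts; each part in turn supplies the
group statistics for the CTH/TBM statistical ROIs while the other two
thirds are evaluated with 100 random 5%-test / 95%-train repetitions;
results are averaged over all 3 × 100 runs. `run_dataset2()` is a
single fixed train/test split with ROIs from a third, disjoint id set.
Every fitted object records the subject ids it touched, and
`audit_ledger()` asserts, for every run, that train and test are
disjoint, ROI-source and evaluation subjects are disjoint, and no fit
touched a test subject. Covariate correction is refit on each training
fold's controls; for contrasts without HC (S-MCI vs P-MCI) the
correction uses the cohort's HC subjects, who are outside the
classification entirely. The MBL embedding is transductive — it is
built from all evaluation subjects jointly, which is legitimate
because the construction never sees a label — and is recomputed per
outer part.

## The phantom: what it emulates and what it does not

All of this is validated on a synthetic 3D phantom
(`make_template()`, `sample_subject()`, `sample_cohort()`) rather
than clinical images. The phantom is geometric: nested ellipsoidal
CSF / GM-ribbon / WM compartments, two hippocampus-like ellipsoids
with an adjacent amygdala-like blob, a ventricle inside the WM core,
and a deterministic 84-cone parcellation of tissue. A fixed smooth
"parenchymal texture" field (8 intensity units SD, 2-voxel
correlation length) is carved into the tissue in anatomy space, so it
deforms with the subject; without it the compartment interiors are
textureless and interior registration would be ill-posed in a way real
tissue is not. Each subject is synthesized by (i) adjusting the
anatomy parameters for group, age and sex — hippocampal semi-axes
scaled to the planted volume factor, the pial surface moved inward for
cortical thinning (the WM core is fixed and the CSF gap widens, as in
real atrophy), (ii) a random smooth B-spline deformation (1 mm
amplitude, 12 mm control spacing), (iii) a radial contraction anchored
at the ventricle wall planting the regional log-Jacobian shift —
anchored there because volume loss is registration-observable only
where it displaces a high-contrast boundary, (iv) a smooth
multiplicative bias field and additive Gaussian noise. Ground truth
(volumes, thickness, atrophy mask, the deformation itself) is recorded
per subject, so every feature extractor has a plant-and-recover test.

Default planted conditions (`effect_spec()`): hippocampal volume
factors 1 / 0.95 / 0.90 / 0.85 and thickness offsets 0 / −0.15 /
−0.30 / −0.50 mm for HC / S-MCI / P-MCI / AD, regional log-Jacobian
shifts 0 / −0.08 / −0.15 / −0.22, a −0.5%/year age slope on volume and
−0.008 mm/year on thickness applied to all groups identically (so
control-trained residualization is testable), 13% of subjects flagged
missing CTH (the deterministic count `floor(n·f + 0.5)`), noise SD 5
on a 10–160 intensity scale and bias amplitude 0.08. These magnitudes
sit in the range reported for mild-to-moderate AD morphometry and are
frozen: tests measure the pipeline against them, not the other way
around.

What passing tests do *not* show: the phantom has no MR physics (no
Rician noise floor, no k-space artefacts), no multi-site scanner
effects, no anatomical variability beyond smooth warps, and its
texture is far poorer than real parenchyma. Consequences are
quantified rather than hidden — e.g. voxelwise agreement between
per-template TBM maps of one subject reaches ~0.3–0.7 correlation on
the phantom where real images give near-perfect agreement, and
per-subject regional Jacobian calibration carries ~10% deformation
noise, so calibration checks use small group means.

## Registration engine

Affine alignment and free-form deformation share one engine: cubic
B-spline displacement fields on a control lattice covering the fixed
domain plus one boundary ring, optimized by L-BFGS on an analytic
gradient. The intensity gradient entering the chain rule is the exact
derivative of the trilinear interpolant — using a resampled
central-difference gradient instead creates false stationary points
the optimizer cannot escape. The default similarity is global
normalized cross-correlation; a windowed (local) NCC is available
(`metric = "lncc"`) and is the standard choice against strong bias
fields, though on this phantom's weak texture the global metric
performs better. Bending energy (squared second differences of the
control lattice, in mm units) regularizes; the transform maps fixed
world coordinates to moving world coordinates (pull-back), so a
Jacobian determinant below 1 means the fixed template contracts into
the subject — the "atrophic" direction when the template is the
reference. Registration is validated by recovery: a known 2-voxel
B-spline warp of the 48³ phantom is recovered with mean residual
< 0.5 voxel (measured by composing the recovered transform with the
true one), and self-registration from random initial affines returns
below 0.25 voxel displacement.

## Numerical and design choices

* *Statistical-ROI weighting.* The weight on a significant voxel is
  w = −log10 p with threshold α = 0.05, the most standard monotone
  choice; both are configurable. "Atrophic direction" is decided by
  the sign of the group-mean difference, making ROIs
  contrast-specific. Parcels with no qualifying voxel fall back to
  the unweighted parcel mean and are flagged.
* *EM segmentation.* Three mixture classes by default in the HV
  pipeline (hippocampus / partial-volume rim / white matter): a
  two-class model absorbs blurred rim voxels into the hippocampus and
  loses ~0.09 Dice at equal registration budget. The spatial prior is
  blended with a uniform floor (α = 0.9) to avoid zero-probability
  lock-in, and the M-step can update global mixing weights
  (`update_mixing`), which counteracts regression toward the atlas
  pool's mean volume; with spatially varying priors that update is
  approximate, so the exact-EM default keeps it off and the
  log-likelihood trace strictly non-decreasing.
* *Atlas selection.* Similarity is computed in a dilated region
  around the pooled hippocampus masks, so queries are matched to
  atlases of similar local anatomy; the pool should span the severity
  range for the same reason.
* *Thickness endpoints.* Both boundary crossings are located on
  indicator functions smoothed by 1 voxel — raw binary indicators
  leave staircase artefacts of ±0.45 mm in the endpoint positions,
  smoothed ones stay within ±0.3 mm on a 3 mm spherical shell.
* *Surface smoothing.* Heat diffusion with the unit-weight symmetric
  graph Laplacian over the 26-neighbourhood of inner-boundary voxels;
  the step count is calibrated from the mean squared edge length so
  the accumulated kernel variance matches (FWHM/√(8 ln 2))². The
  symmetric Laplacian preserves the global mean exactly.
* *Eigenmaps.* Solved through the symmetric normalized Laplacian with
  a dense eigendecomposition (cohort sizes are hundreds, not
  millions); eigenvector columns are unit-norm (scale-free in W) with
  the sign fixed so the largest-magnitude entry is positive; a
  disconnected graph is an error naming the component sizes, and
  `mbl_features()` grows k until the graph connects.
* *Stepwise selection.* Partial-F forward steps and coefficient
  t-test backward steps on a linear model of the 0/1 label, with
  deterministic tie-breaks by feature name; `p_enter ≤ p_remove` plus
  an iteration cap guarantees termination.
* *Counter-based seeding.* Every repetition of the protocols derives
  its seed from (master seed, part, repetition), so runs are
  reproducible and order-independent.
* *Degenerate inputs.* Variance floors in the EM; ridge conditioning
  of the LDA pooled covariance (1e-6·tr(S)/p, logged) when n ≤ p or
  the covariance is ill-conditioned; features unobserved on a
  training fold are dropped from that fold; test draws that miss a
  class are redrawn (capped and logged).

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run the full image pipeline
at 48³ voxels with 1 mm spacing (template, 16–40 subjects per
experiment, atlas pools of 5–8, template libraries of 3) and the
protocol machinery at feature-table scale (up to 1000 subjects per
group, 84 features, 3 × 34 to 3 × 100 repetitions). These sizes were
chosen so each check isolates one property at the smallest scale where
its signal clearly exceeds phantom noise; the pipeline itself has no
such limits, and `pipeline_config()` exposes all of them.

## Known limitations

* Per-subject regional Jacobian values are noise-limited at 1 mm
  resolution; only group-level TBM quantities are calibrated.
* The CTH node correspondence across subjects is voxel-binned in
  template space after (optionally affine) alignment, a coarser
  correspondence than mesh-based pipelines.
* The SVM wraps libSVM with the variance-scaled default bandwidth;
  the optional inner-CV grid search is small and deterministic.
* The phantom's four planted effects are independent by construction;
  real disease couples them, so combined-feature gains measured here
  are an upper bound on redundancy-free complementarity.
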