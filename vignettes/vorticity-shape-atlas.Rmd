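---
title: "Linking right-ventricular flow vorticity to biventricular shape"
author: "vortexatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking right-ventricular flow vorticity to biventricular shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vortexatlas)
```

## The problem

In adults with a surgically repaired right-heart defect, chronic pulmonary
regurgitation remodels the right ventricle (RV). Time-resolved phase-contrast
MRI ("4D flow") measures a 3-component velocity vector in every voxel of the
heart over the cardiac cycle, and the **vorticity** of that field,
$\omega = \nabla \times v$ (units s$^{-1}$), quantifies local swirl —
diastolic inflow vortices, outflow-tract recirculation. Statistical shape
atlases summarize biventricular geometry with a handful of principal-component
mode scores. This package implements the full analysis chain connecting the
two: velocity preprocessing, ROI vorticity quantification, atlas construction
and scoring, and covariate-adjusted regression that renders the independent
effect of vorticity on shape as a *morphometric mode*. Because patient MRI of
this kind is not generally shareable, a synthetic-data module generates shape
populations and analytic flow phantoms with known ground truth, so every stage
is testable end to end.

## Velocity preprocessing

A `VelocityField` is a `(nx, ny, nz, 3, nFrames)` lattice of velocities in
cm/s with voxel spacing in mm, a frame duration in ms, the velocity-encoding
limit (VENC) in cm/s, and an explicit diastolic frame range. Diastole is
metadata, not detected: clinical timeframe standardization is acquisition
specific, and the synthetic data labels its diastolic frames directly.

**Antialiasing.** Velocities beyond $\pm$VENC wrap by $2\,\mathrm{VENC}$.
`unwrapVelocity()` performs a single-wrap correction (usable range
$\pm 2\,\mathrm{VENC}$, matching an acquisition that recovers 0–300 cm/s at
VENC 150): per voxel and component it chooses offsets
$k_t \in \{-1, 0, 1\}$ minimizing the summed squared temporal second
difference of the trace. The minimization is an exact dynamic program over
the nine $(k_{t-1}, k_t)$ states with a vanishing ($10^{-9}(2\,\mathrm{VENC})^2 k^2$)
preference for $k = 0$ that breaks the global-offset degeneracy (shifting
every frame by $2\,\mathrm{VENC}$ leaves all differences unchanged). The
correction is exact for traces whose true second difference stays well below
$2\,\mathrm{VENC}$ per frame — smooth physiological traces — and is exercised
by a wrap/unwrap round trip on a phantom peaking at 170 cm/s with VENC 150.
A hard on/off temporal envelope defeats any temporal-continuity criterion at
the diastole edges, which is why the phantom generator also offers a smooth
$\sin^2$ envelope; wrapped *step* traces are not recoverable by construction.

**Background phase correction.** `correctBackgroundPhase()` fits, per
component, a polynomial of order 0–2 in the voxel coordinates to the
time-averaged velocity over a user-supplied static-tissue mask and subtracts
it everywhere. The fit is ordinary least squares, so polynomial offsets of
the stated order are removed exactly. The correction region is a user choice
because scanner-specific phase offsets have no canonical mask; order 1 is the
default.

**Denoising.** The preprocessing chain has a pluggable denoising slot with a
fixed contract — output grid, spacing, and frame count identical to the input.
The package ships `method = "none"` and an isotropic spatial Gaussian
(`sd` in voxels, truncated-kernel renormalization at boundaries; constants are
preserved everywhere and linear fields in the interior). Learned denoisers
honoring the same contract can stand in for it. On noisy rotation phantoms the
Gaussian reduces voxelwise RMSE severalfold, and windowed ROI vorticity agrees
with the noiseless value within a few percent — the property that matters for
the downstream statistics.

**Transvalvular volumes.** `computeTransvalvularVolumes()` integrates
$v \cdot n$ over a circular aperture on a static valve plane, by trilinear
interpolation on a raster of pitch ¼ voxel (sub-voxel accuracy with bounded
cost; halving the pitch changes the pipe-phantom forward volume by < 0.5%).
Forward and reverse volumes accumulate $\max(\pm Q, 0)\,\Delta t$ over the
cycle; the regurgitant fraction is reverse/forward and the indexed regurgitant
volume divides by body surface area (BSA). BSA uses the Mosteller formula
$\sqrt{hw/3600}$ — the simplest standard choice; swap in Du Bois externally if
preferred. A static plane (no valve tracking) is a stated limitation.

## Vorticity quantification

`computeCurlField()` evaluates $\nabla \times v$ with central differences on
interior voxels and one-sided differences at the grid boundary, spacing
converted mm→cm so cm/s velocities give s$^{-1}$ vorticity. Central
differences are exact on linear fields — the rigid-rotation phantom
($v = (-\Omega y, \Omega x, 0)$, $|\omega| = 2\Omega$) is reproduced to
machine precision — and second-order accurate in general: on the Lamb–Oseen
vortex, whose core vorticity has the closed form
$\omega_z(0) = \Gamma / (\pi r_c^2)$, the discrete estimate at the core is
exactly $\frac{1-e^{-u}}{u}\,\omega_z(0)$ with $u = h^2/r_c^2$, a deficit of
$\approx h^2/(2 r_c^2)$. Two practical consequences: the core must be
resolved by about 5 voxels per $r_c$ for 2% accuracy, and grid halving shows
the expected order-2 convergence.

ROI summaries (`summarizeRoiVorticity()`) sum and average the vorticity
*magnitude* over voxels whose centers fall inside a sphere — no
partial-volume weighting, so mean × count = sum holds exactly and
`roiBoundarySensitivity()` quantifies boundary leakage by dilating the
radius. Both the sum and the mean are retained; indexed reporting uses the
mean. `windowedDiastolicAverage()` implements the overlapping-timeframe
convention — the window is the central frame ±2 (configurable), truncated at
the diastole edges — and reports both the windowed mean and the windowed
maximum. The maximum is taken over per-frame means, not voxelwise maxima (the
alternative reading; flagged here because conventions differ).
`indexVorticity()` divides by BSA and by 100, the reporting scale
(1/s)/100 per m².

## The shape atlas

A `BiventricularShape` holds P corresponded points at end diastole (ED) and
end systole (ES) — fixed point order *is* the correspondence contract — with
anatomical labels (LV/RV endo- and epicardium, four annulus rings) and a
closed triangle surface per chamber. `generalizedProcrustesAlign()` removes
pose only: iterative alignment of every ED point set to the evolving mean by
the optimal rotation + translation (Kabsch with a determinant guard — never a
reflection, and never scaling: size is signal), tolerance $10^{-7}$ mm mean
movement, 100-iteration cap. Each subject's ED transform is applied verbatim
to its ES points, preserving systolic motion relative to ED.

`buildShapeAtlas()` concatenates each subject's ED and ES coordinates into a
6P-vector, centers, and eigendecomposes the sample covariance via SVD with
the $1/(n-1)$ convention; mode signs are fixed deterministically (largest
loading positive). `selectModeCount()` returns the smallest K reaching a
cumulative variance fraction (default 0.90, the conventional truncation).
`projectToAtlas()` scores a new subject after rigid alignment to the atlas
mean ED; scores are normalized by $\sqrt{\lambda_k}$, so they are in
population-SD units ("how far from the mean along this mode"). Raw scores are
retained in an attribute. Two numerical notes, both consequences of the same
fact: atlas modes are not exactly orthogonal to the rigid-motion manifold.
First, for shapes already in atlas pose, `align = FALSE` makes
projection/reconstruction an exact inverse pair (machine precision); with
re-alignment the round trip is exact only to $\sim 10^{-3}\sqrt{\lambda}$.
Second, score normalization divides by the *atlas* SD, so a regression
coefficient planted on raw scores of SD $s$ reappears on atlas scores
rescaled by $1/s$. Normalization by atlas SD rather than re-z-scoring within
a new study sample is the implemented convention (the alternative is a
one-liner on the returned scores).

Chamber volumes use the divergence theorem (signed tetrahedra over the
endocardial triangles, mm³→mL), exact up to surface discretization — a
1000-point half-ellipsoid LV is within 0.5% of its closed form. Mass is
(epi − endo volume) × 1.05 g/mL, the standard myocardial density; SV, EF,
and BSA-indexed variants follow their defining identities exactly.

## Association statistics and the morphometric mode

`univariateModeAssociations()` computes Pearson r per mode with a two-sided
t-based p (for standardized variables this is the slope test of the
univariate regression), after standardizing both sides. Bonferroni families
are *per variable* with family size K = number of modes tested, and the
family size is reported in the output — analyses correlating several
vorticity variables should widen the family themselves if they want a global
guarantee. `compareGroups()` uses a Welch t-test for two groups; for more it
gates one-way ANOVA on per-group Shapiro–Wilk normality at 0.05, falling back
to Kruskal–Wallis, and records which test ran.

`fitMorphometricMode()` regresses each retained mode score on the
standardized predictor plus standardized covariates (sex 0/1, height, weight,
age — the binary covariate is standardized too, for comparability). The
predictor's per-mode coefficients assemble the morphometric displacement
$\Delta = \sum_k \beta_k \sqrt{\lambda_k}\, \phi_k$, the shape change per +1
SD of predictor with covariate effects held fixed; `renderModeShapes()`
renders mean $\pm \alpha \Delta$ (default spectrum $\alpha = \pm 2$ SD).
The displacement is basis-independent within the retained span — it equals
the projection of the raw shape-on-predictor regression onto the retained
modes — which is why end-to-end recovery of a planted deformation direction
is insensitive to eigenvector mixing among planted modes. Rank-deficient
designs fail loudly, naming the collinear columns; missing data are not
imputed (complete cases only).

## What the synthetic data emulates — and what it does not

`generateTemplateShape()` builds a parametric two-chamber template: LV endo-
and epicardium as capped half-ellipsoids (the LV endocardial cavity has the
closed form $\tfrac{2}{3}\pi abc$), RV surfaces as crescent-modulated
half-ellipsoids wrapped around the LV, annuli as labeled point loops. ES is a
uniform per-chamber radial contraction toward the chamber axis (LV 0.65, RV
0.78), giving ejection fractions of $1 - f^2$ — 58% and 39% — and exact
volume ratios for testing. Correspondence holds by construction, standing in
for the interactive segmentation and diffeomorphic registration that produce
corresponded meshes from real images.

`generateShapePopulation()` draws shapes as template
$+\sum_k z_{ik}\sqrt{\lambda_k} D_k + \varepsilon_i$ with a random rigid pose
per subject (shared by ED and ES). The four default displacement fields
mirror the remodeling patterns reported for this disease — RV dilation with
basal bulging, apical bulging, tricuspid-annulus tilt, LV size change — and
are projected onto the complement of the rigid-motion tangent space before
orthonormalization: a tilt field is locally rotation-like, and without this
projection Procrustes alignment would absorb part of it, making planted-mode
recovery ill-posed. Mode variances should be read per point: a mode of
variance $\lambda$ over 6P coordinates displaces each point by
$\sqrt{\lambda/6P}$ mm RMS, and recovery against coordinate noise of sd
$\sigma$ is well-conditioned when that RMS comfortably exceeds $\sigma$ —
the package's sizing rule for simulated studies (defaults: per-point RMS
0.3–1.6 mm against 0.1–0.5 mm noise).

The planted association follows
$z_{k} = \beta_k p + c^\top \gamma_k + e$, with $p$ the sample-standardized
predictor ("average vorticity") and $c$ standardized covariates. The
generative order matters: `generateSubjectCovariates()` draws predictor and
covariates first and derives the scores, because inverting the relation
(solving for $p$ from pre-drawn scores) correlates the predictor with the
residual and biases OLS recovery — so the canonical chain is ground truth →
covariates → shape population, and `generateShapePopulation()` only draws its
own standard-normal scores when no truth is supplied.

Flow phantoms (`generateFlowPhantom()`) are analytic — rigid rotation,
Lamb–Oseen vortex, uniform pipe — confined to stated supports so ROI tests
have exact expectations, scaled by a binary or smooth diastolic envelope,
with additive per-component Gaussian noise (velocity maps are signed;
Rician magnitude noise is out of scope). One root seed with per-subject and
per-frame substreams makes every generator a pure function of its spec, and
subsetting a population stable. What the synthetic data does **not**
emulate: k-space physics, spatially correlated noise, eddy currents,
intra-voxel dephasing, segmentation error, or real chamber anatomy — so
passing tests demonstrate the correctness of the *computational chain*, not
clinical performance on scanner data.

## The pipeline

`runPipeline()` executes simulate → flow → atlas → associate from one YAML
config (see `inst/extdata/pipeline.yaml`; defaults: VENC 150 cm/s, 2.4 mm
voxels, ±2-frame diastolic window, 90% variance truncation, α = 0.05).
The flow stage ties each subject's vortex circulation to the planted
predictor, runs wrap → unwrap → background correction → denoising → curl →
ROI summary → windowed average → BSA indexing, and the association stage
regresses atlas scores on the *measured* indexed vorticity — the full loop
from planted truth to recovered morphometric mode. Stages communicate only
through files, so downstream stages re-run in isolation; CSV outputs are
byte-reproducible for a fixed config and seed (the run report's wall-clock
times are the only run-dependent field). Problem sizes used by the shipped
validation runs — e.g. n = 320 subjects, 20³ flow grids, 8 frames for the
end-to-end recovery; n = 200 subjects for atlas recovery; 500 replicates for
statistical calibration — were chosen so each check has the power it needs
(the cohort size sets the morphometric direction SNR — approximately
$\beta\sqrt{\lambda_3 n / \sum_k \lambda_{k,\mathrm{eff}}}$ — and n = 320 puts it
near 6, comfortably resolving the planted deformation) while a complete run stays in the minutes
range on one CPU.

## Known limitations

Single-wrap antialiasing only (true range beyond ±2 VENC is not recovered);
a static regurgitation plane; voxel-center ROI membership (no partial
volumes); atlas modes not exactly orthogonal to rigid motions (see the
projection notes above); synthetic anatomy is idealized (mild LV/RV surface
interpenetration at the septum is tolerated); and the atlas archive is an
RDS file rather than a language-neutral container.
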