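---
title: "Voxel-wise head motion and the RDI correction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise head motion and the RDI correction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdiconn)
```

## The problem

In-scanner head motion contaminates resting-state fMRI connectivity
estimates, and the contamination is not spatially uniform. A head rotation
displaces tissue in proportion to its distance from the rotation axis, so
two brain regions experience different apparent motion within the same
frame. Because motion-coupled intensity changes are partly shared between
regions, the Pearson correlation of two regional BOLD time courses — the
basis of functional connectivity — acquires a bias that depends on how
similar the two regions' displacement histories are. When head motion
behaves as a subject trait and groups differ in their typical motion
*pattern* (not merely its amplitude), group comparisons of connectivity can
report differences of purely mechanical origin.

`rdiconn` implements the full chain needed to quantify and correct this:
displacement geometry, BOLD change metrics, first-level denoising,
connectivity, and the second-level Regional Displacement Interaction (RDI)
correction, together with a synthetic-cohort generator that plants the
mechanism so every stage can be validated end to end.

## Displacement measures

Rigid-body realignment yields one homogeneous transform $T_t$ per frame
(identity at the mid-series reference). For a voxel at world position $x$,
the local displacement relative to the reference is
$d_t(x) = \lVert T_t^{-1}x - x \rVert_2$, and the stored voxel-wise field
is its absolute first temporal derivative
$D_t(x) = |d_t(x) - d_{t-1}(x)|$, with $D$ at the first retained frame
defined as 0. From $D$:

* **FD** (frame-wise displacement): spatial mean of $D_t$ over the brain
  mask — a per-frame scalar in mm/frame;
* **RD** (regional displacement): the same mean per atlas region — a
  region × frame matrix;
* **deltaRD**: $\overline{\mathrm{RD}_r - \mathrm{FD}}$ averaged over
  frames — one scalar per region, the spatially varying part of a
  subject's motion. By construction the voxel-count-weighted average of
  deltaRD over a partition is zero, which is what decorrelates it from
  mean FD in the second-level models.

Two conventions are configurable because the field admits both: the norm
of the 3-vector position change (default Euclidean; `norm = "rms"` divides
by $\sqrt3$), and the derivative sign (default absolute;
`signed = TRUE` for diagnostics). A `frame_to_frame = TRUE` variant uses
$\lVert T_t^{-1}x - T_{t-1}^{-1}x\rVert$, which upper-bounds the default
definition.

## BOLD change and motion-BOLD coupling

DVARS is the root mean square over mask voxels of the frame-to-frame
intensity difference; RDVARS is its per-region analogue, computed on
realigned data before any confound regression or filtering so that it can
be related to RD. Subtracting the global quantity from the regional one
gives the residual measures $rRD_r(t) = RD_r(t) - FD(t)$ and
$rRDVARS_r(t) = RDVARS_r(t) - DVARS(t)$; `coupling_analysis()` correlates
them (pooled over regions and frames, per subject) and relates that
regional coupling to the global FD-DVARS correlation across subjects. A
positive residual coupling means motion leaves a *spatially structured*
imprint on the BOLD signal beyond the global effect — the phenomenon the
RDI covariates are designed to absorb.

## First-level denoising and connectivity

Nine standard nuisance strategies are implemented over regional time
courses: NOREG, WMCSF (eroded white-matter and CSF means), GSREG (global
signal), COMPCOR (five principal components of a low-tSNR noise ROI),
each optionally with six rigid-body parameters (+M6), and the 36-parameter
expansion (9 core signals, their backward differences, and both sets
squared). Regression happens before filtering, matching the order the
strategies are defined in; `--filter-first` style reordering is available
through the function arguments. Filtering is a fourth-order Butterworth
band-pass (0.01–0.1 Hz) applied forward and backward for zero phase, with
odd-reflection padding so the passes do not ring against the series ends;
the temporal mean is removed so the output carries no DC. Connectivity is
the Fisher-Z transformed Pearson correlation of the denoised regional
series, with correlations clipped at $\pm(1-10^{-7})$ before `atanh` (or
dropped, by option). No spatial smoothing exists anywhere in the pipeline,
deliberately, so that neighbouring regions do not acquire artificial
shared signal.

CompCor's noise ROI is the lowest 2% of the brain-mask tSNR distribution
by default; the threshold is configurable and logged because no canonical
value exists. WM/CSF erosion is one 6-connectivity iteration.

## The second-level models

For each edge $(A, B)$, connectivity $Z_{AB,i}$ of subject $i$ is
modelled by ordinary least squares (the Gaussian IWLS fixed point):

* **STD**: $Z \sim 1 + \mathrm{GRP} + \mathrm{age} + \mathrm{IQ} +
  \mathrm{gender} + \overline{\mathrm{FD}}$;
* **STD+RDI**: STD plus $\Delta RD_A + \Delta RD_B +
  \Delta RD_A \cdot \Delta RD_B$.

The RDI triplet lets the expected connectivity of an edge depend on the
spatial motion pattern of each subject at both endpoints, and — through
the product term — on their *interaction*: connectivity rises when the two
endpoint displacements deviate from the global mean in the same direction
and falls otherwise. The effect of interest is the group coefficient
(t-test on residual degrees of freedom, two-sided); the contribution of
the RDI triplet itself is assessed by the nested F-test
$F = \frac{(RSS_{\mathrm{STD}} - RSS_{\mathrm{RDI}})/3}
{RSS_{\mathrm{RDI}}/(n - p)}$, by default on the models with the group
term excluded. A pooled variant stacks all edges of all subjects into one
model whose interaction coefficient summarises the direction of the
effect; its predicted surface over a deltaRD lattice is available through
`predict()`/`plot()`. The variance inflation factor of the effect of
interest is reported per edge, since the grouping factor and the motion
covariates can be related in motion-defined comparisons. Multiple-testing
control is Benjamini-Hochberg (a deterministic, assumption-light choice;
the local-fdr alternative used elsewhere in the literature gives similar
thresholds but depends on density estimation). Edge-wise results threshold
into statistical parametric networks at p < 0.01 or FDR q < 0.05.

Degenerate zero-residual fits are flagged rather than silently reported;
age and IQ enter unstandardised (standardising changes no test statistic).

## The synthetic cohort generator

The generator exists so that the pipeline's claims are testable against a
known ground truth. Its defaults are the study conditions used throughout
the tests: 2 × 30 subjects, 150 frames at TR = 2 s, a 24³ grid of 3 mm
voxels whose ellipsoidal "brain" holds CSF and white-matter cores plus 20
contiguous cortical parcels (k-means Voronoi cells on voxel coordinates),
and the following per-subject model:

* **Motion.** Six rigid-body parameter series follow stationary AR(1)
  processes (φ = 0.95 — motion is slow and persistent) with innovation
  SDs of 2×10⁻³ rad and 0.07 mm, scaled per subject by a lognormal
  amplitude trait (sdlog 0.35). These values were set so the simulated
  cohorts have mean FD ≈ 0.07 ± 0.03 mm, the scale reported for real
  developmental cohorts. Rotations act about a per-subject centre drawn
  around the group's mean rotation centre with 12 mm per-axis scatter;
  the scatter makes within-group displacement patterns heterogeneous, as
  they are in splits of a real population, keeps the grouping factor and
  the RDI covariates from becoming artificially collinear, and was
  calibrated so the matched-group null rejection rate of the end-to-end
  pipeline sits at its nominal level.
* **Latent signals.** Regional signals are band-limited (0.01–0.1 Hz)
  Gaussian processes mixed so their *empirical* correlation matrix equals
  the target exactly (QR-orthonormalised filtered noise times the
  Cholesky factor); the default target is a distance-dependent
  exponential kernel over parcel centres. Planting a group effect shifts
  selected edges by a fixed Fisher-Z amount in group 2's matrix, with an
  eigenvalue-floor repair if the shift leaves the positive-definite cone.
* **Artifact.** Each voxel receives $\gamma \, s(x) \, D_t(x)$ — intensity
  change proportional to its local displacement derivative. The default
  coupling γ = 8 (BOLD a.u. per mm/frame) puts the regional artifact SD
  at roughly a quarter of the latent signal SD, a moderate contamination;
  the sign field $s$ is +1 by default and can be randomised per voxel.
* **Noise.** iid Gaussian voxel noise (SD 7 a.u. against unit-SD latent
  signals); the region-level fast path adds its exact ROI average,
  $\mathcal N(0, \sigma^2/n_r)$, and equals ROI-averaging of the voxel
  model identically when σ = 0 — an equality the tests assert.

What the generator does *not* emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise, scanner drift, susceptibility
distortion, and sub-TR intra-volume motion. Passing tests therefore show
that the algorithms behave as specified under a controlled mechanism, not
that the correction removes every motion effect in real data — in
particular, spin-history and slice-interleaving effects may couple motion
to BOLD in ways no volume-level displacement model captures.

## The validation experiments

`motion_group_experiment()` is the package's headline study: cohorts with
identical latent connectivity whose groups rotate about mean centres
+40 mm vs −40 mm along z ("distinct"; group-mean displacement maps
anticorrelate) or share a centre ("matched"). Any significant group
difference in the distinct condition is artifactual. At the default
conditions the STD model reports roughly 12 significant edges per cohort
at p < 0.01 (the null expectation is 1.9 of 190), while adding RDI
returns the count to the null level and almost always to zero FDR
discoveries — with the caveat that at this deliberately extreme contrast
the grouping factor and RDI covariates are collinear (VIF ≈ 6), so in a
minority of low-artifact cohorts the RDI-adjusted count exceeds STD's by
sampling noise. `preservation_experiment()` plants ten true 0.3-Z group
differences under matched motion and measures how many of STD's
detections survive the RDI augmentation (all of them, at these
conditions). `glm_null_calibration()` and `rdi_recovery_sim()` check the
statistical core directly: type-I error at nominal level, uniform null
p-values for the t and F tests, unbiased interaction recovery
(β̂ = 0.400 at β = 0.4) with F-test power ≈ 1 at n = 200, σ = 0.2 on
standardised covariates. The recovery simulation is run in standardised
units deliberately: measured deltaRD values are of order 0.01 mm, so an
effect stated per-unit-deltaRD would be vacuous at mm scale, whereas the
standardised design makes effect size and noise directly comparable.

Problem sizes (50 + 20 + 20 cohorts, 5000 null simulations, 2000
uniformity replicates) were chosen as the smallest runs at which the
binomial/KS bands in the tests are meaningfully tight.

## Numerical choices and degenerate inputs

* Correlation clipping at $1-10^{-7}$ bounds Fisher-Z at ≈ 8.1; zero
  variance regions produce NA edges with a warning rather than an error.
* OLS uses QR throughout; rank-deficient designs fail loudly, naming the
  collinear columns; constant-zero nuisance columns (identity motion) are
  dropped with a warning.
* Zero-residual fits (interpolation) report p = 0 with a `degenerate`
  flag rather than NaN.
* Atlas thresholding is strict (> threshold); probability ties take the
  lower region id; merge-target ties take the larger neighbour, then the
  lower id — all deterministic.
* The "30" minimum ROI volume is interpreted in voxels by default because
  its unit is not recoverable; `unit = "mm3"` converts through the
  affine.
* Odd cohort sizes split 52/53-style, extra subject to group 1; every
  random draw in the cohort machinery and generator derives from a single
  integer seed and is recorded in the manifest.

## Known limitations

The RDI correction is a population-level regression device: it needs
sample sizes at which nine coefficients per edge are estimable, and it is
conservative when the variable of interest is genuinely correlated with
motion pattern (shared variance is absorbed by the covariates). The
per-edge GLM ignores dependence between edges, and the pooled model
ignores within-subject dependence across edges; both follow standard
practice and are flagged as such. Displacement is derived from
volume-level realignment, so everything faster than one TR is invisible.
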