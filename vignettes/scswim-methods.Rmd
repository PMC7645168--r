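---
title: "Structurally constrained susceptibility mapping: model, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structurally constrained susceptibility mapping: model, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inverse problem

Gradient-echo phase measures the B0 field shift produced by tissue magnetic
susceptibility $\chi$ through a convolution with the unit dipole response,
which in k-space is

$$D(\mathbf k) = \frac13 - \frac{(\mathbf k\cdot\hat b)^2}{|\mathbf k|^2},$$

so that $\varphi = \gamma B_0\,TE\;F^{-1}\{D\,F\{\chi\}\}$ with
$\gamma = 2.675\times10^{8}$ rad/s/T.  $D$ vanishes on the magic-angle cone
($54.7^\circ$ to $\hat b$), making single-orientation inversion ill-posed:
unregularized solutions streak, and thresholded k-space division (TKD)
systematically underestimates focal susceptibility.  The DC coefficient of
$D$ is undefined and set to 0, so every single-orientation map is mean-free
and must be referenced (we reference to CSF wherever absolute comparisons
are made).

The package's core estimator minimizes

$$f(\chi) = \tfrac12\,\lVert W\,(F^{-1}DF\chi - \delta B)\rVert_2^2
  + \lambda_1 \lVert P\,G\chi\rVert_1
  + \tfrac{\lambda_2}{2}\,\lVert R\,\chi\rVert_2^2 ,$$

where $W$ is the magnitude-proportional fidelity weight (normalized to unit
mean over the brain, zero where there is no usable signal), $G$ is the
forward-difference gradient (1/mm), $P = P_{\mathrm{struct}} \times
P_{\hat\chi}$ is a per-axis binary edge-exclusion mask, and $R \in [0,1]$
is a structural protection weight that is zero over deep gray matter, veins
and any region where the high-pass-filtered initial susceptibility exceeds
a threshold (default 250 ppb).  The two weights are tied,
$\lambda_1 = 0.005\,\lambda_2$, which puts the two penalties on a common
order of magnitude; $\lambda_2$ is chosen per echo by L-curve analysis.

### What the two penalties do

* The edge-gated $\ell_1$ term smooths wherever neither the structural image
  nor the initial susceptibility shows an edge.  With exact edge masks the
  true piecewise-constant anatomy incurs **zero** penalty, so the term can
  be strong without biasing region levels: it removes noise and streaks,
  while region means remain pinned by data fidelity.
* The $R$-gated $\ell_2$ term suppresses background oscillation but is
  switched off over every protected (high-$\chi$) structure, so iron-rich
  nuclei, veins, microbleeds and calcifications are not pulled toward zero.

### Units and the regularization scale

Fields are handled in ppm and susceptibility in ppb at every interface, but
the objective itself is evaluated on dimensionless quantities
($\chi_{\mathrm{abs}} = 10^{-9}\chi_{\mathrm{ppb}}$).  The regularization
presets (simulated: $\lambda_2 = \{6.81, 1.47, 3.16, 1.00\}\times10^{-3}$
in chain order; in vivo: $\{1, 1.47, 1, 1\}\times10^{-4}$) and the IRLS
smoothing $\varepsilon = 10^{-6}$ are calibrated on that scale.  A practical
consequence: tissue-scale gradients (tens of ppb per mm, i.e.
$10^{-8}$–$10^{-7}$ absolute) sit below $\varepsilon$, so ordinary texture
is penalized quadratically while only large unmasked discontinuities feel
the linear regime.  On this scale the solver converges in two to three
outer iterations on the simulated data.

### Solver

The $\ell_1$ term is smoothed as $\sqrt{x^2+\varepsilon^2}$ and minimized by
iteratively reweighted least squares; each outer iteration solves the
reweighted normal equations by preconditioned conjugate gradient.  The
preconditioner is circulant: the normal operator with every spatial weight
replaced by its mean is a convolution
($\bar W^2 D^2 + \lambda_1 \sum_a \bar V_a\,|G_a(\mathbf k)|^2 +
\lambda_2 \bar R^2$), inverted exactly in k-space, so CG only has to fight
the spatial variation of the masks.  A Jacobi (diagonal) preconditioner was
tried first and could not handle the Laplacian-dominated spectrum of the
reweighted operator; the circulant version cut outer iterations from ten to
about three and inner iterations by an order of magnitude.  Stopping rules:
relative $\chi$ change below `outer_tol` ($10^{-2}$), CG relative residual
below `cg_tol` ($10^{-3}$), caps `outer_max_iter = 10`, `cg_max_iter = 100`.
$\lambda = 0$ is accepted as the documented fidelity-only limit.  The three
axis terms of the $\ell_1$ penalty share one $\lambda_1$.

## Multi-echo pipeline

STAGE acquires two double-echo scans at 6 and 24 degrees (TE 7.5/17.5 ms
and 8.75/18.75 ms, TR 25 ms, 3 T).  The pipeline:

1. per-echo Laplacian unwrapping and scaling to ppm
   ($\delta B = \varphi / (\gamma B_0 TE)$);
2. a multi-echo R2\*-weighted iSWIM as the shared initial estimate
   $\hat\chi$ (also the basis of the $P_{\hat\chi}$ and $R_{\hat\chi}$
   masks; computed once, not per echo — the block-diagram reading of the
   method);
3. the constrained inversion chained through the echoes in the order
   low-flip TE1, high-flip TE1, low-flip TE2, high-flip TE2, each echo
   initialized with the previous echo's solution;
4. fusion $\chi = \sum_i w_i^2\chi_i / \sum_i w_i^2$ with
   $w_i = TE_i\,e^{-TE_i R_2^*}$, where $R_2^* =
   \ln(\rho_2/\rho_1)/(TE_1 - TE_2)$ averaged over the two flip angles.
   Exactly-zero voxels of an echo contribute no weight, so tissue lost at a
   long echo is repopulated from shorter ones.

### Phase aliasing at strong focal sources, and model-guided re-unwrapping

A 3 mm, 3000 ppb insert produces surface phase of ~12 rad at TE1 with
radial gradients far above $\pi$ per voxel: no spatial unwrapper can
recover that shell from a single echo, and the voxels must initially be
excluded (the phase-quality gate removes voxels whose unwrapped-phase
gradient exceeds $\pi$/voxel; a Rayleigh-floor gate removes voxels whose
magnitude is indistinguishable from background noise).  A first-pass
reconstruction then predicts each echo's phase, and the measured wrapped
phase is re-unwrapped as `model + wrap(measured - model)` — exact wherever
the prediction is within $\pi$ of the truth, however steep the true phase.
The second pass runs the refinement **sequentially through the echo
chain**, so the long echoes (whose aliasing is worst) are predicted from
freshly refined short-echo solutions.  This two-pass scheme is what closes
the last ~10–15% underestimation of the $\pm3000$ ppb 3 mm inserts; the
re-solved values agree with a control reconstruction given the exact
noiseless field to within a few ppb.

## The simulated phantom

The generator is a deterministic parametric stand-in for a labeled human
brain: an ellipsoidal cortex (GM) over white matter, paired ellipsoidal
deep-gray structures (CN, PT, GP, THA, RN, SN, crus cerebri) at
anatomically plausible offsets, medial ventricles (CSF), straight-sinus and
internal-vein capsules, and five spherical inserts — microbleed-like
(+3000 ppb r = 3 mm, +1000 ppb r = 5 mm, frontal white matter),
calcification-like (−1000 ppb r = 5 mm, −3000 ppb r = 3 mm, posterior
white matter) and a pineal-gland-like midline sphere (−3000 ppb r = 3 mm).
Tissue susceptibility, T1 and relative proton density take the standard
literature values tabulated in `tissue_table()`;
$R_2^* = 20/\mathrm{s} + 0.125\,\chi$ with the inserts fixed at 40/s and
zero proton density (signal voids).  Magnitudes follow the Ernst equation;
complex Gaussian noise gives a magnitude SNR of 10, referenced to the
white-matter signal level (the tissue whose SNR the specification of the
noise is naturally read against).  Anatomy scales with the grid; sphere
radii do not.

The default grid is 96 x 96 x 64 voxels at 1 x 1 x 1.5 mm.  That size keeps
a full two-pass, four-echo reconstruction in the single-digit minutes on
one CPU while leaving every structure at least ~40 voxels; a
`preset = "paper"` grid of 160 x 160 x 96 is available.  Because the true
anatomy of the original laboratory model is not published, structure
geometry is approximate: ROI means are robust to that (each structure is a
homogeneous region whose level is set by data fidelity), but whole-volume
RMSE/SSIM and anything sensitive to structure volumes should be read as
scaled-down analogues rather than exact reproductions.

What the phantom does **not** emulate: background fields from air-tissue
interfaces (SHARP is therefore off by default for simulated runs and
available for measured data), B1 inhomogeneity, flow, motion, noise
correlations, and realistic vascular trees (capsule primitives stand in
for veins).  Passing tests on the phantom therefore validate the
inversion, constraint construction, fusion and metrics — not robustness to
those acquisition effects.

## Baselines

* **TKD**: division by $D$ clipped at threshold 0.1, sign-preserving on the
  cone (the variant consistent with the later k-space refilling).
* **iSWIM**: TKD followed by 4 iterations of refilling the cone region of
  k-space with the spectrum of a thresholded high-susceptibility constraint
  map.  The detection filter is a k-space high-pass (complement of a
  separable 32-sample Hanning window) and the threshold defaults to
  250 ppb; neither value is fixed by the method's description, both are
  config-exposed.  Well-conditioned k-space samples are never modified.
* **COSMOS**: voxelwise-in-k weighted least squares across orientations,
  expressed by rotating $\hat b$ rather than resampling volumes; used as
  the noiseless-inversion control.

## Constraint construction details

Derivative noise levels for the edge thresholds ($\mu = 2.5\times$ noise)
use $1.4826\times$MAD over the brain mask — robust to the edges themselves.
If an input is piecewise constant (zero noise floor), edge detection falls
back to exact nonzero-gradient voxels.  $R$ is the max-normalized
structural image with hard zeros at protected voxels (a binary variant is
available for ablation); outside the brain $R = 1$, pinning the signal-free
exterior to zero susceptibility — leaving it unconstrained makes the
normal operator nearly singular there and was the single largest source of
slow convergence in development.  DGM labels are an input (phantom ground
truth here; any segmentation for measured data).

## L-curve selection

For each $\lambda_2$ on a log grid (default 8 points per decade over
$[10^{-5}, 10^{-1}]$) the solver runs to convergence; the corner of the
log residual vs log regularization curve is found by maximum curvature,
computed by three-point finite differences after monotone (PCHIP)
interpolation onto a dense grid.  On simulated data the scan can also
record RMSE against the ground truth; both criteria are reported because
either may be used to pick the final value.  The scan warns (but still
answers) if the residual is not monotone across the grid, which can happen
within solver tolerance.

## Evaluation

RMSE and SSIM are computed within the brain mask (the evaluation choice;
the padded exterior would dilute both).  SSIM uses a 3D Gaussian window
($\sigma = 1.5$ voxels), $K_1 = 0.01$, $K_2 = 0.03$, with the data range
taken from the reference inside the mask.  ROI statistics cover the entire
3D structure.  The accuracy regression zero-references both sides to their
own CSF mean, averages bilateral structures, and fits measured on
reference by ordinary least squares over the deep-gray set.

## Problem sizes used by the shipped tests and scripts

The quantitative checks simulate the default 96 x 96 x 64 phantom at
SNR 10 and reconstruct all four echoes with the simulation preset; faster
component tests use a 64 x 64 x 48 phantom with identical anatomy and a
range of 16–96 voxel cubes for operator-level identities.  These sizes are
the package's reference configuration for desk-scale reproduction; the
`paper` preset reproduces the full-size geometry when more runtime is
acceptable.

## Known limitations

* Laplacian unwrapping can absorb a harmonic component of the true phase;
  the interface accepts externally unwrapped phase for users with a
  path-following unwrapper.
* The model-guided second pass assumes the first pass is within $\pi$ of
  the truth at each reliable voxel; pathologies far outside the simulated
  susceptibility range may need a third pass (`refine_unwrap` applies one).
* The SHARP deconvolution threshold (0.05) is a convention; the method's
  description does not fix it.
* Manual fine-tuning of deep-gray segmentations, atlas-based segmentation,
  brain extraction and background-field-heavy in vivo processing are out of
  scope: masks and labels are inputs.
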