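---
title: "Registration methods for 2D functional ultrasound vascular maps"
author: "fusireg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration methods for 2D functional ultrasound vascular maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fusireg)
```

## Scope and data model

`fusireg` aligns 2D grayscale power-Doppler vascular maps across sessions
and animals and evaluates the result. The package works on three
containers: `FUSImage` (one frame, intensities nominally in [0, 1],
physical units only through the pixel spacing in mm), `FUSISeries`
(a frame stack with a frame rate, default 1 Hz), and `DeformationField`
(a dense per-pixel displacement). One convention is used everywhere and
is worth stating once:

* **Backward (pull-back) displacements.** For every fixed-grid pixel x
  the warped image samples the moving image at x + d(x). Warping is a
  single interpolation pass on the fixed grid, which is also where every
  optimizer evaluates its similarity. The impulse-translation unit test
  pins this convention down; a pure forward translation by (tx, ty)
  appears in the field as the constant (−tx, −ty).
* **Coordinates** are 1-based (row, col) at pixel centers, row = depth,
  col = width. Millimetres enter only via the spacing (default 0.1 mm
  isotropic, the standard fUSI acquisition geometry).
* **Out-of-view policy.** Samples that fall outside the moving image are
  filled with 0 and flagged in a validity mask, mimicking the dark
  background beyond the imaging window. Metrics can restrict to the
  valid region; the registration forces ignore invalid pixels near the
  borders.

## Interpolation

The default interpolator is cubic convolution (Keys kernel, a = −1/2).
It interpolates exactly at grid nodes — which the "warping with the
identity field is the exact identity" invariant requires — without the
prefiltering pass a true B-spline interpolator needs, and it preserves
speckle texture much better than bilinear interpolation. That matters
beyond cosmetics: on speckled images, any resampling blurs the texture
and *lowers* raw intensity similarity, so an optimizer that warps with a
strongly smoothing interpolator can prefer doing nothing. The demons and
TV inner loops therefore warp with the cubic kernel; bilinear and
nearest-neighbor remain available for tests and masks.

## Rigid registration

`registerRigid()` estimates an Euler transform (rotation about the image
center plus translation) coarse-to-fine over a Gaussian pyramid
(3 levels, factor 2, Gaussian antialiasing before decimation), with
three optimizer/metric pairings:

* **`es11`** — a (1+1) evolution strategy on mutual information
  (joint-histogram estimator, 32 bins by default, no Parzen windowing;
  the simplest defensible estimator since none is prescribed by the
  methods this mirrors). Gaussian mutation with the 1/5-success rule for
  step-size adaptation; an offspring replaces the parent when its
  fitness is better *or equal* (the tie goes to the offspring).
* **`cyclic1d`** — golden-section line search (via `stats::optimize`)
  on each parameter in turn, cycling θ, tx, ty with a contracting
  bracket until the relative cost change falls below 1e-6. The metric is
  the correlation ratio η(B|A), computed over iso-intensity sets of the
  reference after binning.
* **`blockmatch`** — per-block sub-pixel translations by normalized
  cross-correlation (integer search plus a fractional refinement on a
  1/upsample grid), then a closed-form 2D Procrustes rigid fit with
  five trimmed-least-squares iterations discarding the worst half of
  the correspondences.

All three expose a monotone best-so-far cost trace for testing. If the
similarity is undefined at initialization (e.g. a constant image), the
identity is returned with `converged = FALSE`.

## Non-rigid registration

**Demons** (`registerDemons`). Per iteration the force
d = (m − s)∇s/((∇s)² + (m − s)²) is evaluated on the currently warped
moving image; its negation (the backward-field update direction) is
smoothed with a small fluid kernel (σ = 1 px) before being added to the
field, and the accumulated field is smoothed with σ = `demonsSigma`
(default 1.5 px, 50 iterations per level, 3 levels). The fluid smoothing
suppresses speckle-driven force noise; without it the update is
dominated by per-pixel intensity noise and the iteration stalls. In
diffeomorphic mode the update is treated as a stationary velocity and
exponentiated by 6 scaling-and-squaring steps before composition, which
bounds folding at large deformations. A divergence guard stops a level
after five strictly consecutive increases of the mean squared intensity
difference and restores the best field seen.

**B-spline FFD** (`registerBspline`). A cubic control lattice (default
spacing 8 px, extended one spacing beyond each border for full support)
is optimized to maximize NCC over `samplesPerIter` (2000) random
continuous coordinates per iteration, re-drawn every iteration
(random-coordinate sampling). The NCC gradient reaches the control
points through the analytic tensor B-spline weights and the moving-image
gradient; steps follow μₖ₊₁ = μₖ − aₖ g(μₖ) with aₖ = a/(k + A)^0.602
(a = 1, A = 20) applied to the max-normalized gradient, so the gain is
calibrated in pixels of control-point motion. Optimization runs in two
stages — a lattice at twice the requested spacing first, then the
requested spacing warm-started from it. The optional bending-energy
penalty (squared second differences of the lattice) shrinks the spatial
gradient of the recovered field as its weight grows.

**TV-regularized local correlation** (`registerTV`). The objective is
−LCC(warp(m, d), s) + υ‖D(d)‖₂,₁, with D(d) the forward-difference
displacement gradient matrix (trailing border differences taken as
zero) and the group 2,1-norm pooling the four gradient components per
pixel. The realization is an inexact ADMM: an auxiliary variable
z = D(d) is updated by group soft thresholding with threshold υ/ρ
(ρ = 2), the field subproblem takes ten proximal gradient steps
(τ = 0.1) toward the data-updated field under the augmented-Lagrangian
coupling, and a scaled dual variable accumulates the constraint
residual. The data step is a demons-type force computed on *locally
z-scored* images — both images are normalized to zero local mean and
unit local variance over Gaussian-weighted `lccPatch` windows (5 px,
σ = 1), so matching the normalized intensities is precisely ascending
the patch-weighted local correlation. A direct pointwise gradient of
the LCC turned out to be ill-conditioned exactly at grid-aligned
displacements (the interpolation kink at integer offsets dominates the
correlation differential), while the normalized-demons step is bounded
(≤ 0.5 px) and well behaved. The data step is scaled by
1/(1 + υ/10) so that, as the regularization weight grows, the
stationary point of the iteration actually approaches the TV-flat
(near-constant) field the objective demands. A level stops when the
mean field update falls below 0.005 px; exhausting the iteration budget
instead raises a warning and returns the current estimate.

**Piecewise-rigid** (`registerPiecewiseRigid`). Overlapping patches
(32 px, 50% overlap) are registered for translation only by NCC with
sub-pixel refinement at 1/`upsampleFactor` (default 1/10) precision.
Patches with a peak correlation below 0.7 — flat texture, or content
that translated out of the field of view — are imputed from the mean of
their valid neighbors, and the patch-center shift grid is interpolated
bilinearly (constant beyond the outer centers) into a smooth dense
field. Note an information-theoretic limit the tests respect: when a
global shift moves content past the image edge, the trailing margin has
no correct correspondence and its field is necessarily an imputation.

**Combined** (`registerCombined`) runs rigid registration, warps, runs
the configured non-rigid method on the rigid-aligned image, and returns
the composition of the two backward fields
(d(x) = d_nr(x) + d_rigid(x + d_nr(x))). With a zero non-rigid
iteration budget the result is exactly the rigid field.

## Evaluation metrics

* **Shifted-NCC profile**: NCC at every integer shift, each normalized
  over its own overlap region (computed with FFT cross-correlations of
  the images, their squares and the support indicator), so a shifted
  copy attains an exact peak at its true offset. Shifts with less than
  `minOverlap` (10%) of the pixels are excluded: with a handful of
  overlapping pixels the correlation is ±1 noise. Full widths at half
  maximum are read off the per-axis profiles through the peak by linear
  interpolation and converted to mm.
* **MS-SSIM**: product form with the luminance term at the coarsest
  scale only, contrast·structure at every scale; 11 × 11 Gaussian
  window σ = 1.5, K₁ = 0.01, K₂ = 0.03 on dynamic range 1, standard
  five-scale exponents, 2 × 2 mean downsampling. The scale count adapts
  to the image (up to 5); with one scale and unit exponent it reduces
  exactly to plain SSIM, which is the test oracle.
* **HaarPSI**: local similarities of first- and second-level Haar
  wavelet coefficient magnitudes through a logistic (α = 4.2,
  C = 30 on a [0, 255] scale), aggregated with third-level
  low-frequency weights, inverse-logistic and squared; images are
  mean-pooled by 2 first. These are the method's published defaults.
* **Dice**: each image is binarized at its own Otsu threshold (256
  bins, maximizing between-class variance — equivalently minimizing
  within-class variance); both foregrounds empty is defined as 0 with a
  warning.
* **Jacobian analysis**: the determinant of the Jacobian of the *total*
  mapping φ = identity + d (central differences inside, one-sided at
  borders), its mean, and the folding rate = percent of pixels with
  det ≤ 0. Rigid fields are affine, so finite differences are exact and
  det = 1 to machine precision.

## Hyperparameter optimization

`gaFitness()` is the negated sum of NCC values of every registered
image against every reference (perfect alignment of n images to N
identical references gives exactly −nN). `runGA()` is a real-coded GA —
tournament selection of size 3, uniform crossover at 0.8, per-gene
mutation at rate 1/(number of genes), one elite — with the stopping
rules: a cap of 100 generations per variable, and a stall stop when the
relative change of the best fitness stays at or below 1e-6 for 50
consecutive generations. `runGridSearch()` enumerates the Cartesian
product (guarded at 1e5 points; ties broken by enumeration order).
`rotationalCV()` forms one fold per reference: the optimizer fits on
the remaining references (fitness summed over them), the fold's
parameters are scored on the held-out reference, and the best held-out
score wins (ties by fold order). GA internals are this package's
choices; only the stopping rules and the fitness are fixed by the
protocol being mirrored.

## Statistical parametric mapping

`percentChange()` converts a series to 100·(frame − baseline mean) /
baseline mean per pixel, flagging pixels with a non-positive baseline.
`spmMap()` runs a per-pixel two-sample test between the baseline-window
and post-window percent-change samples — Welch's t by default (the
per-pixel test is not prescribed anywhere authoritative; the choice is
recorded in the map's settings), or a tie-corrected normal-approximation
rank sum — adjusts p-values by Benjamini–Hochberg, thresholds the
adjusted values at α (default 0.001), and retains the top
`topFraction` (default 30%) of significant pixels ranked by |z| (ties
by p, then row-major index), with the exact cardinality
round(topFraction · #significant). The z-score is baseline-referenced:
(mean post %Δ − mean baseline %Δ) / sd(baseline %Δ). Degenerate pixels
get p = 1 and z = 0. Note the retention rule's consequence: if the
significant set coincides with the true activation, a 30% retention can
cover at most 30% of it — power analyses that ask for full coverage of
a known region should set `topFraction = 1`.

## The synthetic phantom: what it does and does not show

`generateVascularPhantom()` draws smooth random-walk centerlines
(spline-resampled control points) with Gaussian cross-sections
(FWHM 1.5–4 px, peak 0.45–1) over a multiplicative log-normal speckle
background (log-sd 0.25 on a 0.15 background), clipped to [0, 1], at
100 × 128 px and 0.1 mm spacing. Frame noise (additive Gaussian,
σ = 0.003) reproduces the near-perfect frame-to-frame stability of
anesthetized acquisitions (mean pairwise NCC ≥ 0.999). Cross-subject
cohorts warp a shared template by a smooth diffeomorphic field plus a
rigid pose and multiply by a global intensity gain (log-sd 0.05).

Ground-truth smooth deformations are low-frequency Gaussian random
fields (correlation length min(H, W)/8) scaled so the displacement
magnitudes fill most of the stated budget — the 98th percentile is
mapped to the maximum and magnitudes are clamped through a tanh, since
a cross-subject deformation moves large regions rather than one spot —
then verified diffeomorphic (det of identity + d strictly positive
everywhere), rescaling down if needed.

Passing recovery tests on these phantoms demonstrates that the
algorithms do what their definitions say under controlled conditions:
known transforms are recovered, similarity improves, geometric
integrity behaves as configured. It does *not* demonstrate performance
on real power-Doppler data, whose speckle statistics, vessel topology,
attenuation with depth and physiological nonstationarity the phantom
deliberately does not model. In particular, at these problem sizes and
regularization defaults all non-rigid methods remain almost fold-free;
the plain-demons-folds-most ordering that motivates the diffeomorphic
variant appears here only as a non-strict inequality.

## Known limitations

* 2D only; no velocity-field (SyN-style) registration beyond the
  diffeomorphic-demons analogue.
* The TV solver is an inexact first-order ADMM tuned for these image
  sizes, not a general-purpose convex solver.
* Intensities are normalized to [0, 1] at ingest; dB scaling is not
  applied.
* The rank-sum option uses the normal approximation, which bounds how
  small its p-values can be for short windows; with 10 + 10 frames it
  cannot reach FDR-adjusted significance at α = 0.001.
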