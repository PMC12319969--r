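# fusireg

Cross-subject alignment of 2D functional ultrasound (fUSI) vascular maps,
with the evaluation metrics, hyperparameter optimization protocol and
pixelwise statistical mapping needed to use it.

## The problem

Power-Doppler fUSI images the brain's vascular volume at ~100 µm
resolution. Comparing such images across sessions or animals — pooling
subjects for pixel-based analyses, building statistical parametric maps
from a group — requires registering every power-Doppler map to a common
reference. Brains differ in size, shape and pose, so the alignment is
partly rigid (an Euler transform: rotation θ about the image center plus
a translation t) and partly non-rigid (a dense backward displacement
field d, where the warped image samples the moving image at x + d(x)).

`fusireg` implements the main families of registration algorithms used
for this task, each authored in full:

* **Rigid**: (1+1) evolution strategy on mutual information, cyclic
  one-dimensional search on the correlation ratio
  η(B|A) = 1 − (1/(Nσ²)) Σᵢ Nᵢσᵢ², and block matching with normalized
  cross-correlation followed by a trimmed-least-squares rigid fit.
* **Demons**: iterates the force
  d = (m − s)∇s / ((∇s)² + (m − s)²) on the warped moving image m
  against the reference s, with Gaussian regularization; a diffeomorphic
  variant exponentiates the update by scaling and squaring.
* **B-spline free-form deformation**: a cubic control lattice optimized
  by adaptive stochastic gradient descent
  (μₖ₊₁ = μₖ − aₖ g(μₖ)) on randomly sampled continuous coordinates,
  maximizing NCC with an optional bending-energy penalty.
* **TV-regularized**: minimizes −LCC(warp(m, d), s) + υ‖D(d)‖₂,₁ — a
  patch-weighted local correlation data term with the isotropic total
  variation of the displacement gradient matrix — via an inexact ADMM
  with group soft thresholding.
* **Piecewise-rigid**: sub-pixel patch translations by normalized
  cross-correlation, interpolated into a smooth motion field.
* **Combined**: rigid alignment first, then any non-rigid method,
  composed into one field.

Around the registration core sit the standard evaluation suite
(shifted-NCC profiles with peak and FWHM, multi-scale SSIM, HaarPSI,
Otsu-binarized Dice, Jacobian determinant and folding-rate analysis of
deformation fields), a genetic-algorithm / grid-search hyperparameter
optimizer with rotational cross-validation over reference images, and
pixelwise statistical parametric mapping of percent signal change with
Benjamini–Hochberg FDR control and top-fraction retention.

Because public fUSI datasets are scarce, the package ships a seedable
synthetic phantom generator — curvilinear bright vessels with Gaussian
cross-sections over multiplicative log-normal speckle, at the standard
12.8 mm × 10 mm field of view (128 × 100 px at 0.1 mm) — plus
ground-truth deformations, cross-subject cohorts and activation-injected
time series, so every stage is testable against known truth.

## Worked example

```r
library(fusireg)
# two synthetic subjects sharing vascular anatomy
spec <- phantomSpec(seed = 7)
cohort <- generateCohort(spec, nSubjects = 2, seed = 42)
moving <- cohort$subjects[[2]]
fixed  <- cohort$subjects[[1]]

field <- registerNonRigid(moving, fixed, nonRigidConfig("demons"))
registered <- warpImage(moving, field)
evaluateRegistration(moving, registered, fixed, field = field)
```

```
MetricReport
  pre:   nccPeak=0.8215 ncc=0.7432 msSSIM=0.8015 haarPSI=0.4647 dice=0.7082
  post:  nccPeak=0.9926 ncc=0.9926 msSSIM=0.9976 haarPSI=0.9239 dice=0.9797
  JacobianMap: mean det 0.9852, folding 0.00%
```

Every similarity metric improves after registration: the shifted-NCC
peak rises from 0.82 to 0.99 (residual misalignment removed), Dice
overlap of the Otsu-binarized vascular masks goes from 0.71 to 0.98, and
the deformation is geometrically benign — mean Jacobian determinant
0.985 (≈ no net area change) with a 0% folding rate (no pixel with a
non-positive determinant, i.e. no topology violation).

`runPipeline()` drives the whole loop (simulate cohort → register every
subject to every reference → metric CSV + manifest), and
`groupSPMComparison()` reproduces the group-level mapping experiment:
pooling subjects *after* registration yields an activation map that
overlaps the true activation region better than pooling unaligned
subjects.

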