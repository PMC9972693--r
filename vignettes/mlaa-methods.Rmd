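---
title: "Joint activity/attenuation reconstruction for 2D TOF-PET: models and methods"
author: "mlaapet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint activity/attenuation reconstruction for 2D TOF-PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

PET attenuation correction normally relies on a CT-derived map of 511 keV
linear attenuation coefficients (the mu-map). Whenever the CT and the PET
emission data disagree — free-breathing motion displacing the liver dome
relative to a breath-hold CT, or metal implants corrupting the CT values —
the correction injects artifacts into the activity image: cold dome bands,
false-positive hot spots around implants, biased SUVs.

With time-of-flight (TOF) data the emission measurements themselves carry
enough information to estimate attenuation: MLAA jointly maximizes the
Poisson likelihood over both the activity image $\lambda$ and the mu-map
$\mu$, using only the emission sinogram. This package implements MLAA at
desk scale — a single 2D slice — together with the clinical reference method
(TOF-OSEM with a supplied mu-map, "CT-OSEM"), a synthetic phantom/acquisition
simulator that reproduces the three clinical scenarios (matched,
respiration-mismatched, metal-corrupted CT), and the SUV-based evaluation
layer used to compare the two reconstructions.

## Forward model

The scanner is a 2D ring: LORs are indexed by signed radial offset and angle
over 180°; the TOF coordinate $t$ runs along the LOR with 0 at the closest
approach to the axis. The Poisson mean is

$$\bar y_{i,t} \;=\; c\, a_i \sum_j l_{ij}\, w_{ijt}\, \lambda_j \;+\; s_{i,t},
\qquad a_i = \exp\Big(-\sum_j l_{ij}\mu_j\Big),$$

with $l_{ij}$ exact pixel chord lengths from a Siddon-type traversal (one ray
per LOR, no detector blur), $w_{ijt}$ Gaussian TOF bin weights (CDF
differences over the bin edges, kernel FWHM $= c\,\Delta t/2$ from the timing
resolution), $c$ a calibration factor, and $s$ a known additive (scatter)
expectation. The backprojector is the exact matrix adjoint of this operator
(verified to $10^{-9}$ relative in the tests). TOF kernels are evaluated out
to $7\sigma$ so that summing the TOF bins reproduces the non-TOF projection
to better than $10^{-6}$ where the kernel is contained in the binned range.

Default geometry: 192×192 image at 3.15 mm pixels, 192 radial bins at
3.15 mm, 100 angles, 13 TOF bins of 30 mm, 418.5 ps timing (62.73 mm spatial
FWHM). 100 angles (rather than a power of two times three) keeps the
10-subset clinical protocol an exact divisor of the angle count. The TOF bin
width sits well below the 62.7 mm kernel so binning adds little blur, and the
±195 mm TOF range covers any chord through the 600 mm FOV objects used here.

## Reconstructions

**CT-OSEM.** Ordered-subsets TOF-MLEM with the supplied mu-map:
$\lambda_j \leftarrow \lambda_j / s_j \cdot \sum_{i,t} c\,a_i l_{ij} w_{ijt}
\, y_{it}/\bar y_{it}$ over each angular subset, $s_j$ the subset
sensitivity. The start image is flat on the FOV, scaled so the forward model
matches the scatter-subtracted total counts (the EM fixed point does not
depend on this, it only shortens the transient). Three iterations of ten
subsets and a 4.5 mm FWHM Gaussian post-filter are the clinical protocol
defaults.

**MLAA.** Alternating updates: per subset, one TOF-MLEM activity sub-update
followed by one MLTR attenuation sub-update (a per-iteration sweep order is
available as a switch). The MLTR step is the standard additive Newton update
for the transmission-type likelihood on TOF-summed data,

$$\mu_j \leftarrow \mu_j + \frac{\sum_i l_{ij}\,(\bar y_i - y_i)}
{\sum_i l_{ij}\big(\sum_k l_{ik}\big)\bar y_i},$$

clipped to $[0, 0.5]$ cm$^{-1}$; the expected counts $\bar y_i$ use the
TOF-mass-weighted line integral so that model and TOF-summed data agree
exactly. The update is validated against a finite-difference Newton oracle
on a one-pixel problem where the separable surrogate equals the exact
Hessian.

**Scale constraint.** TOF data determine the joint solution only up to a
global activity/attenuation trade-off. The package resolves it the way the
clinical implementation does: the total tracer activity is computed in
advance by an OSEM reconstruction with the reference mu-map, and after every
full MLAA iteration the activity is rescaled so its total outside the
exclusion mask equals that prior exactly (a hard rescale; the attenuation
re-balances in subsequent MLTR updates). A penalty formulation would also be
possible; the hard constraint is simpler and testable to machine precision.

**Exclusion mask.** Pixels whose *reference* mu is below 0.02 cm$^{-1}$
inside the filled body support (air/lung-boundary zones, where respiratory
mismatch concentrates) or above 0.18 cm$^{-1}$ (dense implants) are excluded
from the prior total *and* frozen in the MLTR update. The reference text is
ambiguous about whether excluded regions leave the prior, the attenuation
update, or both; both are done here and both behaviours are reachable
through the exposed arguments. The low threshold is deliberately qualified
by the body support: a bare `mu < low` rule would freeze all exterior air.

**Initialization and estimation support.** Both images start uniform — but
on a data-driven object support rather than the whole FOV disk. The support
is the visible hull of the object: the scatter-corrected TOF-summed
projections are thresholded at 5% of each angle's maximum and the strips are
intersected by backprojection. Initializing on the full 600 mm FOV makes the
first iterations spend all their work carving ~25,000 water-filled pixels
down to a ~3,000-pixel object, and at the 3-iteration clinical protocol the
reconstruction is still far from converged; initializing on the support, and
restricting the MLTR surrogate chord $\sum_k l_{ik}$ to the support (pixels
outside are known air), makes the Newton steps scale with the object instead
of the grid. With this choice the 3-iteration cylinder reconstruction lands
within ~1% of the fill concentration, reproducing the reference behaviour of
the method at its clinical settings. The visible-hull estimate is robust to
hot lesions and to the interior suppression that defeats thresholding of
non-attenuation-corrected images; its cost is a convexified outline, a few
hundred extra margin pixels whose attenuation the MLTR has to remove.

**Post-filter.** Separable Gaussian, sampled kernel truncated at $6\sigma$
and normalized to unit sum, so the image total is conserved to $10^{-6}$ for
objects away from the grid boundary; the impulse-response FWHM is exact by
construction (verified by a Gaussian fit in the tests).

## Synthetic data

`make_uniform_cylinder()` is the uniformity phantom: a 20 cm water disk
(0.096 cm$^{-1}$) at 15.36 kBq/cc, the clinically representative
concentration used for parameter calibration. `make_torso_phantom(seed)` is
a coronal torso slice: soft tissue (1.0 kBq/cc, 0.096 cm$^{-1}$), two lungs
(0.25, 0.030), liver (2.5, 0.098), spine (1.5, 0.130), and 2–5 hot lesion
disks (8–12 kBq/cc, i.e. ≥ 3× liver contrast), at least one inside the
liver-dome band (the top 25% of liver rows — a fixed, testable stand-in for
the anatomical dome) and one outside. Dose/weight default to 70 MBq / 70 kg
so the liver SUVmean is 2.5, inside the clinical range. Rasterization is
pixel-centre-in-shape with no antialiasing, so every region statistic on the
truth images is exactly reproducible.

Acquisitions are Poisson draws from the forward model at 2×10⁶ expected true
counts and scatter fraction 0.2 — plausible single-slice statistics at which
noise is visible but recovery is stable. Scatter is a heavily smoothed copy
of the trues, scaled to the requested fraction and handed to the
reconstructor *exactly*, mirroring a pre-computed scatter estimate; this
isolates the joint-estimation mechanism from scatter-estimation error.

The three scenarios corrupt only the "CT" map handed to the reconstruction,
never the emission data: `matched` is the identity; `respiratory` translates
the horizontal band containing the liver dome caudally (default 12 mm,
vacated rows taking lung attenuation), producing the classic cold-dome
undercorrection; `metal` inflates the implant-region mu (default 3×, with
alternating streak ripples), producing the false-positive overcorrection.

**What the generator does not emulate:** continuous respiratory motion
during the acquisition (the emission data are always consistent with the
true anatomy), randoms, detector normalization and blur, 3D scatter,
anatomical variability beyond lesion placement. Passing tests therefore show
that the algorithm removes *attenuation-map* inconsistencies, not that it
compensates intra-scan motion.

## Evaluation layer

SUV = concentration × weight / dose (1 g ≈ 1 cc). Per ROI the package
reports SUVmean/SUVmax for both reconstructions, the percent difference with
CT-OSEM as reference, the dome-versus-middle liver variation (middle as
reference), and OLS regressions (slope $k$, squared Pearson $R^2$) over
organ ROIs and lesion groups; lesions are motion-affected iff they intersect
the dome or lung-base rows. Regressions include an intercept — the reference
figures do not state zero-intercept fitting, so the intercept is computed
and reported but never asserted. ROIs are drawn once from the truth label
map and applied identically to both reconstructions. The 40% threshold
lesion delineation keeps the 4-connected component of pixels at ≥ 40% of the
regional peak.

## Numerical choices and degenerate inputs

* TOF weights: bin-edge CDF differences, 7σ support (mass loss ~10⁻¹²);
  zero timing resolution degenerates to a single-bin indicator.
* MLEM: bins with $\bar y = 0$ contribute ratio 0; pixels with zero subset
  sensitivity are left unchanged; zero activity is absorbing.
* MLTR: pixels with zero curvature are skipped; relaxation defaults to 1 and
  is exposed; mu is clipped to $[0, 0.5]$ cm$^{-1}$.
* Scale constraint refuses a zero current total; zero data reconstruct to
  zero images.
* All reconstructions are deterministic; the only randomness in the package
  is the Poisson draw in the simulator, driven by an explicit seed that is
  saved and restored around the draw.

## Problem sizes used in the checks

The package's own quantitative checks run the full default geometry
(192×192 image, 192×100×13 sinogram) for the cylinder uniformity study, the
1–7 iteration sweep, and the three torso scenarios at 2×10⁶ counts; operator
oracles (adjointness, quadrature, chord sums, fixed points) use 16–48 pixel
grids where exhaustive and brute-force comparisons are cheap. The iteration
sweep reuses the deterministic prefix property of the ordered-subsets
schedule: a 7-iteration run snapshotted after each iteration is identical to
seven separate runs.

## Known limitations

* 2D single slice: quantities are ROI statistics, which the 2D analog
  exercises, but absolute noise levels differ from 3D multi-bed imaging.
* The visible-hull support convexifies concave outlines; strongly concave
  anatomy (arms-down imaging) would put some exterior air inside the
  estimation domain.
* The scale prior inherits any bias of the reference OSEM total — with a
  corrupted reference map the prior is slightly off; the mismatch
  experiments show the residual effect is small compared to the artifacts
  it fixes.
* MLTR convergence of the mu image itself is slower than the activity ROI
  statistics; the estimated mu-map at 3 iterations is adequate for
  correction but visibly smoother than a CT-derived map.
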