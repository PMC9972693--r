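# mlaapet

Joint maximum-likelihood reconstruction of **activity and attenuation** for
2D time-of-flight PET, with a synthetic acquisition simulator and a
quantitative SUV evaluation layer.

## The problem

Clinical PET attenuation correction uses a CT-derived map of 511 keV linear
attenuation coefficients. When CT and PET disagree — respiratory motion
shifting the liver dome against a breath-hold CT, or metal implants
corrupting the CT — the correction produces artifacts: cold bands at the
dome of the liver, false-positive hot spots around implants, biased SUVs.
With time-of-flight data the emission measurements themselves constrain the
attenuation, and **MLAA** estimates both images jointly from the emission
sinogram alone.

This package is a desk-scale (single 2D slice) implementation of that
workflow for people studying reconstruction behaviour: the TOF Poisson
forward model

    ybar(i,t) = c · exp(-Σ_j l_ij μ_j) · Σ_j l_ij w_ijt λ_j + s(i,t)

with exact Siddon chords `l`, Gaussian TOF bin weights `w` and a known
additive scatter term `s`; ordered-subsets **TOF-MLEM** (the clinical
CT-OSEM reference, `tof_osem()`); and **MLAA** (`mlaa()`), which alternates
TOF-MLEM activity sub-updates with **MLTR** Newton-type attenuation
sub-updates,

    μ_j ← μ_j + Σ_i l_ij (ybar_i − y_i) / Σ_i l_ij (Σ_k l_ik) ybar_i ,

resolves the global TOF scale ambiguity with a total-activity prior computed
from a reference OSEM reconstruction, freezes CT-threshold exclusion zones,
and post-filters with a 4.5 mm FWHM Gaussian. A phantom simulator generates
the three study scenarios (matched, respiration-mismatched and
metal-corrupted attenuation maps) with exact ground truth, and the
evaluation module computes ROI SUV statistics, percent SUV differences,
liver dome-vs-middle variation, 40%-threshold lesion delineation and
slope/R² agreement regressions.

## Worked example

The uniformity study: a 20 cm cylinder filled at 15.36 kBq/cc, a Poisson TOF
acquisition with 2×10⁶ true counts and 20% scatter, reconstructed with both
methods at the clinical protocol (3 iterations × 10 subsets, 4.5 mm filter).

```r
library(mlaapet)
geom    <- pet_geometry()
phantom <- make_uniform_cylinder(15.36, 200, geom)
sim     <- simulate_acquisition(phantom, geom, expected_true_counts = 2e6,
                                scatter_fraction = 0.2, seed = 7)
fit <- mlaa(sim$data, reference_mu = sim$truth$mu,
            control = recon_control(track_loglik = FALSE))
fit
#> MLAA reconstruction (3 iterations x 10 subsets, 4.5 mm post-filter)
#>   activity : 192 x 192, range [0, 18.9] kBq/cc
#>   mu       : jointly estimated, range [0, 0.133] /cm; prior total 1520 kBq

ref <- tof_osem(sim$data, sim$truth$mu, recon_control(track_loglik = FALSE))
roi <- disk_roi("central", 0, 0, 75, geom)
roi_stats(fit$activity, roi)$suv_mean   # 15.19
roi_stats(ref$activity, roi)$suv_mean   # 15.33
```

Both reconstructions recover the fill concentration inside a centred 15 cm
ROI: CT-OSEM (which is handed the true μ-map) to 0.2%, MLAA (which estimates
the μ-map from the emission data) to about 1%. `convergence_curve()` traces
the same ROI over 1–7 iterations; `plot(fit)` and `plot(fit, "mu")` show the
reconstructed images, and `fitted()`, `residuals()`, `logLik()` expose the
sinogram-domain fit.

End-to-end scenario studies (simulate → reconstruct both → evaluate → write
NIfTI/CSV/manifest) run through `run_experiment(experiment_config(...), dir)`
or the thin CLI in `inst/cli/mlaapet.R`; `torso_rois()` builds the organ,
lesion, dome and middle-liver ROIs from the simulated truth, and
`experiment_report()` assembles the comparison tables.

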