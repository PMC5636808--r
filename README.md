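# dmriTemplate

Robust template construction for diffusion MRI by q-space patch matching
and mean-shift mode seeking.

## The problem

Diffusion MRI templates are built by registering a population of
diffusion-weighted volumes to a common space and fusing the aligned
signals. Registration aligns anatomy, not microstructure: at a given voxel
the fiber orientations and configurations still differ across subjects, so
the usual voxel-wise average blurs fiber peaks and is dragged off by
discrepant subjects (a few crossing-fiber profiles contaminating a
single-fiber majority leave a spurious secondary peak in the average).
`dmriTemplate` is for researchers building single-shell diffusion
templates — or studying fusion rules on synthetic benchmarks — who want
the fused profile to follow the *majority* of the population rather than
its mean.

## The method

At every point (**x**ᵢ, **q**ₖ) of the joint voxel × gradient-direction
domain the D aligned subject signals are treated as draws from a
distribution whose **mode** is sought by mean shift. Candidates (j, l, d)
come from a local x–q neighbourhood (‖**x**ᵢ − **x**ⱼ‖ ≤ r_s, axis angle
within the search cone). Each candidate is weighted by similarity of
*q-space patches*: the directions within α_p of a patch centre are mapped
to the unit disc by the azimuthal equidistant projection, resampled on a
polar grid via a spherical-harmonic fit, and summarised by the magnitudes
|M_{n,l}| of complex exponential disc moments (−m ≤ n, l ≤ m) — a feature
vector invariant to in-plane patch rotation, so reoriented but equivalent
fiber geometry matches. Weights are

  w ∝ exp(−‖**M**ᵢₖ − **M**ⱼₗ(d)‖² / h_M²) · exp(−‖**x**ᵢ − **x**ⱼ‖² / h_x²),

normalised to sum to one, with h_M = √(2 β σ² N) (N the patch size) and
h_x = √2 σ_x. The template update is the Rician bias-corrected weighted
quadratic mean S̄ = √(Σ w S² − 2σ²), iterated from the bias-corrected
simple average S̄ = √(D⁻¹ Σ S² − 2σ²) (which is also the baseline method)
until the mean absolute change falls below γσ. Templates are scored by
PSNR = 10 log₁₀(MAX²/MSE) against ground truth and by the orientational
discrepancy OD — the symmetric average-Hausdorff angle between extracted
fiber peaks and the true axes under d(g₁, g₂) = cos⁻¹|g₁·g₂|.

The package also ships the synthetic dispersed-fiber benchmark the method
is validated on (Watson-distributed fiber orientations with
κ = 2/sin²(θ_T), multi-tensor signals on an 81-direction b = 3000 s/mm²
shell, complex-domain Rician noise at p% of the maximum signal 150), a
Q-ball peak extractor, and minimal NIfTI/bvec/bval I/O plus an `Rscript`
CLI (`inst/scripts/dmritemplate`) with `simulate`, `fuse`, `evaluate` and
`benchmark` subcommands.

## Worked example

Fuse a simulated population of 20 subjects whose two crossing fiber
bundles (90° apart) are dispersed across subjects with θ_T = 30° under 9%
Rician noise:

```r
library(dmriTemplate)

scheme <- defaultScheme(81, seed = 1)        # 81 directions, b = 3000
pop <- makePopulation(simulationConfig(thetaT = 30, noisePercent = 9),
                      fiberConfig("cross90eq"), scheme,
                      volumeDim = c(3, 3, 3), seed = 1)
avg <- simpleAverage(pop)
tpl <- meanShiftFuse(pop, fusionConfig(), verbose = TRUE)
#> iteration 1: tol = 2.80479 (threshold 0.0135)
#> ...
#> iteration 5: tol = 0.00748229 (threshold 0.0135)

psnr(templateSignals(avg), groundTruth(pop))   # 27.37 dB
psnr(templateSignals(tpl), groundTruth(pop))   # 30.96 dB

estimatePeaks(templateSignals(tpl)[14, ], scheme)
#> PeakSet: 2 peak(s)
#>   [1] ( 1.000, -0.006, -0.028)  value 213.1
#>   [2] ( 0.016,  1.000,  0.023)  value 210.3
```

The mean-shift template gains 3.6 dB PSNR over simple averaging, and its
extracted peaks sit on the two true axes (x and y) to about 1°. Averaged
over the 27 voxels, the orientational discrepancy against the true axes
drops from 11.2° (averaging) to 2.4° (mean shift): the iteration stops at
tolerance below γσ = 0.0135 and recovers both crossing arms that the
average blurs.

## Acceptance script

`scripts/acceptance.R` re-runs the synthetic benchmark from scratch with
the installed package: it simulates the dispersed-fiber populations,
fuses each with mean shift and with bias-corrected simple averaging, and
recomputes (t1) the mean PSNR improvement of mean shift over averaging
across the four fiber configurations at θ_T = 30° under 5% and 9% noise,
and (t2–t4) the mean orientational discrepancy of the averaging template's
peaks for the high-dispersion θ_T = 45° cells (single fiber at 9% noise;
60° crossing at 9% and 5%). Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
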