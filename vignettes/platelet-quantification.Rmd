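---
title: "Quantifying platelet activation from localization microscopy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying platelet activation from localization microscopy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(plateletquant)
```

## The problem

Platelets activate at sites of vascular injury: within about twenty minutes
of stimulation (e.g. by the PKC agonist PMA) a resting discoid platelet of
2--4 µm diameter spreads to a "fried-egg" shape of up to ~50 µm², its actin
reorganizes into bundles and nodules, the marginal band of microtubules
unwinds, and organelles -- mitochondria, granules, the dense tubular system,
the open canalicular system (OCS) -- are transported towards the cell
centre. Because all of this happens below the diffraction limit,
single-molecule localization microscopy (STORM) is the natural readout, and
the readout is inherently quantitative: activation state is characterized by
cluster counts and sizes, positive-pixel loads, radial density profiles, and
the directionality of cytoskeletal structure.

`plateletquant` implements that quantification chain as a reusable, tested
pipeline, together with a synthetic-scene generator that produces platelet
images with full ground truth. The generator is not decoration: because raw
clinical imaging data is rarely shareable, every stage of the pipeline is
validated by recovering known generator parameters, and the package's
verification studies are phrased entirely in those terms.

## Coordinate conventions

Positions are continuous, in nanometres, origin at the image top-left
corner, x rightward, y downward. Pixel `(i, j)` (row, column, 1-based) of an
image with pixel size `p` covers the half-open square
`[(j-1)p, jp) x [(i-1)p, ip)`; its centre is `((j-0.5)p, (i-0.5)p)`.
Orientations are degrees in `[-90, 90)`, measured from +x towards +y, so a
structure running along image rows scores 0° and along columns ±90°.

## The synthetic scene generator

A scene is a disk-shaped platelet (`platelet_geometry()`) carrying:

* **Organelle clusters** -- `n` centres drawn under a `radial_law()`:
  `uniform` over the disk; `centralized`, where the radial coordinate
  follows a half-Gaussian of scale `concentration` truncated at the disk
  radius; or `peripheral`, where the distance from the rim follows that
  half-Gaussian. These two-parameter families are chosen for testability:
  they span the range from homogeneous (resting) to strongly centralized
  (activated) patterns that radial profiling must distinguish. They are a
  modelling device, not a claim about the true biological placement law.
  Each cluster is filled with localizations uniform on its disk convolved
  with isotropic Gaussian localization noise (the "precision").
* **Filament fields** -- straight chords of the disk whose orientations
  follow an axial von Mises distribution (period 180°, sampled by the
  Best--Fisher algorithm); `kappa = 0` is isotropic, `kappa -> Inf`
  perfectly aligned.
* **Frames** -- `simulate_frames()` renders raw EMCCD-like acquisitions:
  per frame each emitter is independently active with probability
  `blink_on_prob` (memoryless blinking -- dark-state kinetics are not
  modelled because nothing downstream depends on them), contributing an
  integrated Gaussian PSF whose per-pixel mass is computed with the
  Gaussian error-function formula (never point sampling, so the fitting
  benchmark is exact even at small sigma/pixel), plus constant background;
  then Poisson shot noise and optional Gaussian readout noise. Stage drift
  displaces positions per frame; frame 0 drift is (0, 0) by definition.

Scenes record every generation parameter including the seed
(`synthetic_platelet_scene()$params`), and regeneration is bit-for-bit
reproducible. Default scene parameters are the activated-platelet study
conditions: platelet radius 1500 nm, six clusters of 410 nm diameter (the
actin-nodule scale; dense granules are emulated at 200--250 nm), 600
localizations per cluster (a realistic STORM labelling density for a
nodule-sized structure), localization precision 20 nm, 10 background
localizations/µm², and a minimum centre separation of 1.5 cluster diameters
-- nodules are discrete, non-overlapping adhesion structures, and the
separation keeps "how many clusters" a well-posed question.

What the generator does **not** emulate: 3D/astigmatic PSFs, fluorophore
photochemistry beyond memoryless blinking, label-density heterogeneity,
sCMOS pixel-dependent noise, or non-circular platelet outlines. Passing
recovery tests therefore demonstrate the correctness of the quantification
machinery, not robustness to every pathology of real data.

## Localization

`detect_spots()` finds 8-neighbourhood local maxima above a threshold, with
ties broken to the earliest raster pixel (so a symmetric noise-free spot
whose PSF peaks on a 2x2 pixel plateau yields exactly one candidate) and a
requirement to exceed at least one neighbour strictly (so flat frames yield
none). `fit_gaussian_psf()` then fits an integrated symmetric 2D Gaussian
plus constant background by Levenberg--Marquardt least squares
(moment-based initialization), in keeping with the 2D quantification scope
-- elliptical/astigmatic 3D fitting is out of scope. A fit is rejected
(`fit_ok = FALSE`) when the solver fails, the fitted sigma leaves
`[0.5, 5]` pixels, or the centre leaves the ROI; these bounds are the
package's own choice to reject noise and debris fits.

Accuracy is benchmarked against the Cramér--Rao lower bound of the Poisson
pixel model, computed numerically by `crlb_gaussian_psf()` from the model
expectation alone. At 1000 photons, background 10, sigma 1.2 px, the
least-squares fitter's RMS error sits near 1.1x the bound, comfortably
within the 1.5x acceptance band; noise-free spots are recovered to better
than 1e-4 px.

## Drift correction

Two estimators are provided because the underlying literature leaves the
choice open; which one to use is a configuration decision, not a scientific
claim:

* **fiducial** -- tracks one marker with a running reference (so large
  total drifts do not escape the search radius), requires >= 90% frame
  visibility, interpolates gaps linearly, and smooths with a running median
  (`runmed`, `endrule = "keep"`), which reproduces linear drift exactly.
* **block_xcorr** -- splits frames into contiguous blocks, renders each as
  a 10 nm histogram, and estimates block-to-block shifts from the FFT
  cross-correlation. Because sparse localization histograms make the
  correlation peak broad (it carries the structure autocorrelation) and
  noisy, the sub-pixel refinement is an iterated baseline-subtracted
  centroid over a ±8 px window rather than a three-point parabola; the
  parabola was measured to be an order of magnitude noisier here. Block
  shifts are interpolated linearly between block centres with linear
  extrapolation at the ends, and the frame-0 estimate is forced to zero.

The block method's verification study uses 2000 frames and ~96,000
localizations (16,000 per cluster) -- a realistic yield for a 2000-frame
STORM acquisition of a labelled platelet -- and recovers a 10 nm linear
drift to an RMS residual of a few nanometres at 15 nm precision.

## Rendering

`render()` reconstructs the super-resolution image either as a localization
histogram or as a sum of unit-mass discretized Gaussians; both conserve
total intensity exactly (kernels clipped at the border are renormalized).
The default rendering pixel of 20 nm sits below typical localization
precision, making downstream pixel statistics insensitive to the grid.

The quantification pipeline segments **gaussian-mode** renderings (kernel
s.d. = localization precision). This matters: on sparse integer histograms
Otsu's threshold degenerates to "any positive pixel", and the Gaussian tail
of a cluster's localizations then fragments into satellite components that
corrupt cluster counts. Gaussian-blob rendering -- the field's standard
STORM visualization -- restores a meaningful bimodal intensity histogram.

Duplicate-emitter merging across frames is deliberately not performed:
downstream statistics are pixel-based, not localization-count-based.

## Cluster segmentation

The fixed pipeline order is median filter → Otsu threshold → 8-connected
labeling → 1-pixel boundary dilation.

* The median filter (default 3x3, mirrored edges) suppresses isolated
  single-localization pixels.
* Otsu's threshold maximizes the between-class variance over a 256-bin
  histogram spanning the image's min--max range, with exact within-bin
  intensity sums and ties broken towards the smallest threshold; the mask
  is `intensity > threshold`. A constant image is a degenerate-input error.
* Labeling uses 8-point connectivity (diagonal neighbours join) with
  deterministic raster-order labels. "Dilated by 1 pixel" is interpreted as
  one pass of the full 3x3 structuring element, consistent with the
  8-connectivity choice, and is applied to the *label map* after labeling
  (so dilation can never merge counts); both post-dilation (headline) and
  pre-dilation ("core") areas and equivalent diameters are reported, since
  dilating boundaries before or after measuring sizes is a genuine
  ambiguity. Equivalent diameter is `2*sqrt(area/pi)`.
* Clusters touching the image border are kept by default
  (`exclude_border = FALSE`); no exclusion rule is assumed.

Under the default nodule-scene conditions, cluster counts are recovered
exactly and the cohort-mean post-dilation equivalent diameter runs ~13%
above the generating 410 nm (the dilation shell plus the precision skirt),
inside the 15% verification band; the core diameter is essentially
unbiased.

## Radial centralization profiles

`radial_density()` bins the distances of organelle-positive pixels from the
platelet centroid, normalized by `R` = the maximum centroid-to-boundary
distance of the **actual mask** -- spread platelets are not ideal disks, and
this definition needs no circularity assumption. Per-bin density fractions
are count fractions divided by annulus **area fractions measured on the
mask** (pixels per annulus), so a uniform pattern reads 1.0 in every bin
and `sum(density * areafrac) = 1` holds identically. Pixels are the default
unit; a localization mode (pass a `loc_table`) is provided for
localization-level profiles. `n_bins` defaults to 10.

## Directionality

`orientation_histogram()` computes 3x3 Sobel gradients, assigns each pixel
the orientation perpendicular to its gradient, and accumulates squared
gradient magnitude (suppressing flat background) into 90 bins of 2°,
normalized to sum 1. `fit_direction_peak()` circularly shifts the histogram
so its maximum bin is central (avoiding wrap-around bias), fits
`baseline + amplitude * exp(-(theta-mu)^2 / (2 sigma^2))`, and reports the
amplitude above baseline as the **non-homogeneity** statistic -- near zero
for isotropic images (a flat histogram reads amplitude 0, non-converged),
increasing with orientation concentration. The absolute peak height is also
emitted for users who prefer it; amplitude-above-baseline is the primary
definition because it is invariant to the isotropic floor.

The verification studies use dense fields of 300 filaments x 200 points,
rendered at 10 nm/px: a power consideration made part of the design. The
±2° orientation-recovery check is only meaningful if the scene's own
realized mean orientation is estimable to ~1° (the axial von Mises
scene-mean s.d. scales as `1/(2*sqrt(kappa * n))`), and the isotropy
calibration (isotropic amplitudes below the 5th percentile of kappa = 1
amplitudes) requires the isotropic noise amplitude to sit below kappa = 1's
lower tail. The finer 10 nm rendering grid matters for the latter: with a
rendering kernel of only ~1 px, Sobel orientation histograms carry a
systematic pixel-grid anisotropy (spurious mass at 0°/±45°/±90°) that puts
a floor under the "isotropic" amplitude; widening the kernel to 2 px
removes it. Sparser scenes or coarser grids leave the two distributions
overlapping.

## Correlative STORM/EM registration

`estimate_similarity()` is the closed-form least-squares (Procrustes)
similarity estimate -- isotropic scale, rotation, translation -- from
matched fiducial coordinates; reflections are excluded (the determinant is
constrained positive) because STORM/EM overlays are not mirrored, and a
full affine model is deliberately not the default. Any n >= 2
non-coincident pairs are accepted; `rms_residual` is reported so users can
judge adequacy. It is defined as the **per-coordinate** RMS, so isotropic
fiducial jitter of per-axis s.d. `s` yields a residual near `s`
(with `n` pairs, expectation `s * sqrt(1 - 2/n)`). `apply_transform()` maps
point sets exactly and resamples images bilinearly; brightness/contrast
adjustments of an overlay are display-only and outside the geometric
contract.

## Morphometric summaries

`summarize_timepoints()` groups per-platelet metrics by activation stage and
reports arithmetic mean ± standard deviation with the n−1 denominator,
averaging **per platelet first** (never pooling clusters or pixels across
platelets -- the per-platelet mean is the sampling unit). `nodule_offset()`
is the area-weighted cluster centre of mass minus the platelet centroid;
`size_distribution()` histograms equivalent diameters; `platelet_area()`
converts the mask to µm². Hypothesis testing between stages is out of
scope: the summaries are descriptive by design.

## Pipeline, I/O and determinism

`run_pipeline()` chains simulate → (localize | load) → render → segment →
radial/directionality → summarize, writing plain-text CSV/JSON artifacts
with a versioned header line and a `provenance.json` (resolved
configuration, seed, package version). Doubles are written with 17
significant digits so files round-trip bit-exactly; this is what makes
"skip the localization stage and supply the equivalent table" produce
byte-identical downstream outputs. All randomness flows from the single
configured seed, so deleting the output directory and re-running reproduces
it exactly. A thin command-line wrapper (`inst/cli/plateletquant.R`,
dispatching through `cli_main()`) exposes the `simulate`, `localize`,
`driftcorr`, `render`, `segment`, `radial`, `directionality`, `register`,
`summarize` and `run` subcommands.

## Problem sizes used in the verification studies

The bundled studies (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run at sizes chosen to make each property decisive
while keeping a full run in minutes on a laptop: 100 random images for the
Otsu oracle; 200 spots for the CRLB benchmark; 2000-frame drift series;
10^4 uniform positives for radial calibration; 100 seeded runs for
centralization detection; 20 scenes for cluster recovery; 300-filament
scenes across kappa in {0, 1, 4, 16} (20 seeds each) for directionality;
100 jittered registrations; two 40-platelet cohorts for the spreading
ratio; and a two-fold repeated demo pipeline for bit-reproducibility.

## Known limitations

* 2D only: no astigmatic z-estimation, no two-color channel registration.
* Blinking is memoryless; localization density, not photokinetics, is the
  tested variable.
* Otsu-based segmentation assumes a dominant background mode; extremely
  sparse histogram renderings should be segmented from gaussian-mode
  images (the pipeline default).
* The radial profile's outer radius comes from the platelet mask; for
  fragmented masks the boundary distance is only as good as the mask.
* `nlsLM` peak fitting of directionality histograms can report small
  positive amplitudes for noisy isotropic images; calibrate against
  isotropic scenes (as the bundled studies do) rather than against zero.

## A worked example

```{r example, eval = FALSE}
scene <- synthetic_platelet_scene(seed = 1)          # 6 x 410 nm clusters
img <- render(scene$locs, 20, "gaussian", gaussian_sd_nm = 20,
              dim_px = c(175, 175))
seg <- segment_clusters(img)
seg$stats[, c("cluster_id", "pixels", "eq_diameter_nm")]

ctr <- scene$geometry$centroid_nm
xc <- (seq_len(175) - 0.5) * 20
pm <- platelet_mask(outer((xc - ctr[2])^2, (xc - ctr[1])^2, "+") <=
                      scene$geometry$radius_nm^2, 20)
radial_density(seg$mask, pm, n_bins = 10)
plot(radial_density(seg$mask, pm, n_bins = 10))
```
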