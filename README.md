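# plateletquant

Quantitative analysis of platelet activation from single-molecule
localization microscopy (STORM), for cell biologists and imaging scientists
who need reproducible, per-platelet morphometrics rather than pictures.

Platelet activation reorganizes the cell below the diffraction limit: a
resting ~2 µm discoid platelet spreads to a fried-egg shape of tens of µm²,
actin condenses into nodules, and organelles (mitochondria, granules, the
dense tubular system, the open canalicular system) centralize. STORM
resolves this, and `plateletquant` turns the images into numbers:

* **Localization** — spot detection and integrated-Gaussian PSF fitting
  (`fit_gaussian_psf`), benchmarked against the Cramér–Rao bound
  `CRLB = sqrt([I(θ)⁻¹]ₓₓ)`, `I(θ) = Σₖ (∂μₖ/∂θ)(∂μₖ/∂θ)ᵀ/μₖ` of the
  Poisson pixel model; fiducial and block-cross-correlation drift
  correction; histogram/Gaussian rendering with exact mass conservation.
* **Cluster segmentation** — the standard chain median filter → Otsu
  threshold (argmax of the between-class variance ω₀ω₁(μ₀−μ₁)²) →
  8-connected labeling → 1-pixel boundary dilation, with per-cluster area,
  equivalent diameter `d = 2√(A/π)`, centroid and positive-pixel counts.
* **Centralization profiles** — annulus-normalized radial density
  `fᵢ = (cᵢ/Σc) / aᵢ`, where `aᵢ` is the area fraction of radial bin `i`
  measured on the actual platelet mask; a uniform pattern reads 1.0
  everywhere, centralized organelles read ≫1 near the centroid.
* **Directionality** — Sobel orientation histograms and a Gaussian peak
  fit `b + A·exp(−(θ−µ)²/2σ²)`; the amplitude `A` is the non-homogeneity
  statistic (0 for isotropic spreading, large for aligned actin bundles).
* **Morphometrics and time courses** — platelet area, nodule offset
  (dx, dy), per-stage mean ± SD summaries, size distributions.
* **Correlative STORM↔EM registration** — closed-form least-squares
  similarity transform (scale, rotation, translation) from fiducial pairs.
* **Synthetic scenes** — a generator producing platelet geometries,
  organelle clusters under uniform/centralized/peripheral radial laws,
  von Mises filament fields, EMCCD frame stacks with blinking, noise and
  drift — all with recorded ground truth, so every stage above is
  verifiable without proprietary microscopy data.

## Worked example

Simulate an activated platelet carrying six 410 nm actin-nodule-scale
clusters, render, segment, and profile it:

```r
library(plateletquant)

scene <- synthetic_platelet_scene(seed = 1)   # defaults: 6 clusters, 410 nm,
                                              # precision 20 nm, R = 1500 nm
img <- render(scene$locs, 20, "gaussian", gaussian_sd_nm = 20,
              dim_px = c(175, 175))
seg <- segment_clusters(img)
seg
#> cluster_set: 6 clusters, mean eq. diameter 463 nm

head(seg$stats[, c("cluster_id", "pixels", "eq_diameter_nm", "eq_diameter_core_nm")])
#>   cluster_id pixels eq_diameter_nm eq_diameter_core_nm
#> 1          1    416       460.2902            409.9605
#> 2          2    424       464.6950            412.4376
#> 3          3    416       460.2902            409.9605
#> 4          4    427       466.3361            416.7372
#> 5          5    427       466.3361            413.0546
#> 6          6    416       460.2902            409.9605
```

The six clusters are recovered exactly; the post-dilation equivalent
diameter (~463 nm) carries the 1-pixel dilation shell and the 20 nm
precision skirt on top of the generating 410 nm, while the pre-dilation
"core" diameter (~411 nm) is essentially unbiased.

```r
ctr <- scene$geometry$centroid_nm; R <- scene$geometry$radius_nm
xc <- (seq_len(175) - 0.5) * 20
pm <- platelet_mask(outer((xc - ctr[2])^2, (xc - ctr[1])^2, "+") <= R^2, 20)
prof <- radial_density(seg$mask, pm, n_bins = 5)
round(prof$density_fraction, 4)
#> [1] 0.0000 0.4576 1.4226 1.4374 0.7193
sum(prof$density_fraction * prof$area_fraction)
#> [1] 1
```

The density fraction says how organelle-positive pixel density varies with
normalized distance from the platelet centroid: a uniform pattern reads 1.0
in every bin (the normalization identity is exact), this particular
six-cluster draw happens to occupy the mid radii, and a centralized scene
would concentrate the mass in the first bins.

## Command line

```sh
Rscript inst/cli/plateletquant.R run \
    --config inst/extdata/demo-config.yaml --seed 1 --out out/
Rscript inst/cli/plateletquant.R register --in pairs.csv --out transform.json
```

Subcommands: `simulate`, `localize`, `driftcorr`, `render`, `segment`,
`radial`, `directionality`, `register`, `summarize`, `run`.

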