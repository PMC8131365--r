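# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form, sharing no code
# with the package internals it checks.

# Mirror-reflected index into 1..n (edge handling of the median filter).
reflect_idx <- function(i, n) {
  i[i < 1] <- 1 - i[i < 1]
  i[i > n] <- 2 * n + 1 - i[i > n]
  i
}

# Brute-force median filter: per-pixel neighbourhood sort.
brute_median_filter <- function(img, window) {
  k <- (window - 1) / 2
  out <- img
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      ii <- reflect_idx((i - k):(i + k), nrow(img))
      jj <- reflect_idx((j - k):(j + k), ncol(img))
      out[i, j] <- stats::median(img[ii, jj])
    }
  }
  out
}

# Brute-force Otsu: exhaustive scan of all interior bin-boundary cut points
# with exact class statistics from the raw (sorted) pixel values; shares no
# code with the package's histogram-cumulative implementation.
brute_otsu <- function(img, n_bins = 256) {
  lo <- min(img); hi <- max(img)
  edges <- seq(lo, hi, length.out = n_bins + 1)
  xs <- sort(as.vector(img))
  cs <- cumsum(xs)
  n <- length(xs)
  best <- -Inf
  best_thr <- NA_real_
  for (t in 1:(n_bins - 1)) {
    thr <- edges[t + 1]
    n0 <- findInterval(thr, xs)   # pixels with value <= thr
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    m0 <- cs[n0] / n0
    m1 <- (cs[n] - cs[n0]) / n1
    bcv <- (n0 / n) * (n1 / n) * (m0 - m1)^2
    if (bcv > best + 1e-15) {  # strict improvement => smallest-threshold ties
      best <- bcv
      best_thr <- thr
    }
  }
  best_thr
}

# Brute-force dilation: union over the 8-neighbourhood of every set pixel.
brute_dilate <- function(mask, radius = 1) {
  for (r in seq_len(radius)) {
    out <- mask
    nr <- nrow(mask); nc <- ncol(mask)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (mask[i, j]) {
        out[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)] <- TRUE
      }
    }
    mask <- out
  }
  mask
}

# Numerical-integration CDF of the centralized (truncated half-Gaussian)
# radial law: P(radius <= r) on a disk of radius R with scale s.
centralized_cdf_numint <- function(r, R, s) {
  dens <- function(x) exp(-x^2 / (2 * s^2))
  stats::integrate(dens, 0, r)$value / stats::integrate(dens, 0, R)$value
}

# Circular mean resultant length of doubled orientation angles (degrees).
axial_resultant <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  sqrt(mean(cos(a))^2 + mean(sin(a))^2)
}

# A circular platelet mask fixture.
disk_platelet <- function(R_nm = 1500, pixel_nm = 20, pad_nm = 200) {
  n <- ceiling(2 * (R_nm + pad_nm) / pixel_nm)
  ctr <- (R_nm + pad_nm)
  xc <- (seq_len(n) - 0.5) * pixel_nm
  g <- outer((xc - ctr)^2, (xc - ctr)^2, "+") <= R_nm^2
  platelet_mask(g, pixel_nm)
}

# Random blobby binary mask (for property tests).
random_mask <- function(nr, nc, p = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(nr * nc) < p, nr, nc)
}

# Render-and-segment a synthetic scene with the package's standard
# quantification settings (gaussian rendering at the localization precision).
segment_scene <- function(scene, pixel_nm = 20) {
  geom <- scene$geometry
  dim_px <- rep(ceiling((geom$centroid_nm[1] + geom$radius_nm + 200) / pixel_nm), 2)
  img <- render(scene$locs, pixel_nm, "gaussian",
                gaussian_sd_nm = max(scene$params$precision_nm, pixel_nm),
                dim_px = dim_px)
  segment_clusters(img)
}

# Standard filament-scene directionality measurement: dense actin-like field
# rendered at 10 nm (kernel 2 px wide, which suppresses the pixel-grid
# anisotropy of Sobel orientation histograms) and summarized by the
# Gaussian peak fit.
filament_amplitude <- function(kappa, seed, mean_deg = -45, n_filaments = 300,
                               points_per_filament = 200) {
  g <- platelet_geometry(1500)
  fs <- make_filament_scene(n_filaments, mean_deg, kappa, g,
                            points_per_filament = points_per_filament,
                            seed = seed, precision_nm = 10)
  dim_px <- rep(ceiling((g$centroid_nm[1] + g$radius_nm + 200) / 10), 2)
  img <- render(fs, 10, "gaussian", gaussian_sd_nm = 20, dim_px = dim_px)
  fit_direction_peak(orientation_histogram(img))
}
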