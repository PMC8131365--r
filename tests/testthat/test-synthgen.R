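test_that("organelle centre sampling respects the disk, the law and the seed", {
  g <- platelet_geometry(1500)

  # a resting platelet carries about seven mitochondria; all inside the disk
  ctr <- sample_organelle_centers(7, radial_law("uniform"), g, seed = 1)
  expect_equal(nrow(ctr), 7)
  r <- sqrt((ctr[, 1] - g$centroid_nm[1])^2 + (ctr[, 2] - g$centroid_nm[2])^2)
  expect_true(all(r <= g$radius_nm))

  # empty case and argument validation
  expect_equal(nrow(sample_organelle_centers(0, radial_law("uniform"), g)), 0)
  expect_error(sample_organelle_centers(-1, radial_law("uniform"), g), "non-negative")

  # seed determinism, bit for bit
  a <- sample_organelle_centers(50, radial_law("centralized", 300), g, seed = 7)
  b <- sample_organelle_centers(50, radial_law("centralized", 300), g, seed = 7)
  expect_identical(a, b)

  # centralized law: fraction inside r/R < 0.5 matches the numerically
  # integrated truncated half-Gaussian within 3 binomial sigma
  law <- radial_law("centralized", 0.2 * 1500)
  cc <- sample_organelle_centers(1e4, law, g, seed = 2)
  rr <- sqrt((cc[, 1] - g$centroid_nm[1])^2 + (cc[, 2] - g$centroid_nm[2])^2)
  p_hat <- mean(rr / 1500 < 0.5)
  p_th <- centralized_cdf_numint(750, 1500, 300)
  expect_lt(abs(p_hat - p_th), 3 * sqrt(p_th * (1 - p_th) / 1e4))

  # closed-form CDF agrees with the independent numerical integral
  for (rq in c(300, 750, 1200)) {
    expect_equal(radial_cdf(law, rq, 1500),
                 centralized_cdf_numint(rq, 1500, 300), tolerance = 1e-6)
  }

  # minimum separation is honoured
  sep <- sample_organelle_centers(6, radial_law("uniform"), g, seed = 3,
                                  margin_nm = 205, min_separation_nm = 615)
  d <- as.matrix(dist(sep))
  expect_true(all(d[upper.tri(d)] >= 615))
})

test_that("radial law families integrate to one and behave at the extremes", {
  for (law in list(radial_law("uniform"),
                   radial_law("centralized", 250),
                   radial_law("peripheral", 200))) {
    expect_equal(radial_cdf(law, 1500, 1500), 1)
    expect_equal(radial_cdf(law, 0, 1500), 0)
    expect_true(all(diff(radial_cdf(law, seq(0, 1500, by = 50), 1500)) >= 0))
  }
  # chi-squared goodness of fit of sampled radii against each law's CDF
  g <- platelet_geometry(1500)
  for (law in list(radial_law("uniform"),
                   radial_law("centralized", 300),
                   radial_law("peripheral", 200))) {
    ctr <- sample_organelle_centers(1e5, law, g, seed = 11)
    rr <- sqrt((ctr[, 1] - g$centroid_nm[1])^2 + (ctr[, 2] - g$centroid_nm[2])^2)
    edges <- seq(0, 1500, length.out = 21)
    obs <- as.vector(table(cut(rr, edges, include.lowest = TRUE)))
    pexp <- diff(radial_cdf(law, edges, 1500))
    # condition on the well-populated bins (expected count >= 5) so the
    # chi-squared approximation is valid; tails are checked by the CDF
    # comparisons above
    keep <- pexp * 1e5 >= 5
    pval <- stats::chisq.test(obs[keep], p = pexp[keep] / sum(pexp[keep]))$p.value
    expect_gt(pval, 0.01)
  }
})

test_that("cluster localizations carry membership and the stated dispersion", {
  ctr <- cbind(c(1000, 3000, 5000, 1000, 3000, 5000),
               c(1000, 1000, 1000, 3000, 3000, 3000))

  # nodule-scale disks with zero precision stay inside their radius
  tb <- sample_cluster_localizations(ctr, 205, 200, 0, seed = 1)
  expect_s3_class(tb, "loc_table")
  d <- sqrt((tb$x_nm - ctr[tb$structure_id, 1])^2 +
            (tb$y_nm - ctr[tb$structure_id, 2])^2)
  expect_true(all(d <= 205))

  # degenerate disk: the localization is the centre
  tb0 <- sample_cluster_localizations(matrix(c(500, 700), 1), 1e-9, 1, 0, seed = 1)
  expect_equal(c(tb0$x_nm, tb0$y_nm), c(500, 700), tolerance = 1e-6)

  # empty centres give an empty, valid table
  te <- sample_cluster_localizations(matrix(numeric(0), ncol = 2), 100, 50, 10)
  expect_equal(nrow(te), 0)
  expect_silent(validate_loc_table(te))

  # variance decomposition: per-axis sd^2 = R^2/4 (uniform disk) + precision^2
  tb2 <- sample_cluster_localizations(ctr[1, , drop = FALSE], 205, 4000, 20, seed = 5)
  expected_sd <- sqrt(205^2 / 4 + 20^2)
  expect_equal(sd(tb2$x_nm - 1000), expected_sd, tolerance = 0.05)
  expect_equal(sd(tb2$y_nm - 1000), expected_sd, tolerance = 0.05)
})

test_that("filament scenes follow the axial von Mises orientation model", {
  g <- platelet_geometry(1500)

  # kappa = 0 is isotropic: tiny resultant length of doubled angles
  fs0 <- make_filament_scene(1000, 0, 0, g, points_per_filament = 1, seed = 1)
  expect_lt(axial_resultant(attr(fs0, "directions_deg")), 0.1)

  # kappa -> Inf: every direction equals the mean
  fsI <- make_filament_scene(5, -45, Inf, g, points_per_filament = 10, seed = 2)
  expect_equal(attr(fsI, "directions_deg"), rep(-45, 5))

  # single segment: points are collinear
  fs1 <- make_filament_scene(1, 30, Inf, g, points_per_filament = 100, seed = 3)
  fitln <- stats::lm(y_nm ~ x_nm, data = fs1)
  expect_lt(max(abs(stats::residuals(fitln))), 1e-8)
  expect_equal(unname(stats::coef(fitln)[2]), tan(30 * pi / 180), tolerance = 1e-9)

  # clipping: everything stays inside the platelet disk
  fs <- make_filament_scene(50, 10, 2, g, points_per_filament = 50, seed = 4)
  r <- sqrt((fs$x_nm - g$centroid_nm[1])^2 + (fs$y_nm - g$centroid_nm[2])^2)
  expect_true(all(r <= g$radius_nm + 1e-9))

  # concentration increases the resultant length monotonically
  res <- vapply(c(0, 1, 4, 16), function(kp) {
    axial_resultant(attr(make_filament_scene(500, 0, kp, g,
                                             points_per_filament = 1,
                                             seed = 9), "directions_deg"))
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("frame simulation conserves photons in expectation and honours blinking", {
  em <- cbind(c(500, 1500), c(700, 1200))

  # no active emitters: pure background
  s0 <- simulate_frames(em, 3, blink_on_prob = 0, photons_mean = 1000,
                        background_rate = 2, seed = 1, dim_px = c(20, 20))
  expect_equal(nrow(s0$events), 0)
  expect_lt(abs(mean(s0$stack) - 2), 3 * sqrt(2 / (3 * 400)) + 0.2)

  # zero frames: empty stack
  se <- simulate_frames(em, 0, dim_px = c(5, 5))
  expect_equal(dim(se$stack), c(5, 5, 0))

  # noise off, one emitter centred on a pixel: discretized Gaussian sums to
  # photons_mean + background * pixels
  s1 <- simulate_frames(matrix(c(1000, 1000), 1), 1, blink_on_prob = 1,
                        photons_mean = 800, psf_sigma_nm = 120,
                        pixel_size_nm = 100, background_rate = 3,
                        shot_noise = FALSE, dim_px = c(21, 21))
  expect_equal(sum(s1$stack[, , 1]), 800 + 3 * 21^2, tolerance = 1e-3)
  expect_true(all(s1$stack >= 0))

  # long-run mean matches the closed-form expectation within 3 MC sigma
  s2 <- simulate_frames(em, 1000, blink_on_prob = 0.5, photons_mean = 500,
                        psf_sigma_nm = 120, pixel_size_nm = 100,
                        background_rate = 5, seed = 2, dim_px = c(25, 25))
  tot <- apply(s2$stack, 3, sum)
  expected <- 0.5 * 2 * 500 + 5 * 25^2
  expect_lt(abs(mean(tot) - expected), 3 * sd(tot) / sqrt(1000))

  # drift displaces the recorded event positions
  dr <- drift_trajectory(10, "linear", total_nm = c(90, -45))
  s3 <- simulate_frames(em, 10, blink_on_prob = 1, drift = dr, seed = 3,
                        dim_px = c(25, 25))
  ev <- s3$events[s3$events$frame == 9 & s3$events$emitter == 1, ]
  expect_equal(ev$x_drifted_nm - ev$x_nm, 90)
  expect_equal(ev$y_drifted_nm - ev$y_nm, -45)

  # seed determinism of the full stack
  a <- simulate_frames(em, 5, seed = 4, dim_px = c(20, 20))
  b <- simulate_frames(em, 5, seed = 4, dim_px = c(20, 20))
  expect_identical(a$stack, b$stack)
})

test_that("drift trajectories start at zero and have the right length", {
  dr <- drift_trajectory(100, "linear", total_nm = c(10, -5))
  expect_equal(nrow(dr), 100)
  expect_equal(c(dr$dx_nm[1], dr$dy_nm[1]), c(0, 0))
  expect_equal(c(dr$dx_nm[100], dr$dy_nm[100]), c(10, -5))
  rw <- drift_trajectory(50, "random_walk", step_sd_nm = 1, seed = 1)
  expect_equal(c(rw$dx_nm[1], rw$dy_nm[1]), c(0, 0))
  expect_equal(nrow(rw), 50)
})

test_that("synthetic scenes are reproducible and respect geometry", {
  a <- synthetic_platelet_scene(seed = 42)
  b <- synthetic_platelet_scene(seed = 42)
  expect_identical(a$locs, b$locs)
  expect_identical(a$organelle_centers, b$organelle_centers)
  # clusters (centre + radius) stay inside the platelet disk
  g <- a$geometry
  r <- sqrt((a$organelle_centers[, 1] - g$centroid_nm[1])^2 +
            (a$organelle_centers[, 2] - g$centroid_nm[2])^2)
  expect_true(all(r + a$organelle_radius_nm <= g$radius_nm + 1e-9))
  # membership recorded for every localization
  expect_true(all(a$locs$structure_type %in% c("cluster", "background")))
  expect_identical(a$params$seed, 42)
})
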