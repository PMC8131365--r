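test_that("spot detection finds isolated maxima and nothing on flat frames", {
  expect_equal(nrow(detect_spots(matrix(5, 16, 16), 1)), 0)

  # one noise-free spot: exactly one candidate at the brightest pixel
  s <- simulate_frames(matrix(c(800, 900), 1), 1, blink_on_prob = 1,
                       photons_mean = 1000, psf_sigma_nm = 120,
                       pixel_size_nm = 100, background_rate = 0,
                       shot_noise = FALSE, dim_px = c(17, 17))
  cand <- detect_spots(s$stack[, , 1], 1)
  expect_equal(nrow(cand), 1)
  expect_equal(unlist(cand[c("row", "col")], use.names = FALSE),
               which(s$stack[, , 1] == max(s$stack[, , 1]), arr.ind = TRUE)[1, ],
               ignore_attr = TRUE)

  # 25 well-separated simulated spots at 5-sigma background threshold:
  # all recovered, none spurious (oracle: the generator's event list)
  em <- as.matrix(expand.grid(x = seq(600, 5400, length.out = 5),
                              y = seq(600, 5400, length.out = 5)))
  sim <- simulate_frames(em, 1, blink_on_prob = 1, photons_mean = 1000,
                         psf_sigma_nm = 120, pixel_size_nm = 100,
                         background_rate = 10, seed = 1, dim_px = c(60, 60))
  thr <- 10 + 5 * sqrt(10)
  cand <- detect_spots(sim$stack[, , 1], thr, min_separation = 3)
  expect_equal(nrow(cand), 25)
  d2 <- outer(cand$col * 100 - 50, em[, 1], "-")^2 +
        outer(cand$row * 100 - 50, em[, 2], "-")^2
  expect_true(all(sqrt(apply(d2, 1, min)) < 150))
})

test_that("integrated-Gaussian fitting is exact without noise and near the CRLB with it", {
  # noise-free spot centred between pixels: recovered to 1e-4 px
  s <- simulate_frames(matrix(c(450, 475), 1), 1, blink_on_prob = 1,
                       photons_mean = 1000, psf_sigma_nm = 120,
                       pixel_size_nm = 100, background_rate = 10,
                       shot_noise = FALSE, dim_px = c(9, 9))
  ft <- fit_gaussian_psf(s$stack[, , 1], pixel_size_nm = 100)
  expect_true(ft$fit_ok)
  expect_lt(abs(ft$x_nm - 450) / 100, 1e-4)
  expect_lt(abs(ft$y_nm - 475) / 100, 1e-4)
  expect_equal(ft$sigma_nm, 120, tolerance = 1e-4)
  expect_equal(ft$photons, 1000, tolerance = 1e-3)

  # degenerate inputs
  expect_error(fit_gaussian_psf(matrix(1, 5, 5)), "7 x 7")
  expect_false(fit_gaussian_psf(matrix(3, 9, 9))$fit_ok)

  # Monte-Carlo accuracy vs the numerically evaluated Cramer-Rao bound
  crlb <- crlb_gaussian_psf(photons = 1000, background = 10, sigma_px = 1.2)
  set.seed(7)
  errs <- replicate(60, {
    x0 <- 400 + runif(1, 0, 100); y0 <- 400 + runif(1, 0, 100)
    sm <- simulate_frames(matrix(c(x0, y0), 1), 1, blink_on_prob = 1,
                          photons_mean = 1000, psf_sigma_nm = 120,
                          pixel_size_nm = 100, background_rate = 10,
                          dim_px = c(9, 9))
    f <- fit_gaussian_psf(sm$stack[, , 1], pixel_size_nm = 100)
    c(f$x_nm - x0, f$y_nm - y0) / 100
  })
  expect_lt(sqrt(mean(errs^2)), 1.5 * crlb)
})

test_that("rendering conserves mass in both modes and handles empty tables", {
  tb <- loc_table(runif(300, 0, 2000), runif(300, 0, 2000))
  for (mode in c("histogram", "gaussian")) {
    img <- render(tb, 20, mode, gaussian_sd_nm = 30)
    expect_equal(sum(img$grid), 300, tolerance = 1e-6)
    expect_true(all(img$grid >= 0))
  }

  # single localization in histogram mode: one pixel set to 1
  one <- render(loc_table(55, 85), 10, "histogram", dim_px = c(12, 12))
  expect_equal(sum(one$grid), 1)
  expect_equal(one$grid[9, 6], 1)  # pixel covering (55, 85) at 10 nm/px

  # empty table: all-zero image of the requested extent
  z <- render(loc_table(), 20, dim_px = c(7, 9))
  expect_equal(dim(z$grid), c(7, 9))
  expect_true(all(z$grid == 0))
})

test_that("fiducial drift correction is exact for noise-free linear drift", {
  nF <- 2000
  dr <- drift_trajectory(nF, "linear", total_nm = c(0.5 * (nF - 1), 100))
  fid <- c(5000, 5000)
  tb <- loc_table(fid[1] + dr$dx_nm, fid[2] + dr$dy_nm, frame = 0:(nF - 1))
  dc <- correct_drift(tb, "fiducial", fiducial_xy_nm = fid)
  expect_lt(max(abs(dc$drift$dx_nm - dr$dx_nm)), 1e-6)
  expect_lt(max(abs(dc$drift$dy_nm - dr$dy_nm)), 1e-6)
  expect_lt(max(abs(dc$table$x_nm - fid[1])), 1e-6)

  # zero drift: output equals input; frames and row count untouched
  tb0 <- loc_table(rep(fid[1], 50), rep(fid[2], 50), frame = 0:49)
  dc0 <- correct_drift(tb0, "fiducial", fiducial_xy_nm = fid)
  expect_equal(dc0$table$x_nm, tb0$x_nm)
  expect_identical(dc0$table$frame, tb0$frame)
  expect_equal(nrow(dc0$table), nrow(tb0))

  # frame-0 drift forced to zero
  expect_equal(c(dc$drift$dx_nm[1], dc$drift$dy_nm[1]), c(0, 0))

  # missing fiducial is a configuration error
  far <- loc_table(runif(100, 0, 100), runif(100, 0, 100), frame = 0:99)
  expect_error(correct_drift(far, "fiducial", fiducial_xy_nm = c(5e4, 5e4)),
               "90")
})

test_that("block cross-correlation recovers drift from a structured scene", {
  g <- platelet_geometry(1500)
  ctr <- sample_organelle_centers(6, radial_law("uniform"), g, seed = 2,
                                  margin_nm = 205, min_separation_nm = 615)
  nF <- 2000
  tb <- sample_cluster_localizations(ctr, 205, 16000, 15, seed = 31,
                                     n_frames = nF)
  truth <- drift_trajectory(nF, "linear", total_nm = c(7, 7.14))
  idx <- tb$frame + 1
  tb$x_nm <- tb$x_nm + truth$dx_nm[idx]
  tb$y_nm <- tb$y_nm + truth$dy_nm[idx]
  dc <- correct_drift(tb, "block_xcorr", n_blocks = 10, bin_nm = 10)
  rms <- sqrt(mean((dc$drift$dx_nm - truth$dx_nm)^2 +
                   (dc$drift$dy_nm - truth$dy_nm)^2))
  expect_lt(rms, 5)
  expect_equal(nrow(dc$table), nrow(tb))
  expect_error(correct_drift(tb, "block_xcorr", n_blocks = 1), "n_blocks")
})

test_that("simulate-detect-fit recovers nearly all events with few false positives", {
  em <- as.matrix(expand.grid(x = seq(800, 5600, length.out = 4),
                              y = seq(800, 5600, length.out = 4)))
  sim <- simulate_frames(em, 30, blink_on_prob = 0.5, photons_mean = 1000,
                         psf_sigma_nm = 120, pixel_size_nm = 100,
                         background_rate = 10, seed = 5, dim_px = c(64, 64))
  tb <- localize_stack(sim$stack, 100)
  crlb_nm <- crlb_gaussian_psf(1000, 10, 1.2) * 100
  match_r <- 3 * crlb_nm
  ev <- sim$events
  matched <- logical(nrow(tb))
  hit <- logical(nrow(ev))
  for (k in seq_len(nrow(tb))) {
    same <- which(ev$frame == tb$frame[k] & !hit)
    if (!length(same)) next
    d <- sqrt((ev$x_drifted_nm[same] - tb$x_nm[k])^2 +
              (ev$y_drifted_nm[same] - tb$y_nm[k])^2)
    j <- which.min(d)
    if (d[j] <= match_r) {
      matched[k] <- TRUE
      hit[same[j]] <- TRUE
    }
  }
  recall <- sum(hit) / nrow(ev)
  fdr <- 1 - sum(matched) / nrow(tb)
  expect_gte(recall, 0.95)
  expect_lte(fdr, 0.05)
})
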