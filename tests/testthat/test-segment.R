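test_that("median filter matches the brute-force neighbourhood median", {
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_equal(median_filter_image(img, 3), brute_median_filter(img, 3))
  expect_equal(median_filter_image(img, 5), brute_median_filter(img, 5))

  # identity window and argument validation
  expect_identical(median_filter_image(img, 1), img)
  expect_error(median_filter_image(img, 4), "odd")

  # an isolated hot pixel is removed
  hot <- matrix(0, 9, 9); hot[5, 5] <- 100
  expect_true(all(median_filter_image(hot, 3) == 0))

  # rendered_image wrapper keeps metadata
  ri <- rendered_image(img, 20)
  out <- median_filter_image(ri, 3)
  expect_s3_class(out, "rendered_image")
  expect_equal(out$pixel_size_nm, 20)
})

test_that("Otsu matches the exhaustive between-class-variance scan", {
  # two-class image: threshold separates the classes
  im2 <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  ot <- otsu_threshold(im2)
  expect_gt(ot$threshold, 10)
  expect_lt(ot$threshold, 200)
  expect_equal(sum(ot$mask), 50)
  expect_true(all(im2[ot$mask] == 200))

  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant")

  # random 8-bit images: identical to brute force every time
  set.seed(2)
  for (k in 1:20) {
    img <- matrix(sample.int(256, 64 * 64, replace = TRUE) - 1, 64, 64)
    expect_equal(otsu_threshold(img)$threshold, brute_otsu(img))
  }
})

test_that("dilation implements the 3x3 full-neighbourhood element", {
  m1 <- matrix(FALSE, 7, 7); m1[4, 4] <- TRUE
  expect_equal(sum(dilate_mask(m1, 1)), 9)
  expect_identical(dilate_mask(m1, 0), m1)
  set.seed(3)
  for (k in 1:5) {
    m <- random_mask(20, 25, 0.15)
    d1 <- dilate_mask(m, 1)
    expect_identical(d1, brute_dilate(m, 1))
    expect_true(all(d1[m]))  # superset of the input
    expect_identical(dilate_mask(m, 2), brute_dilate(m, 2))
  }
})

test_that("labeling is 8-connected with consistent per-cluster statistics", {
  # two diagonally touching pixels form one cluster
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  cs <- label_clusters(m, 20)
  expect_equal(nrow(cs$stats), 1)

  # empty mask: zero clusters
  expect_equal(nrow(label_clusters(matrix(FALSE, 4, 4), 20)$stats), 0)

  # statistics invariants on random masks (property test)
  set.seed(4)
  for (k in 1:8) {
    m <- random_mask(30, 30, 0.25)
    cs <- label_clusters(m, 15)
    st <- cs$stats
    if (nrow(st)) {
      expect_identical(st$cluster_id, seq_len(nrow(st)))
      expect_equal(sum(st$pixels), sum(m))
      expect_equal(st$area_nm2, st$pixels * 15^2)
      expect_equal(st$eq_diameter_nm, 2 * sqrt(st$area_nm2 / pi))
    }
    expect_equal(sort(unique(as.vector(cs$label_map))),
                 c(0L, st$cluster_id)[seq_len(nrow(st) + 1)])
  }

  # well-separated blobs are recovered exactly with centroids within 1 px
  g <- platelet_geometry(2500)
  ctr <- sample_organelle_centers(10, radial_law("uniform"), g, seed = 5,
                                  margin_nm = 300, min_separation_nm = 700)
  tb <- sample_cluster_localizations(ctr, 150, 500, 0, seed = 6)
  img <- render(tb, 20, "gaussian", gaussian_sd_nm = 20,
                dim_px = c(280, 280))
  seg <- segment_clusters(img, dilate_radius = 0)
  expect_equal(nrow(seg$stats), 10)
  d <- sqrt(outer(seg$stats$cx_nm, ctr[, 1], "-")^2 +
            outer(seg$stats$cy_nm, ctr[, 2], "-")^2)
  expect_true(all(apply(d, 1, min) < 20))
})

test_that("positive pixel counting intersects mask and platelet exactly", {
  pm <- disk_platelet(400, 20, 100)
  full <- binary_mask(pm$grid, 20)
  expect_equal(positive_pixel_count(full, pm), sum(pm$grid))
  none <- binary_mask(!pm$grid, 20)
  expect_equal(positive_pixel_count(none, pm), 0)
  set.seed(5)
  m <- random_mask(nrow(pm$grid), ncol(pm$grid), 0.3)
  expect_equal(positive_pixel_count(binary_mask(m, 20), pm),
               sum(m & pm$grid))
  expect_error(positive_pixel_count(binary_mask(matrix(TRUE, 2, 2), 20), pm),
               "shape")
})

test_that("platelet segmentation finds the disk, fills holes and errors on blanks", {
  # synthetic binary disk: centroid within 0.5 px, area within 2% of pi R^2
  R <- 1784; p <- 20
  n <- ceiling(2 * (R + 200) / p)
  ctr <- R + 200
  xc <- (seq_len(n) - 0.5) * p
  g <- outer((xc - ctr)^2, (xc - ctr)^2, "+") <= R^2
  img <- rendered_image(g * 1, p)
  pm <- platelet_mask_from_image(img)
  expect_lt(max(abs(pm$centroid_nm - ctr)), 0.5 * p)
  expect_equal(pm$area_nm2, pi * R^2, tolerance = 0.02)
  expect_equal(platelet_area(pm), pi * (R / 1000)^2, tolerance = 0.02)

  # interior holes are filled
  gh <- g
  gh[(ctr / p - 5):(ctr / p + 5), (ctr / p - 5):(ctr / p + 5)] <- FALSE
  pmh <- platelet_mask_from_image(rendered_image(gh * 1, p))
  expect_equal(sum(pmh$grid), sum(g))

  # all-background image cannot be segmented
  expect_error(platelet_mask_from_image(rendered_image(matrix(0, 10, 10), p)))
})

test_that("cluster counts are invariant to positive intensity rescaling", {
  sc <- synthetic_platelet_scene(seed = 12)
  dimp <- rep(ceiling((sc$geometry$centroid_nm[1] + sc$geometry$radius_nm + 200) / 20), 2)
  img <- render(sc$locs, 20, "gaussian", gaussian_sd_nm = 20, dim_px = dimp)
  base <- segment_clusters(img)
  for (fac in c(0.25, 7, 1000)) {
    scaled <- rendered_image(img$grid * fac, 20)
    expect_equal(nrow(segment_clusters(scaled)$stats), nrow(base$stats))
  }
})

test_that("the pipeline order median->otsu->label->dilate is applied as a unit", {
  sc <- synthetic_platelet_scene(seed = 3)
  dimp <- rep(ceiling((sc$geometry$centroid_nm[1] + sc$geometry$radius_nm + 200) / 20), 2)
  img <- render(sc$locs, 20, "gaussian", gaussian_sd_nm = 20, dim_px = dimp)
  seg <- segment_clusters(img, window = 3, dilate_radius = 1)
  # composing the stages by hand gives the same label geography
  manual_mask <- otsu_threshold(median_filter_image(img, 3))$mask
  manual <- label_clusters(manual_mask)
  expect_equal(nrow(seg$stats), nrow(manual$stats))
  expect_equal(seg$stats$pixels_core, manual$stats$pixels)
  # dilation only grows clusters, by at most the 1-px shell
  expect_true(all(seg$stats$pixels > seg$stats$pixels_core))
  expect_equal(sum(seg$stats$pixels), sum(seg$mask$grid))
})
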