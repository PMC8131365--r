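#' Binary mask
#'
#' A logical image with a physical pixel size; output of thresholding,
#' input to labeling and radial profiling.
#'
#' @param grid Logical matrix.
#' @param pixel_size_nm Pixel size, nm.
#' @return Object of class `binary_mask`.
#' @export
binary_mask <- function(grid, pixel_size_nm) {
  stopifnot(is.matrix(grid), is.logical(grid), pixel_size_nm > 0)
  structure(list(grid = grid, pixel_size_nm = as.numeric(pixel_size_nm)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px at %.1f nm/px, %d positive\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_nm, sum(x$grid)))
  invisible(x)
}

# Mirror-pad a matrix by k pixels on every side.
.mirror_pad <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc) stop("pad size exceeds image size")
  ri <- c(k:1, 1:nr, nr:(nr - k + 1))
  ci <- c(k:1, 1:nc, nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# Row-wise medians via a pmin/pmax selection network (odd column count).
.row_median_sortnet <- function(M) {
  m <- ncol(M)
  for (j in seq_len(m - 1)) {
    for (i in (j + 1):m) {
      lo <- pmin(M[, j], M[, i])
      hi <- pmax(M[, j], M[, i])
      M[, j] <- lo; M[, i] <- hi
    }
  }
  M[, (m + 1) %/% 2]
}

#' Median-filter a rendered image
#'
#' Replaces each pixel by the median of its `window x window`
#' neighbourhood, with mirrored edges; `window = 1` is the identity. This
#' is the first step of the cluster quantification pipeline, suppressing
#' isolated single-localization pixels before thresholding.
#'
#' @param img A [rendered_image()] (or plain matrix).
#' @param window Odd window side (>= 1).
#' @return Same type as `img`.
#' @export
median_filter_image <- function(img, window = 3) {
  if (window %% 2 != 1 || window < 1) stop("`window` must be an odd integer >= 1")
  grid <- if (inherits(img, "rendered_image")) img$grid else img
  stopifnot(is.matrix(grid))
  if (window > 1) {
    k <- (window - 1) %/% 2
    pad <- .mirror_pad(grid, k)
    nr <- nrow(grid); nc <- ncol(grid)
    cols <- vector("list", window^2)
    idx <- 1L
    for (dj in 0:(window - 1)) for (di in 0:(window - 1)) {
      cols[[idx]] <- as.vector(pad[(1 + di):(nr + di), (1 + dj):(nc + dj)])
      idx <- idx + 1L
    }
    med <- .row_median_sortnet(do.call(cbind, cols))
    grid <- matrix(med, nr, nc)
  }
  if (inherits(img, "rendered_image")) rendered_image(grid, img$pixel_size_nm, img$origin_nm)
  else grid
}

#' Otsu intensity threshold
#'
#' Computes the threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over a 256-bin histogram spanning the image's
#' min--max intensity range. Candidate thresholds are the interior bin
#' boundaries; class statistics use exact within-bin intensity sums (not
#' bin centres), and ties are broken towards the smallest threshold. The
#' mask is `intensity > threshold`.
#'
#' @param img A [rendered_image()] or plain matrix with >= 2 distinct
#'   values.
#' @param n_bins Histogram bin count (default 256).
#' @return A list: `threshold` (intensity value) and `mask`
#'   (a [binary_mask()], or a logical matrix for matrix input).
#' @export
otsu_threshold <- function(img, n_bins = 256) {
  grid <- if (inherits(img, "rendered_image")) img$grid else img
  stopifnot(is.matrix(grid), n_bins >= 2)
  lo <- min(grid); hi <- max(grid)
  if (lo == hi) stop("Otsu threshold is undefined for a constant image")
  edges <- seq(lo, hi, length.out = n_bins + 1)
  # left-open binning: bin b holds values in (edges[b], edges[b+1]], the
  # minimum value lands in bin 1; class 0 at cut t is {x <= edges[t+1]}
  b <- findInterval(grid, edges, left.open = TRUE)
  b[b < 1L] <- 1L
  cnt <- tabulate(b, nbins = n_bins)
  smd <- numeric(n_bins)
  smd[sort(unique(as.vector(b)))] <- as.vector(rowsum(as.vector(grid), as.vector(b)))
  n <- length(grid)
  c0 <- cumsum(cnt)[1:(n_bins - 1)]
  s0 <- cumsum(smd)[1:(n_bins - 1)]
  c1 <- n - c0
  s1 <- sum(grid) - s0
  valid <- c0 > 0 & c1 > 0
  bcv <- rep(-Inf, n_bins - 1)
  bcv[valid] <- (c0[valid] / n) * (c1[valid] / n) *
    (s0[valid] / c0[valid] - s1[valid] / c1[valid])^2
  t_idx <- which.max(bcv)  # which.max returns the first (smallest) maximizer
  threshold <- edges[t_idx + 1]
  maskm <- grid > threshold
  mask <- if (inherits(img, "rendered_image")) binary_mask(maskm, img$pixel_size_nm) else maskm
  list(threshold = threshold, mask = mask)
}

#' Dilate a binary mask
#'
#' Morphological dilation with the full 3x3 (8-neighbourhood) structuring
#' element, applied `radius` times; `radius = 0` is the identity. This is
#' the "boundaries dilated by 1 pixel" step of the cluster pipeline.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param radius Number of dilation passes (>= 0).
#' @return Same type as `mask` (always a superset of the input).
#' @export
dilate_mask <- function(mask, radius = 1) {
  stopifnot(radius >= 0, radius == round(radius))
  grid <- if (inherits(mask, "binary_mask")) mask$grid else mask
  stopifnot(is.matrix(grid), is.logical(grid))
  if (radius > 0 && any(grid)) {
    br <- EBImage::makeBrush(3, shape = "box")
    g <- grid * 1
    for (k in seq_len(radius)) g <- EBImage::dilate(g, br)
    grid <- g > 0
  }
  if (inherits(mask, "binary_mask")) binary_mask(grid, mask$pixel_size_nm) else grid
}

# Grey dilation of an integer label map with the 3x3 box element, `radius`
# passes; conflicts (a pixel reached by two labels) go to the larger label.
.dilate_labels <- function(lab, radius = 1) {
  nr <- nrow(lab); nc <- ncol(lab)
  for (k in seq_len(radius)) {
    out <- lab
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      src_r <- max(1, 1 - di):min(nr, nr - di)
      src_c <- max(1, 1 - dj):min(nc, nc - dj)
      dst_r <- src_r + di; dst_c <- src_c + dj
      out[dst_r, dst_c] <- pmax(out[dst_r, dst_c], lab[src_r, src_c])
    }
    lab <- out
  }
  lab
}

# Tiny union-find used to merge diagonally adjacent 4-connected labels.
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Label connected clusters in a binary mask
#'
#' Connected-component labeling under 8-point connectivity (diagonal
#' neighbours join), with deterministic consecutive labels assigned in
#' raster order (row-major order of each cluster's first pixel), and
#' per-cluster statistics: pixel count, area (`pixels * pixel_size^2`),
#' equivalent circular diameter (`2 * sqrt(area / pi)`), and intensity-free
#' centroid (mean of pixel centres, nm).
#'
#' @param mask A [binary_mask()] (or logical matrix with `pixel_size_nm`).
#' @param pixel_size_nm Pixel size, nm (taken from `mask` when it is a
#'   [binary_mask()]).
#' @return An object of class `cluster_set`: a list with `label_map`
#'   (integer matrix, 0 = background), `stats` (data.frame with columns
#'   `cluster_id`, `pixels`, `area_nm2`, `eq_diameter_nm`, `cx_nm`,
#'   `cy_nm`), and `pixel_size_nm`. An empty mask yields 0 clusters.
#' @export
label_clusters <- function(mask, pixel_size_nm = NULL) {
  if (inherits(mask, "binary_mask")) {
    pixel_size_nm <- mask$pixel_size_nm
    grid <- mask$grid
  } else grid <- mask
  stopifnot(is.matrix(grid), is.logical(grid), !is.null(pixel_size_nm))
  nr <- nrow(grid); nc <- ncol(grid)
  lab4 <- EBImage::bwlabel(grid * 1)
  lab4 <- matrix(as.integer(lab4), nr, nc)
  nlab <- max(lab4)
  if (nlab > 0) {
    parent <- seq_len(nlab)
    # merge labels that touch only diagonally (EBImage::bwlabel is 4-connected)
    for (d in list(c(1, 1), c(1, -1))) {
      di <- d[1]; dj <- d[2]
      src_r <- max(1, 1 - di):min(nr, nr - di)
      src_c <- max(1, 1 - dj):min(nc, nc - dj)
      a <- lab4[src_r, src_c]
      bl <- lab4[src_r + di, src_c + dj]
      sel <- a > 0 & bl > 0 & a != bl
      if (any(sel)) {
        pairs <- unique(cbind(a[sel], bl[sel]))
        for (r in seq_len(nrow(pairs))) {
          ra <- .uf_find(parent, pairs[r, 1])
          rb <- .uf_find(parent, pairs[r, 2])
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    root <- vapply(seq_len(nlab), function(i) .uf_find(parent, i), integer(1))
    lab <- matrix(0L, nr, nc)
    fg <- lab4 > 0
    lab[fg] <- root[lab4[fg]]
    # relabel consecutively by raster order (row-major) of first pixel
    ij <- which(fg, arr.ind = TRUE)
    raster <- order(ij[, 1], ij[, 2])
    first <- lab[fg][raster]
    newid <- integer(nlab)
    nxt <- 0L
    for (lb in first) {
      if (newid[lb] == 0L) { nxt <- nxt + 1L; newid[lb] <- nxt }
    }
    lab[fg] <- newid[lab[fg]]
    nlab <- nxt
  } else lab <- matrix(0L, nr, nc)
  stats <- .cluster_stats(lab, pixel_size_nm)
  structure(list(label_map = lab, stats = stats, pixel_size_nm = pixel_size_nm),
            class = "cluster_set")
}

# Per-label pixel counts, areas, equivalent diameters and centroids.
.cluster_stats <- function(lab, p) {
  nlab <- max(lab)
  if (nlab == 0) {
    return(data.frame(cluster_id = integer(), pixels = integer(),
                      area_nm2 = numeric(), eq_diameter_nm = numeric(),
                      cx_nm = numeric(), cy_nm = numeric()))
  }
  fg <- which(lab > 0, arr.ind = TRUE)
  ids <- lab[lab > 0]
  px <- tabulate(ids, nbins = nlab)
  cx <- as.vector(rowsum((fg[, 2] - 0.5) * p, ids)) / px
  cy <- as.vector(rowsum((fg[, 1] - 0.5) * p, ids)) / px
  area <- px * p^2
  data.frame(cluster_id = seq_len(nlab), pixels = px, area_nm2 = area,
             eq_diameter_nm = 2 * sqrt(area / pi), cx_nm = cx, cy_nm = cy)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters, mean eq. diameter %.0f nm\n",
              nrow(x$stats),
              if (nrow(x$stats)) mean(x$stats$eq_diameter_nm) else NA))
  invisible(x)
}

#' Platelet mask
#'
#' Segment the platelet footprint from a DIC-like image: Otsu threshold,
#' largest 8-connected component, hole filling; the centroid is the mean of
#' mask pixel centres, the area `pixels * pixel_size^2`, and `radius_nm`
#' the maximum centroid-to-pixel-centre distance (the outer radius used to
#' normalize radial profiles of irregular spread shapes).
#'
#' @param dic_like A [rendered_image()] containing one dominant object.
#' @return An object of class `platelet_mask`: list with `grid`,
#'   `pixel_size_nm`, `centroid_nm`, `area_nm2`, `radius_nm`, `boundary`
#'   (matrix of boundary pixel centres, nm).
#' @export
platelet_mask_from_image <- function(dic_like) {
  stopifnot(inherits(dic_like, "rendered_image"))
  ot <- otsu_threshold(dic_like)
  if (!any(ot$mask$grid)) stop("platelet segmentation found no foreground")
  cs <- label_clusters(ot$mask)
  main <- cs$stats$cluster_id[which.max(cs$stats$pixels)]
  grid <- cs$label_map == main
  grid <- matrix(as.integer(EBImage::fillHull(grid * 1)) > 0,
                 nrow(grid), ncol(grid))
  platelet_mask(grid, dic_like$pixel_size_nm)
}

#' Construct a platelet mask from a logical grid
#'
#' @param grid Logical matrix (the platelet footprint).
#' @param pixel_size_nm Pixel size, nm.
#' @return A `platelet_mask` (see [platelet_mask_from_image()]).
#' @export
platelet_mask <- function(grid, pixel_size_nm) {
  stopifnot(is.matrix(grid), is.logical(grid), any(grid), pixel_size_nm > 0)
  p <- pixel_size_nm
  ij <- which(grid, arr.ind = TRUE)
  cx <- mean(ij[, 2] - 0.5) * p
  cy <- mean(ij[, 1] - 0.5) * p
  d <- sqrt(((ij[, 2] - 0.5) * p - cx)^2 + ((ij[, 1] - 0.5) * p - cy)^2)
  inner <- grid
  inner[] <- FALSE
  if (nrow(grid) > 2 && ncol(grid) > 2) {
    core <- grid[2:(nrow(grid) - 1), 2:(ncol(grid) - 1)] &
      grid[1:(nrow(grid) - 2), 2:(ncol(grid) - 1)] &
      grid[3:nrow(grid), 2:(ncol(grid) - 1)] &
      grid[2:(nrow(grid) - 1), 1:(ncol(grid) - 2)] &
      grid[2:(nrow(grid) - 1), 3:ncol(grid)]
    inner[2:(nrow(grid) - 1), 2:(ncol(grid) - 1)] <- core
  }
  bnd <- which(grid & !inner, arr.ind = TRUE)
  structure(
    list(grid = grid, pixel_size_nm = p, centroid_nm = c(cx, cy),
         area_nm2 = nrow(ij) * p^2, radius_nm = max(d),
         boundary = cbind(x_nm = (bnd[, 2] - 0.5) * p,
                          y_nm = (bnd[, 1] - 0.5) * p)),
    class = "platelet_mask"
  )
}

#' @export
print.platelet_mask <- function(x, ...) {
  cat(sprintf(
    "platelet_mask: area %.2f um^2, centroid (%.0f, %.0f) nm, R = %.0f nm\n",
    x$area_nm2 / 1e6, x$centroid_nm[1], x$centroid_nm[2], x$radius_nm))
  invisible(x)
}

#' Count organelle-positive pixels inside the platelet
#'
#' The "positive-pixel number per platelet" statistic: the number of true
#' pixels of `mask` that fall inside the platelet footprint.
#'
#' @param mask A [binary_mask()] or logical matrix.
#' @param platelet A [platelet_mask()].
#' @return Integer count.
#' @export
positive_pixel_count <- function(mask, platelet) {
  grid <- if (inherits(mask, "binary_mask")) mask$grid else mask
  stopifnot(inherits(platelet, "platelet_mask"))
  if (!all(dim(grid) == dim(platelet$grid)))
    stop("mask and platelet mask shapes differ")
  sum(grid & platelet$grid)
}

#' Cluster segmentation pipeline
#'
#' The full organelle quantification chain in its fixed order: median
#' filter, Otsu threshold, 8-connected labeling, then 1-pixel boundary
#' dilation of the labeled clusters. Cluster count is taken before
#' dilation; sizes are reported both post-dilation (`pixels`, `area_nm2`,
#' `eq_diameter_nm` -- the headline statistics) and pre-dilation
#' (`pixels_core`, `area_core_nm2`, `eq_diameter_core_nm`).
#'
#' @param img A [rendered_image()].
#' @param window Median-filter window (odd; default 3).
#' @param dilate_radius Boundary dilation passes (default 1).
#' @param exclude_border Drop clusters touching the image border
#'   (default `FALSE`; no exclusion rule is applied by default).
#' @return A `cluster_set` whose `stats` carry both post- and pre-dilation
#'   sizes, plus the `mask` (post-dilation [binary_mask()]) and
#'   `threshold`.
#' @export
segment_clusters <- function(img, window = 3, dilate_radius = 1,
                             exclude_border = FALSE) {
  stopifnot(inherits(img, "rendered_image"))
  filt <- median_filter_image(img, window)
  ot <- otsu_threshold(filt)
  cs <- label_clusters(ot$mask)
  lab <- cs$label_map
  if (exclude_border && max(lab) > 0) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    edge <- setdiff(edge, 0L)
    if (length(edge)) {
      lab[lab %in% edge] <- 0L
      keep <- setdiff(sort(unique(as.vector(lab))), 0L)
      relab <- integer(max(cs$label_map))
      relab[keep] <- seq_along(keep)
      lab[lab > 0] <- relab[lab[lab > 0]]
    }
  }
  core_stats <- .cluster_stats(lab, img$pixel_size_nm)
  labd <- if (dilate_radius > 0) .dilate_labels(lab, dilate_radius) else lab
  stats <- .cluster_stats(labd, img$pixel_size_nm)
  names(core_stats) <- c("cluster_id", "pixels_core", "area_core_nm2",
                         "eq_diameter_core_nm", "cx_core_nm", "cy_core_nm")
  stats <- merge(stats, core_stats[, 1:4], by = "cluster_id")
  structure(list(label_map = labd, label_map_core = lab, stats = stats,
                 pixel_size_nm = img$pixel_size_nm,
                 mask = binary_mask(labd > 0, img$pixel_size_nm),
                 threshold = ot$threshold),
            class = "cluster_set")
}
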