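#' Rendered super-resolution image
#'
#' A 2D intensity grid with a physical pixel size and origin (nm coordinate
#' of the top-left image corner). Output of [render()], input to the
#' segmentation and directionality stages.
#'
#' @param grid Numeric matrix (rows = y, columns = x), non-negative.
#' @param pixel_size_nm Pixel size, nm (> 0).
#' @param origin_nm Length-2 nm coordinate of the top-left corner.
#' @return Object of class `rendered_image`.
#' @export
rendered_image <- function(grid, pixel_size_nm, origin_nm = c(0, 0)) {
  stopifnot(is.matrix(grid), pixel_size_nm > 0, length(origin_nm) == 2)
  structure(list(grid = grid, pixel_size_nm = as.numeric(pixel_size_nm),
                 origin_nm = as.numeric(origin_nm)),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("rendered_image: %d x %d px at %.1f nm/px, sum = %.4g\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_nm, sum(x$grid)))
  invisible(x)
}

#' Detect candidate spots in a raw frame
#'
#' Candidates are strict local maxima of the 8-neighbourhood with intensity
#' at least `min_intensity`; candidates closer than `min_separation` pixels
#' are reduced to the brightest one (greedy, by decreasing intensity, ties
#' broken in raster order so the result is deterministic).
#'
#' @param frame Numeric matrix (one acquisition frame).
#' @param min_intensity Minimum peak intensity.
#' @param min_separation Minimum candidate separation, pixels.
#' @return A data.frame with columns `row`, `col`, `value` (possibly empty).
#' @export
detect_spots <- function(frame, min_intensity, min_separation = 3) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < 3 || nc < 3) return(data.frame(row = integer(), col = integer(), value = numeric()))
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- frame
  # a candidate must beat every neighbour (ties resolved to the earliest
  # pixel in raster order, so symmetric plateaus yield one candidate) and be
  # strictly greater than at least one in-image neighbour (a uniform
  # plateau, e.g. a flat frame, contains no maxima)
  is_max <- matrix(TRUE, nr, nc)
  any_strict <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
    later <- di > 0 | (di == 0 & dj > 0)
    is_max <- is_max & (is.na(nb) | frame > nb | (frame == nb & later))
    any_strict <- any_strict | (!is.na(nb) & frame > nb)
  }
  keep <- which(is_max & any_strict & frame >= min_intensity, arr.ind = TRUE)
  if (!nrow(keep)) return(data.frame(row = integer(), col = integer(), value = numeric()))
  val <- frame[keep]
  # raster (row-major) order for deterministic tie-breaking
  o <- order(-val, keep[, 1], keep[, 2])
  keep <- keep[o, , drop = FALSE]; val <- val[o]
  sel <- logical(nrow(keep))
  for (k in seq_len(nrow(keep))) {
    if (any(sel)) {
      d2 <- (keep[sel, 1] - keep[k, 1])^2 + (keep[sel, 2] - keep[k, 2])^2
      if (any(d2 < min_separation^2)) next
    }
    sel[k] <- TRUE
  }
  out <- data.frame(row = keep[sel, 1], col = keep[sel, 2], value = val[sel])
  out[order(out$row, out$col), , drop = FALSE]
}

# Expected pixel values of an integrated symmetric Gaussian + background,
# in ROI pixel units (pixel (i, j) spans [j-1, j) x [i-1, i)).
.psf_expected <- function(nr, nc, x0, y0, sigma, N, b) {
  mx <- .gauss_pixel_mass(0:nc, x0, sigma)
  my <- .gauss_pixel_mass(0:nr, y0, sigma)
  N * outer(my, mx) + b
}

#' Fit an integrated 2D Gaussian PSF to a region of interest
#'
#' Nonlinear least-squares fit (Levenberg--Marquardt via
#' \pkg{minpack.lm}) of a symmetric integrated Gaussian plus constant
#' background, the model the STORM centroid-estimation step uses. Pixel
#' masses are Gaussian error-function integrals, so the fit is unbiased even
#' at small sigma/pixel. Initialization is moment-based. The fit is flagged
#' not-OK when the solver fails, the fitted sigma leaves `[0.5, 5]` pixels,
#' or the centre leaves the ROI.
#'
#' @param roi Numeric matrix, side >= 7 pixels.
#' @param init Optional length-2 initial centre `c(row, col)` in pixels
#'   (e.g. a [detect_spots()] candidate); default is the intensity centroid.
#' @param pixel_size_nm Physical pixel size used to scale the returned
#'   coordinates (default 1, i.e. pixel units).
#' @param origin_nm Length-2 nm coordinate of the ROI top-left corner.
#' @return A list: `x_nm`, `y_nm`, `sigma_nm`, `photons`, `background`,
#'   `fit_ok`.
#' @export
fit_gaussian_psf <- function(roi, init = NULL, pixel_size_nm = 1,
                             origin_nm = c(0, 0)) {
  stopifnot(is.matrix(roi))
  nr <- nrow(roi); nc <- ncol(roi)
  if (nr < 7 || nc < 7) stop("ROI must be at least 7 x 7 pixels")
  bad <- list(x_nm = NA_real_, y_nm = NA_real_, sigma_nm = NA_real_,
              photons = NA_real_, background = NA_real_, fit_ok = FALSE)
  if (max(roi) == min(roi)) return(bad)
  b0 <- stats::median(c(roi[1, ], roi[nr, ], roi[, 1], roi[, nc]))
  w <- pmax(roi - b0, 0)
  if (sum(w) <= 0) return(bad)
  xc <- (seq_len(nc) - 0.5); yc <- (seq_len(nr) - 0.5)
  if (is.null(init)) {
    x0 <- sum(colSums(w) * xc) / sum(w)
    y0 <- sum(rowSums(w) * yc) / sum(w)
  } else {
    y0 <- init[1] - 0.5; x0 <- init[2] - 0.5
  }
  s0 <- sqrt(max(
    (sum(colSums(w) * xc^2) / sum(w) - (sum(colSums(w) * xc) / sum(w))^2 +
     sum(rowSums(w) * yc^2) / sum(w) - (sum(rowSums(w) * yc) / sum(w))^2) / 2,
    0.25))
  s0 <- min(max(s0, 0.6), 4)
  N0 <- sum(w)
  z <- as.vector(roi)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ as.vector(.psf_expected(nr, nc, x0p, y0p, sp, Np, bp)),
      start = list(x0p = x0, y0p = y0, sp = s0, Np = N0, bp = max(b0, 0)),
      lower = c(-1, -1, 0.05, 1e-9, 0),
      upper = c(nc + 1, nr + 1, 10, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(bad)
  cf <- stats::coef(fit)
  ok <- is.finite(cf["sp"]) && cf["sp"] >= 0.5 && cf["sp"] <= 5 &&
    cf["x0p"] > 0 && cf["x0p"] < nc && cf["y0p"] > 0 && cf["y0p"] < nr &&
    cf["Np"] > 0
  list(
    x_nm = origin_nm[1] + unname(cf["x0p"]) * pixel_size_nm,
    y_nm = origin_nm[2] + unname(cf["y0p"]) * pixel_size_nm,
    sigma_nm = unname(cf["sp"]) * pixel_size_nm,
    photons = unname(cf["Np"]),
    background = unname(cf["bp"]),
    fit_ok = isTRUE(ok)
  )
}

#' Localize emitters in a frame stack
#'
#' Runs [detect_spots()] and [fit_gaussian_psf()] on every frame and
#' collects successful fits into a [loc_table()] in nm coordinates.
#' Candidates whose ROI would cross the image border are skipped.
#'
#' @param stack rows x cols x frames array (e.g. from [simulate_frames()]).
#' @param pixel_size_nm Camera pixel size, nm.
#' @param min_intensity Spot-detection threshold; default
#'   `background + 5 * sqrt(background)` with background estimated as the
#'   stack median.
#' @param min_separation Candidate separation, pixels.
#' @param roi_halfsize ROI half-width, pixels (ROI side `2*h + 1`).
#' @return A [loc_table()] of accepted fits.
#' @export
localize_stack <- function(stack, pixel_size_nm, min_intensity = NULL,
                           min_separation = 5, roi_halfsize = 4) {
  stopifnot(length(dim(stack)) == 3, pixel_size_nm > 0)
  if (is.null(min_intensity)) {
    bg <- stats::median(stack)
    min_intensity <- bg + 5 * sqrt(max(bg, 1))
  }
  h <- roi_halfsize
  rows <- vector("list", dim(stack)[3])
  for (f in seq_len(dim(stack)[3])) {
    frame <- stack[, , f]
    cand <- detect_spots(frame, min_intensity, min_separation)
    if (!nrow(cand)) next
    res <- vector("list", nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand$row[k]; j <- cand$col[k]
      if (i - h < 1 || i + h > nrow(frame) || j - h < 1 || j + h > ncol(frame)) next
      roi <- frame[(i - h):(i + h), (j - h):(j + h)]
      ft <- fit_gaussian_psf(roi, init = c(h + 1, h + 1),
                             pixel_size_nm = pixel_size_nm,
                             origin_nm = c((j - h - 1), (i - h - 1)) * pixel_size_nm)
      if (ft$fit_ok) {
        res[[k]] <- data.frame(frame = f - 1L, x_nm = ft$x_nm, y_nm = ft$y_nm,
                               photons = ft$photons, sigma_nm = ft$sigma_nm,
                               background = ft$background, fit_ok = TRUE)
      }
    }
    rows[[f]] <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(loc_table())
  out <- out[c("frame", "x_nm", "y_nm", "photons", "sigma_nm", "background", "fit_ok")]
  class(out) <- c("loc_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Cramer--Rao lower bound for integrated-Gaussian localization
#'
#' Numerically evaluates the Fisher information of the Poisson pixel model
#' (integrated symmetric Gaussian of `photons` expected photons, PSF s.d.
#' `sigma_px`, constant `background` photons/pixel, ROI side `roi_side`)
#' for the five parameters (x, y, sigma, N, b) and returns the lower bound
#' on the s.d. of the x (= y, by symmetry) position estimate, in pixels.
#' This is the textbook benchmark the localization accuracy of any unbiased
#' fitter is compared against; it is computed from the model expectation
#' alone, independently of the fitting code path.
#'
#' @param photons Expected photons in the spot.
#' @param background Background, photons/pixel.
#' @param sigma_px PSF s.d., pixels.
#' @param roi_side ROI side, pixels (odd).
#' @param x0,y0 True centre in ROI pixel units (defaults: ROI centre).
#' @return Lower bound on the x-position s.d., pixels.
#' @export
crlb_gaussian_psf <- function(photons, background, sigma_px, roi_side = 9,
                              x0 = roi_side / 2, y0 = roi_side / 2) {
  theta <- c(x = x0, y = y0, s = sigma_px, N = photons, b = background)
  mu_of <- function(th) as.vector(.psf_expected(roi_side, roi_side,
                                                th[1], th[2], th[3], th[4], th[5]))
  mu <- mu_of(theta)
  J <- matrix(NA_real_, length(mu), 5)
  for (k in 1:5) {
    hstep <- max(1e-5 * abs(theta[k]), 1e-6)
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + hstep; tm[k] <- tm[k] - hstep
    J[, k] <- (mu_of(tp) - mu_of(tm)) / (2 * hstep)
  }
  FI <- t(J) %*% (J / mu)
  sqrt(solve(FI)[1, 1])
}

#' Render a localization table into a super-resolution image
#'
#' Reconstructs the STORM image from the collection of centroids, either as
#' a 2D histogram (localization counts per pixel) or as a sum of unit-mass
#' discretized Gaussians. Total intensity equals the number of rendered
#' (in-extent) localizations in both modes.
#'
#' @param table A [loc_table()].
#' @param pixel_size_nm Rendering pixel size, nm. The package default of
#'   20 nm sits below typical SMLM localization precision so downstream
#'   pixel statistics are robust to the rendering grid.
#' @param mode `"histogram"` or `"gaussian"`.
#' @param gaussian_sd_nm Gaussian rendering kernel s.d., nm (> 0 for
#'   gaussian mode).
#' @param dim_px Length-2 (rows, cols) output size; default covers all
#'   localizations (plus a kernel apron in gaussian mode).
#' @param origin_nm nm coordinate of the top-left image corner.
#' @return A [rendered_image()].
#' @export
render <- function(table, pixel_size_nm = 20,
                   mode = c("histogram", "gaussian"), gaussian_sd_nm = NULL,
                   dim_px = NULL, origin_nm = c(0, 0)) {
  mode <- match.arg(mode)
  stopifnot(pixel_size_nm > 0)
  if (mode == "gaussian") stopifnot(!is.null(gaussian_sd_nm), gaussian_sd_nm > 0)
  p <- pixel_size_nm
  if (is.null(dim_px)) {
    apron <- if (mode == "gaussian") 4 * gaussian_sd_nm else 0
    if (nrow(table)) {
      nc <- ceiling((max(table$x_nm) - origin_nm[1] + apron) / p) + 1L
      nr <- ceiling((max(table$y_nm) - origin_nm[2] + apron) / p) + 1L
    } else nr <- nc <- 1L
    dim_px <- c(nr, nc)
  }
  nr <- dim_px[1]; nc <- dim_px[2]
  grid <- matrix(0, nr, nc)
  if (nrow(table) == 0) return(rendered_image(grid, p, origin_nm))
  xs <- (table$x_nm - origin_nm[1]) / p
  ys <- (table$y_nm - origin_nm[2]) / p
  if (mode == "histogram") {
    j <- floor(xs) + 1L
    i <- floor(ys) + 1L
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    if (any(ok)) {
      idx <- (j[ok] - 1L) * nr + i[ok]
      tab <- tabulate(idx, nbins = nr * nc)
      grid <- matrix(grid + tab, nr, nc)
    }
  } else {
    s <- gaussian_sd_nm / p
    half <- ceiling(4 * s) + 1L
    offs <- -half:half
    jc <- floor(xs) + 1L
    ic <- floor(ys) + 1L
    # separable per-offset pixel masses, vectorized over localizations:
    # column jc + a has mass pnorm((u + a)/s) - pnorm((u + a - 1)/s) with
    # u = jc - xs in (0, 1]
    ux <- jc - xs
    uy <- ic - ys
    PX <- vapply(c(offs[1] - 1L, offs), function(a) stats::pnorm((ux + a) / s),
                 numeric(length(xs)))
    PY <- vapply(c(offs[1] - 1L, offs), function(a) stats::pnorm((uy + a) / s),
                 numeric(length(ys)))
    MX <- PX[, -1, drop = FALSE] - PX[, -ncol(PX), drop = FALSE]
    MY <- PY[, -1, drop = FALSE] - PY[, -ncol(PY), drop = FALSE]
    # zero the out-of-image offsets, then normalize each localization to
    # unit total mass over its visible window (mass conservation)
    JJ <- outer(jc, offs, "+")
    II <- outer(ic, offs, "+")
    MX[JJ < 1L | JJ > nc] <- 0
    MY[II < 1L | II > nr] <- 0
    tot <- rowSums(MX) * rowSums(MY)
    keep <- which(tot > 0)
    if (length(keep)) {
      # separable splat as one sparse product: grid[i, j] gets
      # sum_k MY[k, i - ic_k] * MX[k, j - jc_k] / tot_k
      n <- length(keep)
      selY <- MY[keep, , drop = FALSE] > 0
      selX <- MX[keep, , drop = FALSE] > 0
      A <- Matrix::sparseMatrix(
        i = II[keep, , drop = FALSE][selY],
        j = row(selY)[selY],
        x = MY[keep, , drop = FALSE][selY],
        dims = c(nr, n))
      B <- Matrix::sparseMatrix(
        i = row(selX)[selX],
        j = JJ[keep, , drop = FALSE][selX],
        x = (MX[keep, , drop = FALSE] / tot[keep])[selX],
        dims = c(n, nc))
      grid <- grid + as.matrix(A %*% B)
    }
  }
  rendered_image(grid, p, origin_nm)
}

#' Correct stage drift in a localization table
#'
#' Two estimators for the slow stage/sample motion that blurs rendered
#' STORM images:
#'
#' * `"fiducial"`: tracks one fiducial marker (nearest localization to
#'   `fiducial_xy_nm` within `search_radius_nm`, required visible in >= 90%
#'   of frames), takes its displacement from the initial position, fills
#'   gaps by linear interpolation and smooths with a running median
#'   (`stats::runmed`, `endrule = "keep"`, window `smooth_k`).
#' * `"block_xcorr"`: splits frames into `n_blocks` contiguous blocks,
#'   renders each as a histogram image (`bin_nm` pixels), estimates the
#'   shift of each block against the first by the argmax of their FFT
#'   cross-correlation with three-point parabolic sub-pixel refinement, and
#'   interpolates linearly between block centres (linear extrapolation at
#'   the ends).
#'
#' The frame-0 drift estimate is forced to (0, 0) and subtracted from all
#' rows; frame indices and row count are never changed.
#'
#' @param table A [loc_table()].
#' @param method `"fiducial"` or `"block_xcorr"`.
#' @param fiducial_xy_nm Approximate marker position (fiducial method).
#' @param search_radius_nm Marker search radius, nm.
#' @param smooth_k Odd running-median window (frames); 1 disables smoothing.
#' @param n_blocks Number of blocks (block method; >= 2).
#' @param bin_nm Block-rendering pixel size, nm.
#' @param max_shift_nm Maximum drift search range, nm.
#' @return A list: `table` (corrected [loc_table()]) and `drift`
#'   (estimated trajectory, columns `frame`, `dx_nm`, `dy_nm`).
#' @export
correct_drift <- function(table, method = c("fiducial", "block_xcorr"),
                          fiducial_xy_nm = NULL, search_radius_nm = 500,
                          smooth_k = 5, n_blocks = 10, bin_nm = 10,
                          max_shift_nm = 200) {
  method <- match.arg(method)
  validate_loc_table(table)
  frames <- 0:max(table$frame)
  nF <- length(frames)
  if (method == "fiducial") {
    if (is.null(fiducial_xy_nm)) stop("fiducial method requires fiducial_xy_nm")
    px <- py <- rep(NA_real_, nF)
    ref <- as.numeric(fiducial_xy_nm)  # running reference follows the marker
    for (f in frames) {
      rows <- which(table$frame == f)
      if (!length(rows)) next
      d2 <- (table$x_nm[rows] - ref[1])^2 + (table$y_nm[rows] - ref[2])^2
      hit <- rows[d2 <= search_radius_nm^2]
      if (length(hit)) {
        px[f + 1] <- mean(table$x_nm[hit])
        py[f + 1] <- mean(table$y_nm[hit])
        ref <- c(px[f + 1], py[f + 1])
      }
    }
    vis <- mean(!is.na(px))
    if (vis < 0.9)
      stop(sprintf("fiducial visible in only %.0f%% of frames (need >= 90%%)", 100 * vis))
    px <- stats::approx(frames[!is.na(px)], px[!is.na(px)], xout = frames, rule = 2)$y
    py <- stats::approx(frames[!is.na(py)], py[!is.na(py)], xout = frames, rule = 2)$y
    dx <- px - px[1]; dy <- py - py[1]
    if (smooth_k > 1) {
      k <- min(smooth_k, if (nF %% 2) nF else nF - 1)
      dx <- stats::runmed(dx, k, endrule = "keep")
      dy <- stats::runmed(dy, k, endrule = "keep")
    }
    dx <- dx - dx[1]; dy <- dy - dy[1]
  } else {
    if (n_blocks < 2) stop("block_xcorr requires n_blocks >= 2")
    cuts <- floor(seq(0, nF, length.out = n_blocks + 1))
    ref <- NULL
    centers <- bx <- by <- numeric(n_blocks)
    origin <- c(min(table$x_nm), min(table$y_nm)) - 4 * bin_nm
    nc <- ceiling((max(table$x_nm) - origin[1]) / bin_nm) + 8L
    nr <- ceiling((max(table$y_nm) - origin[2]) / bin_nm) + 8L
    for (b in seq_len(n_blocks)) {
      inb <- table$frame >= cuts[b] & table$frame < cuts[b + 1]
      if (!any(inb)) stop("block ", b, " contains no localizations")
      img <- render(table[inb, , drop = FALSE], bin_nm, "histogram",
                    dim_px = c(nr, nc), origin_nm = origin)$grid
      centers[b] <- (cuts[b] + cuts[b + 1] - 1) / 2
      if (b == 1) {
        ref <- img
        bx[b] <- 0; by[b] <- 0
      } else {
        sh <- .xcorr_shift(ref, img, max_shift_px = ceiling(max_shift_nm / bin_nm))
        bx[b] <- sh[1] * bin_nm
        by[b] <- sh[2] * bin_nm
      }
    }
    dx <- .interp_extrap(centers, bx, frames)
    dy <- .interp_extrap(centers, by, frames)
    dx <- dx - dx[1]; dy <- dy - dy[1]
  }
  est <- data.frame(frame = frames, dx_nm = dx, dy_nm = dy)
  out <- table
  idx <- match(table$frame, frames)
  out$x_nm <- table$x_nm - dx[idx]
  out$y_nm <- table$y_nm - dy[idx]
  list(table = out, drift = est)
}

# Shift of image B relative to image A ((dx, dy) in pixels such that B is A
# displaced by +shift), via FFT cross-correlation. The integer argmax
# (restricted to |shift| <= max_shift_px) is refined to sub-pixel precision
# by an iterated baseline-subtracted centroid over a +/- refine_px window:
# sparse localization histograms make the correlation peak broad (it carries
# the structure autocorrelation) and noisy, so a windowed centroid is far
# more stable than a 3-point parabola.
.xcorr_shift <- function(A, B, max_shift_px = 20, refine_px = 8) {
  nr <- nrow(A); nc <- ncol(A)
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (nr * nc)
  # index k (0-based) corresponds to shift k, wrapped; fold to signed shifts
  sy <- c(0:(nr - 1)); sy[sy > nr / 2] <- sy[sy > nr / 2] - nr
  sx <- c(0:(nc - 1)); sx[sx > nc / 2] <- sx[sx > nc / 2] - nc
  ok <- outer(abs(sy) <= max_shift_px, abs(sx) <= max_shift_px)
  cc_ok <- cc; cc_ok[!ok] <- -Inf
  pk <- which(cc_ok == max(cc_ok), arr.ind = TRUE)[1, , drop = TRUE]
  cy <- sy[pk[1]]; cx <- sx[pk[2]]
  w <- refine_px
  off <- -w:w
  for (it in 1:3) {
    iy <- ((round(cy) + off) %% nr) + 1
    ix <- ((round(cx) + off) %% nc) + 1
    patch <- pmax(cc[iy, ix] - min(cc[iy, ix]), 0)
    tot <- sum(patch)
    if (tot <= 0) break
    cy <- round(cy) + sum(rowSums(patch) * off) / tot
    cx <- round(cx) + sum(colSums(patch) * off) / tot
  }
  c(cx, cy)
}

# Piecewise-linear interpolation with linear extrapolation at both ends.
.interp_extrap <- function(x, y, xout) {
  if (length(x) == 1) return(rep(y, length(xout)))
  out <- stats::approx(x, y, xout = xout, rule = 2)$y
  lo <- xout < x[1]
  if (any(lo)) {
    sl <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + sl * (xout[lo] - x[1])
  }
  n <- length(x)
  hi <- xout > x[n]
  if (any(hi)) {
    sl <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + sl * (xout[hi] - x[n])
  }
  out
}
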