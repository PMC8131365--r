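#' Estimate a similarity transform from matched points
#'
#' Closed-form least-squares (Procrustes/Umeyama) estimate of the
#' similarity transform -- isotropic scale, rotation and translation, no
#' reflection -- mapping `src` onto `dst`, minimizing the sum of squared
#' residuals. This is the geometric model for overlaying STORM and EM
#' images of the same field from fiducial reference coordinates detected in
#' both modalities.
#'
#' @param src,dst Matrices of matched 2D points (n x 2, equal n >= 2);
#'   `src` must not be fully coincident.
#' @return An object of class `similarity_transform`: `scale`,
#'   `rotation_deg`, `translation` (length 2, destination units),
#'   `rms_residual` (per-coordinate root-mean-square residual, so that
#'   isotropic fiducial jitter of per-axis s.d. `s` yields a residual near
#'   `s`), and the 2x2 rotation `matrix`.
#' @examples
#' src <- cbind(c(0, 1, 0), c(0, 0, 1))
#' estimate_similarity(src, src * 2)
#' @export
estimate_similarity <- function(src, dst) {
  src <- matrix(as.numeric(as.matrix(src)), ncol = 2)
  dst <- matrix(as.numeric(as.matrix(dst)), ncol = 2)
  n <- nrow(src)
  if (n < 2 || nrow(dst) != n)
    stop("need equally many src and dst points, at least 2 pairs")
  sc <- colMeans(src); dc <- colMeans(dst)
  S <- sweep(src, 2, sc); D <- sweep(dst, 2, dc)
  varS <- sum(S^2)
  if (varS < 1e-18) stop("src points are coincident; transform is degenerate")
  H <- t(S) %*% D
  sv <- svd(H)
  sgn <- diag(c(1, sign(det(sv$v %*% t(sv$u)))))
  Rm <- sv$v %*% sgn %*% t(sv$u)
  scale <- sum(diag(diag(sv$d) %*% sgn)) / varS
  trans <- dc - scale * as.vector(Rm %*% sc)
  res <- dst - (t(scale * Rm %*% t(src)) + matrix(trans, n, 2, byrow = TRUE))
  structure(
    list(scale = scale,
         rotation_deg = atan2(Rm[2, 1], Rm[1, 1]) * 180 / pi,
         translation = as.numeric(trans),
         # per-coordinate RMS, commensurate with the per-axis s.d. of
         # isotropic fiducial jitter
         rms_residual = sqrt(mean(res^2)),
         matrix = Rm),
    class = "similarity_transform"
  )
}

#' Build a similarity transform from parameters
#'
#' @param scale Isotropic scale (> 0).
#' @param rotation_deg Rotation angle, degrees (x towards y).
#' @param translation Length-2 translation.
#' @return A `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 translation = c(0, 0)) {
  stopifnot(scale > 0, length(translation) == 2)
  a <- rotation_deg * pi / 180
  structure(
    list(scale = scale, rotation_deg = rotation_deg,
         translation = as.numeric(translation), rms_residual = NA_real_,
         matrix = matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)),
    class = "similarity_transform"
  )
}

#' Invert a similarity transform
#'
#' @param transform A `similarity_transform`.
#' @return The inverse `similarity_transform`; composing the two is the
#'   identity.
#' @export
invert_similarity <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  Rinv <- t(transform$matrix)
  structure(
    list(scale = 1 / transform$scale,
         rotation_deg = -transform$rotation_deg,
         translation = as.numeric(-(Rinv %*% transform$translation) / transform$scale),
         rms_residual = NA_real_,
         matrix = Rinv),
    class = "similarity_transform"
  )
}

#' Apply a similarity transform
#'
#' Maps a point set exactly, or resamples a rendered image onto the
#' destination grid with bilinear interpolation (each destination pixel
#' centre is pulled back through the inverse transform and sampled in the
#' source; out-of-source pixels are 0).
#'
#' @param transform A `similarity_transform`.
#' @param target An n x 2 point matrix, a [loc_table()], or a
#'   [rendered_image()].
#' @param dim_px Output image size (rows, cols) for image targets; default
#'   the source size.
#' @param pixel_size_nm Output pixel size for image targets; default the
#'   source pixel size.
#' @return Same type as `target`.
#' @export
apply_transform <- function(transform, target, dim_px = NULL,
                            pixel_size_nm = NULL) {
  stopifnot(inherits(transform, "similarity_transform"))
  s <- transform$scale; Rm <- transform$matrix; tr <- transform$translation
  if (inherits(target, "rendered_image")) {
    p_out <- if (is.null(pixel_size_nm)) target$pixel_size_nm else pixel_size_nm
    nd <- if (is.null(dim_px)) dim(target$grid) else dim_px
    nr <- nd[1]; nc <- nd[2]
    inv <- invert_similarity(transform)
    xc <- (seq_len(nc) - 0.5) * p_out
    yc <- (seq_len(nr) - 0.5) * p_out
    X <- matrix(xc, nr, nc, byrow = TRUE)
    Y <- matrix(yc, nr, nc)
    sx <- inv$scale * (inv$matrix[1, 1] * X + inv$matrix[1, 2] * Y) + inv$translation[1]
    sy <- inv$scale * (inv$matrix[2, 1] * X + inv$matrix[2, 2] * Y) + inv$translation[2]
    # source pixel-centre coordinates (continuous, 1-based pixel index space)
    u <- (sx - target$origin_nm[1]) / target$pixel_size_nm + 0.5
    v <- (sy - target$origin_nm[2]) / target$pixel_size_nm + 0.5
    g <- target$grid
    snr <- nrow(g); snc <- ncol(g)
    j0 <- floor(u); i0 <- floor(v)
    fu <- u - j0; fv <- v - i0
    pick <- function(ii, jj) {
      ok <- ii >= 1 & ii <= snr & jj >= 1 & jj <= snc
      out <- matrix(0, nr, nc)
      out[ok] <- g[cbind(ii[ok], jj[ok])]
      out
    }
    grid <- (1 - fu) * (1 - fv) * pick(i0, j0) +
            fu * (1 - fv) * pick(i0, j0 + 1) +
            (1 - fu) * fv * pick(i0 + 1, j0) +
            fu * fv * pick(i0 + 1, j0 + 1)
    return(rendered_image(grid, p_out, c(0, 0)))
  }
  if (inherits(target, "loc_table") ||
      (is.data.frame(target) && all(c("x_nm", "y_nm") %in% names(target)))) {
    pts <- cbind(target$x_nm, target$y_nm)
    mapped <- t(s * Rm %*% t(pts)) + matrix(tr, nrow(pts), 2, byrow = TRUE)
    out <- target
    out$x_nm <- mapped[, 1]; out$y_nm <- mapped[, 2]
    return(out)
  }
  pts <- matrix(as.numeric(as.matrix(target)), ncol = 2)
  t(s * Rm %*% t(pts)) + matrix(tr, nrow(pts), 2, byrow = TRUE)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity_transform: scale %.6g, rotation %.4g deg, translation (%.4g, %.4g), rms %.4g\n",
    x$scale, x$rotation_deg, x$translation[1], x$translation[2],
    x$rms_residual))
  invisible(x)
}
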