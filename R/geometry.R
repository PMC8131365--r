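#' Platelet geometry
#'
#' Describes the idealized geometry of a (spread) platelet used by the
#' synthetic-scene generator: a disk of radius `radius_nm` centred at
#' `centroid_nm`, with an optional central "yolk" region of radius
#' `yolk_radius_nm` emulating the fried-egg morphology of spread platelets,
#' and an activation stage label in minutes.
#'
#' Coordinates are continuous, in nanometres, with the origin at the image
#' top-left corner, x rightward and y downward. Pixel `(i, j)` (row `i`,
#' column `j`, 1-based) of an image with pixel size `p` covers the half-open
#' square `[(j-1)p, jp) x [(i-1)p, ip)`; its centre is at
#' `((j-0.5)p, (i-0.5)p)`.
#'
#' @param radius_nm Platelet disk radius in nm (> 0). Resting platelets are
#'   2--4 um in diameter; spread platelets reach areas of roughly
#'   10--50 um^2.
#' @param centroid_nm Numeric length-2, platelet centre (x, y) in nm.
#' @param yolk_radius_nm Radius of the central organelle-rich "yolk" region,
#'   in nm; `0 <= yolk_radius_nm <= radius_nm`.
#' @param stage_min Activation time point label in minutes (the study design
#'   uses 0, 5, 10, 15 and 20 min, but any label is accepted).
#' @return An object of class `platelet_geometry`.
#' @examples
#' geom <- platelet_geometry(radius_nm = 1500)
#' geom$radius_nm
#' @export
platelet_geometry <- function(radius_nm,
                              centroid_nm = c(radius_nm + 200, radius_nm + 200),
                              yolk_radius_nm = 0,
                              stage_min = 0) {
  stopifnot(is.numeric(radius_nm), length(radius_nm) == 1, radius_nm > 0)
  stopifnot(length(centroid_nm) == 2, all(is.finite(centroid_nm)))
  stopifnot(yolk_radius_nm >= 0, yolk_radius_nm <= radius_nm)
  structure(
    list(
      centroid_nm = as.numeric(centroid_nm),
      radius_nm = as.numeric(radius_nm),
      yolk_radius_nm = as.numeric(yolk_radius_nm),
      stage_min = stage_min
    ),
    class = "platelet_geometry"
  )
}

#' Radial placement law
#'
#' Parameterizes how organelle centres are distributed with radial distance
#' `r` from the platelet centroid. Three two-parameter families cover the
#' patterns quantified by centralization profiles:
#'
#' * `uniform`: uniform over the disk (`concentration` is ignored);
#' * `centralized`: the radial coordinate follows a half-Gaussian with scale
#'   `concentration` (nm), truncated at the disk radius;
#' * `peripheral`: the distance from the rim, `R - r`, follows a
#'   half-Gaussian with scale `concentration` (nm), truncated to `[0, R]`.
#'
#' The angular coordinate is always uniform, so the induced density over the
#' disk integrates to 1.
#'
#' @param kind One of `"uniform"`, `"centralized"`, `"peripheral"`.
#' @param concentration Scale of the half-Gaussian, in nm (> 0 unless
#'   `kind = "uniform"`).
#' @return An object of class `radial_law`.
#' @examples
#' radial_law("centralized", concentration = 300)
#' @export
radial_law <- function(kind = c("uniform", "centralized", "peripheral"),
                       concentration = NA_real_) {
  kind <- match.arg(kind)
  if (kind != "uniform") {
    stopifnot(is.numeric(concentration), length(concentration) == 1,
              is.finite(concentration), concentration > 0)
  }
  structure(list(kind = kind, concentration = as.numeric(concentration)),
            class = "radial_law")
}

#' Cumulative distribution of the radial coordinate under a placement law
#'
#' Closed-form CDF of the radial distance `r` for points drawn on a disk of
#' radius `R_nm` under a [radial_law()]. Used by the generator's inverse-CDF
#' sampler and available for calibration checks.
#'
#' @param law A [radial_law()].
#' @param r Radial distances, nm.
#' @param R_nm Disk radius, nm.
#' @return `P(radius <= r)` for each element of `r`.
#' @export
radial_cdf <- function(law, r, R_nm) {
  stopifnot(inherits(law, "radial_law"), R_nm > 0)
  r <- pmin(pmax(r, 0), R_nm)
  switch(law$kind,
    uniform = (r / R_nm)^2,
    centralized = {
      s <- law$concentration
      (2 * stats::pnorm(r / s) - 1) / (2 * stats::pnorm(R_nm / s) - 1)
    },
    peripheral = {
      # R - r is truncated half-Gaussian, so P(radius <= r) = P(R - r' >= R - r)
      s <- law$concentration
      z <- 2 * stats::pnorm(R_nm / s) - 1
      1 - (2 * stats::pnorm((R_nm - r) / s) - 1) / z
    }
  )
}

# Inverse-CDF draw of n radial distances on [0, R_nm] under `law`.
.sample_radius <- function(n, law, R_nm) {
  u <- stats::runif(n)
  switch(law$kind,
    uniform = R_nm * sqrt(u),
    centralized = {
      s <- law$concentration
      s * stats::qnorm((1 + u * (2 * stats::pnorm(R_nm / s) - 1)) / 2)
    },
    peripheral = {
      s <- law$concentration
      R_nm - s * stats::qnorm((1 + (1 - u) * (2 * stats::pnorm(R_nm / s) - 1)) / 2)
    }
  )
}

#' @export
print.platelet_geometry <- function(x, ...) {
  cat(sprintf(
    "platelet_geometry: R = %.0f nm, yolk = %.0f nm, centroid = (%.0f, %.0f) nm, stage = %s min\n",
    x$radius_nm, x$yolk_radius_nm, x$centroid_nm[1], x$centroid_nm[2],
    format(x$stage_min)
  ))
  invisible(x)
}

#' @export
print.radial_law <- function(x, ...) {
  cat(sprintf("radial_law: %s (concentration = %s nm)\n", x$kind,
              format(x$concentration)))
  invisible(x)
}
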