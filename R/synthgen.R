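#' Sample organelle centres inside a platelet disk
#'
#' Draws `n` organelle centres under a [radial_law()] (uniform, centralized
#' or peripheral), optionally keeping a margin from the rim (so that
#' finite-size organelles stay inside the disk) and enforcing a minimum
#' pairwise separation (organelle clusters such as actin nodules are
#' discrete, non-overlapping structures).
#'
#' @param n Number of centres (>= 0).
#' @param law A [radial_law()].
#' @param geometry A [platelet_geometry()].
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param margin_nm Centres are restricted to radius `radius_nm - margin_nm`.
#' @param min_separation_nm Minimum pairwise centre distance (rejection
#'   sampling; errors if the packing is infeasible).
#' @return An `n x 2` matrix of (x, y) centres in nm.
#' @examples
#' g <- platelet_geometry(1500)
#' sample_organelle_centers(7, radial_law("uniform"), g, seed = 1)
#' @export
sample_organelle_centers <- function(n, law, geometry, seed = NULL,
                                     margin_nm = 0, min_separation_nm = 0) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != round(n))
    stop("`n` must be a non-negative integer")
  stopifnot(inherits(law, "radial_law"), inherits(geometry, "platelet_geometry"))
  if (!is.null(seed)) set.seed(seed)
  R_eff <- geometry$radius_nm - margin_nm
  if (R_eff <= 0) stop("margin_nm leaves no room inside the platelet")
  out <- matrix(numeric(0), ncol = 2,
                dimnames = list(NULL, c("x_nm", "y_nm")))
  if (n == 0) return(out)
  accepted <- matrix(NA_real_, nrow = n, ncol = 2)
  k <- 0L
  tries <- 0L
  max_tries <- 10000L * n
  while (k < n) {
    m <- max(n - k, 32L)
    r <- .sample_radius(m, law, R_eff)
    th <- stats::runif(m, 0, 2 * pi)
    cand <- cbind(geometry$centroid_nm[1] + r * cos(th),
                  geometry$centroid_nm[2] + r * sin(th))
    for (i in seq_len(m)) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("could not place ", n, " centres with min_separation_nm = ",
             min_separation_nm, " (packing too dense)")
      if (k > 0 && min_separation_nm > 0) {
        d2 <- (accepted[seq_len(k), 1] - cand[i, 1])^2 +
              (accepted[seq_len(k), 2] - cand[i, 2])^2
        if (any(d2 < min_separation_nm^2)) next
      }
      k <- k + 1L
      accepted[k, ] <- cand[i, ]
      if (k == n) break
    }
  }
  colnames(accepted) <- c("x_nm", "y_nm")
  accepted
}

#' Sample localizations around cluster centres
#'
#' Emulates the localization point pattern of labelled organelle clusters:
#' per cluster, points are drawn uniformly on a disk of radius
#' `cluster_radius_nm` and convolved with isotropic Gaussian localization
#' noise of standard deviation `precision_nm`. Ground-truth membership is
#' recorded in the `structure_id` column.
#'
#' @param centers Matrix of cluster centres (one row per cluster, columns
#'   x, y in nm), e.g. from [sample_organelle_centers()].
#' @param cluster_radius_nm Cluster disk radius, nm (> 0).
#' @param locs_per_cluster Localizations per cluster.
#' @param precision_nm Localization precision (Gaussian s.d.), nm (>= 0).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param n_frames Localizations are assigned uniformly at random to frames
#'   `0 .. n_frames - 1`.
#' @param photons Photon count recorded per localization.
#' @return A [loc_table()] with `structure_id` and `structure_type`
#'   (`"cluster"`) columns. Empty `centers` give an empty table.
#' @export
sample_cluster_localizations <- function(centers, cluster_radius_nm,
                                         locs_per_cluster, precision_nm,
                                         seed = NULL, n_frames = 1L,
                                         photons = 1000) {
  stopifnot(cluster_radius_nm > 0, precision_nm >= 0, locs_per_cluster >= 0)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (!is.null(seed)) set.seed(seed)
  n_cl <- nrow(centers)
  n <- n_cl * locs_per_cluster
  if (n == 0) {
    return(loc_table(structure_id = integer(), structure_type = character()))
  }
  id <- rep(seq_len(n_cl), each = locs_per_cluster)
  r <- cluster_radius_nm * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- centers[id, 1] + r * cos(th) + stats::rnorm(n, 0, precision_nm)
  y <- centers[id, 2] + r * sin(th) + stats::rnorm(n, 0, precision_nm)
  frame <- sample.int(n_frames, n, replace = TRUE) - 1L
  loc_table(x_nm = x, y_nm = y, frame = frame, photons = photons,
            sigma_nm = precision_nm, fit_ok = TRUE,
            structure_id = id, structure_type = "cluster")
}

# Von Mises sampler on (-pi, pi], Best & Fisher (1979) rejection scheme.
# kappa = 0 degenerates to the uniform circular distribution.
.rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  k <- 0L
  while (k < n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      k <- k + 1L
      out[k] <- sign(u3 - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Wrap orientation angles (degrees) into [-90, 90).
.wrap180 <- function(theta_deg) ((theta_deg + 90) %% 180) - 90

#' Generate a filament field inside a platelet
#'
#' Emulates STORM images of actin filaments: straight filaments whose
#' orientations follow an axial von Mises distribution (period 180 degrees)
#' with mean `orientation_mean_deg` and concentration `kappa`; `kappa = 0`
#' gives isotropic orientations. Each filament is the full chord of the
#' platelet disk through a uniformly drawn interior anchor point, sampled
#' with `points_per_filament` localizations plus Gaussian localization
#' noise.
#'
#' Orientation convention: angles in degrees in `[-90, 90)`, measured from
#' the +x axis towards +y (y downward, matching the image convention).
#'
#' @param n_filaments Number of filaments.
#' @param orientation_mean_deg Mean orientation, degrees in `[-90, 90)`.
#' @param orientation_kappa Von Mises concentration (>= 0) of the doubled
#'   angles; `Inf` makes every filament exactly `orientation_mean_deg`.
#' @param geometry A [platelet_geometry()].
#' @param points_per_filament Localizations per filament.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param precision_nm Localization noise s.d., nm.
#' @return A [loc_table()] with `structure_id`/`structure_type`
#'   (`"filament"`) columns and attributes `directions_deg` (ground-truth
#'   orientations) and `segments` (n x 4 matrix of chord endpoints).
#' @export
make_filament_scene <- function(n_filaments, orientation_mean_deg,
                                orientation_kappa, geometry,
                                points_per_filament = 200, seed = NULL,
                                precision_nm = 0) {
  stopifnot(orientation_mean_deg >= -90, orientation_mean_deg < 90,
            orientation_kappa >= 0, n_filaments >= 0,
            inherits(geometry, "platelet_geometry"))
  if (!is.null(seed)) set.seed(seed)
  R <- geometry$radius_nm
  cx <- geometry$centroid_nm[1]; cy <- geometry$centroid_nm[2]
  if (is.infinite(orientation_kappa)) {
    theta <- rep(orientation_mean_deg, n_filaments)
  } else {
    psi <- .rvonmises(n_filaments, 0, orientation_kappa)
    theta <- .wrap180(orientation_mean_deg + psi * (180 / pi) / 2)
  }
  xs <- ys <- numeric(0)
  ids <- integer(0)
  segs <- matrix(NA_real_, nrow = n_filaments, ncol = 4,
                 dimnames = list(NULL, c("x0", "y0", "x1", "y1")))
  for (i in seq_len(n_filaments)) {
    # anchor uniform in the disk; chord through it along direction theta[i]
    ra <- R * sqrt(stats::runif(1)); ta <- stats::runif(1, 0, 2 * pi)
    ax <- ra * cos(ta); ay <- ra * sin(ta)
    d <- c(cos(theta[i] * pi / 180), sin(theta[i] * pi / 180))
    # solve |a + t d| = R for t
    bq <- ax * d[1] + ay * d[2]
    disc <- bq^2 - (ra^2 - R^2)
    t0 <- -bq - sqrt(disc); t1 <- -bq + sqrt(disc)
    tt <- stats::runif(points_per_filament, t0, t1)
    xs <- c(xs, cx + ax + tt * d[1])
    ys <- c(ys, cy + ay + tt * d[2])
    ids <- c(ids, rep(i, points_per_filament))
    segs[i, ] <- c(cx + ax + t0 * d[1], cy + ay + t0 * d[2],
                   cx + ax + t1 * d[1], cy + ay + t1 * d[2])
  }
  if (precision_nm > 0 && length(xs)) {
    xs <- xs + stats::rnorm(length(xs), 0, precision_nm)
    ys <- ys + stats::rnorm(length(ys), 0, precision_nm)
  }
  tb <- loc_table(x_nm = xs, y_nm = ys, frame = 0L, sigma_nm = precision_nm,
                  structure_id = ids, structure_type = "filament")
  attr(tb, "directions_deg") <- theta
  attr(tb, "segments") <- segs
  tb
}

#' Stage drift trajectory
#'
#' Per-frame stage displacement in nm; frame 0 displacement is (0, 0) by
#' construction.
#'
#' @param n_frames Number of frames.
#' @param type `"none"`, `"linear"` (ramps to `total_nm`), or
#'   `"random_walk"` (per-axis Gaussian increments of s.d. `step_sd_nm`).
#' @param total_nm Length-2 total displacement reached at the final frame
#'   (linear type).
#' @param step_sd_nm Random-walk step s.d., nm.
#' @param seed Integer RNG seed (random walk only).
#' @return A `data.frame` with columns `frame`, `dx_nm`, `dy_nm`.
#' @export
drift_trajectory <- function(n_frames, type = c("none", "linear", "random_walk"),
                             total_nm = c(0, 0), step_sd_nm = 0.5, seed = NULL) {
  type <- match.arg(type)
  stopifnot(n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  f <- seq_len(n_frames) - 1L
  s <- if (n_frames > 1) f / (n_frames - 1) else 0
  d <- switch(type,
    none = cbind(0 * s, 0 * s),
    linear = cbind(total_nm[1] * s, total_nm[2] * s),
    random_walk = {
      dx <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd_nm)))
      dy <- cumsum(c(0, stats::rnorm(n_frames - 1, 0, step_sd_nm)))
      cbind(dx, dy)
    }
  )
  data.frame(frame = f, dx_nm = d[, 1], dy_nm = d[, 2])
}

#' Assemble a synthetic platelet scene
#'
#' Bundles the ground truth of a simulated platelet: geometry, organelle
#' cluster centres and radius, emitter positions (cluster localizations,
#' filament points and uniform background over the platelet disk), and all
#' generation parameters including the seed, so that regeneration with the
#' same parameters is bit-for-bit reproducible.
#'
#' @param geometry A [platelet_geometry()].
#' @param n_clusters Number of organelle clusters.
#' @param cluster_diameter_nm Cluster diameter, nm (the activated-platelet
#'   actin-nodule scale is about 410 nm; dense granules 200--250 nm).
#' @param law A [radial_law()] for cluster placement.
#' @param locs_per_cluster Localizations per cluster.
#' @param precision_nm Localization precision s.d., nm.
#' @param background_per_um2 Uniform background localization density over
#'   the platelet disk, localizations per um^2.
#' @param min_separation_nm Minimum cluster centre separation; the default
#'   (1.5 x diameter) keeps clusters resolvable as distinct components.
#' @param n_frames Number of acquisition frames localizations are spread over.
#' @param seed Integer RNG seed recorded in `params`.
#' @return An object of class `synthetic_scene`: a list with `geometry`,
#'   `organelle_centers`, `organelle_radius_nm`, `locs` (a [loc_table()]
#'   with ground-truth membership), and `params`.
#' @examples
#' sc <- synthetic_platelet_scene(seed = 1, n_clusters = 6)
#' nrow(sc$locs)
#' @export
synthetic_platelet_scene <- function(geometry = platelet_geometry(1500),
                                     n_clusters = 6,
                                     cluster_diameter_nm = 410,
                                     law = radial_law("uniform"),
                                     locs_per_cluster = 600,
                                     precision_nm = 20,
                                     background_per_um2 = 10,
                                     min_separation_nm = 1.5 * cluster_diameter_nm,
                                     n_frames = 1L,
                                     seed = 1L) {
  stopifnot(inherits(geometry, "platelet_geometry"))
  set.seed(seed)
  rad <- cluster_diameter_nm / 2
  centers <- sample_organelle_centers(n_clusters, law, geometry, seed = NULL,
                                      margin_nm = rad,
                                      min_separation_nm = min_separation_nm)
  locs <- sample_cluster_localizations(centers, rad, locs_per_cluster,
                                       precision_nm, seed = NULL,
                                       n_frames = n_frames)
  n_bg <- stats::rpois(1, background_per_um2 * pi * (geometry$radius_nm / 1000)^2)
  if (n_bg > 0) {
    r <- geometry$radius_nm * sqrt(stats::runif(n_bg))
    th <- stats::runif(n_bg, 0, 2 * pi)
    bg <- loc_table(x_nm = geometry$centroid_nm[1] + r * cos(th),
                    y_nm = geometry$centroid_nm[2] + r * sin(th),
                    frame = sample.int(n_frames, n_bg, replace = TRUE) - 1L,
                    sigma_nm = precision_nm,
                    structure_id = 0L, structure_type = "background")
    locs <- rbind(locs, bg)
    class(locs) <- c("loc_table", "data.frame")
  }
  structure(
    list(
      geometry = geometry,
      organelle_centers = centers,
      organelle_radius_nm = rad,
      locs = locs,
      params = list(
        n_clusters = n_clusters, cluster_diameter_nm = cluster_diameter_nm,
        law = unclass(law), locs_per_cluster = locs_per_cluster,
        precision_nm = precision_nm, background_per_um2 = background_per_um2,
        min_separation_nm = min_separation_nm, n_frames = n_frames, seed = seed
      )
    ),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "synthetic_scene: %d clusters (d = %.0f nm) in platelet R = %.0f nm, %d localizations\n",
    nrow(x$organelle_centers), 2 * x$organelle_radius_nm,
    x$geometry$radius_nm, nrow(x$locs)
  ))
  invisible(x)
}

# Mass of a 1D unit Gaussian integrated over pixels with the given edges.
.gauss_pixel_mass <- function(edges, center, sd) {
  diff(stats::pnorm((edges - center) / sd))
}

#' Simulate an EMCCD frame stack from emitter positions
#'
#' Renders raw acquisition frames: per frame, each emitter is independently
#' active with probability `blink_on_prob` (memoryless blinking); active
#' emitters contribute an integrated symmetric Gaussian PSF of
#' `photons_mean` expected photons (per-pixel mass via the Gaussian
#' error-function integral, not point sampling); a constant background
#' expectation is added; then per-pixel Poisson shot noise and additive
#' Gaussian readout noise are applied. Stage drift displaces true positions
#' frame by frame.
#'
#' @param emitters Matrix of emitter positions (x, y) in nm, or a
#'   `synthetic_scene` (its distinct cluster localization positions are not
#'   used; emitters must be supplied explicitly for scenes -- pass
#'   `scene$organelle_centers` or any n x 2 matrix).
#' @param n_frames Number of frames (0 gives an empty stack).
#' @param blink_on_prob Per-frame activation probability.
#' @param photons_mean Expected photons per active emitter per frame.
#' @param psf_sigma_nm PSF standard deviation, nm.
#' @param pixel_size_nm Camera pixel size, nm.
#' @param background_rate Expected background, photons/pixel/frame.
#' @param readout_sd Gaussian readout noise s.d., photons.
#' @param drift A [drift_trajectory()] with at least `n_frames` rows, or
#'   `NULL` for no drift.
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param dim_px Length-2 image size (rows, cols); default covers all
#'   emitters plus a 5 sigma apron.
#' @param shot_noise Apply Poisson shot noise (set `FALSE`, with
#'   `readout_sd = 0` and `blink_on_prob = 1`, for noise-free expectation
#'   frames).
#' @return A list: `stack` (rows x cols x n_frames array, photons),
#'   `events` (data.frame of ground-truth active-emitter events with true
#'   and drifted positions), `pixel_size_nm`, `drift`.
#' @export
simulate_frames <- function(emitters, n_frames, blink_on_prob = 0.5,
                            photons_mean = 1000, psf_sigma_nm = 120,
                            pixel_size_nm = 100, background_rate = 10,
                            readout_sd = 0, drift = NULL, seed = NULL,
                            dim_px = NULL, shot_noise = TRUE) {
  stopifnot(blink_on_prob >= 0, blink_on_prob <= 1, photons_mean >= 0,
            psf_sigma_nm > 0, pixel_size_nm > 0, background_rate >= 0,
            readout_sd >= 0, n_frames >= 0)
  if (inherits(emitters, "synthetic_scene")) emitters <- emitters$organelle_centers
  emitters <- matrix(as.numeric(emitters), ncol = 2)
  if (!is.null(seed)) set.seed(seed)
  p <- pixel_size_nm
  if (is.null(dim_px)) {
    apron <- 5 * psf_sigma_nm
    nc <- ceiling((max(emitters[, 1], 0) + apron) / p)
    nr <- ceiling((max(emitters[, 2], 0) + apron) / p)
    dim_px <- c(nr, nc)
  }
  nr <- dim_px[1]; nc <- dim_px[2]
  if (n_frames == 0) {
    return(list(stack = array(0, c(nr, nc, 0)),
                events = data.frame(frame = integer(), emitter = integer(),
                                    x_nm = numeric(), y_nm = numeric(),
                                    x_drifted_nm = numeric(), y_drifted_nm = numeric()),
                pixel_size_nm = p, drift = drift))
  }
  if (is.null(drift)) drift <- drift_trajectory(n_frames, "none")
  stopifnot(nrow(drift) >= n_frames)
  stack <- array(0, c(nr, nc, n_frames))
  nE <- nrow(emitters)
  half <- ceiling(4 * psf_sigma_nm / p) + 1L
  ev <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    expected <- matrix(background_rate, nr, nc)
    active <- which(stats::runif(nE) < blink_on_prob)
    if (length(active)) {
      xs <- emitters[active, 1] + drift$dx_nm[f]
      ys <- emitters[active, 2] + drift$dy_nm[f]
      for (k in seq_along(active)) {
        jc <- floor(xs[k] / p) + 1L
        ic <- floor(ys[k] / p) + 1L
        j0 <- max(1L, jc - half); j1 <- min(nc, jc + half)
        i0 <- max(1L, ic - half); i1 <- min(nr, ic + half)
        if (j0 > j1 || i0 > i1) next
        mx <- .gauss_pixel_mass(((j0 - 1):j1) * p, xs[k], psf_sigma_nm)
        my <- .gauss_pixel_mass(((i0 - 1):i1) * p, ys[k], psf_sigma_nm)
        expected[i0:i1, j0:j1] <- expected[i0:i1, j0:j1] +
          photons_mean * outer(my, mx)
      }
      ev[[f]] <- data.frame(frame = f - 1L, emitter = active,
                            x_nm = emitters[active, 1], y_nm = emitters[active, 2],
                            x_drifted_nm = xs, y_drifted_nm = ys)
    }
    frame <- if (shot_noise) matrix(stats::rpois(nr * nc, expected), nr, nc) else expected
    if (readout_sd > 0) frame <- frame + matrix(stats::rnorm(nr * nc, 0, readout_sd), nr, nc)
    stack[, , f] <- frame
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(frame = integer(), emitter = integer(),
                         x_nm = numeric(), y_nm = numeric(),
                         x_drifted_nm = numeric(), y_drifted_nm = numeric())
  list(stack = stack, events = events, pixel_size_nm = p, drift = drift[seq_len(n_frames), ])
}
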