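# Plain-text I/O. Every CSV starts with a single versioned comment line so
# files are self-describing; readers skip lines starting with '#'.

.fmt_version <- "plateletquant-v1"

.write_csv_versioned <- function(df, path, kind) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    # doubles are written with 17 significant digits so values round-trip
    # bit-exactly through write -> read (stage-skip equivalence depends on it)
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- "NA"
      df[[nm]] <- v
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s", .fmt_version, kind), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_versioned <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write localization tables
#'
#' CSV dialect: `frame,x_nm,y_nm,photons,sigma_nm,background,fit_ok` (plus
#' any extra ground-truth columns), one versioned comment header line.
#'
#' @param table A [loc_table()].
#' @param path File path.
#' @return `read_localizations` returns a [loc_table()];
#'   `write_localizations` returns `path` invisibly.
#' @export
write_localizations <- function(table, path) {
  validate_loc_table(table)
  .write_csv_versioned(as.data.frame(table), path, "localizations")
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  tb <- .read_csv_versioned(path)
  tb$fit_ok <- as.logical(tb$fit_ok)
  for (nm in c("x_nm", "y_nm", "photons", "sigma_nm", "background")) {
    tb[[nm]] <- as.numeric(tb[[nm]])  # all-NA columns parse as logical
  }
  class(tb) <- c("loc_table", "data.frame")
  validate_loc_table(tb)
  tb
}

#' Read and write drift trajectories
#'
#' CSV columns: `frame,dx_nm,dy_nm`.
#'
#' @param drift A drift trajectory data.frame.
#' @param path File path.
#' @export
write_drift <- function(drift, path) {
  stopifnot(all(c("frame", "dx_nm", "dy_nm") %in% names(drift)))
  .write_csv_versioned(drift, path, "drift")
}

#' @rdname write_drift
#' @export
read_drift <- function(path) .read_csv_versioned(path)

#' Write cluster statistics
#'
#' CSV columns `cluster_id,area_nm2,eq_diameter_nm,cx_nm,cy_nm,pixels`
#' (plus pre-dilation core columns when present).
#'
#' @param clusters A `cluster_set`.
#' @param path File path.
#' @export
write_clusters <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  st <- clusters$stats
  lead <- c("cluster_id", "area_nm2", "eq_diameter_nm", "cx_nm", "cy_nm", "pixels")
  st <- st[c(lead, setdiff(names(st), lead))]
  .write_csv_versioned(st, path, "clusters")
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) .read_csv_versioned(path)

#' Write a radial profile
#'
#' CSV columns `bin_lo,bin_hi,counts,area_fraction,density_fraction`.
#'
#' @param profile A `radial_profile`.
#' @param path File path.
#' @export
write_radial_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  .write_csv_versioned(as.data.frame(profile), path, "radial_profile")
}

#' @rdname write_radial_profile
#' @export
read_radial_profile <- function(path) {
  out <- .read_csv_versioned(path)
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Write a directionality histogram and peak fit
#'
#' The histogram goes to CSV (`theta_deg,amount`); the peak fit to JSON
#' (`mu_deg, sigma_deg, amplitude, baseline, peak_height, converged,
#' method`).
#'
#' @param hist A `directionality_histogram`.
#' @param path File path.
#' @export
write_directionality <- function(hist, path) {
  .write_csv_versioned(as.data.frame(hist), path, "directionality")
}

#' @rdname write_directionality
#' @export
read_directionality <- function(path) {
  out <- .read_csv_versioned(path)
  attr(out, "method") <- "gradient"
  class(out) <- c("directionality_histogram", "data.frame")
  out
}

#' @param fit A `direction_peak`.
#' @rdname write_directionality
#' @export
write_peak_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit)[c("mu_deg", "sigma_deg", "amplitude",
                                      "baseline", "peak_height", "converged",
                                      "method")],
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write and read a similarity transform as JSON
#'
#' @param transform A `similarity_transform`.
#' @param path File path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "similarity_transform"))
  jsonlite::write_json(
    list(format = .fmt_version, scale = transform$scale,
         rotation_deg = transform$rotation_deg,
         translation = transform$translation,
         rms_residual = transform$rms_residual),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- similarity_transform(js$scale, js$rotation_deg, js$translation)
  tr$rms_residual <- js$rms_residual
  tr
}

#' Read matched fiducial point pairs
#'
#' CSV columns `src_x,src_y,dst_x,dst_y`.
#'
#' @param path File path.
#' @return A list with `src` and `dst` n x 2 matrices.
#' @export
read_point_pairs <- function(path) {
  df <- .read_csv_versioned(path)
  stopifnot(all(c("src_x", "src_y", "dst_x", "dst_y") %in% names(df)))
  list(src = cbind(df$src_x, df$src_y), dst = cbind(df$dst_x, df$dst_y))
}

#' Write and read images as TIFF
#'
#' Rendered images are written as 32-bit float TIFF; frame stacks as
#' multi-page TIFF. Intensities are stored as-is divided by `scale`
#' (`tiff::writeTIFF` expects values in [0, 1]); the scale is returned and
#' also stored in a JSON sidecar (`<path>.json`) together with the pixel
#' size.
#'
#' @param img A [rendered_image()], matrix, or 3D array (stack).
#' @param path Output TIFF path.
#' @param pixel_size_nm Pixel size recorded in the sidecar (taken from
#'   `img` for rendered images).
#' @export
write_image_tiff <- function(img, path, pixel_size_nm = NA_real_) {
  if (inherits(img, "rendered_image")) {
    pixel_size_nm <- img$pixel_size_nm
    data <- img$grid
  } else data <- img
  scale <- max(data, 1e-12)
  if (length(dim(data)) == 3) {
    pages <- lapply(seq_len(dim(data)[3]), function(k) data[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    tiff::writeTIFF(data / scale, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(list(format = .fmt_version, intensity_scale = scale,
                            pixel_size_nm = pixel_size_nm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1) {
    rendered_image(pages[[1]] * meta$intensity_scale, meta$pixel_size_nm)
  } else {
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$intensity_scale
    attr(arr, "pixel_size_nm") <- meta$pixel_size_nm
    arr
  }
}

#' Write scene ground truth
#'
#' One CSV row per emitter (`x_nm,y_nm,structure_id,structure_type`) plus a
#' JSON parameter sidecar holding all generation parameters including the
#' seed.
#'
#' @param scene A `synthetic_scene`.
#' @param csv_path Ground-truth CSV path.
#' @param json_path Parameter sidecar path (default `<csv_path>.json`).
#' @export
write_scene_truth <- function(scene, csv_path,
                              json_path = paste0(csv_path, ".json")) {
  stopifnot(inherits(scene, "synthetic_scene"))
  gt <- scene$locs[c("x_nm", "y_nm", "structure_id", "structure_type")]
  .write_csv_versioned(gt, csv_path, "scene_truth")
  jsonlite::write_json(
    c(scene$params,
      list(format = .fmt_version,
           geometry = unclass(scene$geometry),
           organelle_centers = unname(apply(scene$organelle_centers, 1, as.numeric,
                                            simplify = FALSE)),
           organelle_radius_nm = scene$organelle_radius_nm)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Write a time-point summary
#'
#' Tidy CSV columns `stage_min,metric,mean,sd,n`.
#'
#' @param summary A `timepoint_summary`.
#' @param path File path.
#' @export
write_summary <- function(summary, path) {
  .write_csv_versioned(as.data.frame(summary), path, "summary")
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  out <- .read_csv_versioned(path)
  class(out) <- c("timepoint_summary", "data.frame")
  out
}
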