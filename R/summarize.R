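#' Platelet area in square micrometres
#'
#' Spread area of the platelet footprint (`pixels * pixel_size^2`,
#' converted to um^2) -- the quantity whose increase from roughly 10 to
#' 50 um^2 tracks activation-induced spreading.
#'
#' @param platelet A [platelet_mask()].
#' @return Area in um^2.
#' @export
platelet_area <- function(platelet) {
  stopifnot(inherits(platelet, "platelet_mask"))
  platelet$area_nm2 / 1e6
}

#' Offset between nodule centre of mass and platelet centroid
#'
#' The (dx, dy) morphometric: the area-weighted mean of cluster centroids
#' minus the platelet centroid. Values near zero indicate that nodules are
#' centred on the spread platelet.
#'
#' @param clusters A `cluster_set` with at least one cluster.
#' @param platelet A [platelet_mask()].
#' @return Named numeric `c(dx_nm, dy_nm)`.
#' @export
nodule_offset <- function(clusters, platelet) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(platelet, "platelet_mask"))
  st <- clusters$stats
  if (!nrow(st)) stop("nodule offset is undefined without clusters")
  w <- st$area_nm2 / sum(st$area_nm2)
  c(dx_nm = sum(w * st$cx_nm) - platelet$centroid_nm[1],
    dy_nm = sum(w * st$cy_nm) - platelet$centroid_nm[2])
}

#' Group per-platelet metrics by activation time point
#'
#' Produces the bar-graph statistics of the activation time course:
#' per-stage arithmetic mean and standard deviation (n - 1 denominator,
#' i.e. mean +/- SD over platelets, not pooled pixels/clusters) of each
#' per-platelet metric.
#'
#' @param per_platelet A data.frame with a `stage_min` column and one row
#'   per platelet; every other numeric column is summarized.
#' @return A tidy data.frame of class `timepoint_summary` with columns
#'   `stage_min`, `metric`, `mean`, `sd`, `n`. Stages with no platelets are
#'   omitted with a warning.
#' @examples
#' d <- data.frame(stage_min = c(0, 0, 5), clusters = c(6, 8, 7))
#' summarize_timepoints(d)
#' @export
summarize_timepoints <- function(per_platelet) {
  stopifnot(is.data.frame(per_platelet), "stage_min" %in% names(per_platelet))
  metrics <- setdiff(names(per_platelet)[vapply(per_platelet, is.numeric, logical(1))],
                     "stage_min")
  if (!length(metrics)) stop("no numeric metric columns to summarize")
  stages <- sort(unique(per_platelet$stage_min))
  out <- do.call(rbind, lapply(stages, function(sg) {
    rows <- per_platelet[per_platelet$stage_min == sg, , drop = FALSE]
    if (!nrow(rows)) {
      warning("stage ", sg, " has no platelets; omitted")
      return(NULL)
    }
    do.call(rbind, lapply(metrics, function(m) {
      v <- rows[[m]]
      data.frame(stage_min = sg, metric = m, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v))
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("timepoint_summary", "data.frame")
  out
}

#' Cluster size distribution
#'
#' Histogram of cluster equivalent diameters, the representation used for
#' OCS size distributions across activation time points.
#'
#' @param clusters A `cluster_set`, or a numeric vector of equivalent
#'   diameters (nm).
#' @param bin_width_nm Diameter bin width, nm (> 0).
#' @return A data.frame with columns `bin_lo_nm`, `bin_hi_nm`, `count`;
#'   counts sum to the number of clusters.
#' @export
size_distribution <- function(clusters, bin_width_nm = 50) {
  stopifnot(bin_width_nm > 0)
  d <- if (inherits(clusters, "cluster_set")) clusters$stats$eq_diameter_nm
       else as.numeric(clusters)
  if (!length(d)) {
    return(data.frame(bin_lo_nm = numeric(), bin_hi_nm = numeric(),
                      count = integer()))
  }
  bin <- floor(d / bin_width_nm)
  rng <- min(bin):max(bin)
  count <- vapply(rng, function(b) sum(bin == b), integer(1))
  data.frame(bin_lo_nm = rng * bin_width_nm,
             bin_hi_nm = (rng + 1) * bin_width_nm,
             count = count)
}
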