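#' Construct a localization table
#'
#' The localization table is the currency between the simulation,
#' localization and rendering stages: one row per single-emitter event with
#' its fitted (or ground-truth) position in nm, the acquisition frame, the
#' fitted photon count, PSF width, local background and a fit-quality flag.
#' The CSV dialect (`frame,x_nm,y_nm,photons,sigma_nm,background,fit_ok`)
#' follows ThunderSTORM-style column naming so tables import into standard
#' SMLM tooling.
#'
#' @param x_nm,y_nm Emitter coordinates, nm.
#' @param frame 0-based acquisition frame index.
#' @param photons Photon count per event.
#' @param sigma_nm Fitted PSF standard deviation, nm.
#' @param background Fitted background, photons/pixel.
#' @param fit_ok Logical fit-quality flag.
#' @param ... Further per-row columns (e.g. ground-truth `structure_id`,
#'   `structure_type`), recycled to the table length.
#' @return A `data.frame` of class `loc_table`.
#' @examples
#' tb <- loc_table(x_nm = c(100, 250), y_nm = c(80, 300))
#' nrow(tb)
#' @export
loc_table <- function(x_nm = numeric(), y_nm = numeric(), frame = 0L,
                      photons = 1000, sigma_nm = NA_real_,
                      background = NA_real_, fit_ok = TRUE, ...) {
  n <- length(x_nm)
  stopifnot(length(y_nm) == n)
  tb <- data.frame(
    frame = as.integer(rep_len(frame, n)),
    x_nm = as.numeric(x_nm),
    y_nm = as.numeric(y_nm),
    photons = rep_len(as.numeric(photons), n),
    sigma_nm = rep_len(as.numeric(sigma_nm), n),
    background = rep_len(as.numeric(background), n),
    fit_ok = rep_len(as.logical(fit_ok), n)
  )
  extra <- list(...)
  for (nm in names(extra)) tb[[nm]] <- rep_len(extra[[nm]], n)
  class(tb) <- c("loc_table", "data.frame")
  tb
}

#' Validate a localization table
#'
#' Checks the structural invariants of a [loc_table()]: required columns,
#' finite coordinates, non-negative frame indices, and positive photon
#' counts for rows flagged `fit_ok`.
#'
#' @param tb A localization table.
#' @return `tb`, invisibly; errors on violation.
#' @export
validate_loc_table <- function(tb) {
  need <- c("frame", "x_nm", "y_nm", "photons", "sigma_nm", "background", "fit_ok")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("loc_table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(tb)) {
    if (!all(is.finite(tb$x_nm)) || !all(is.finite(tb$y_nm)))
      stop("loc_table coordinates must be finite")
    if (any(tb$frame < 0)) stop("loc_table frame indices must be >= 0")
    ok <- tb$fit_ok & !is.na(tb$photons)
    if (any(tb$photons[ok] <= 0)) stop("fit_ok rows must have photons > 0")
  }
  invisible(tb)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("loc_table: %d localizations, %d frame(s)\n", nrow(x),
              length(unique(x$frame))))
  NextMethod()
}
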