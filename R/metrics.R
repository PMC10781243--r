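# Image-quality metrics. All contrast metrics operate on the LINEAR
# envelope magnitude; log compression is only for display.

#' Log-compressed display map
#'
#' `20 log10(|y| / max |y|)`, clipped at `-dynamic_range_db`.
#'
#' @param image A `pw_image` or complex/numeric matrix.
#' @param dynamic_range_db Display dynamic range in dB (default 60).
#' @return Numeric matrix of dB values in `[-dynamic_range_db, 0]`.
#' @export
envelope_log <- function(image, dynamic_range_db = 60) {
  env <- if (inherits(image, "pw_image")) Mod(image$data) else Mod(image)
  m <- max(env)
  if (m == 0) stop("cannot log-compress an all-zero image")
  db <- 20 * log10(env / m)
  db[!is.finite(db)] <- -dynamic_range_db
  pmax(db, -dynamic_range_db)
}

.grid_index <- function(v, at) which.min(abs(v - at))

#' Lateral full width at half maximum of a point target
#'
#' Finds the envelope peak near `(target_x, target_depth)`, takes the
#' lateral profile through the peak row and measures the width between the
#' two half-maximum (-6.02 dB) crossings with linear interpolation between
#' pixel samples. A profile that never falls below half maximum on one side
#' yields `NaN`.
#'
#' @param image A `pw_image`.
#' @param target_depth,target_x Expected target position in meters.
#' @param search_radius Half-size of the peak search window in meters
#'   (default 1.5 mm).
#' @return Width in millimeters, or `NaN` when a crossing is missing.
#' @export
fwhm_lateral <- function(image, target_depth, target_x, search_radius = 1.5e-3) {
  env <- Mod(image$data)
  xg <- image$grid$lateral_x
  zg <- image$grid$axial_z
  rows <- which(abs(zg - target_depth) <= search_radius)
  cols <- which(abs(xg - target_x) <= search_radius)
  if (!length(rows) || !length(cols)) stop("search window is outside the grid")
  sub <- env[rows, cols, drop = FALSE]
  pk <- arrayInd(which.max(sub), dim(sub))
  pr <- rows[pk[1]]; pc <- cols[pk[2]]
  prof <- env[pr, ]
  half <- prof[pc] / 2
  if (half <= 0) return(NaN)
  cross <- function(side) {
    js <- if (side < 0) seq(pc - 1, 1) else seq(pc + 1, length(prof))
    if (pc + side < 1 || pc + side > length(prof)) return(NaN)
    for (j in js) {
      if (prof[j] < half) {
        j0 <- j - side  # neighbor closer to the peak, still >= half
        frac <- (prof[j0] - half) / (prof[j0] - prof[j])
        return(xg[j0] + frac * (xg[j] - xg[j0]))
      }
    }
    NaN
  }
  xl <- cross(-1L); xr <- cross(1L)
  1e3 * (xr - xl)
}

#' Contrast ratio
#'
#' `CR = 20 log10(mu_bck / mu_cyst)` on linear envelope magnitudes.
#'
#' @param cyst_pixels,bck_pixels Numeric vectors of envelope magnitudes.
#' @return dB value; `Inf` for an exactly echo-free cyst ROI.
#' @export
cr <- function(cyst_pixels, bck_pixels) {
  stopifnot(length(cyst_pixels) > 0, length(bck_pixels) > 0)
  20 * log10(mean(bck_pixels) / mean(cyst_pixels))
}

#' Contrast-to-noise ratio (log-scaled)
#'
#' `CNR = 20 log10(|mu_cyst - mu_bck| / sqrt((sd_cyst^2 + sd_bck^2) / 2))`
#' on linear envelope magnitudes; typical well-resolved cysts score in the
#' low tens.
#'
#' @inheritParams cr
#' @export
cnr <- function(cyst_pixels, bck_pixels) {
  stopifnot(length(cyst_pixels) > 1, length(bck_pixels) > 1)
  den <- sqrt((stats::var(cyst_pixels) + stats::var(bck_pixels)) / 2)
  if (den == 0) stop("zero pooled standard deviation in CNR")
  20 * log10(abs(mean(cyst_pixels) - mean(bck_pixels)) / den)
}

#' Generalized contrast-to-noise ratio
#'
#' `gCNR = 1 - sum(min(p_cyst, p_bck))` over a shared histogram spanning the
#' pooled range of both ROIs; 1 means complete separation of the envelope
#' distributions and the measure is invariant to monotone transforms of the
#' envelope (up to binning error).
#'
#' @inheritParams cr
#' @param n_bins Number of shared histogram bins (default 100).
#' @return Value in `[0, 1]`.
#' @export
gcnr <- function(cyst_pixels, bck_pixels, n_bins = 100) {
  stopifnot(length(cyst_pixels) > 0, length(bck_pixels) > 0)
  rng <- range(c(cyst_pixels, bck_pixels))
  if (rng[1] == rng[2]) return(0)
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  pc <- tabulate(findInterval(cyst_pixels, br, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(cyst_pixels)
  pb <- tabulate(findInterval(bck_pixels, br, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(bck_pixels)
  1 - sum(pmin(pc, pb))
}

#' Circular region of interest
#'
#' @param x,z Center in meters.
#' @param radius Radius in meters (> 0).
#' @param role `"cyst"` or `"background"`.
#' @export
roi_circle <- function(x, z, radius, role = c("cyst", "background")) {
  stopifnot(radius > 0)
  structure(list(x = x, z = z, radius = radius, role = match.arg(role)),
            class = "pw_roi")
}

#' Envelope magnitudes inside a circular ROI
#'
#' @param image A `pw_image`.
#' @param roi A [roi_circle()].
#' @return Numeric vector of linear envelope values.
#' @export
extract_roi <- function(image, roi) {
  env <- Mod(image$data)
  xg <- image$grid$lateral_x
  zg <- image$grid$axial_z
  if (roi$x - roi$radius < min(xg) || roi$x + roi$radius > max(xg) ||
      roi$z - roi$radius < min(zg) || roi$z + roi$radius > max(zg))
    stop("ROI extends outside the image grid")
  inside <- outer(zg - roi$z, xg - roi$x,
                  function(dz, dx) dz^2 + dx^2) <= roi$radius^2
  env[inside]
}

#' Image-quality report
#'
#' Evaluates the standard metrics of a beamformed image: lateral FWHM per
#' point target (and their mean), and CR/CNR/gCNR averaged over cyst ROIs
#' against their paired background ROIs.
#'
#' @param image A `pw_image`.
#' @param point_targets Optional data frame with columns `x`, `z` (meters).
#' @param cyst_rois,bck_rois Optional equal-length lists of [roi_circle()]s,
#'   paired by position.
#' @param n_bins Histogram bins for gCNR.
#' @return Object of class `pw_metrics`: list with `fwhm_mm`,
#'   `fwhm_mean_mm`, `cr_db`, `cnr`, `gcnr`, `method`, `params`.
#' @export
metrics_report <- function(image, point_targets = NULL, cyst_rois = NULL,
                           bck_rois = NULL, n_bins = 100) {
  fw <- NULL
  if (!is.null(point_targets)) {
    fw <- mapply(function(x, z) fwhm_lateral(image, z, x),
                 point_targets$x, point_targets$z)
  }
  cr_v <- cnr_v <- gcnr_v <- NULL
  if (!is.null(cyst_rois)) {
    stopifnot(length(cyst_rois) == length(bck_rois))
    for (k in seq_along(cyst_rois)) {
      cp <- extract_roi(image, cyst_rois[[k]])
      bp <- extract_roi(image, bck_rois[[k]])
      cr_v <- c(cr_v, cr(cp, bp))
      cnr_v <- c(cnr_v, cnr(cp, bp))
      gcnr_v <- c(gcnr_v, gcnr(cp, bp, n_bins))
    }
  }
  structure(list(
    fwhm_mm = fw,
    fwhm_mean_mm = if (is.null(fw)) NA_real_ else mean(fw, na.rm = TRUE),
    cr_db = if (is.null(cr_v)) NA_real_ else mean(cr_v),
    cnr = if (is.null(cnr_v)) NA_real_ else mean(cnr_v),
    gcnr = if (is.null(gcnr_v)) NA_real_ else mean(gcnr_v),
    method = image$method, params = image$params
  ), class = "pw_metrics")
}

#' @export
print.pw_metrics <- function(x, ...) {
  parts <- c(
    if (!is.na(x$fwhm_mean_mm))
      sprintf("FWHM %s mm", formatC(x$fwhm_mean_mm, digits = 3, format = "fg")),
    if (!is.na(x$cr_db))
      sprintf("CR %s dB", formatC(x$cr_db, digits = 4, format = "fg")),
    if (!is.na(x$cnr))
      sprintf("CNR %s", formatC(x$cnr, digits = 4, format = "fg")),
    if (!is.na(x$gcnr))
      sprintf("gCNR %s", formatC(x$gcnr, digits = 3, format = "fg")))
  cat(sprintf("%-12s %s\n", x$method, paste(parts, collapse = "  ")))
  invisible(x)
}
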