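# Bolus arrival time (BAT) mapping by the peak-gradient method: the arrival
# at a voxel is taken as the left endpoint of the frame interval with the
# maximal forward-difference slope of the enhancement curve, earliest
# interval on ties. These conventions are fixed here for determinism. A
# curve that never increases (constant, or monotone decreasing) has no
# defined arrival and is flagged invalid rather than clipped.

#' Arterial input function from an aorta ROI
#'
#' Framewise mean of the enhancement over the ROI, normalised to unit peak.
#'
#' @param enh a [dynamic_image()] of enhancements.
#' @param aorta_roi logical 3D array or a [label_map()]; if a label map and
#'   an `aorta` label exists it is used, otherwise any nonzero voxel.
#' @return an [aif_curve()] with peak 1.
#' @export
extract_aif <- function(enh, aorta_roi) {
  stopifnot(inherits(enh, "dynamic_image"))
  m <- if (inherits(aorta_roi, "label_map") &&
           "aorta" %in% names(aorta_roi$labels) &&
           any(aorta_roi$values == aorta_roi$labels[["aorta"]]))
    label_mask(aorta_roi, "aorta") else as_mask(aorta_roi)
  if (!any(m)) stop("aorta ROI is empty", call. = FALSE)
  nf <- dim(enh$values)[4]
  vox <- matrix(enh$values, ncol = nf)[which(m), , drop = FALSE]
  curve <- colMeans(vox)
  peak <- max(curve)
  if (!is.finite(peak) || peak <= 0)
    stop("AIF peak is not positive", call. = FALSE)
  aif_curve(enh$times, curve / peak)
}

#' Bolus arrival time of a single curve
#'
#' Peak-gradient arrival: the left time of the interval with the largest
#' forward-difference slope. Earliest interval wins ties. Returns `NA` for
#' curves with no positive gradient anywhere (undefined arrival).
#'
#' @param curve numeric vector of intensities.
#' @param times sample times in s (same length, >= 3 samples).
#' @return arrival time in s, or `NA_real_` if undefined.
#' @export
bolus_arrival_time <- function(curve, times) {
  if (length(curve) < 3 || length(curve) != length(times))
    stop("need >= 3 samples with matching times", call. = FALSE)
  g <- diff(curve) / diff(times)
  if (!any(is.finite(g)) || max(g, na.rm = TRUE) <= 0) return(NA_real_)
  times[which.max(g)]
}

#' Voxelwise bolus arrival time map
#'
#' Applies the peak-gradient arrival estimator to every voxel in the mask.
#'
#' Voxels whose curve never reaches `min_peak` are flagged invalid: an
#' arrival estimated from a curve with no measurable enhancement (bolus not
#' yet arrived, or pure noise) is meaningless. The default 0 disables the
#' gate; pipelines set it from the measured pre-contrast noise.
#'
#' @param enh a [dynamic_image()] of enhancements.
#' @param mask logical 3D array or [label_map()] restricting the
#'   computation.
#' @param min_peak minimum peak enhancement for a defined arrival (same
#'   units as `enh`).
#' @return a list of class `bat_map` with `values` (an [image3d()], `NA`
#'   where undefined) and `valid` (logical 3D array).
#' @export
bat_map <- function(enh, mask, min_peak = 0) {
  stopifnot(inherits(enh, "dynamic_image"))
  m <- as_mask(mask)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  sh <- dim(enh$values)[1:3]
  nf <- dim(enh$values)[4]
  sel <- which(m)
  vox <- matrix(enh$values, ncol = nf)[sel, , drop = FALSE]
  dt <- diff(enh$times)
  g <- (vox[, -1, drop = FALSE] - vox[, -nf, drop = FALSE])
  g <- sweep(g, 2, dt, "/")
  j <- max.col(g, ties.method = "first")
  gmax <- g[cbind(seq_along(j), j)]
  bat <- enh$times[j]
  ok <- is.finite(gmax) & gmax > 0
  if (min_peak > 0) {
    peak <- vox[cbind(seq_len(nrow(vox)), max.col(vox, "first"))]
    ok <- ok & peak >= min_peak
  }
  bat[!ok] <- NA_real_
  vals <- array(NA_real_, sh)
  vals[sel] <- bat
  valid <- array(FALSE, sh)
  valid[sel] <- ok
  structure(list(values = image3d(vals, spacing = enh$spacing,
                                  origin = enh$origin),
                 valid = valid),
            class = "bat_map")
}

#' @export
print.bat_map <- function(x, ...) {
  cat(sprintf("<bat_map> %d valid voxels, BAT range [%.4g, %.4g] s\n",
              sum(x$valid),
              suppressWarnings(min(x$values$values, na.rm = TRUE)),
              suppressWarnings(max(x$values$values, na.rm = TRUE))))
  invisible(x)
}
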