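# Contrast-to-saturation conversion. Contrast enhancement is linearly
# proportional to local contrast concentration, so after subtracting the
# pre-contrast baseline and dividing by the arterial peak, tissue and
# arterial signals live on one dimensionless saturation scale. The unknown
# proportionality constant cancels in arrival times, speeds, and
# correlations.

#' Pre-contrast baseline volume
#'
#' Voxelwise mean of the first `n_pre` frames, acquired before contrast
#' injection.
#'
#' @param img a [dynamic_image()].
#' @param n_pre number of pre-contrast frames, `1 <= n_pre < n_frames`.
#' @return an [image3d()] baseline in the same units as `img`.
#' @export
compute_baseline <- function(img, n_pre) {
  stopifnot(inherits(img, "dynamic_image"))
  nf <- dim(img$values)[4]
  if (!is.numeric(n_pre) || length(n_pre) != 1 || n_pre < 1 || n_pre >= nf)
    stop("`n_pre` must satisfy 1 <= n_pre < number of frames", call. = FALSE)
  n_pre <- as.integer(n_pre)
  d <- dim(img$values)[1:3]
  m <- matrix(img$values, ncol = nf)
  base <- array(rowMeans(m[, seq_len(n_pre), drop = FALSE]), d)
  image3d(base, spacing = img$spacing, origin = img$origin)
}

#' Framewise contrast enhancement
#'
#' Subtracts the baseline from every frame: `I(x, t) - I_b(x)`. Negative
#' values (noise) are retained, not clipped, so that downstream fits can
#' express negative fractional plasma volumes.
#'
#' @param img a [dynamic_image()].
#' @param baseline an [image3d()] on the same grid.
#' @return a [dynamic_image()] of enhancements.
#' @export
enhancement <- function(img, baseline) {
  stopifnot(inherits(img, "dynamic_image"), inherits(baseline, "image3d"))
  if (!same_grid(img, baseline))
    stop("`img` and `baseline` are not on the same grid", call. = FALSE)
  vals <- img$values - as.vector(baseline$values)
  dynamic_image(vals, spacing = img$spacing, origin = img$origin,
                times = img$times)
}

#' Normalise enhancement to the arterial saturation scale
#'
#' Divides all enhancements by the AIF peak so the output is dimensionless
#' and the arterial peak maps to 1.
#'
#' @param enh a [dynamic_image()] of enhancements.
#' @param aif an [aif_curve()] with a positive peak.
#' @return a dimensionless [dynamic_image()].
#' @export
normalize_to_saturation <- function(enh, aif) {
  stopifnot(inherits(enh, "dynamic_image"), inherits(aif, "aif_curve"))
  peak <- max(aif$saturation)
  if (!is.finite(peak) || peak <= 0)
    stop("AIF peak must be positive", call. = FALSE)
  dynamic_image(enh$values / peak, spacing = enh$spacing,
                origin = enh$origin, times = enh$times)
}
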