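# Core data containers shared by every stage of the pipeline. Geometry is a
# regular grid with per-axis spacing (mm) and a world origin (mm); world
# coordinate of voxel index (i, j, k) (0-based) is origin + index * spacing.

grid_of <- function(x) list(dim = dim(x$values)[1:3], spacing = x$spacing,
                            origin = x$origin)

same_grid <- function(a, b) {
  isTRUE(all.equal(grid_of(a)$dim, grid_of(b)$dim)) &&
    isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

check_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
}

#' 4D dynamic contrast image
#'
#' A time-resolved scalar field: one 3D volume per acquisition frame on a
#' shared grid, with frame acquisition times in seconds. Intensities are in
#' Hounsfield units for raw CT input, or dimensionless after saturation
#' normalisation.
#'
#' @param values 4D numeric array (x, y, z, frame).
#' @param spacing per-axis voxel size in mm (length 3, positive).
#' @param times frame acquisition times in s, strictly increasing, one per
#'   frame.
#' @param origin world position of voxel (0,0,0) in mm.
#' @return an object of class `dynamic_image`.
#' @export
dynamic_image <- function(values, spacing, times, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 4L)
    stop("`values` must be a 4D array (x, y, z, frame)", call. = FALSE)
  check_spacing(spacing)
  if (length(times) != dim(values)[4])
    stop("length(times) must equal the number of frames", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), times = as.numeric(times)),
            class = "dynamic_image")
}

#' 3D scalar image
#'
#' Holds a single volume: a baseline, a distance map, a bolus-arrival-time
#' map, a speed field, a permeability map, or any other derived voxelwise
#' quantity.
#'
#' @param values 3D numeric array.
#' @param spacing per-axis voxel size in mm.
#' @param origin world position of voxel (0,0,0) in mm.
#' @return an object of class `image3d`.
#' @export
image3d <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  check_spacing(spacing)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image3d")
}

#' Integer label map
#'
#' Voxelwise region labels on the image grid. The label dictionary maps
#' semantic names (vessel, tumor, parenchyma, aorta, background) to integer
#' codes; 0 is background by convention.
#'
#' @param values 3D integer array.
#' @param spacing per-axis voxel size in mm.
#' @param labels named integer vector giving the label dictionary.
#' @param origin world position of voxel (0,0,0) in mm.
#' @return an object of class `label_map`.
#' @export
label_map <- function(values, spacing,
                      labels = c(background = 0L, vessel = 1L, tumor = 2L,
                                 parenchyma = 3L, aorta = 4L),
                      origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  check_spacing(spacing)
  vals <- unique(as.vector(values))
  unknown <- setdiff(vals, labels)
  if (length(unknown))
    stop("label values not in the dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(values = array(as.integer(values), dim(values)),
                 spacing = as.numeric(spacing), origin = as.numeric(origin),
                 labels = labels),
            class = "label_map")
}

#' Extract a binary mask for one semantic label
#'
#' @param lm a [label_map()].
#' @param name label name present in the dictionary.
#' @return logical 3D array.
#' @export
label_mask <- function(lm, name) {
  stopifnot(inherits(lm, "label_map"))
  if (!name %in% names(lm$labels))
    stop("unknown label name: ", name, call. = FALSE)
  lm$values == lm$labels[[name]]
}

#' Arterial input function curve
#'
#' Sampled arterial saturation (dimensionless) versus time, extracted from an
#' aorta region of interest or produced analytically by the phantom
#' generator.
#'
#' @param times sample times in s, strictly increasing.
#' @param saturation dimensionless saturation values, same length as `times`.
#' @return an object of class `aif_curve`.
#' @export
aif_curve <- function(times, saturation) {
  if (length(times) != length(saturation))
    stop("`times` and `saturation` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times),
                 saturation = as.numeric(saturation)),
            class = "aif_curve")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dynamic_image> %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing: %s mm; times: %.4g .. %.4g s\n",
              paste(signif(x$spacing, 4), collapse = " x "),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
print.image3d <- function(x, ...) {
  d <- dim(x$values)
  rng <- range(x$values, finite = TRUE)
  cat(sprintf("<image3d> %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "), rng[1], rng[2]))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<label_map> %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(factor(x$values, levels = x$labels,
                      labels = names(x$labels)))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-12s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("<aif_curve> %d samples, t in [%.4g, %.4g] s, peak %.4g at t = %.4g s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              max(x$saturation), x$times[which.max(x$saturation)]))
  invisible(x)
}

# world coordinates (mm) of every voxel centre along one axis
axis_world <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing
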