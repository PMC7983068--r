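# NIfTI-1 readers/writers. Voxel spacing travels in the NIfTI pixdim field;
# the world origin, frame times, and label dictionaries travel in a JSON
# sidecar (<file>.json) so that a series round-trips exactly.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

nifti_spacing <- function(nii, ndim) {
  pd <- attr(nii, "pixdim")
  if (is.null(pd)) pd <- RNifti::pixdim(nii)
  as.numeric(pd[seq_len(ndim)])
}

#' Read and write 3D scalar volumes as NIfTI-1
#'
#' @param img an [image3d()].
#' @param path file path (`.nii` or `.nii.gz`); a JSON sidecar holding the
#'   world origin is written alongside.
#' @return `read_image3d` returns an [image3d()]; `write_image3d` returns
#'   `path` invisibly.
#' @export
write_image3d <- function(img, path) {
  stopifnot(inherits(img, "image3d"))
  nii <- RNifti::asNifti(img$values, pixdim = img$spacing)
  RNifti::writeNifti(nii, path)
  write_sidecar(path, list(origin = img$origin, spacing = img$spacing))
  invisible(path)
}

#' @rdname write_image3d
#' @export
read_image3d <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  vals <- array(as.numeric(nii), dim(nii))
  meta <- read_sidecar(path)
  spacing <- if (!is.null(meta$spacing)) meta$spacing else nifti_spacing(nii, 3)
  origin <- if (!is.null(meta$origin)) meta$origin else c(0, 0, 0)
  image3d(vals, spacing = spacing, origin = origin)
}

#' Read and write label maps as integer NIfTI-1
#'
#' The label dictionary is carried in the JSON sidecar.
#'
#' @param lm a [label_map()].
#' @param path file path.
#' @return `read_label_map` returns a [label_map()].
#' @export
write_label_map <- function(lm, path) {
  stopifnot(inherits(lm, "label_map"))
  nii <- RNifti::asNifti(lm$values, pixdim = lm$spacing, datatype = "int16")
  RNifti::writeNifti(nii, path)
  write_sidecar(path, list(origin = lm$origin, spacing = lm$spacing,
                           labels = as.list(lm$labels)))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  vals <- array(as.integer(nii), dim(nii))
  meta <- read_sidecar(path)
  spacing <- if (!is.null(meta$spacing)) meta$spacing else nifti_spacing(nii, 3)
  origin <- if (!is.null(meta$origin)) meta$origin else c(0, 0, 0)
  labels <- if (!is.null(meta$labels)) unlist(meta$labels) else
    c(background = 0L, vessel = 1L, tumor = 2L, parenchyma = 3L, aorta = 4L)
  label_map(vals, spacing = spacing, origin = origin,
            labels = setNames(as.integer(labels), names(labels)))
}

#' Write and read a 4D dynamic series as a single NIfTI-1 volume
#'
#' Frame times (s) and the world origin are stored in the JSON sidecar.
#'
#' @param img a [dynamic_image()].
#' @param path file path.
#' @return `read_dynamic_image` returns a [dynamic_image()].
#' @export
write_dynamic_image <- function(img, path) {
  stopifnot(inherits(img, "dynamic_image"))
  nii <- RNifti::asNifti(img$values, pixdim = c(img$spacing, 1))
  RNifti::writeNifti(nii, path)
  write_sidecar(path, list(origin = img$origin, spacing = img$spacing,
                           times = img$times))
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  nii <- RNifti::readNifti(path)
  vals <- array(as.numeric(nii), dim(nii))
  meta <- read_sidecar(path)
  if (is.null(meta$times))
    stop("missing times sidecar for 4D series: ", sidecar_path(path),
         call. = FALSE)
  spacing <- if (!is.null(meta$spacing)) meta$spacing else nifti_spacing(nii, 3)
  origin <- if (!is.null(meta$origin)) meta$origin else c(0, 0, 0)
  dynamic_image(vals, spacing = spacing, origin = origin, times = meta$times)
}

#' Load an ordered list of 3D volumes as one dynamic series
#'
#' All volumes must share one grid (dimensions and spacing); frames are
#' stacked in the given temporal order.
#'
#' @param paths ordered character vector of NIfTI file paths, one per frame.
#' @param times acquisition times in s, one per path, strictly increasing.
#' @return a [dynamic_image()].
#' @export
load_dynamic_series <- function(paths, times) {
  if (length(paths) != length(times))
    stop("`paths` and `times` must have equal length", call. = FALSE)
  vols <- lapply(paths, read_image3d)
  ref <- vols[[1]]
  for (v in vols[-1]) {
    if (!identical(dim(v$values), dim(ref$values)) ||
        !isTRUE(all.equal(v$spacing, ref$spacing)))
      stop("frames do not share one grid", call. = FALSE)
  }
  vals <- array(0, c(dim(ref$values), length(vols)))
  for (i in seq_along(vols)) vals[, , , i] <- vols[[i]]$values
  dynamic_image(vals, spacing = ref$spacing, origin = ref$origin,
                times = times)
}
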