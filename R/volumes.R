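#' @useDynLib lamcrib, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rgamma runif sd cov median
#' @importFrom utils head write.csv
NULL

# Plane/axis convention used throughout the package: a volume is indexed
# (a, s, c) with a and s the two lateral directions and c the depth (the
# OCT "axial" direction). Axial slices fix a, sagittal slices fix s and
# coronal slices fix c; the en-face plane is (a, s). Frame indices are
# 1-based. See the methods vignette.
PLANES <- c(axial = 1L, sagittal = 2L, coronal = 3L)

match_plane <- function(plane) {
  if (length(plane) != 1L || !plane %in% names(PLANES))
    stop("unknown plane '", paste(plane, collapse = ","),
         "'; must be one of axial, sagittal, coronal", call. = FALSE)
  PLANES[[plane]]
}

LABEL_CODES <- c(background = 0L, LC = 1L, PPS = 2L)

#' OCT intensity volume
#'
#' A 3D grayscale scalar grid with physical voxel spacing, representing a
#' scanned (or simulated) OCT cube of the optic nerve head. Dimensions are
#' ordered (axial, sagittal, coronal): the first two axes are lateral, the
#' third is depth.
#'
#' @param data 3D numeric array, values expected in `[0, 1]`.
#' @param spacing_mm numeric length-3, physical voxel pitch in mm per axis.
#' @param laterality `"OD"` (right eye), `"OS"` (left eye) or `"unknown"`.
#' @return An `intensity_volume` object (a classed array).
#' @export
intensity_volume <- function(data, spacing_mm = c(1, 1, 1) / 100,
                             laterality = "unknown") {
  data <- as_volume_array(data, "numeric")
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  laterality <- match.arg(laterality, c("OD", "OS", "unknown"))
  structure(data, spacing_mm = as.numeric(spacing_mm),
            laterality = laterality,
            class = c("intensity_volume", "oct_volume"))
}

#' Categorical label volume
#'
#' A 3D grid over the codes 0 = background, 1 = lamina cribrosa (LC),
#' 2 = peripapillary sclera (PPS).
#'
#' @param data 3D array of integer codes in `{0, 1, 2}`.
#' @inheritParams intensity_volume
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, spacing_mm = c(1, 1, 1) / 100,
                         laterality = "unknown") {
  data <- as_volume_array(data, "integer")
  bad <- !data %in% LABEL_CODES
  if (any(bad))
    stop("label volume contains codes outside {0, 1, 2}", call. = FALSE)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  laterality <- match.arg(laterality, c("OD", "OS", "unknown"))
  structure(data, spacing_mm = as.numeric(spacing_mm),
            laterality = laterality,
            class = c("label_volume", "oct_volume"))
}

as_volume_array <- function(data, mode) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  storage.mode(data) <- if (mode == "integer") "integer" else "double"
  data
}

#' @export
print.oct_volume <- function(x, ...) {
  kind <- if (inherits(x, "label_volume")) "label" else "intensity"
  cat(sprintf("<%s volume> %s voxels (a x s x c), spacing %s mm, %s\n",
              kind, paste(dim(x), collapse = " x "),
              paste(signif(attr(x, "spacing_mm"), 3), collapse = " x "),
              attr(x, "laterality")))
  invisible(x)
}

spacing_mm <- function(volume)
  attr(volume, "spacing_mm") %||% (c(1, 1, 1) / 100)
laterality_of <- function(volume) attr(volume, "laterality") %||% "unknown"
`%||%` <- function(a, b) if (is.null(a)) b else a

volume_like <- function(data, template) {
  if (inherits(template, "label_volume"))
    label_volume(data, spacing_mm(template), laterality_of(template))
  else
    intensity_volume(data, spacing_mm(template), laterality_of(template))
}

#' Extract the 2D slice series of a volume along one plane
#'
#' Frame `k` of the series is the section of the volume at index `k` along
#' the plane-normal axis; values are copied, never resampled, so extraction
#' is lossless. For the default acquisition grid this yields 256 axial,
#' 222 sagittal and 190 coronal frames.
#'
#' @param volume an [intensity_volume()] or [label_volume()].
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @return A `slice_series`: list with `plane`, `frames` (list of matrices),
#'   `source_shape`, `spacing_mm`, `laterality` and `kind`.
#' @seealso [stack_slices()] for the exact inverse.
#' @export
extract_slices <- function(volume, plane) {
  axis <- match_plane(plane)
  stopifnot(length(dim(volume)) == 3L)
  n <- dim(volume)[axis]
  frames <- switch(axis,
    lapply(seq_len(n), function(k) volume[k, , , drop = TRUE]),
    lapply(seq_len(n), function(k) volume[, k, , drop = TRUE]),
    lapply(seq_len(n), function(k) volume[, , k, drop = TRUE]))
  frames <- lapply(frames, function(f) {
    if (is.null(dim(f))) dim(f) <- dim(volume)[-axis]
    f
  })
  structure(list(plane = plane, frames = frames,
                 source_shape = dim(volume),
                 spacing_mm = spacing_mm(volume),
                 laterality = laterality_of(volume),
                 kind = if (inherits(volume, "label_volume")) "label"
                        else "intensity"),
            class = "slice_series")
}

#' @export
print.slice_series <- function(x, ...) {
  cat(sprintf("<slice series> %d %s %s frames of %s (source %s)\n",
              length(x$frames), x$plane, x$kind,
              paste(dim(x$frames[[1]]), collapse = " x "),
              paste(x$source_shape, collapse = " x ")))
  invisible(x)
}

#' Reassemble a slice series into a volume
#'
#' Exact inverse of [extract_slices()] under the package's fixed plane/axis
#' convention: `stack_slices(extract_slices(v, p))` is identical to `v`.
#'
#' @param series a `slice_series`.
#' @return An [intensity_volume()] or [label_volume()] matching the series'
#'   `kind`.
#' @export
stack_slices <- function(series) {
  stopifnot(inherits(series, "slice_series"))
  frames <- series$frames
  if (length(frames) == 0L) stop("empty frame list", call. = FALSE)
  shp <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), shp), logical(1))
  if (!all(ok)) stop("inconsistent frame shapes in series", call. = FALSE)
  axis <- match_plane(series$plane)
  n <- length(frames)
  dims <- append(shp, n, after = axis - 1L)
  flat <- unlist(frames, use.names = FALSE)
  arr <- array(flat, dim = c(shp, n))          # (h, w, frame)
  arr <- aperm(arr, append(c(1L, 2L), 3L, after = axis - 1L))
  stopifnot(identical(dim(arr), as.integer(dims)))
  if (series$kind == "label")
    label_volume(arr, series$spacing_mm, series$laterality)
  else
    intensity_volume(arr, series$spacing_mm, series$laterality)
}
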