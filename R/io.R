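#' Read a volume from a multi-page TIFF stack or a NIfTI-1 file
#'
#' TIFF page order defines the axial (first-axis) frame order; no implicit
#' flips are applied, so a write/read cycle is bit-faithful for label data
#' and 16-bit-quantized for intensity data. NIfTI files carry their voxel
#' spacing; TIFF files do not, so `spacing_mm` is taken from the argument.
#'
#' @param path file path ending in `.tif`/`.tiff`, `.nii` or `.nii.gz`.
#' @param kind `"intensity"` or `"label"`; decides the returned class and,
#'   for TIFF, how sample values are decoded.
#' @param spacing_mm voxel spacing used for TIFF input (ignored for NIfTI).
#' @param laterality eye laterality to attach to the volume.
#' @return An [intensity_volume()] or [label_volume()].
#' @export
read_volume <- function(path, kind = c("intensity", "label"),
                        spacing_mm = c(1, 1, 1) / 100,
                        laterality = "unknown") {
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("cannot read volume: no such file '", path, "'", call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e)
                        stop("failed to read TIFF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    shp <- dim(pages[[1]])
    arr <- array(0, dim = c(length(pages), shp))
    for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
    if (kind == "label")
      label_volume(arr, spacing_mm, laterality)
    else
      intensity_volume(arr / 65535, spacing_mm, laterality)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop("failed to read NIfTI '", path, "': ",
                           conditionMessage(e), call. = FALSE))
    arr <- array(as.vector(img), dim = dim(img))
    sp <- RNifti::pixdim(img)[seq_len(3)]
    if (kind == "label") label_volume(arr, sp, laterality)
    else intensity_volume(arr, sp, laterality)
  } else {
    stop("unsupported volume format for '", path,
         "' (use .tif/.tiff or .nii/.nii.gz)", call. = FALSE)
  }
}

#' Write a volume as a multi-page TIFF stack or a NIfTI-1 file
#'
#' Label volumes are stored as 8-bit samples with the codes
#' {0 = background, 1 = LC, 2 = PPS} preserved exactly; intensity volumes
#' (values in `[0, 1]`) are stored as 16-bit grayscale TIFF or 32-bit float
#' NIfTI. One TIFF page per axial frame.
#'
#' @param volume an [intensity_volume()] or [label_volume()].
#' @param path destination path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  is_label <- inherits(volume, "label_volume")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    n <- dim(volume)[1]
    pages <- lapply(seq_len(n), function(k) {
      m <- volume[k, , , drop = TRUE]
      if (is.null(dim(m))) dim(m) <- dim(volume)[-1]
      if (is_label) m / 255 else pmin(pmax(m, 0), 1)
    })
    ok <- tryCatch(
      tiff::writeTIFF(pages, path,
                      bits.per.sample = if (is_label) 8L else 16L),
      error = function(e) stop("failed to write TIFF '", path, "': ",
                               conditionMessage(e), call. = FALSE))
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- array(as.vector(volume), dim = dim(volume))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- spacing_mm(volume)
    RNifti::writeNifti(img, path,
                       datatype = if (is_label) "uint8" else "float")
  } else {
    stop("unsupported volume format for '", path,
         "' (use .tif/.tiff or .nii/.nii.gz)", call. = FALSE)
  }
  invisible(path)
}
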