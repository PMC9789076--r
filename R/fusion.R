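#' Fuse the three plane-wise label volumes into one 3D segmentation
#'
#' Per-voxel majority vote over the axial, sagittal and coronal dense
#' predictions. A three-way tie (all votes distinct) is broken by the fixed
#' priority LC > PPS > background, favoring anatomy over background so that
#' disagreement does not open spurious gaps. The confidence volume stores
#' votes-for-winner / 3.
#'
#' @param axial,sagittal,coronal [label_volume()]s of identical shape.
#' @return List with `labels` (the fused [label_volume()]) and `confidence`
#'   (numeric array in `{1/3, 2/3, 1}`).
#' @export
fuse_planes <- function(axial, sagittal, coronal) {
  d1 <- dim(axial); d2 <- dim(sagittal); d3 <- dim(coronal)
  if (!identical(d1, d2) || !identical(d1, d3))
    stop("shape mismatch between plane predictions: ",
         paste(d1, collapse = "x"), ", ", paste(d2, collapse = "x"),
         ", ", paste(d3, collapse = "x"), call. = FALSE)
  a <- unclass(axial); s <- unclass(sagittal); c3 <- unclass(coronal)
  n1 <- (a == 1L) + (s == 1L) + (c3 == 1L)
  n2 <- (a == 2L) + (s == 2L) + (c3 == 2L)
  n0 <- 3L - n1 - n2
  fused <- array(0L, dim = d1)
  fused[n2 >= 2L] <- 2L
  fused[n1 >= 2L] <- 1L
  three_way <- n0 == 1L & n1 == 1L & n2 == 1L
  fused[three_way] <- 1L                      # tie priority LC > PPS > bg
  conf <- pmax(n0, n1, n2) / 3
  conf[three_way] <- 1 / 3
  list(labels = volume_like(fused, axial), confidence = conf)
}
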