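#' Simulate sparse manual labeling of a slice series
#'
#' Emulates a single expert reader who labels the LC and PPS on every 3rd
#' to 5th frame of each plane, within the contiguous range of frames that
#' actually contain anatomy. The first annotated frame is the first frame
#' with any non-background voxel; successive strides are drawn uniformly
#' from `min_stride:max_stride` under the given seed. Each annotated frame
#' carries the exact ground-truth labels (a perfect reader); `label_noise`
#' optionally flips a fraction of labeled pixels to simulate reader error
#' (off by default).
#'
#' @param truth a [label_volume()] of ground-truth labels.
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param policy list with `min_stride` and `max_stride` (defaults 3 and 5).
#' @param seed RNG seed for the stride draws.
#' @param label_noise fraction of annotated tissue pixels whose label is
#'   re-drawn at random (0 = perfect reader).
#' @return A `sparse_annotation` object: list with `plane`, `entries` (2D
#'   label matrices named by frame index), `frame_indices`, `stride_policy`
#'   and `seed`. A volume with no anatomy yields an empty set.
#' @export
simulate_sparse_annotation <- function(truth, plane,
                                       policy = list(min_stride = 3L,
                                                     max_stride = 5L),
                                       seed = 1L, label_noise = 0) {
  stopifnot(inherits(truth, "label_volume"))
  axis <- match_plane(plane)
  stopifnot(policy$min_stride >= 1, policy$max_stride >= policy$min_stride)
  nz <- which(apply(unclass(truth) != 0L, axis, any))
  empty <- structure(list(plane = plane, entries = list(),
                          frame_indices = integer(0),
                          stride_policy = policy, seed = as.integer(seed)),
                     class = "sparse_annotation")
  if (length(nz) == 0L) return(empty)
  first <- min(nz); last <- max(nz)
  strides <- seq.int(policy$min_stride, policy$max_stride)
  idx <- withr::with_seed(seed, {
    out <- integer(0)
    i <- first
    while (i <= last) {
      out <- c(out, i)
      i <- i + strides[sample.int(length(strides), 1L)]
    }
    out
  })
  series <- extract_slices(truth, plane)
  entries <- lapply(idx, function(k) {
    fr <- series$frames[[k]]
    if (label_noise > 0) {
      fr <- withr::with_seed(seed + k, {
        flip <- which(runif(length(fr)) < label_noise & fr != 0L)
        fr[flip] <- sample(0:2, length(flip), replace = TRUE)
        fr
      })
    }
    fr
  })
  names(entries) <- as.character(idx)
  structure(list(plane = plane, entries = entries, frame_indices = idx,
                 stride_policy = policy, seed = as.integer(seed)),
            class = "sparse_annotation")
}

#' Number of annotated frames in a sparse annotation set
#'
#' For the default phantom anatomy (spanning 210 frames) and strides drawn
#' from 3-5 this lies in the 40-70 range typical of manual LC labeling.
#'
#' @param set a `sparse_annotation`.
#' @return Integer count of annotated frames.
#' @export
count_annotations <- function(set) {
  stopifnot(inherits(set, "sparse_annotation"))
  length(set$entries)
}

#' @export
print.sparse_annotation <- function(x, ...) {
  cat(sprintf("<sparse annotation> %d %s frames (strides %d-%d, seed %d)\n",
              length(x$entries), x$plane, x$stride_policy$min_stride,
              x$stride_policy$max_stride, x$seed))
  invisible(x)
}

#' Write / read a sparse annotation set as TIFF frames plus a JSON index
#'
#' @param set a `sparse_annotation`.
#' @param dir directory to create/read.
#' @return `dir` (write) or a `sparse_annotation` (read).
#' @export
write_annotation_set <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(set$entries))
    tiff::writeTIFF(set$entries[[nm]] / 255,
                    file.path(dir, sprintf("frame_%s.tif", nm)),
                    bits.per.sample = 8L)
  jsonlite::write_json(
    list(plane = set$plane, frame_indices = set$frame_indices,
         stride_policy = set$stride_policy, seed = set$seed),
    file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_annotation_set
#' @export
read_annotation_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "index.json"),
                              simplifyVector = TRUE)
  idx <- as.integer(meta$frame_indices)
  entries <- lapply(idx, function(k) {
    m <- tiff::readTIFF(file.path(dir, sprintf("frame_%d.tif", k)),
                        as.is = TRUE)
    storage.mode(m) <- "integer"
    m
  })
  names(entries) <- as.character(idx)
  structure(list(plane = meta$plane, entries = entries, frame_indices = idx,
                 stride_policy = as.list(meta$stride_policy),
                 seed = as.integer(meta$seed)),
            class = "sparse_annotation")
}
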