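#' Configuration of a per-plane 2D segmenter
#'
#' Two model kinds are available. `"baseline"` is a deterministic,
#' non-learned segmenter: frames are flat-field corrected (divided by a
#' broad local mean, which undoes smooth multiplicative signal loss such
#' as temporal attenuation), thresholded at a level estimated from the
#' annotated frames, cleaned by a 3x3 morphological opening, and split
#' into LC/PPS by en-face distance from the disc axis. `"cnn"`
#' is a small trainable 2D encoder-decoder (see the methods vignette)
#' optimized with Adam on weighted pixelwise cross-entropy. Both predict
#' only the codes {0, 1, 2} and are interchangeable downstream.
#'
#' @param model_kind `"baseline"` or `"cnn"`.
#' @param epochs training epochs (cnn only).
#' @param patch_or_full `"downsample2"` trains and predicts at half lateral
#'   resolution (upsampling the predicted labels), `"full"` works at native
#'   resolution.
#' @param learning_rate Adam step size.
#' @param class_weights length-3 positive weights for background/LC/PPS, or
#'   `NULL` to use inverse class frequencies from the annotated frames.
#' @param seed RNG seed for weight initialization and frame shuffling.
#' @param channels encoder width of the cnn.
#' @param device_hint free text, informational only (training is CPU).
#' @return A `segmenter_config` list.
#' @export
segmenter_config <- function(model_kind = c("baseline", "cnn"),
                             epochs = 8L,
                             patch_or_full = c("downsample2", "full"),
                             learning_rate = 2e-3, class_weights = NULL,
                             seed = 1L, channels = 8L,
                             device_hint = "cpu") {
  model_kind <- match.arg(model_kind)
  patch_or_full <- match.arg(patch_or_full)
  stopifnot(epochs >= 1, learning_rate > 0)
  if (!is.null(class_weights))
    stopifnot(length(class_weights) == 3, all(class_weights > 0))
  structure(list(model_kind = model_kind, epochs = as.integer(epochs),
                 patch_or_full = patch_or_full,
                 learning_rate = learning_rate,
                 class_weights = class_weights, seed = as.integer(seed),
                 channels = as.integer(channels),
                 device_hint = device_hint),
            class = "segmenter_config")
}

# en-face (a, s) coordinates of every pixel of frame k in a given plane
frame_enface_coords <- function(plane, k, shp) {
  rows <- seq_len(shp[1]); cols <- seq_len(shp[2])
  switch(plane,
    axial = list(a = matrix(k, shp[1], shp[2]),
                 s = matrix(rows, shp[1], shp[2])),
    sagittal = list(a = matrix(rows, shp[1], shp[2]),
                    s = matrix(k, shp[1], shp[2])),
    coronal = list(a = matrix(rows, shp[1], shp[2]),
                   s = matrix(cols, shp[1], shp[2], byrow = TRUE)))
}

#' Train a per-plane 2D segmenter on sparse annotations
#'
#' Supervised training restricted to the annotated frames of one plane of
#' one eye: one model per plane per eye, with no pooling across eyes.
#'
#' @param frames intensity `slice_series` of the plane.
#' @param ann a [simulate_sparse_annotation()] result for the same plane.
#' @param config a [segmenter_config()].
#' @return A `trained_segmenter` with `plane`, `config`, `parameters` and a
#'   `training_report` (`final_loss`, `train_dice_per_class`).
#' @export
train_plane_segmenter <- function(frames, ann, config = segmenter_config()) {
  stopifnot(inherits(frames, "slice_series"),
            inherits(ann, "sparse_annotation"))
  if (!identical(frames$plane, ann$plane))
    stop("annotation plane '", ann$plane, "' does not match frame plane '",
         frames$plane, "'", call. = FALSE)
  if (count_annotations(ann) == 0)
    stop("no annotated frames: check that the annotation span covers ",
         "frames containing anatomy", call. = FALSE)
  model <- if (config$model_kind == "baseline")
    train_baseline(frames, ann, config)
  else
    train_cnn(frames, ann, config)
  model$plane <- frames$plane
  model$config <- config
  class(model) <- "trained_segmenter"
  # training report: dice against the annotations themselves
  preds <- lapply(ann$frame_indices, function(k)
    predict_frame(model, frames$frames[[k]], k))
  dpc <- vapply(0:2, function(code) {
    aa <- unlist(lapply(preds, function(p) p == code))
    bb <- unlist(lapply(ann$entries, function(e) e == code))
    den <- sum(aa) + sum(bb)
    if (den == 0) 1 else 2 * sum(aa & bb) / den
  }, numeric(1))
  model$training_report$train_dice_per_class <- dpc
  if (is.null(model$training_report$final_loss))
    model$training_report$final_loss <- 1 - mean(dpc)
  model
}

# flat-field correction: divide by a broad local mean so that smooth
# multiplicative signal loss (temporal attenuation, vessel shadows) does
# not push tissue below a global threshold
correct_illumination <- function(frame, window = 31L) {
  w <- min(window, 2L * (min(dim(frame)) %/% 2L) - 1L)
  box <- matrix(1 / (w * w), w, w)
  b <- as.matrix(EBImage::filter2(EBImage::Image(frame), box,
                                  boundary = "replicate"))
  frame / pmax(b, 0.05)
}

# baseline preprocessing: flat-field correction, then a small Gaussian
# despeckle so a global threshold is not at the mercy of per-pixel
# multiplicative noise. The blur trades a ~1-voxel halo at tissue borders
# for robust recovery of noise-thinned tissue; at protocol resolution the
# plate is 7-9 voxels thick and the trade is clearly worth it.
preprocess_frame <- function(frame) {
  cf <- correct_illumination(frame)
  k <- min(7L, 2L * (min(dim(frame)) %/% 2L) - 1L)
  g <- EBImage::makeBrush(k, "gaussian", sigma = 1.5)
  as.matrix(EBImage::filter2(EBImage::Image(cf), g,
                             boundary = "replicate"))
}

# histogram split: the intensity cut that misclassifies the fewest
# annotated pixels (tissue above, background below)
optimal_split <- function(values, is_tissue) {
  ord <- order(values)
  v <- values[ord]; t <- is_tissue[ord]
  n <- length(v)
  # errors when cutting after position i: tissue at or below i plus
  # background above i
  tissue_below <- cumsum(t)
  bg_above <- sum(!t) - cumsum(!t)
  errs <- tissue_below + bg_above
  i <- which.min(errs)
  if (i >= n) v[n] + 1e-6 else (v[i] + v[i + 1]) / 2
}

train_baseline <- function(frames, ann, config) {
  ints <- lapply(ann$frame_indices,
                 function(k) preprocess_frame(frames$frames[[k]]))
  labs <- ann$entries
  iv <- unlist(ints, use.names = FALSE)
  lv <- unlist(labs, use.names = FALSE)
  if (!any(lv > 0) || !any(lv == 0))
    stop("baseline segmenter needs both tissue and background pixels in ",
         "the annotations", call. = FALSE)
  thr <- optimal_split(iv, lv > 0)
  # en-face disc center/extent of the LC from the annotated frames
  acc_a <- acc_s <- numeric(0)
  for (i in seq_along(labs)) {
    k <- ann$frame_indices[i]
    en <- frame_enface_coords(ann$plane, k, dim(labs[[i]]))
    sel <- labs[[i]] == 1L
    acc_a <- c(acc_a, en$a[sel]); acc_s <- c(acc_s, en$s[sel])
  }
  if (length(acc_a) == 0)
    stop("baseline segmenter needs LC pixels in the annotations",
         call. = FALSE)
  ca <- mean(acc_a); cs <- mean(acc_s)
  r <- sqrt((acc_a - ca)^2 + (acc_s - cs)^2)
  r_split <- unname(quantile(r, 0.999)) + 0.5
  list(parameters = list(threshold = thr, center_a = ca, center_s = cs,
                         r_split = r_split),
       training_report = list(final_loss = NULL))
}

train_cnn <- function(frames, ann, config) {
  prep <- function(m) {
    if (config$patch_or_full == "downsample2")
      m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)]
    else m
  }
  xs <- lapply(ann$frame_indices, function(k) prep(frames$frames[[k]]))
  ys <- lapply(ann$entries, prep)
  cw <- config$class_weights
  if (is.null(cw)) {
    freq <- tabulate(unlist(ys, use.names = FALSE) + 1L, nbins = 3L)
    cw <- sum(freq) / (3 * pmax(freq, 1))
    cw <- pmin(cw / mean(cw), 25)
  }
  final_loss <- NA_real_
  par <- withr::with_seed(config$seed, {
    par <- cnn_init(config$channels)
    st <- adam_init(par)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(seq_along(xs))
      ep_loss <- 0
      for (i in ord) {
        fw <- cnn_forward(xs[[i]], par)
        lg <- cnn_loss_grad(fw$logits, ys[[i]], cw)
        ep_loss <- ep_loss + lg$loss
        grads <- cnn_backward(fw$cache, lg$dlogits, par)
        upd <- adam_step(par, grads, st, config$learning_rate)
        par <- upd$par; st <- upd$state
      }
      final_loss <- ep_loss / length(xs)
    }
    par
  })
  list(parameters = list(weights = par, class_weights = cw),
       training_report = list(final_loss = final_loss))
}

predict_frame <- function(model, frame, k) {
  cfg <- model$config
  if (cfg$model_kind == "baseline") {
    p <- model$parameters
    tissue <- preprocess_frame(frame) >= p$threshold
    tissue <- as.matrix(EBImage::opening(
      EBImage::Image(tissue * 1), EBImage::makeBrush(3, "box"))) > 0.5
    en <- frame_enface_coords(model$plane, k, dim(frame))
    r <- sqrt((en$a - p$center_a)^2 + (en$s - p$center_s)^2)
    out <- matrix(0L, nrow(frame), ncol(frame))
    out[tissue & r <= p$r_split] <- 1L
    out[tissue & r > p$r_split] <- 2L
    out
  } else {
    x <- frame
    if (cfg$patch_or_full == "downsample2")
      x <- x[seq(1, nrow(x), 2), seq(1, ncol(x), 2)]
    fw <- cnn_forward(x, model$parameters$weights)
    lm <- matrix(fw$logits, prod(dim(x)), 3)
    lab <- matrix(max.col(lm, ties.method = "first") - 1L,
                  nrow(x), ncol(x))
    if (cfg$patch_or_full == "downsample2") {
      lab <- lab[rep(seq_len(nrow(lab)), each = 2),
                 rep(seq_len(ncol(lab)), each = 2)]
      lab <- lab[seq_len(nrow(frame)), seq_len(ncol(frame))]
    }
    storage.mode(lab) <- "integer"
    lab
  }
}

#' Predict dense labels for every frame of a plane
#'
#' One label frame per intensity frame, same shape; annotated frames are
#' re-predicted, not copied.
#'
#' @param model a [train_plane_segmenter()] result.
#' @param frames intensity `slice_series` of the model's plane.
#' @return A label `slice_series` (stacks to a [label_volume()]).
#' @export
predict_plane <- function(model, frames) {
  stopifnot(inherits(model, "trained_segmenter"),
            inherits(frames, "slice_series"))
  if (!identical(frames$plane, model$plane))
    stop("frame plane '", frames$plane, "' does not match model plane '",
         model$plane, "'", call. = FALSE)
  preds <- lapply(seq_along(frames$frames), function(k)
    predict_frame(model, frames$frames[[k]], k))
  structure(list(plane = frames$plane, frames = preds,
                 source_shape = frames$source_shape,
                 spacing_mm = frames$spacing_mm,
                 laterality = frames$laterality, kind = "label"),
            class = "slice_series")
}

#' @export
print.trained_segmenter <- function(x, ...) {
  cat(sprintf("<%s segmenter> plane %s, final loss %.4g, train dice %s\n",
              x$config$model_kind, x$plane,
              x$training_report$final_loss,
              paste(sprintf("%.3f", x$training_report$train_dice_per_class),
                    collapse = "/")))
  invisible(x)
}

#' One-row summary of a trained segmenter
#'
#' @param x a `trained_segmenter`.
#' @param ... unused.
#' @return A one-row tibble with the plane, model kind, epochs, final loss
#'   and per-class training Dice.
#' @export
glance.trained_segmenter <- function(x, ...) {
  d <- x$training_report$train_dice_per_class
  tibble::tibble(plane = x$plane, model_kind = x$config$model_kind,
                 epochs = x$config$epochs,
                 final_loss = x$training_report$final_loss,
                 dice_background = d[1], dice_lc = d[2], dice_pps = d[3])
}

#' Save / load a trained segmenter as a single JSON checkpoint
#'
#' The config is embedded; weights are serialized as flat numeric arrays,
#' so the checkpoint is plain text.
#'
#' @param model a `trained_segmenter`.
#' @param path destination `.json` path.
#' @return `path` (save) or the restored `trained_segmenter` (load).
#' @export
save_segmenter <- function(model, path) {
  ser <- list(plane = model$plane,
              config = unclass(model$config),
              kind = model$config$model_kind,
              training_report = model$training_report)
  if (model$config$model_kind == "baseline") {
    ser$parameters <- model$parameters
  } else {
    w <- model$parameters$weights
    ser$parameters <- list(
      class_weights = model$parameters$class_weights,
      shapes = lapply(w, function(p) dim(p) %||% length(p)),
      values = lapply(w, as.vector))
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ser$config
  cw <- unlist(cfg$class_weights)
  if (length(cw) == 0) cw <- NULL
  config <- segmenter_config(cfg$model_kind, cfg$epochs, cfg$patch_or_full,
                             cfg$learning_rate, cw, cfg$seed,
                             cfg$channels, cfg$device_hint)
  if (ser$kind == "baseline") {
    parameters <- as.list(ser$parameters)
  } else {
    w <- ser$parameters$values
    for (nm in names(w)) {
      shp <- unlist(ser$parameters$shapes[[nm]])
      if (length(shp) == 2) dim(w[[nm]]) <- shp
      if (grepl("^k", nm)) w[[nm]] <- as.integer(w[[nm]])
    }
    parameters <- list(weights = w,
                       class_weights = ser$parameters$class_weights)
  }
  structure(list(parameters = parameters,
                 training_report = as.list(ser$training_report),
                 plane = ser$plane, config = config),
            class = "trained_segmenter")
}
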