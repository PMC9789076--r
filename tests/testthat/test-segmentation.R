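noise_free_phantom <- function()
  cached_phantom("noise_free",
                 small_spec(seed = 31, noise_level = 0, vessel_count = 0L,
                            temporal_attenuation = 0.2))

test_that("baseline segmenter recovers noise-free frames almost exactly", {
  # protocol-scale phantom: the per-class guarantee concerns plates at
  # their physical thickness, not the thin plates of the scaled test grid
  gt <- cached_phantom("noise_free_full",
                       phantom_spec(seed = 31, noise_level = 0,
                                    vessel_count = 0L,
                                    temporal_attenuation = 0.2))
  fr <- extract_slices(gt$intensity, "axial")
  ann <- simulate_sparse_annotation(gt$labels, "axial", seed = 1)
  m <- train_plane_segmenter(fr, ann, segmenter_config("baseline"))
  truth <- extract_slices(gt$labels, "axial")
  k <- ann$frame_indices[ceiling(length(ann$frame_indices) / 2)]
  pred <- predict_plane(m, fr)$frames[[k]]
  for (code in 0:2)
    expect_gte(dice(pred, truth$frames[[k]], code), 0.95)
})

test_that("baseline predictions agree with annotations on >= 90% of tissue", {
  gt <- noise_free_phantom()
  fr <- extract_slices(gt$intensity, "sagittal")
  ann <- simulate_sparse_annotation(gt$labels, "sagittal", seed = 2)
  m <- train_plane_segmenter(fr, ann, segmenter_config("baseline"))
  pred <- predict_plane(m, fr)
  agree <- vapply(seq_along(ann$frame_indices), function(i) {
    k <- ann$frame_indices[i]
    tissue <- ann$entries[[i]] != 0L
    mean(pred$frames[[k]][tissue] == ann$entries[[i]][tissue])
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("dense prediction covers every frame with codes in {0,1,2}", {
  gt <- small_clean_phantom()
  fr <- extract_slices(gt$intensity, "coronal")
  ann <- simulate_sparse_annotation(gt$labels, "coronal", seed = 3)
  m <- train_plane_segmenter(fr, ann, segmenter_config("baseline"))
  pred <- predict_plane(m, fr)
  expect_length(pred$frames, length(fr$frames))
  expect_true(all(unlist(pred$frames) %in% 0:2))
  expect_identical(dim(stack_slices(pred)), dim(gt$labels))
  # a constant-zero frame maps to all-background
  zeros <- fr
  zeros$frames <- lapply(fr$frames, function(f) f * 0)
  pz <- predict_plane(m, zeros)
  expect_true(all(unlist(pz$frames) == 0L))
})

test_that("plane mismatches and empty annotation sets are rejected", {
  gt <- small_clean_phantom()
  fr <- extract_slices(gt$intensity, "axial")
  ann <- simulate_sparse_annotation(gt$labels, "sagittal", seed = 1)
  expect_error(train_plane_segmenter(fr, ann), "does not match")
  empty_ann <- simulate_sparse_annotation(
    label_volume(array(0L, dim = dim(gt$labels))), "axial")
  expect_error(train_plane_segmenter(fr, empty_ann), "annotation span")
  ann_ax <- simulate_sparse_annotation(gt$labels, "axial", seed = 1)
  m <- train_plane_segmenter(fr, ann_ax, segmenter_config("baseline"))
  expect_error(predict_plane(m, extract_slices(gt$intensity, "coronal")),
               "does not match")
})

test_that("convolutional gradients match numerical differentiation", {
  withr::with_seed(42, {
    par <- lamcrib:::cnn_init(3L)
    x <- matrix(runif(11 * 9), 11, 9)
    y <- matrix(sample(0:2, 11 * 9, TRUE), 11, 9)
  })
  cw <- c(1, 2, 3)
  lossfun <- function(p) {
    fw <- lamcrib:::cnn_forward(x, p)
    lamcrib:::cnn_loss_grad(fw$logits, y, cw)$loss
  }
  fw <- lamcrib:::cnn_forward(x, par)
  lg <- lamcrib:::cnn_loss_grad(fw$logits, y, cw)
  gr <- lamcrib:::cnn_backward(fw$cache, lg$dlogits, par)
  eps <- 1e-5
  for (nm in c("W1", "W2", "W3", "W4", "W5", "b1", "b3", "b5")) {
    for (i in seq_len(min(4, length(par[[nm]])))) {
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- par; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]), 1e-6 * max(1, abs(num)))
    }
  }
})

cnn_fixture <- function(seed = 1L, epochs = 2L) {
  gt <- small_clean_phantom()
  fr <- extract_slices(gt$intensity, "axial")
  ann <- simulate_sparse_annotation(
    gt$labels, "axial", policy = list(min_stride = 10L, max_stride = 10L),
    seed = 4)
  m <- train_plane_segmenter(fr, ann,
                             segmenter_config("cnn", epochs = epochs,
                                              seed = seed, channels = 4L))
  list(gt = gt, fr = fr, ann = ann, model = m)
}

test_that("the cnn contract holds for a one-frame, one-epoch training", {
  gt <- small_clean_phantom()
  fr <- extract_slices(gt$intensity, "axial")
  ann <- simulate_sparse_annotation(
    gt$labels, "axial", policy = list(min_stride = 300L, max_stride = 300L),
    seed = 1)
  expect_identical(count_annotations(ann), 1L)
  m <- train_plane_segmenter(fr, ann,
                             segmenter_config("cnn", epochs = 1L,
                                              channels = 4L))
  pred <- predict_plane(m, fr)
  expect_true(all(unlist(pred$frames) %in% 0:2))
  expect_length(pred$frames, length(fr$frames))
})

test_that("cnn training is reproducible for a fixed seed", {
  a <- cnn_fixture(seed = 5L)$model
  b <- cnn_fixture(seed = 5L)$model
  expect_lt(abs(a$training_report$final_loss -
                b$training_report$final_loss), 1e-6)
  expect_equal(a$parameters$weights$W1, b$parameters$weights$W1,
               tolerance = 1e-10)
})

test_that("trained segmenters survive a checkpoint round trip", {
  fx <- cnn_fixture(seed = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  save_segmenter(fx$model, path)
  back <- load_segmenter(path)
  k <- fx$ann$frame_indices[1]
  expect_identical(lamcrib:::predict_frame(back, fx$fr$frames[[k]], k),
                   lamcrib:::predict_frame(fx$model, fx$fr$frames[[k]], k))
  expect_s3_class(glance(back), "tbl_df")
  # baseline checkpoint too
  ann <- simulate_sparse_annotation(fx$gt$labels, "axial", seed = 4)
  mb <- train_plane_segmenter(fx$fr, ann, segmenter_config("baseline"))
  pb <- withr::local_tempfile(fileext = ".json")
  save_segmenter(mb, pb)
  backb <- load_segmenter(pb)
  expect_identical(lamcrib:::predict_frame(backb, fx$fr$frames[[k]], k),
                   lamcrib:::predict_frame(mb, fx$fr$frames[[k]], k))
})
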