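test_that("clean phantom uses exactly the three label codes and no rim gap", {
  gt <- small_clean_phantom()
  codes <- sort(unique(as.vector(unclass(gt$labels))))
  expect_identical(codes, c(0L, 1L, 2L))
  expect_gt(sum(gt$labels == 1L), 0)
  expect_gt(sum(gt$labels == 2L), 0)
  # no full-thickness gap at the rim: every en-face column in the rim band
  # contains tissue
  spec <- gt$spec
  L <- unclass(gt$labels)
  has_tissue <- apply(L != 0L, c(1, 2), any)
  da <- seq_len(dim(L)[1]) - spec$disc_center[1]
  ds <- seq_len(dim(L)[2]) - spec$disc_center[2]
  r <- sqrt(outer(da^2, ds^2, "+"))
  rim <- abs(r - spec$disc_radius_vox) <= spec$lcd_radial_vox / 2
  expect_true(all(has_tissue[rim]))
})

test_that("generation is bit-reproducible for a fixed seed", {
  spec <- small_spec(seed = 123, has_lcd = TRUE)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(unclass(a$intensity), unclass(b$intensity))
  expect_identical(unclass(a$labels), unclass(b$labels))
})

test_that("ground-truth defect centroid recovers the requested rim angle", {
  # brute-force oracle: tissue-free en-face columns in the rim band
  for (ang in c(0, 10, 200)) {
    gt <- generate_phantom(small_spec(seed = 5, has_lcd = TRUE,
                                      lcd_angle_deg = ang))
    spec <- gt$spec
    L <- unclass(gt$labels)
    no_tissue <- apply(L == 0L, c(1, 2), all)
    da <- seq_len(dim(L)[1]) - spec$disc_center[1]
    ds <- seq_len(dim(L)[2]) - spec$disc_center[2]
    r <- sqrt(outer(da^2, ds^2, "+"))
    sel <- which(no_tissue & abs(r - spec$disc_radius_vox) <=
                   spec$lcd_radial_vox, arr.ind = TRUE)
    expect_gt(nrow(sel), 0)
    est <- atan2(mean(sel[, 2] - spec$disc_center[2]),
                 mean(sel[, 1] - spec$disc_center[1])) * 180 / pi
    err <- abs((est - ang + 180) %% 360 - 180)
    expect_lt(err, 5)
  }
  # defect at 0 deg in an OD eye lies in the temporal quadrant
  gt <- small_defect_phantom()
  rep <- small_detect(gt$labels)
  expect_identical(rep$regions[[1]]$quadrant, "temporal")
})

test_that("increasing speckle strictly decreases the LC/background contrast", {
  contrasts <- vapply(c(0, 0.15, 0.3, 0.45), function(nl) {
    gt <- generate_phantom(small_spec(seed = 9, noise_level = nl))
    I <- unclass(gt$intensity); L <- unclass(gt$labels)
    (mean(I[L == 1L]) - mean(I[L == 0L])) /
      sqrt((var(I[L == 1L]) + var(I[L == 0L])) / 2)
  }, numeric(1))
  expect_true(all(diff(contrasts) < 0))
})

test_that("invalid phantom geometry is rejected with the offending field", {
  expect_error(small_spec(disc_center = c(5, 28, 24)), "disc_center")
  expect_error(small_spec(disc_radius_vox = 40), "grid bounds")
  expect_error(small_spec(has_lcd = TRUE, pore_radius_vox = 5,
                          lcd_radial_vox = 4), "pore_radius_vox")
  expect_error(phantom_spec(intensity_lc = 0.1, intensity_bg = 0.5),
               "intensity_lc")
})

test_that("cohort generation hits the defect count exactly and jitters eyes", {
  cohort <- generate_cohort(42, 12 / 42, small_spec(), seed = 1)
  n_pos <- sum(vapply(cohort, function(g) g$spec$has_lcd, logical(1)))
  expect_identical(n_pos, 12L)
  expect_identical(length(cohort), 42L)
  ids <- vapply(cohort, function(g) g$spec$volume_id, "")
  expect_false(anyDuplicated(ids) > 0)

  none <- generate_cohort(5, 0, small_spec(), seed = 2)
  expect_identical(sum(vapply(none, function(g) g$spec$has_lcd, logical(1))),
                   0L)

  all_pos <- generate_cohort(10, 1, small_spec(), seed = 3)
  expect_identical(
    sum(vapply(all_pos, function(g) g$spec$has_lcd, logical(1))), 10L)
  # distinct volumes: nuisance jitter makes intensities differ
  sums <- vapply(all_pos, function(g) sum(unclass(g$intensity)), numeric(1))
  expect_identical(length(unique(sums)), 10L)
})

test_that("laminar pores darken the intensity but never the labels", {
  base <- small_spec(seed = 21, noise_level = 0, vessel_count = 0L)
  no_pores <- base; no_pores$pore_count <- 0L
  with_pores <- base; with_pores$pore_count <- 15L
  a <- generate_phantom(no_pores)
  b <- generate_phantom(with_pores)
  expect_identical(unclass(a$labels), unclass(b$labels))
  expect_gt(sum(unclass(a$intensity) != unclass(b$intensity)), 0)
})
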