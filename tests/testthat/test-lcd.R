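test_that("disc geometry is recovered from ground-truth labels", {
  gt <- cached_phantom("untilted", small_spec(seed = 2, tilt_deg = 0))
  g <- estimate_disc_geometry(gt$labels)
  expect_lt(max(abs(g$center[1:2] - gt$spec$disc_center[1:2])), 2)
  expect_gt(abs(g$axis[3]), cos(5 * pi / 180))   # axis within 5 deg of depth
  expect_lt(abs(g$radius_vox - gt$spec$disc_radius_vox), 3)

  one <- array(0L, dim = c(9, 9, 9)); one[4, 5, 6] <- 1L
  g1 <- estimate_disc_geometry(label_volume(one))
  expect_identical(g1$center, c(4, 5, 6))
  expect_gt(g1$radius_vox, 0)
  expect_error(estimate_disc_geometry(label_volume(array(0L, c(3, 3, 3)))),
               "no LC voxels")
})

test_that("the ground-truth defect is found as one full-thickness region", {
  gt <- small_defect_phantom()
  rep <- small_detect(gt$labels)
  expect_true(rep$has_lcd)
  expect_length(rep$regions, 1)
  r <- rep$regions[[1]]
  expect_true(r$full_thickness)
  expect_identical(r$quadrant, "temporal")
  expect_lt(abs((r$centroid_angle_deg - gt$spec$lcd_angle_deg + 180) %%
                  360 - 180), 5)
  # brute-force column-scan oracle: every region column is LC-free
  lc_proj <- apply(unclass(gt$labels) == 1L, c(1, 2), any)
  cols <- unique(r$voxels[, 1:2, drop = FALSE])
  expect_true(all(!lc_proj[cols]))
})

test_that("clean phantoms and over-thresholded defects yield empty reports", {
  gt <- small_clean_phantom()
  rep <- small_detect(gt$labels)
  expect_false(rep$has_lcd)
  expect_length(rep$regions, 0)

  gtd <- small_defect_phantom()
  size <- small_detect(gtd$labels)$regions[[1]]$size_vox
  over <- detect_lcd(gtd$labels, min_size = size + 1L, min_enface_diam = 4,
                     depth_halfwidth_vox = 1)
  expect_false(over$has_lcd)
})

test_that("raising min_size never adds regions", {
  gt <- small_defect_phantom()
  counts <- vapply(c(10L, 40L, 200L, 2000L), function(ms)
    length(detect_lcd(gt$labels, min_size = ms, min_enface_diam = 4,
                      depth_halfwidth_vox = 1)$regions), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("quadrants follow the laterality-aware 90-degree sectors", {
  expect_identical(classify_location(0), "temporal")
  expect_identical(classify_location(90), "superior")
  expect_identical(classify_location(180), "nasal")
  expect_identical(classify_location(270), "inferior")
  expect_identical(classify_location(44.9), "temporal")
  expect_identical(classify_location(315), "temporal")

  # OD defect at 10 deg is temporal; read as an OS eye the same en-face
  # position becomes nasal
  gt <- cached_phantom("defect10",
                       small_spec(seed = 3, has_lcd = TRUE,
                                  lcd_angle_deg = 10))
  od <- small_detect(gt$labels, estimate_disc_geometry(gt$labels, "OD"))
  os <- small_detect(gt$labels, estimate_disc_geometry(gt$labels, "OS"))
  expect_identical(od$regions[[1]]$quadrant, "temporal")
  expect_identical(os$regions[[1]]$quadrant, "nasal")
})

test_that("mirroring a volume and flipping laterality preserves quadrants", {
  gt <- cached_phantom("defect10",
                       small_spec(seed = 3, has_lcd = TRUE,
                                  lcd_angle_deg = 10))
  mir <- label_volume(unclass(gt$labels)[dim(gt$labels)[1]:1, , ],
                      attr(gt$labels, "spacing_mm"), "OS")
  orig <- small_detect(gt$labels, estimate_disc_geometry(gt$labels, "OD"))
  flip <- small_detect(mir, estimate_disc_geometry(mir, "OS"))
  expect_identical(flip$regions[[1]]$quadrant, orig$regions[[1]]$quadrant)
  expect_lt(abs(flip$regions[[1]]$centroid_angle_deg -
                orig$regions[[1]]$centroid_angle_deg), 2)
})

test_that("orientation classification follows the en-face principal axis", {
  strip <- function(a, s) {
    structure(list(voxels = cbind(a, s, 5L)), class = "lcd_region")
  }
  vert <- classify_orientation(strip(rep(5L, 20), 1:20))
  expect_identical(vert$class, "vertical")
  expect_equal(vert$orientation_deg, 90)
  horiz <- classify_orientation(strip(1:20, rep(5L, 20)))
  expect_identical(horiz$class, "horizontal")
  expect_equal(horiz$orientation_deg %% 180, 0)
  obli <- classify_orientation(strip(1:20, 1:20))
  expect_identical(obli$class, "oblique")
  single <- classify_orientation(strip(5L, 5L))
  expect_identical(single$class, "oblique")
  expect_true(single$degenerate)
  expect_true(is.na(single$orientation_deg))
  # the temporal wedge defect runs along the vertical rim
  gt <- small_defect_phantom()
  expect_identical(small_detect(gt$labels)$regions[[1]]$orientation_class,
                   "vertical")
})

test_that("pores never alter the report; anterior-face components are not
           reported", {
  base <- small_spec(seed = 21, noise_level = 0, vessel_count = 0L,
                     has_lcd = TRUE)
  no_pores <- base; no_pores$pore_count <- 0L
  with_pores <- base; with_pores$pore_count <- 15L
  a <- generate_phantom(no_pores); b <- generate_phantom(with_pores)
  ra <- small_detect(a$labels); rb <- small_detect(b$labels)
  expect_identical(tidy(ra), tidy(rb))

  # a gap whose component reaches the anterior volume face (depth index 1)
  # is treated as a vessel shadow and excluded
  dims <- c(40L, 40L, 5L)
  arr <- array(0L, dim = dims)
  da <- seq_len(40) - 20.5; ds <- seq_len(40) - 20.5
  r <- sqrt(outer(da^2, ds^2, "+"))
  for (k in 1:5) {
    sl <- array(0L, dim = c(40, 40))
    sl[r <= 10] <- 1L
    sl[r > 10 & r <= 17] <- 2L
    arr[, , k] <- sl
  }
  theta <- atan2(matrix(ds, 40, 40, byrow = TRUE), matrix(da, 40, 40))
  wedge <- abs(theta) < 20 * pi / 180 & r >= 8 & r <= 12
  for (k in 1:5) { sl <- arr[, , k]; sl[wedge] <- 0L; arr[, , k] <- sl }
  lv <- label_volume(arr, laterality = "OD")
  geom <- estimate_disc_geometry(lv)
  with_rules <- detect_lcd(lv, geom, min_size = 20, min_enface_diam = 3,
                           depth_halfwidth_vox = 3)
  without <- detect_lcd(lv, geom, min_size = 20, min_enface_diam = 3,
                        depth_halfwidth_vox = 3, exclusion_rules = FALSE)
  expect_false(with_rules$has_lcd)
  expect_true(without$has_lcd)
})

test_that("a shadow tube crossing the rim annulus is not called a defect", {
  gt <- small_clean_phantom()
  arr <- unclass(gt$labels)
  ci <- gt$spec$disc_center[1]
  # kill all tissue in a 7-voxel-wide radial strip from the disc center out
  strip_a <- (round(ci) - 3):(round(ci) + 3)
  arr[strip_a, seq_len(round(gt$spec$disc_center[2])), ] <- 0L
  shadowed <- label_volume(arr, attr(gt$labels, "spacing_mm"), "OD")
  rep <- small_detect(shadowed, estimate_disc_geometry(shadowed, "OD"))
  expect_false(rep$has_lcd)
})

test_that("reports tidy into one row per region and serialize to disk", {
  gt <- small_defect_phantom()
  rep <- small_detect(gt$labels)
  rep$volume_id <- "eye_A"
  tab <- tidy(rep)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$volume_id, "eye_A")
  expect_true(all(c("size_vox", "quadrant", "orientation_deg",
                    "centroid_angle_deg", "full_thickness") %in%
                    names(tab)))
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_lcd_report(rep, js, cs)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_identical(parsed$volume_id, "eye_A")
  expect_true(parsed$has_lcd)
  expect_identical(nrow(utils::read.csv(cs)), 1L)
})
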