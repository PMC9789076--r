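test_that("dice handles identity, disjointness and partial overlap", {
  a <- random_label_volume(c(6, 6, 6), seed = 1)
  expect_equal(dice(a, a, 1L), 1)
  x <- array(0L, dim = c(4, 4, 4)); y <- array(0L, dim = c(4, 4, 4))
  x[1:2, 1, 1] <- 1L; y[3:4, 1, 1] <- 1L
  expect_equal(dice(label_volume(x), label_volume(y), 1L), 0)
  # |A| = 8, |B| = 8, overlap 4 -> 2*4/16 = 0.5 by direct count
  x <- array(0L, dim = c(4, 4, 4)); y <- array(0L, dim = c(4, 4, 4))
  x[1:8] <- 1L; y[5:12] <- 1L
  expect_equal(dice(label_volume(x), label_volume(y), 1L), 0.5)
  # both empty -> 1 by convention
  expect_equal(dice(label_volume(x), label_volume(y), 2L), 1)
  expect_error(dice(label_volume(x), random_label_volume(c(3, 3, 3)), 1L),
               "shape mismatch")
})

test_that("dice is symmetric and bounded on random masks", {
  for (seed in 1:10) {
    a <- random_label_volume(c(5, 5, 5), seed = seed)
    b <- random_label_volume(c(5, 5, 5), seed = seed + 50)
    for (code in 0:2) {
      d1 <- dice(a, b, code)
      expect_equal(d1, dice(b, a, code))
      expect_gte(d1, 0); expect_lte(d1, 1)
    }
  }
})

fake_report <- function(id, positive, angle = 0) {
  regions <- if (positive)
    list(list(centroid_angle_deg = angle, quadrant = classify_location(angle),
              size_vox = 100L))
  else list()
  structure(list(volume_id = id, regions = regions, has_lcd = positive),
            class = "lcd_report")
}

fake_spec <- function(id, positive, angle = 0)
  list(volume_id = id, has_lcd = positive, lcd_angle_deg = angle)

test_that("detection metrics reproduce 2x2 arithmetic", {
  ids <- sprintf("v%02d", 1:20)
  truth_pos <- c(rep(TRUE, 10), rep(FALSE, 10))
  specs <- Map(fake_spec, ids, truth_pos, ifelse(truth_pos, 10, 0))
  # perfect reports
  perfect <- Map(fake_report, ids, truth_pos, 10)
  m <- detection_metrics(perfect, specs)
  expect_equal(m$sensitivity, 1); expect_equal(m$specificity, 1)
  expect_identical(m$n_tp + m$n_fp + m$n_tn + m$n_fn, 20L)
  # all-negative reports
  negs <- Map(fake_report, ids, FALSE)
  expect_equal(detection_metrics(negs, specs)$sensitivity, 0)
  # 9 TP, 1 FN, 1 FP -> sensitivity 0.9, specificity 0.9
  calls <- c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 9))
  mixed <- Map(fake_report, ids, calls, 25)
  m2 <- detection_metrics(mixed, specs)
  expect_equal(m2$sensitivity, 0.9)
  expect_equal(m2$specificity, 0.9)
  expect_identical(m2$n_tp, 9L); expect_identical(m2$n_fp, 1L)
  # angle errors are wrapped and reported only for true positives
  expect_length(m2$angle_errors, 9)
  expect_true(all(abs(m2$angle_errors - 15) < 1e-9))
  # sensitivity * n_pos equals n_tp exactly
  expect_equal(m2$sensitivity * (m2$n_tp + m2$n_fn), m2$n_tp)
  # misaligned ids abort
  expect_error(detection_metrics(perfect[1:19], specs), "volume_id")
})

test_that("the prevalence formatter reproduces clinical percentages", {
  expect_identical(format_count_pct(12, 42), "12 (29%)")
  expect_identical(format_count_pct(30, 42), "30 (71%)")
  expect_identical(format_count_pct(11, 12), "11 (92%)")
  expect_identical(format_count_pct(0, 5), "0 (0%)")
  # round half away from zero, not banker's rounding
  expect_identical(format_count_pct(1, 8), "1 (13%)")
  expect_identical(format_count_pct(3, 8), "3 (38%)")
})

test_that("cohort summaries count presence and quadrant breakdowns", {
  ids <- sprintf("v%02d", 1:42)
  pos <- seq_len(42) <= 12
  angles <- c(rep(0, 11), 250, rep(0, 30))     # 11 temporal, 1 inferior
  reports <- Map(fake_report, ids, pos, angles)
  tab <- prevalence_summary(reports)
  expect_identical(tab$formatted[tab$group == "lcd_present"], "12 (29%)")
  expect_identical(tab$formatted[tab$group == "lcd_absent"], "30 (71%)")
  expect_identical(tab$formatted[tab$group == "location_temporal"],
                   "11 (92%) of 12")
  expect_identical(tab$count[tab$group == "location_inferior"], 1L)
  expect_error(prevalence_summary(list()), "no reports")
})
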