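round_half_up <- function(x) floor(x + 0.5)

#' Dice similarity coefficient for one label class
#'
#' `2|A n B| / (|A| + |B|)` between the voxels of `class_code` in the
#' prediction and the truth; defined as 1 when the class is absent from
#' both volumes.
#'
#' @param pred,truth [label_volume()]s (or plain arrays) of equal shape.
#' @param class_code label code (0, 1 or 2).
#' @return Numeric in `[0, 1]`.
#' @export
dice <- function(pred, truth, class_code) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), call. = FALSE)
  a <- unclass(pred) == class_code
  b <- unclass(truth) == class_code
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Detection performance of LCD reports against known phantom truth
#'
#' Standard 2x2 counts on the presence call, plus signed centroid-angle
#' errors (wrapped to `[-180, 180]` degrees) for the true positives.
#'
#' @param reports list of [detect_lcd()] reports.
#' @param truths list of `phantom_spec`s (or `ground_truth`s), aligned with
#'   `reports` by `volume_id`.
#' @return List with `sensitivity`, `specificity`, `n_tp`, `n_fp`, `n_tn`,
#'   `n_fn` and `angle_errors`.
#' @export
detection_metrics <- function(reports, truths) {
  specs <- lapply(truths, function(t) if (inherits(t, "ground_truth")) t$spec else t)
  rid <- vapply(reports, function(r) r$volume_id %||% NA_character_, "")
  tid <- vapply(specs, function(s) s$volume_id %||% NA_character_, "")
  if (anyNA(rid) || anyNA(tid) || !setequal(rid, tid) ||
      anyDuplicated(rid) || anyDuplicated(tid))
    stop("reports and truths do not align by volume_id", call. = FALSE)
  specs <- specs[match(rid, tid)]
  pred <- vapply(reports, function(r) isTRUE(r$has_lcd), logical(1))
  truth <- vapply(specs, function(s) isTRUE(s$has_lcd), logical(1))
  n_tp <- sum(pred & truth); n_fp <- sum(pred & !truth)
  n_tn <- sum(!pred & !truth); n_fn <- sum(!pred & truth)
  angle_errors <- numeric(0)
  tp_idx <- which(pred & truth)
  if (length(tp_idx) > 0) {
    angle_errors <- vapply(tp_idx, function(i) {
      est <- reports[[i]]$regions[[1]]$centroid_angle_deg
      (est - specs[[i]]$lcd_angle_deg + 180) %% 360 - 180
    }, numeric(1))
    names(angle_errors) <- rid[tp_idx]
  }
  list(sensitivity = if (n_tp + n_fn > 0) n_tp / (n_tp + n_fn) else NA_real_,
       specificity = if (n_tn + n_fp > 0) n_tn / (n_tn + n_fp) else NA_real_,
       n_tp = n_tp, n_fp = n_fp, n_tn = n_tn, n_fn = n_fn,
       angle_errors = angle_errors)
}

#' Format a count with its percentage, clinical-report style
#'
#' Percentages are rounded half away from zero to the nearest integer, the
#' rounding under which 12/42 prints as "29%" and 11/12 as "92%".
#'
#' @param k count, `n` denominator.
#' @return Character like `"12 (29%)"`.
#' @export
format_count_pct <- function(k, n) {
  stopifnot(n > 0)
  sprintf("%d (%d%%)", k, round_half_up(100 * k / n))
}

#' Cohort prevalence and location summary of LCD reports
#'
#' Counts eyes with and without detected defects and breaks the positives
#' down by disc quadrant, formatted as in a clinical case series
#' ("12 (29%)", "11 (92%) of 12").
#'
#' @param reports non-empty list of [detect_lcd()] reports.
#' @return A tibble with columns `group`, `count`, `denom`, `formatted`.
#' @export
prevalence_summary <- function(reports) {
  if (length(reports) == 0) stop("no reports to summarize", call. = FALSE)
  n <- length(reports)
  pos <- vapply(reports, function(r) isTRUE(r$has_lcd), logical(1))
  n_pos <- sum(pos)
  rows <- list(
    list(group = "lcd_present", count = n_pos, denom = n,
         formatted = format_count_pct(n_pos, n)),
    list(group = "lcd_absent", count = n - n_pos, denom = n,
         formatted = format_count_pct(n - n_pos, n)))
  if (n_pos > 0) {
    quads <- vapply(reports[pos],
                    function(r) r$regions[[1]]$quadrant, "")
    for (q in c("temporal", "superior", "nasal", "inferior")) {
      k <- sum(quads == q)
      rows <- c(rows, list(list(
        group = paste0("location_", q), count = k, denom = n_pos,
        formatted = paste0(format_count_pct(k, n_pos), " of ", n_pos))))
    }
  }
  tibble::tibble(
    group = vapply(rows, `[[`, "", "group"),
    count = vapply(rows, function(r) as.integer(r$count), 1L),
    denom = vapply(rows, function(r) as.integer(r$denom), 1L),
    formatted = vapply(rows, `[[`, "", "formatted"))
}
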