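#' Per-case signed errors between two measurement methods
#'
#' Joins predicted and ground-truth whole-muscle summaries on case and
#' muscle and computes signed errors, predicted minus ground truth, in
#' percentage points.
#'
#' @param predicted,truth Tibbles as returned by [whole_muscle_ff()] /
#'   [class_derived_ff()] / [binary_ff()] (columns `case_id`, `muscle`,
#'   `mean_ff`).
#' @return Tibble with columns `case_id`, `muscle`, `predicted`, `truth`,
#'   `error`.
#' @export
case_errors <- function(predicted, truth) {
  p <- dplyr::select(predicted, "case_id", "muscle", predicted = "mean_ff")
  t <- dplyr::select(truth, "case_id", "muscle", truth = "mean_ff")
  out <- dplyr::inner_join(p, t, by = c("case_id", "muscle"))
  if (nrow(out) != nrow(p) || nrow(out) != nrow(t))
    stop("unmatched case/muscle pairs between predicted and truth",
         call. = FALSE)
  dplyr::mutate(out, error = .data$predicted - .data$truth)
}

#' Per-muscle error summary between two measurement methods
#'
#' Mean and sample standard deviation (n-1 denominator) of the per-case
#' signed errors from [case_errors()], per muscle; the per-case errors are
#' attached as attribute `"errors"` so the summary is recomputable.
#'
#' @inheritParams case_errors
#' @return Tibble of class `ff_error_summary` with columns `muscle`, `n`,
#'   `mean_error`, `sd_error`, `mean_abs_error`.
#' @export
error_summary <- function(predicted, truth) {
  errs <- case_errors(predicted, truth)
  out <- errs |>
    dplyr::group_by(.data$muscle) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_error = mean(.data$error),
                     sd_error = stats::sd(.data$error),
                     mean_abs_error = mean(abs(.data$error)),
                     .groups = "drop")
  attr(out, "errors") <- errs
  class(out) <- c("ff_error_summary", class(out))
  out
}

#' Wilcoxon signed-rank comparison of paired absolute errors
#'
#' Two-sided Wilcoxon signed-rank test on paired values, used to compare
#' the absolute whole-muscle FF errors of two measurement methods against
#' the same ground truth. Zero differences are dropped (classic Wilcoxon
#' convention); the statistic is the sum of ranks of positive differences
#' `a - b`. For n <= 25 effective pairs the exact null distribution is
#' computed by the generating-function convolution over the (possibly
#' tied, midranked) ranks; for larger n the normal approximation with
#' continuity correction and tie-corrected variance is used.
#'
#' @param abs_errors_a,abs_errors_b Equal-length paired numeric vectors
#'   (n >= 5 pairs).
#' @param exact_max Largest n for which the exact null is enumerated.
#' @return Object of class `ff_method_comparison` with elements
#'   `statistic` (W+), `p.value`, `n` (nonzero pairs), `n_zero`, `method`.
#' @export
compare_methods <- function(abs_errors_a, abs_errors_b, exact_max = 25L) {
  a <- as.numeric(abs_errors_a); b <- as.numeric(abs_errors_b)
  if (length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  if (length(a) < 5L)
    stop("need at least 5 pairs", call. = FALSE)
  d <- a - b
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all pairs tied: no nonzero differences to rank", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact signed-rank"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  structure(
    list(statistic = W, p.value = min(p, 1), n = n, n_zero = n_zero,
         method = method, alternative = "two.sided"),
    class = "ff_method_comparison"
  )
}

# Exact two-sided p for the signed-rank statistic with (mid)ranks r and
# observed W: distribution of W under random signs via polynomial
# convolution on doubled (integer) ranks.
signed_rank_exact_p <- function(r, W) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1L)   # f[w + 1] = P(2W = w)
  f[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(tot + 1L - ri)])
    f <- (f + shifted) / 2
  }
  w2 <- as.integer(round(2 * W))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(tot + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.ff_method_comparison <- function(x, ...) {
  cat("Wilcoxon signed-rank comparison of paired absolute errors\n")
  cat(sprintf("  W+ = %g, n = %d (%d zero pair%s dropped)\n", x$statistic,
              x$n, x$n_zero, if (x$n_zero == 1) "" else "s"))
  cat(sprintf("  two-sided p = %.4g (%s)\n", x$p.value, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ff_method_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value, n = x$n,
                 n_zero = x$n_zero, method = x$method,
                 alternative = x$alternative)
}

#' @export
glance.ff_method_comparison <- function(x, ...) tidy(x)

#' Slice-wise prediction error stratified by ground-truth fat class
#'
#' For every slice and every ground-truth fat class present in it, the
#' error between the slice means of predicted and ground-truth fat
#' fraction over the muscle voxels of that class is computed; classes are
#' then summarised by the mean and sample SD of these slice-wise errors.
#' Classes absent from the volume are reported with `n_slices = 0`.
#'
#' @param predicted_ff,truth_ff [ff_volume()]s on the same grid.
#' @param truth_classes `ff_class_mask` giving each voxel's ground-truth
#'   class.
#' @param mask [seg_mask()].
#' @return Tibble of class `per_class_error` with columns `class`,
#'   `n_slices`, `mean_error`, `sd_error`.
#' @export
per_class_error <- function(predicted_ff, truth_ff, truth_classes, mask) {
  check_same_grid(predicted_ff, mask)
  check_same_grid(truth_ff, mask)
  vox <- muscle_voxels(mask)
  idx <- which(vox, arr.ind = TRUE)
  K <- n_classes(truth_classes$scheme)
  cells <- tibble::tibble(
    slice = idx[, mask$slice_axis],
    class = truth_classes$classes[vox],
    pred = predicted_ff$values[vox],
    truth = truth_ff$values[vox]
  ) |>
    dplyr::group_by(.data$slice, .data$class) |>
    dplyr::summarise(error = mean(.data$pred) - mean(.data$truth),
                     .groups = "drop")
  out <- cells |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_slices = dplyr::n(),
                     mean_error = mean(.data$error),
                     sd_error = stats::sd(.data$error),
                     .groups = "drop") |>
    dplyr::right_join(tibble::tibble(class = 0:(K - 1L)), by = "class") |>
    dplyr::arrange(.data$class) |>
    dplyr::mutate(n_slices = dplyr::coalesce(.data$n_slices, 0L))
  class(out) <- c("per_class_error", class(out))
  out
}

#' Tally Goutallier grades across a cohort
#'
#' Counts per-muscle and total occurrences of each Goutallier grade (0--4)
#' from per-muscle grade records. Grades are clinical inputs (expert
#' consensus readings), not computed from images.
#'
#' @param records Tibble/data frame with columns `muscle` and `grade` (one
#'   row per graded muscle instance).
#' @return Object of class `gg_tally`: tibble with columns `muscle`,
#'   `grade`, `n` on the complete muscle-by-grade grid.
#' @export
gg_tally <- function(records) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("muscle", "grade") %in% names(records)))
  g <- as.integer(records$grade)
  if (nrow(records) && (any(is.na(g)) || any(g < 0L) || any(g > 4L)))
    stop("grades must be integers in 0..4", call. = FALSE)
  out <- tidyr::complete(
    dplyr::count(tibble::tibble(muscle = as.character(records$muscle),
                                grade = g),
                 .data$muscle, .data$grade),
    muscle = rc_muscles, grade = 0:4, fill = list(n = 0L)
  )
  out <- dplyr::filter(out, .data$muscle %in% unique(c(rc_muscles,
                                                       records$muscle)))
  class(out) <- c("gg_tally", class(out))
  out
}

#' Total count per Goutallier grade
#' @param tally A [gg_tally()].
#' @return Tibble with columns `grade`, `n`.
#' @export
gg_totals <- function(tally) {
  tally |>
    dplyr::group_by(.data$grade) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
}

#' Percentage of muscles at or above a Goutallier grade
#' @param tally A [gg_tally()].
#' @param k Grade cut (default 3).
#' @return Percentage on 0--100.
#' @export
gg_percent_at_least <- function(tally, k = 3) {
  100 * sum(tally$n[tally$grade >= k]) / sum(tally$n)
}

#' Published cohort Goutallier grade records
#'
#' The per-muscle Goutallier grade counts of the 99-patient clinical
#' cohort, expanded to one record per graded muscle (396 records). These
#' printed counts are inputs for cohort-summary operations such as
#' [gg_tally()]; they are not derived from images here.
#'
#' @return Tibble with columns `muscle`, `grade` (396 rows).
#' @export
rc_cohort_grades <- function() {
  counts <- tibble::tribble(
    ~muscle, ~g0, ~g1, ~g2, ~g3, ~g4,
    "SSP", 18L, 38L, 32L, 7L, 4L,
    "ISP", 11L, 53L, 33L, 0L, 2L,
    "TM",  53L, 37L,  8L, 0L, 1L,
    "SSC", 34L, 47L, 13L, 1L, 4L
  )
  long <- tidyr::pivot_longer(counts, -"muscle", names_to = "grade",
                              names_prefix = "g", values_to = "n")
  long$grade <- as.integer(long$grade)
  tidyr::uncount(long, .data$n)
}
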