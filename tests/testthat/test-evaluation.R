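meas_tbl <- function(ids, muscle, vals, method = "m") {
  tibble::tibble(case_id = ids, muscle = muscle, method = method,
                 mean_ff = vals, voxel_count = 10L)
}

test_that("error summaries use signed predicted-minus-truth with n-1 SD", {
  truth <- meas_tbl(c("a", "b"), "SSP", c(10, 20))
  perfect <- error_summary(meas_tbl(c("a", "b"), "SSP", c(10, 20)), truth)
  expect_equal(perfect$mean_error, 0)
  expect_equal(perfect$sd_error, 0)

  off <- error_summary(meas_tbl(c("a", "b"), "SSP", c(11, 19)), truth)
  expect_equal(off$mean_error, 0)
  expect_equal(off$sd_error, sqrt(2))

  expect_error(error_summary(meas_tbl("a", "SSP", 10), truth), "unmatched")

  # random cohort vs loop-and-sum oracle
  set.seed(7)
  ids <- sprintf("c%02d", 1:15)
  t2 <- meas_tbl(ids, "ISP", runif(15, 5, 30))
  p2 <- meas_tbl(ids, "ISP", t2$mean_ff + rnorm(15))
  es <- error_summary(p2, t2)
  errs <- p2$mean_ff - t2$mean_ff
  m <- sum(errs) / length(errs)
  s <- sqrt(sum((errs - m)^2) / (length(errs) - 1))
  expect_equal(es$mean_error, m, tolerance = 1e-12)
  expect_equal(es$sd_error, s, tolerance = 1e-12)
  expect_equal(attr(es, "errors")$error, errs)
})

test_that("one-sided dominance yields W = 0 and the minimal exact p", {
  a <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  cmp <- compare_methods(a, a + 5)
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p.value, 2 / 1024)
  # exchanging the samples leaves the two-sided p unchanged
  cmp2 <- compare_methods(a + 5, a)
  expect_equal(cmp2$p.value, cmp$p.value)
})

test_that("zero differences are dropped; all-tied input is an error", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(1, 2, 3, 7, 9, 11)     # three zero pairs
  cmp <- compare_methods(a, b)
  expect_equal(cmp$n, 3)
  expect_equal(cmp$n_zero, 3)
  expect_error(compare_methods(a, a), "all pairs tied")
  expect_error(compare_methods(1:4, 2:5), "at least 5")
  expect_error(compare_methods(1:6, 1:5), "equal length")
})

test_that("exact p agrees with full sign-pattern enumeration for n <= 12", {
  set.seed(8)
  for (n in 5:12) {
    for (rep in 1:3) {
      a <- round(runif(n, 0, 10), 1)
      b <- round(runif(n, 0, 10), 1)
      if (all(a == b)) next
      cmp <- compare_methods(a, b)
      oracle <- oracle_signed_rank_p(a - b)
      expect_equal(cmp$statistic, oracle$statistic)
      expect_equal(cmp$p.value, oracle$p.value, tolerance = 1e-12)
    }
  }
})

test_that("the large-sample branch approximates the exact p", {
  set.seed(9)
  a <- runif(40); b <- runif(40)
  approx <- compare_methods(a, b)                 # n = 40 > 25
  exact <- compare_methods(a, b, exact_max = 40L)
  expect_match(approx$method, "approximation")
  expect_equal(approx$p.value, exact$p.value, tolerance = 0.01)
  w <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                           exact = FALSE, correct = TRUE))
  expect_equal(approx$p.value, unname(w$p.value), tolerance = 1e-9)
})

test_that("per-class errors group slice cells by ground-truth class", {
  ph <- generate_phantom(phantom_spec(
    severity = c(SSP = .9, ISP = .5, SSC = .2, TM = .05), seed = 27))
  cls <- ff_quantize(ph$case$ff, ph$case$mask)
  perfect <- per_class_error(ph$case$ff, ph$case$ff, cls, ph$case$mask)
  present <- perfect[perfect$n_slices > 0, ]
  expect_gt(nrow(present), 1)
  expect_true(all(abs(present$mean_error) < 1e-12))

  shifted_vals <- pmin(ph$case$ff$values + 2, 100)
  stopifnot(all(ph$case$ff$values[muscle_voxels(ph$case$mask)] <= 98))
  shifted <- ff_volume(shifted_vals, ph$case$ff$spacing)
  pce <- per_class_error(shifted, ph$case$ff, cls, ph$case$mask)
  expect_true(all(abs(pce$mean_error[pce$n_slices > 0] - 2) < 1e-12))

  # groupby oracle: recompute one class's slice cells by hand
  pred <- ff_dequantize(cls)
  pce2 <- per_class_error(pred, ph$case$ff, cls, ph$case$mask)
  vox <- muscle_voxels(ph$case$mask)
  idx <- which(vox, arr.ind = TRUE)
  df <- data.frame(slice = idx[, 1], class = cls$classes[vox],
                   p = pred$values[vox], t = ph$case$ff$values[vox])
  for (k in unique(df$class)) {
    cells <- sapply(split(df[df$class == k, ], df$slice[df$class == k]),
                    function(d) mean(d$p) - mean(d$t))
    row <- pce2[pce2$class == k, ]
    expect_equal(row$n_slices, length(cells))
    expect_equal(row$mean_error, mean(cells), tolerance = 1e-9)
    expect_equal(row$sd_error, sd(cells), tolerance = 1e-9)
  }
  # all five classes are reported, absent ones explicitly empty
  expect_equal(pce2$class, 0:4)
})

test_that("Goutallier tallies and derived percentages are consistent", {
  tally <- gg_tally(rc_cohort_grades())
  totals <- gg_totals(tally)
  expect_equal(totals$n, c(116L, 175L, 86L, 8L, 11L))
  expect_equal(sum(tally$n), 396L)
  expect_equal(round(gg_percent_at_least(tally, 3), 1), 4.8)

  empty <- gg_tally(tibble::tibble(muscle = character(),
                                   grade = integer()))
  expect_true(all(empty$n == 0L))
  expect_equal(nrow(empty), 20)

  expect_error(gg_tally(tibble::tibble(muscle = "SSP", grade = 5L)), "0..4")
})
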