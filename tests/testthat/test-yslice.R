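bar_mask <- function(merge_from = 10, n_slices = 16) {
  # scapula: two bars on slices before `merge_from`, merged bar after;
  # humerus at the medial... lateral end chosen so iteration starts at 1
  labels <- array(0L, dim = c(n_slices, 12, 12))
  labels[, 3:10, 3] <- 5L
  labels[seq_len(merge_from - 1), 3:10, 5] <- 5L   # second bar, gap col 4
  labels[merge_from:n_slices, 3:10, 4:5] <- 5L     # merged
  labels[1:2, 1, 5:8] <- 6L                        # humerus at low indices
  seg_mask(labels, c(3.5, 1, 1))
}

test_that("lateral direction is the sign of humerus minus scapula centroid", {
  m <- bar_mask()
  expect_equal(detect_lateral_direction(m), -1L)
  # mirrored along the slice axis
  flipped <- seg_mask(m$labels[dim(m$labels)[1]:1, , ], m$spacing)
  expect_equal(detect_lateral_direction(flipped), 1L)
  # missing bone is an explicit error
  no_hum <- m$labels; no_hum[no_hum == 6L] <- 0L
  expect_error(detect_lateral_direction(seg_mask(no_hum, m$spacing)),
               "humerus")
})

test_that("detect_y_slice finds the first single-component slice", {
  m <- bar_mask(merge_from = 10)
  y <- detect_y_slice(m)
  expect_equal(y$slice_index, 10L)
  expect_equal(y$lateral_direction, -1L)
  expect_equal(unname(y$component_counts[9]), 2L)
  expect_equal(unname(y$component_counts[10]), 1L)

  # single rectangle everywhere: the most lateral non-empty scapula slice
  labels <- array(0L, dim = c(8, 12, 12))
  labels[3:7, 3:9, 3:6] <- 5L
  labels[7:8, 1, 5:8] <- 6L           # lateral at high indices
  y2 <- detect_y_slice(seg_mask(labels, c(3.5, 1, 1)))
  expect_equal(y2$slice_index, 7L)

  # always fragmented: explicit failure
  frag <- array(0L, dim = c(8, 12, 12))
  frag[, 3:9, 3] <- 5L
  frag[, 3:9, 5] <- 5L
  frag[7:8, 1, 8:9] <- 6L
  expect_error(detect_y_slice(seg_mask(frag, c(3.5, 1, 1))),
               "always fragmented")
})

test_that("empty-scapula slices are skipped, not counted as one component", {
  labels <- array(0L, dim = c(8, 12, 12))
  labels[2:6, 3:9, 3] <- 5L                 # scapula absent on slices 7-8
  labels[2, 3:9, 5] <- 5L                   # slice 2 fragmented
  labels[7:8, 1, 5:8] <- 6L                 # lateral end at high indices
  y <- detect_y_slice(seg_mask(labels, c(3.5, 1, 1)))
  expect_true(is.na(y$component_counts[7]) && is.na(y$component_counts[8]))
  expect_equal(y$slice_index, 6L)
})

test_that("result is invariant to relabeling non-scapula structures", {
  ph <- generate_phantom(phantom_spec(seed = 14))
  y1 <- detect_y_slice(ph$case$mask)
  labels <- ph$case$mask$labels
  # permute the four muscle labels
  relabeled <- labels
  relabeled[labels == 1L] <- 4L
  relabeled[labels == 4L] <- 1L
  y2 <- detect_y_slice(seg_mask(relabeled, ph$case$mask$spacing))
  expect_equal(y2$slice_index, y1$slice_index)
  expect_equal(y2$lateral_direction, y1$lateral_direction)
})

test_that("axis reversal maps index i to n+1-i and flips the direction", {
  ph <- generate_phantom(phantom_spec(seed = 15, y_slice_true = 6L))
  m <- ph$case$mask
  n <- dim(m)[1]
  y <- detect_y_slice(m)
  rev_mask <- seg_mask(m$labels[n:1, , ], m$spacing)
  y_rev <- detect_y_slice(rev_mask)
  expect_equal(y_rev$slice_index, n + 1L - y$slice_index)
  expect_equal(y_rev$lateral_direction, -y$lateral_direction)
})

test_that("connected-component labeling agrees with flood fill", {
  set.seed(3)
  for (i in 1:20) {
    sl <- matrix(runif(15 * 15) < 0.35, 15, 15)
    for (conn in c(4, 8)) {
      expect_equal(max(label_components_2d(sl, conn)),
                   flood_fill_components(sl, conn))
    }
  }
  # 4- vs 8-connectivity differ on a diagonal pair
  diag2 <- matrix(FALSE, 3, 3); diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(max(label_components_2d(diag2, 8)), 1)
  expect_equal(max(label_components_2d(diag2, 4)), 2)
})

test_that("a single tiny lateral component is flagged for review", {
  labels <- array(0L, dim = c(8, 12, 12))
  labels[2:6, 3:9, 3:6] <- 5L
  labels[7, 5, 5] <- 5L                 # lone acromion-tip pixel, 1 mm^2
  labels[7:8, 1, 5:8] <- 6L
  y <- detect_y_slice(seg_mask(labels, c(3.5, 1, 1)))
  expect_equal(y$slice_index, 7L)       # the rule fires there, verbatim
  expect_true(y$small_component)
})
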