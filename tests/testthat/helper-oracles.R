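# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (vectorized indexing, igraph, convolution) so they can
# serve as ground truth for the implementation.

# Stack-based flood fill, counting 2D connected components of a logical
# matrix under 4- or 8-connectivity.
flood_fill_components <- function(slice, connectivity = 8) {
  nr <- nrow(slice); nc <- ncol(slice)
  seen <- matrix(FALSE, nr, nc)
  if (connectivity == 8) {
    nb <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  comps <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!slice[r, cc] || seen[r, cc]) next
    comps <- comps + 1L
    stack <- list(c(r, cc))
    seen[r, cc] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            slice[r2, c2] && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  comps
}

# Per-voxel loop over one muscle's voxels: running sum and count.
oracle_muscle_mean <- function(ff_values, labels, code) {
  s <- 0; n <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == code) {
      s <- s + ff_values[i]
      n <- n + 1L
    }
  }
  s / n
}

oracle_binary_ff <- function(ff_values, labels, code, threshold) {
  fat <- 0L; n <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == code) {
      n <- n + 1L
      if (ff_values[i] > threshold) fat <- fat + 1L
    }
  }
  100 * fat / n
}

# Per-slice means along axis 1 (the phantom slice axis) by explicit loop.
oracle_slice_means <- function(ff_values, labels, code) {
  ns <- dim(labels)[1]
  out <- data.frame(slice = integer(0), n = integer(0), mean_ff = numeric(0))
  for (s in seq_len(ns)) {
    vals <- c(); n <- 0L
    for (j in seq_len(dim(labels)[2])) for (k in seq_len(dim(labels)[3])) {
      if (labels[s, j, k] == code) {
        n <- n + 1L
        vals <- c(vals, ff_values[s, j, k])
      }
    }
    if (n > 0)
      out <- rbind(out, data.frame(slice = s, n = n, mean_ff = mean(vals)))
  }
  out
}

# Exhaustive signed-rank null: all 2^n sign patterns on the (mid)ranks.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    pos <- as.logical(bitwAnd(bits, 2^(0:(n - 1))))
    sum(r[pos])
  }, numeric(1))
  p_le <- mean(ws <= W)
  p_ge <- mean(ws >= W)
  list(statistic = W, p.value = min(1, 2 * min(p_le, p_ge)))
}

# Build a minimal case from raw arrays, with every non-mask voxel background.
make_case <- function(ff_values, labels, spacing = c(3.5, 1, 1),
                      t1_values = NULL, case_id = "tiny",
                      slice_axis = 1L) {
  if (is.null(t1_values)) t1_values <- 100 + 2 * ff_values
  shoulder_case(
    case_id,
    t1 = ff_volume(t1_values, spacing, "t1_intensity", slice_axis),
    ff = ff_volume(ff_values, spacing, "fat_fraction_percent", slice_axis),
    mask = seg_mask(labels, spacing, slice_axis = slice_axis)
  )
}

# A tiny deterministic case: one SSP block, scapula and humerus present so
# Y-slice detection works; 8 slices, 12 x 12 in-plane at 1 mm.
tiny_case <- function(ff_fill = 30, spacing = c(3.5, 1, 1)) {
  labels <- array(0L, dim = c(8, 12, 12))
  labels[2:7, 3:10, 3:10] <- 1L          # SSP block: 64 mm^2 per slice
  labels[, 3:10, 1] <- 5L                # scapula bar on every slice
  labels[7:8, 1, 5:8] <- 6L              # humerus at the lateral end
  ff <- array(0, dim = dim(labels))
  ff[labels == 1L] <- ff_fill
  make_case(ff, labels, spacing)
}
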