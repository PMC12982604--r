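#' Voxel-wise fat-class predictors
#'
#' A predictor maps a T1-like volume plus muscle mask to a
#' fat-fraction-class mask. Three reference implementations share one
#' contract:
#'
#' * `oracle`: passes the case's own ground-truth fat-fraction volume
#'   through [ff_quantize()]. Useful to exercise the evaluation chain; it is
#'   the only kind allowed to read ground truth at predict time.
#' * `calibrated_threshold` ([calibrate_threshold()]): per-class cut-points
#'   on z-score-normalized T1 intensity, fitted to maximize per-voxel class
#'   agreement on training cases. A deliberately simple baseline: it is
#'   exactly invertible when T1 is a clean monotone map of fat fraction,
#'   and degrades under coil falloff, which makes intensity alone
#'   non-identifiable.
#' * `mini_cnn` ([train_mini_cnn()]): a small patch-wise convolutional
#'   classifier -- a single-hidden-layer network applied to every 3x3x3
#'   neighbourhood of the z-scored masked T1 plus the voxel's normalized
#'   spatial coordinates, evaluated convolutionally over the volume. The
#'   spatial inputs let it compensate position-dependent signal falloff
#'   that defeats pure thresholding.
#'
#' Prediction is restricted to muscle voxels (inputs are masked); all other
#' voxels carry the sentinel class -1.
#'
#' @param scheme A [class_scheme()].
#' @return An object of class `ff_predictor`.
#' @name ff_predictor
NULL

#' @rdname ff_predictor
#' @export
oracle_predictor <- function(scheme = class_scheme()) {
  structure(list(kind = "oracle", scheme = scheme), class = "ff_predictor")
}

#' @export
print.ff_predictor <- function(x, ...) {
  cat("<ff_predictor> kind:", x$kind, "\n")
  invisible(x)
}

# z-score T1 within the muscle mask; returns the full-volume z array with
# non-muscle voxels set to 0 (masked input convention)
zscore_t1 <- function(t1, mask) {
  vox <- muscle_voxels(mask)
  v <- t1$values[vox]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate T1 data: single intensity value within the muscle mask",
         call. = FALSE)
  z <- array(0, dim = dim(t1$values))
  z[vox] <- (v - mean(v)) / s
  z
}

training_pairs <- function(cases, scheme) {
  purrr::map(cases, function(cs) {
    vox <- muscle_voxels(cs$mask)
    cls <- ff_quantize(cs$ff, cs$mask, scheme)
    list(z = zscore_t1(cs$t1, cs$mask)[vox],
         y = cls$classes[vox])
  })
}

#' Calibrate per-class intensity cut-points
#'
#' Fits the `calibrated_threshold` predictor: voxels of all training cases
#' are z-score normalized within their muscle masks and pooled with their
#' ground-truth classes, then each cut-point between adjacent classes is
#' placed to maximize total per-voxel class agreement. The objective
#' separates per cut-point (the count of correctly classified voxels
#' decomposes into one term per boundary), so each boundary is optimized
#' exactly by a sorted scan; the cut-points are then sorted to enforce
#' monotonicity.
#'
#' @param cases List of [shoulder_case()] training cases.
#' @param scheme A [class_scheme()].
#' @return An `ff_predictor` of kind `calibrated_threshold`.
#' @export
calibrate_threshold <- function(cases, scheme = class_scheme()) {
  stopifnot(length(cases) >= 1L)
  pairs <- training_pairs(cases, scheme)
  z <- unlist(purrr::map(pairs, "z"))
  y <- unlist(purrr::map(pairs, "y"))
  K <- n_classes(scheme)
  cuts <- numeric(K - 1L)
  for (j in seq_len(K - 1L)) {
    lo <- z[y == j - 1L]; hi <- z[y == j]
    if (!length(lo) || !length(hi)) {
      # class absent from training: place the cut at the top of whatever
      # data exists below it so it never misclassifies observed voxels
      cuts[j] <- if (length(lo)) max(lo) else if (length(hi))
        min(hi) - 1e-9 else if (j > 1) cuts[j - 1] else 0
      next
    }
    v <- c(lo, hi)
    w <- c(rep(1, length(lo)), rep(-1, length(hi)))
    o <- order(v)
    v <- v[o]; cum <- cumsum(w[o])
    best <- which.max(cum)
    cuts[j] <- if (cum[best] <= 0) v[1] - 1e-9 else
      if (best < length(v)) (v[best] + v[best + 1]) / 2 else v[best] + 1e-9
  }
  structure(list(kind = "calibrated_threshold", scheme = scheme,
                 cutpoints = sort(cuts)),
            class = "ff_predictor")
}

patch_offsets <- function() {
  as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
}

# feature matrix for the given voxel index matrix (n x 3): 27 patch
# intensities (edge-clamped) + 3 normalized coordinates
patch_features <- function(z, idx, shape) {
  off <- patch_offsets()
  X <- matrix(0, nrow(idx), nrow(off) + 3L)
  for (o in seq_len(nrow(off))) {
    ii <- pmin(pmax(idx[, 1] + off[o, 1], 1L), shape[1])
    jj <- pmin(pmax(idx[, 2] + off[o, 2], 1L), shape[2])
    kk <- pmin(pmax(idx[, 3] + off[o, 3], 1L), shape[3])
    X[, o] <- z[cbind(ii, jj, kk)]
  }
  for (a in 1:3)
    X[, nrow(off) + a] <- (idx[, a] - 0.5) / shape[a]
  X
}

#' Train the patch-wise convolutional class predictor
#'
#' Trains a single-hidden-layer softmax network (via [nnet::nnet()]) on
#' 3x3x3 patches of z-scored masked T1 intensity plus normalized voxel
#' coordinates, sampled from the muscle voxels of the training cases. At
#' predict time the network is applied at every muscle voxel, i.e. slid
#' convolutionally over the masked volume. Deterministic under `seed`
#' (which fixes both the voxel subsample and the initial weights).
#'
#' @param cases List of [shoulder_case()] training cases.
#' @param scheme A [class_scheme()].
#' @param hidden Hidden units.
#' @param maxit Optimizer iterations.
#' @param n_per_case Maximum training voxels sampled per case.
#' @param decay Weight decay.
#' @param seed Integer seed.
#' @return An `ff_predictor` of kind `mini_cnn`.
#' @export
train_mini_cnn <- function(cases, scheme = class_scheme(), hidden = 16L,
                           maxit = 200L, n_per_case = 3000L, decay = 1e-4,
                           seed = 1L) {
  stopifnot(length(cases) >= 1L)
  set.seed(seed)
  K <- n_classes(scheme)
  feats <- list(); targs <- list()
  for (cs in cases) {
    vox <- muscle_voxels(cs$mask)
    idx <- which(vox, arr.ind = TRUE)
    if (nrow(idx) > n_per_case)
      idx <- idx[sample.int(nrow(idx), n_per_case), , drop = FALSE]
    z <- zscore_t1(cs$t1, cs$mask)
    cls <- ff_quantize(cs$ff, cs$mask, scheme)
    feats[[length(feats) + 1L]] <- patch_features(z, idx, dim(cs$mask))
    targs[[length(targs) + 1L]] <- cls$classes[idx]
  }
  X <- do.call(rbind, feats)
  y <- factor(unlist(targs), levels = 0:(K - 1L))
  Y <- nnet::class.ind(y)
  fit <- nnet::nnet(X, Y, size = hidden, softmax = TRUE, maxit = maxit,
                    decay = decay, trace = FALSE, MaxNWts = 5000)
  structure(list(kind = "mini_cnn", scheme = scheme, fit = fit,
                 levels = 0:(K - 1L)),
            class = "ff_predictor")
}

#' Predict a fat-fraction-class mask for a case
#'
#' Applies a fitted predictor to a shoulder case. Only the `oracle` kind
#' reads the case's fat-fraction volume; the others use the masked T1
#' intensities alone.
#'
#' @param object An `ff_predictor`.
#' @param case A [shoulder_case()].
#' @param ... Unused.
#' @return An `ff_class_mask`.
#' @export
predict.ff_predictor <- function(object, case, ...) {
  stopifnot(inherits(case, "shoulder_case"))
  mask <- case$mask
  vox <- muscle_voxels(mask)
  cls <- array(-1L, dim = dim(mask))
  if (object$kind == "oracle") {
    return(ff_quantize(case$ff, mask, object$scheme))
  } else if (object$kind == "calibrated_threshold") {
    z <- zscore_t1(case$t1, mask)
    cls[vox] <- findInterval(z[vox], object$cutpoints)
  } else if (object$kind == "mini_cnn") {
    z <- zscore_t1(case$t1, mask)
    idx <- which(vox, arr.ind = TRUE)
    X <- patch_features(z, idx, dim(mask))
    p <- stats::predict(object$fit, X)
    cls[vox] <- object$levels[max.col(p, ties.method = "first")]
  } else stop("unknown predictor kind: ", object$kind, call. = FALSE)
  new_ff_class_mask(cls, mask$spacing, mask$slice_axis, object$scheme)
}

#' Per-voxel class accuracy of a predictor on a case
#'
#' @param object An `ff_predictor`.
#' @param case A [shoulder_case()] with ground-truth FF.
#' @return Fraction of muscle voxels assigned their ground-truth class.
#' @export
class_accuracy <- function(object, case) {
  truth <- ff_quantize(case$ff, case$mask, object$scheme)
  pred <- predict(object, case)
  vox <- muscle_voxels(case$mask)
  mean(pred$classes[vox] == truth$classes[vox])
}
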