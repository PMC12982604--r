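#' Specification of a synthetic shoulder phantom
#'
#' Defines the geometry, fat-infiltration severity and imaging confounds of
#' a synthetic, co-registered shoulder case with known ground truth. The
#' phantom emulates the features the analysis pipeline depends on:
#'
#' * four disjoint ellipsoid-like rotator cuff muscles spanning a contiguous
#'   slice range, tapering at their ends so the 50 mm^2 slice-area filter is
#'   exercised;
#' * a humerus blob on the lateral side and a scapula on the medial side, so
#'   centroid comparison recovers the lateral direction;
#' * a scapula whose per-slice cross-section has two disjoint 2D components
#'   on every slice strictly lateral of `y_slice_true` and exactly one
#'   component from `y_slice_true` medially (the Y-slice transition);
#' * a spatially structured fat-fraction field: per-muscle base level
#'   monotone in severity, smooth low-frequency variation, and bright fatty
#'   streaks whose number grows with severity;
#' * a T1-like intensity that is a monotone (piecewise-linear) map of fat
#'   fraction, confounded by a smooth coil-distance signal falloff and,
#'   optionally, contrast-agent lesions: low-fat regions rendered at
#'   top-decile T1 intensity.
#'
#' @param shape Grid shape, slice axis first by default.
#' @param spacing Voxel spacing in mm. Slice thickness 3.5 mm matches
#'   clinical sagittal shoulder MRI; the in-plane spacing of 1 mm is the
#'   phantom-scale choice that keeps four > 50 mm^2 muscles representable on
#'   desk-sized grids.
#' @param slice_axis Axis index of the slice stack.
#' @param severity Named per-muscle severity in `[0, 1]`; controls both the
#'   base fat level and the number of fatty streaks. Defaults approximate a
#'   mildly infiltrated cohort (whole-muscle FF near 12--16 %).
#' @param n_streaks Number of candidate fatty streaks per muscle; the first
#'   `round(severity * n_streaks)` are active.
#' @param streak_width_mm In-plane streak width.
#' @param falloff Relative T1 intensity retained at the far edge of the coil
#'   falloff field (1 = no falloff).
#' @param noise_sd Additive Gaussian T1 noise standard deviation.
#' @param contrast_lesions Number of contrast-agent lesions (default 0).
#' @param lesion_radius_mm Lesion radius.
#' @param y_slice_true Ground-truth Y-slice index (scapula connectivity
#'   transition); defaults to the middle slice.
#' @param lateral_direction `+1` if the lateral (humeral) side is at high
#'   slice indices, `-1` otherwise.
#' @param case_id Identifier for the generated case.
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 32L, 32L),
                         spacing = c(3.5, 1, 1),
                         slice_axis = 1L,
                         severity = c(SSP = 0.20, ISP = 0.15,
                                      SSC = 0.18, TM = 0.12),
                         n_streaks = 8L,
                         streak_width_mm = 2,
                         falloff = 0.3,
                         noise_sd = 5,
                         contrast_lesions = 0L,
                         lesion_radius_mm = 3,
                         y_slice_true = NULL,
                         lateral_direction = 1L,
                         case_id = "phantom",
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 4L))
  slice_axis <- as.integer(slice_axis)
  stopifnot(slice_axis %in% 1:3)
  if (is.null(y_slice_true)) y_slice_true <- ceiling(shape[slice_axis] / 2)
  y_slice_true <- as.integer(y_slice_true)
  if (y_slice_true < 1L || y_slice_true > shape[slice_axis])
    stop("y_slice_true outside the slice range", call. = FALSE)
  severity <- severity[rc_muscles]
  if (any(is.na(severity)) || any(severity < 0) || any(severity > 1))
    stop("severity must be named per muscle, each in [0, 1]", call. = FALSE)
  if (falloff < 0 || falloff > 1)
    stop("falloff must be in [0, 1]", call. = FALSE)
  if (!lateral_direction %in% c(-1L, 1L))
    stop("lateral_direction must be +1 or -1", call. = FALSE)
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         slice_axis = slice_axis, severity = severity,
         n_streaks = as.integer(n_streaks),
         streak_width_mm = streak_width_mm, falloff = falloff,
         noise_sd = noise_sd, contrast_lesions = as.integer(contrast_lesions),
         lesion_radius_mm = lesion_radius_mm,
         y_slice_true = y_slice_true,
         lateral_direction = as.integer(lateral_direction),
         case_id = case_id, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Fixed fractional geometry of the phantom, chosen so all structures are
# pairwise disjoint at any raster resolution:
#   scapula columns [0.03, 0.18]; muscles columns >= 0.295; humerus rows
#   [0.02, 0.13] vs muscle rows >= 0.15.
phantom_geometry <- function() {
  list(
    muscle_centers = list(SSP = c(r = 0.33, c = 0.45),
                          ISP = c(r = 0.33, c = 0.80),
                          SSC = c(r = 0.73, c = 0.45),
                          TM  = c(r = 0.73, c = 0.80)),
    muscle_semi = c(r = 0.18, c = 0.155),
    taper = 0.7,                 # in-plane area scale = 1 - taper * t^2
    scapula_rows = c(0.20, 0.80),
    scapula_bar1 = c(0.03, 0.08),
    scapula_bar2 = c(0.13, 0.18),
    humerus_rows = c(0.02, 0.13),
    humerus_cols = c(0.35, 0.60),
    humerus_frac = 0.2           # fraction of slices at the lateral end
  )
}

#' Build the continuous phantom model from a spec
#'
#' Draws every random parameter of the phantom (streak geometry, smooth
#' field phases, lesion placement) once, in an order and count independent
#' of the severity values, and stores them together with the fixed
#' fractional geometry. The model lives in continuous coordinates relative
#' to the physical volume extent, so [render_phantom()] can rasterize the
#' same phantom onto any grid of matching extent -- which is how native
#' dual-resolution renderings for cross-orientation tests are produced.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(spec) {
  geom <- phantom_geometry()
  nS <- spec$shape[spec$slice_axis]
  set.seed(spec$seed)
  slice_jitter <- matrix(stats::runif(8, -0.04, 0.04), nrow = 4)
  smooth_par <- lapply(rc_muscles, function(m) {
    list(freq = matrix(sample(1:3, 6, replace = TRUE), nrow = 2),
         phase = stats::runif(2, 0, 2 * pi))
  })
  names(smooth_par) <- rc_muscles
  streaks <- lapply(rc_muscles, function(m) {
    ctr <- geom$muscle_centers[[m]]
    n <- spec$n_streaks
    list(us = stats::runif(n, 0.25, 0.75),
         ur = ctr[["r"]] + stats::runif(n, -0.6, 0.6) * geom$muscle_semi[["r"]],
         uc = ctr[["c"]] + stats::runif(n, -0.6, 0.6) * geom$muscle_semi[["c"]],
         theta = stats::runif(n, 0, pi),
         halflen = stats::runif(n, 0.06, 0.14),
         halfspan = stats::runif(n, 0.08, 0.2),
         value = stats::runif(n, 70, 95))
  })
  names(streaks) <- rc_muscles
  lesions <- NULL
  if (spec$contrast_lesions > 0L) {
    lesions <- list(
      muscle = sample(rc_muscles, spec$contrast_lesions, replace = TRUE),
      us = stats::runif(spec$contrast_lesions, 0.3, 0.7),
      dr = stats::runif(spec$contrast_lesions, -0.5, 0.5),
      dc = stats::runif(spec$contrast_lesions, -0.5, 0.5),
      ff = stats::runif(spec$contrast_lesions, 5, 12)
    )
  }
  noise_seed <- sample.int(.Machine$integer.max, 1)
  # muscle slice extents as fractions of the slice axis
  extents <- lapply(seq_along(rc_muscles), function(i) {
    c(lo = 0.10 + slice_jitter[i, 1], hi = 0.90 + slice_jitter[i, 2])
  })
  names(extents) <- rc_muscles
  structure(
    list(spec = spec, geom = geom,
         extent_mm = spec$shape * spec$spacing,
         y_frac = (spec$y_slice_true - 0.5) / nS,
         muscle_extents = extents,
         smooth = smooth_par, streaks = streaks, lesions = lesions,
         noise_seed = noise_seed),
    class = "phantom_model"
  )
}

#' Rasterize a phantom model onto a grid
#'
#' @param model A [phantom_model()].
#' @param shape,spacing Target grid; defaults to the spec's grid. The
#'   physical extent `shape * spacing` must match the model's extent within
#'   half a coarse voxel per axis.
#' @param slice_axis Slice axis of the target grid.
#' @return A list with elements `case` (a [shoulder_case()]) and `truth`
#'   (ground-truth record: per-muscle whole-volume FF, Y-slice index for
#'   this grid, lateral direction, per-muscle voxel counts).
#' @export
render_phantom <- function(model, shape = model$spec$shape,
                           spacing = model$spec$spacing,
                           slice_axis = model$spec$slice_axis) {
  spec <- model$spec
  geom <- model$geom
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  ext <- shape * spacing
  if (any(abs(ext - model$extent_mm) > pmax(spacing, model$spec$spacing)))
    stop("target grid extent incompatible with the phantom model",
         call. = FALSE)
  nS <- shape[slice_axis]
  inplane <- setdiff(1:3, slice_axis)
  nR <- shape[inplane[1]]; nC <- shape[inplane[2]]
  extR <- ext[inplane[1]]; extC <- ext[inplane[2]]

  # fractional voxel-centre coordinates, arranged as (slice, row, col) and
  # permuted back to the target axis order at the end
  us <- (seq_len(nS) - 0.5) / nS
  ur <- (seq_len(nR) - 0.5) / nR
  uc <- (seq_len(nC) - 0.5) / nC
  d3 <- c(nS, nR, nC)
  US <- array(us, dim = d3)
  UR <- array(rep(ur, each = nS), dim = d3)
  UC <- array(rep(uc, each = nS * nR), dim = d3)

  y_index <- which.min(abs(us - model$y_frac))
  lat <- spec$lateral_direction
  lateral_of_y <- if (lat > 0) US > us[y_index] else US < us[y_index]

  labels <- array(0L, dim = d3)

  # scapula: rows band; two bars lateral of the Y-slice, one bar medially
  in_rows <- UR >= geom$scapula_rows[1] & UR < geom$scapula_rows[2]
  bar1 <- UC >= geom$scapula_bar1[1] & UC < geom$scapula_bar1[2]
  bar2 <- UC >= geom$scapula_bar2[1] & UC < geom$scapula_bar2[2]
  gap  <- UC >= geom$scapula_bar1[2] & UC < geom$scapula_bar2[1]
  scap <- in_rows & ((bar1 | bar2) | (!lateral_of_y & gap))
  # rasterization feasibility: both bars and the gap must contain at least
  # one column, and the row band at least one row, else the connectivity
  # contract cannot hold on this grid
  if (!any(bar1) || !any(bar2) || !any(gap) || !any(in_rows))
    stop("grid too coarse: scapula bars/gap do not rasterize; ",
         "phantom spec geometrically infeasible on this grid", call. = FALSE)
  labels[scap] <- 5L

  # humerus: box on the lateral end of the slice axis
  hum_slices <- if (lat > 0) US > 1 - geom$humerus_frac else
    US < geom$humerus_frac
  hum <- hum_slices &
    UR >= geom$humerus_rows[1] & UR < geom$humerus_rows[2] &
    UC >= geom$humerus_cols[1] & UC < geom$humerus_cols[2]
  if (!any(hum))
    stop("grid too coarse: humerus does not rasterize", call. = FALSE)
  labels[hum] <- 6L

  # muscles: tapered ellipsoids, disjoint from bones by construction
  ff <- array(0, dim = d3)
  regions <- vector("list", 4L); names(regions) <- rc_muscles
  for (i in seq_along(rc_muscles)) {
    m <- rc_muscles[i]
    extent <- model$muscle_extents[[m]]
    ctr <- geom$muscle_centers[[m]]
    usc <- mean(extent); usr <- diff(extent) / 2
    t <- (US - usc) / usr
    rad2 <- ((UR - ctr[["r"]]) / geom$muscle_semi[["r"]])^2 +
      ((UC - ctr[["c"]]) / geom$muscle_semi[["c"]])^2
    reg <- abs(t) <= 1 & rad2 <= 1 - geom$taper * t^2
    if (!any(reg))
      stop("grid too coarse: muscle ", m, " does not rasterize",
           call. = FALSE)
    labels[reg] <- i
    regions[[m]] <- reg

    sev <- spec$severity[[m]]
    base <- 5 + 55 * sev
    sm <- model$smooth[[m]]
    smooth <- 4 * (sin(2 * pi * (sm$freq[1, 1] * UR[reg] +
                                   sm$freq[1, 2] * UC[reg] +
                                   sm$freq[1, 3] * US[reg]) + sm$phase[1]) +
                     sin(2 * pi * (sm$freq[2, 1] * UR[reg] +
                                     sm$freq[2, 2] * UC[reg] +
                                     sm$freq[2, 3] * US[reg]) + sm$phase[2]))
    vals <- pmin(pmax(base + smooth, 0), 100)

    # active fatty streaks: the first round(severity * n) candidates, so a
    # higher severity activates a superset and FF is monotone in severity
    k <- round(sev * spec$n_streaks)
    if (k > 0) {
      st <- model$streaks[[m]]
      pr <- UR[reg] * extR; pc <- UC[reg] * extC
      for (j in seq_len(k)) {
        sus <- extent[["lo"]] + st$us[j] * diff(extent)
        cr <- st$ur[j] * extR; cc <- st$uc[j] * extC
        dirr <- cos(st$theta[j]); dirc <- sin(st$theta[j])
        L <- st$halflen[j] * sqrt(extR * extC)
        # distance to the streak segment in mm
        relr <- pr - cr; relc <- pc - cc
        proj <- pmin(pmax(relr * dirr + relc * dirc, -L), L)
        dist2 <- (relr - proj * dirr)^2 + (relc - proj * dirc)^2
        hit <- dist2 <= (spec$streak_width_mm / 2)^2 &
          abs(US[reg] - sus) <= st$halfspan[j] * usr
        vals[hit] <- pmax(vals[hit], st$value[j])
      }
    }
    ff[reg] <- vals
  }

  # contrast lesions: low fat fraction, later forced to top-decile T1
  lesion_vox <- array(FALSE, dim = d3)
  if (!is.null(model$lesions)) {
    les <- model$lesions
    for (j in seq_along(les$muscle)) {
      m <- les$muscle[j]
      ctr <- geom$muscle_centers[[m]]
      extent <- model$muscle_extents[[m]]
      cs <- (extent[["lo"]] + les$us[j] * diff(extent)) * ext[slice_axis]
      cr <- (ctr[["r"]] + les$dr[j] * geom$muscle_semi[["r"]]) * extR
      cc <- (ctr[["c"]] + les$dc[j] * geom$muscle_semi[["c"]]) * extC
      blob <- regions[[m]] &
        ((US * ext[slice_axis] - cs)^2 + (UR * extR - cr)^2 +
           (UC * extC - cc)^2) <= spec$lesion_radius_mm^2
      ff[blob] <- les$ff[j]
      lesion_vox <- lesion_vox | blob
    }
  }

  # T1: monotone piecewise-linear map of FF inside muscle, bone and
  # background plateaus outside; lesions take top-decile intensity; the
  # whole field is attenuated by a smooth coil falloff and noised
  any_muscle <- labels >= 1L & labels <= 4L
  t1 <- array(30, dim = d3)
  t1[labels == 5L | labels == 6L] <- 220
  t1[any_muscle] <- 100 + 2 * ff[any_muscle]
  if (any(lesion_vox))
    t1[lesion_vox] <- stats::quantile(t1[any_muscle], 0.95)
  falloff_field <- 1 - (1 - spec$falloff) * UR
  t1 <- t1 * falloff_field
  if (spec$noise_sd > 0) {
    set.seed(model$noise_seed)
    t1 <- t1 + stats::rnorm(length(t1), sd = spec$noise_sd)
  }
  t1 <- pmax(t1, 0)

  # permute (slice, row, col) back to the requested axis order
  perm <- order(c(slice_axis, inplane))
  labels <- aperm(labels, perm)
  ff <- aperm(ff, perm)
  t1 <- array(aperm(t1, perm), dim = shape)

  mask <- seg_mask(labels, spacing, slice_axis = slice_axis)
  case <- shoulder_case(
    spec$case_id,
    t1 = ff_volume(t1, spacing, "t1_intensity", slice_axis),
    ff = ff_volume(ff, spacing, "fat_fraction_percent", slice_axis),
    mask = mask
  )
  truth <- list(
    ff_by_muscle = vapply(rc_muscles, function(m)
      mean(ff[aperm(regions[[m]], perm)]), numeric(1)),
    voxels_by_muscle = vapply(rc_muscles, function(m)
      sum(regions[[m]]), numeric(1)),
    y_slice = y_index,
    lateral_direction = lat
  )
  list(case = case, truth = truth)
}

#' Generate a synthetic shoulder phantom
#'
#' Convenience wrapper: builds the continuous model with [phantom_model()]
#' and rasterizes it on the spec's own grid. Deterministic under the spec's
#' seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `case` (a [shoulder_case()]) and `truth` (per-muscle
#'   whole-volume FF, Y-slice index, lateral direction).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  render_phantom(phantom_model(spec))
}

#' Generate a phantom cohort with severities spanning all fat classes
#'
#' Draws per-case, per-muscle severities uniformly on a configurable range
#' (default the full `[0, 1]`, which spans whole-muscle base fat levels from
#' 5 to 60 % plus streaks, so all five fat classes occur across a cohort of
#' moderate size) and generates one phantom per case.
#'
#' @param n_cases Number of phantoms.
#' @param seed Cohort seed; case `i` uses `seed + i`.
#' @param severity_range Range severities are drawn from.
#' @param ... Passed to [phantom_spec()] (e.g. `shape`, `noise_sd`).
#' @return A list of `n_cases` elements, each a list with `case` and
#'   `truth` as from [generate_phantom()].
#' @export
generate_cohort <- function(n_cases, seed = 1L, severity_range = c(0, 1),
                            ...) {
  set.seed(seed)
  sev <- matrix(stats::runif(4 * n_cases, severity_range[1],
                             severity_range[2]),
                ncol = 4, dimnames = list(NULL, rc_muscles))
  lapply(seq_len(n_cases), function(i) {
    spec <- phantom_spec(severity = sev[i, ],
                         case_id = sprintf("phantom_%03d", i),
                         seed = seed + i, ...)
    generate_phantom(spec)
  })
}
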