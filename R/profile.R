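#' Slice-wise fat-fraction profile of one muscle
#'
#' For every slice where the muscle appears, computes the muscle mask area
#' (voxel count times in-plane pixel area), the mean fat fraction over the
#' muscle voxels in that slice, and the signed lateral distance to the
#' Y-slice (`(slice - y_slice) * slice_spacing * lateral_direction`;
#' positive is lateral, negative medial). Slices are marked `included` only
#' when the muscle area is strictly larger than `min_area_mm2` (default
#' 50 mm^2), so thin muscle tips do not contribute unstable means.
#'
#' @param ff [ff_volume()] of kind `fat_fraction_percent`.
#' @param mask [seg_mask()] on the same grid.
#' @param muscle One muscle role.
#' @param y A `y_slice_result` from [detect_y_slice()].
#' @param min_area_mm2 Strict area inclusion threshold (mm^2).
#' @param case_id Identifier copied into the output.
#' @return Tibble of class `slice_profile` with columns `case_id`,
#'   `muscle`, `slice`, `distance_mm`, `area_mm2`, `mean_ff`, `included`.
#' @export
slice_profile <- function(ff, mask, muscle, y, min_area_mm2 = 50,
                          case_id = NA_character_) {
  stopifnot(inherits(ff, "ff_volume"), ff$value_kind == "fat_fraction_percent",
            inherits(y, "y_slice_result"))
  check_same_grid(ff, mask)
  muscle <- match.arg(muscle, rc_muscles)
  vox <- role_voxels(mask, muscle)
  if (!any(vox))
    stop("muscle ", muscle, " is empty on all slices", call. = FALSE)
  axis <- mask$slice_axis
  parea <- pixel_area(mask)
  sp <- mask$spacing[axis]
  rows <- purrr::map_dfr(slice_indices(mask), function(i) {
    sl <- get_slice(vox, axis, i)
    n <- sum(sl)
    if (n == 0L) return(NULL)
    tibble::tibble(
      case_id = case_id, muscle = muscle, slice = i,
      distance_mm = (i - y$slice_index) * sp * y$lateral_direction,
      area_mm2 = n * parea,
      mean_ff = mean(get_slice(ff$values, axis, i)[sl]),
      included = n * parea > min_area_mm2
    )
  })
  class(rows) <- c("slice_profile", class(rows))
  rows
}

#' Resample a slice profile onto a uniform distance grid
#'
#' Linearly interpolates the (distance, mean FF) pairs of the included
#' slices onto a uniform grid with `step`-mm spacing anchored at 0 (the
#' Y-slice). The grid covers only the included extent of the profile: no
#' extrapolation.
#'
#' @param profile A [slice_profile()].
#' @param step Grid step in mm (default 5).
#' @return Tibble of class `resampled_profile` with columns `case_id`,
#'   `muscle`, `distance_mm`, `mean_ff`.
#' @export
resample_profile <- function(profile, step = 5) {
  inc <- profile[profile$included, , drop = FALSE]
  if (nrow(inc) < 2L)
    stop("need at least 2 included slices to resample", call. = FALSE)
  inc <- inc[order(inc$distance_mm), ]
  grid <- step * seq(ceiling(min(inc$distance_mm) / step),
                     floor(max(inc$distance_mm) / step))
  out <- tibble::tibble(
    case_id = inc$case_id[1], muscle = inc$muscle[1],
    distance_mm = grid,
    mean_ff = stats::approx(inc$distance_mm, inc$mean_ff, xout = grid,
                            method = "linear", rule = 1)$y
  )
  class(out) <- c("resampled_profile", class(out))
  out
}

#' Aggregate resampled profiles across a cohort
#'
#' At every grid position with at least `min_n` contributing cases, the
#' across-case sample mean and standard deviation (n-1 denominator) of the
#' slice-wise fat fraction are reported, per muscle. Positions covered by
#' fewer cases are dropped, so cohort curves are only drawn where they are
#' supported (the cohort analyses use 20 of 24 cases as the cut).
#'
#' @param profiles A list of [resample_profile()] results, or one tibble of
#'   their rows.
#' @param min_n Minimum number of contributing cases per position.
#' @return Tibble of class `cohort_profile` with columns `muscle`,
#'   `distance_mm`, `n`, `mean_ff`, `sd_ff`.
#' @export
aggregate_cohort <- function(profiles, min_n = 20) {
  tbl <- if (is.data.frame(profiles)) profiles else dplyr::bind_rows(profiles)
  if (!nrow(tbl)) {
    out <- tibble::tibble(muscle = character(), distance_mm = numeric(),
                          n = integer(), mean_ff = numeric(),
                          sd_ff = numeric())
  } else {
    out <- tbl |>
      dplyr::group_by(.data$muscle, .data$distance_mm) |>
      dplyr::summarise(n = dplyr::n(),
                       sd_ff = stats::sd(.data$mean_ff),
                       mean_ff = mean(.data$mean_ff),
                       .groups = "drop") |>
      dplyr::filter(.data$n >= min_n) |>
      dplyr::relocate("sd_ff", .after = "mean_ff")
  }
  class(out) <- c("cohort_profile", class(out))
  out
}

#' Resample a coronal case onto the grid of a sagittal case
#'
#' Interpolates the coronal fat-fraction and T1 volumes (trilinear) and the
#' segmentation mask (nearest neighbour) of one subject onto the voxel grid
#' of that subject's sagittal acquisition, so slice-wise analysis can be
#' run on a common grid. Both grids must be axis-aligned and cover the same
#' physical extent within one coarse voxel per axis.
#'
#' @param coronal,sagittal [shoulder_case()] objects for the same subject.
#' @return A [shoulder_case()] on the sagittal grid carrying the resampled
#'   coronal data (orientation `"coronal"`).
#' @export
coronal_to_sagittal <- function(coronal, sagittal) {
  stopifnot(inherits(coronal, "shoulder_case"),
            inherits(sagittal, "shoulder_case"))
  ext_c <- dim(coronal$mask) * coronal$mask$spacing
  ext_s <- dim(sagittal$mask) * sagittal$mask$spacing
  if (any(abs(ext_c - ext_s) >
            pmax(coronal$mask$spacing, sagittal$mask$spacing)))
    stop("incompatible physical extents between coronal and sagittal grids",
         call. = FALSE)
  shape_s <- dim(sagittal$mask)
  sp_s <- sagittal$mask$spacing
  sp_c <- coronal$mask$spacing
  shape_c <- dim(coronal$mask)
  # physical voxel-centre coordinates of the target grid, per axis
  coords <- lapply(1:3, function(a) (seq_len(shape_s[a]) - 0.5) * sp_s[a])
  # FF is a masked field (zeroed outside muscle), so plain interpolation
  # would dilute boundary voxels with background zeros; interpolate
  # FF * support and the support itself, and renormalize where supported
  support <- muscle_voxels(coronal$mask) * 1
  w <- interp_trilinear(support, sp_c, coords)
  ff <- interp_trilinear(coronal$ff$values * support, sp_c, coords)
  ff <- ifelse(w > 1e-6, ff / pmax(w, 1e-6), 0)
  t1 <- interp_trilinear(coronal$t1$values, sp_c, coords)
  labels <- interp_nearest(coronal$mask$labels, sp_c, coords)
  shoulder_case(
    coronal$case_id,
    t1 = ff_volume(t1, sp_s, "t1_intensity", sagittal$t1$slice_axis),
    ff = ff_volume(pmin(pmax(ff, 0), 100), sp_s, "fat_fraction_percent",
                   sagittal$ff$slice_axis),
    mask = seg_mask(labels, sp_s, coronal$mask$label_map,
                    sagittal$mask$slice_axis),
    orientation = "coronal", gg = coronal$gg
  )
}

# Trilinear interpolation of a 3D array (voxel centres at (i-0.5)*spacing)
# at the tensor grid given by `coords` (list of 3 physical coordinate
# vectors). Queries outside the source grid clamp to the edge.
interp_trilinear <- function(arr, spacing, coords) {
  d <- dim(arr)
  ax <- lapply(1:3, function(a) {
    j <- coords[[a]] / spacing[a] + 0.5          # fractional voxel index
    i0 <- pmin(pmax(floor(j), 1), d[a] - 1)
    if (d[a] == 1L) i0 <- rep(1, length(j))
    f <- pmin(pmax(j - i0, 0), 1)
    list(i0 = as.integer(i0),
         i1 = as.integer(pmin(i0 + 1, d[a])), f = f)
  })
  n <- vapply(coords, length, integer(1))
  g <- expand.grid(a = seq_len(n[1]), b = seq_len(n[2]), c = seq_len(n[3]))
  out <- numeric(nrow(g))
  for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
    ia <- if (da) ax[[1]]$i1 else ax[[1]]$i0
    ib <- if (db) ax[[2]]$i1 else ax[[2]]$i0
    ic <- if (dc) ax[[3]]$i1 else ax[[3]]$i0
    wa <- if (da) ax[[1]]$f else 1 - ax[[1]]$f
    wb <- if (db) ax[[2]]$f else 1 - ax[[2]]$f
    wc <- if (dc) ax[[3]]$f else 1 - ax[[3]]$f
    out <- out + wa[g$a] * wb[g$b] * wc[g$c] *
      arr[cbind(ia[g$a], ib[g$b], ic[g$c])]
  }
  array(out, dim = n)
}

interp_nearest <- function(arr, spacing, coords) {
  d <- dim(arr)
  ix <- lapply(1:3, function(a)
    as.integer(pmin(pmax(round(coords[[a]] / spacing[a] + 0.5), 1), d[a])))
  n <- vapply(coords, length, integer(1))
  g <- expand.grid(a = seq_len(n[1]), b = seq_len(n[2]), c = seq_len(n[3]))
  array(arr[cbind(ix[[1]][g$a], ix[[2]][g$b], ix[[3]][g$c])], dim = n)
}
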