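#' Rotator cuff muscle roles
#'
#' The four rotator cuff muscles analysed throughout the package:
#' supraspinatus (SSP), infraspinatus (ISP), subscapularis (SSC) and
#' teres minor (TM).
#'
#' @format Character vector of length four.
#' @export
rc_muscles <- c("SSP", "ISP", "SSC", "TM")

#' Default label map for shoulder segmentation masks
#'
#' Integer codes for each role in a shoulder segmentation mask. Background is
#' always 0; the four muscles, scapula and humerus follow. Foreign data with
#' other conventions can supply their own named vector wherever a
#' `label_map` argument is accepted.
#'
#' @return Named integer vector with one code per role.
#' @export
default_label_map <- function() {
  c(background = 0L, SSP = 1L, ISP = 2L, SSC = 3L, TM = 4L,
    scapula = 5L, humerus = 6L)
}

label_roles <- c("background", "SSP", "ISP", "SSC", "TM", "scapula", "humerus")

#' Construct a 3D image volume
#'
#' A scalar 3D grid with per-axis voxel spacing in millimetres and a declared
#' slice axis (the stack direction along which 2D slices are taken). The
#' volume carries either T1-like intensities or quantitative fat-fraction
#' values on the 0--100 percent scale; fat fractions on the 0--1 scale are
#' rejected rather than silently rescaled.
#'
#' @param values Numeric 3D array.
#' @param spacing Numeric vector of 3 positive voxel spacings (mm).
#' @param value_kind Either `"t1_intensity"` or `"fat_fraction_percent"`.
#' @param slice_axis Axis index (1--3) of the slice stack direction.
#' @return An object of class `ff_volume`.
#' @export
ff_volume <- function(values, spacing,
                      value_kind = c("fat_fraction_percent", "t1_intensity"),
                      slice_axis = 1L) {
  value_kind <- match.arg(value_kind)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  slice_axis <- as.integer(slice_axis)
  if (length(slice_axis) != 1L || slice_axis < 1L || slice_axis > 3L)
    stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume contains non-finite values", call. = FALSE)
  if (value_kind == "fat_fraction_percent") {
    rng <- range(values)
    if (rng[1] < 0 || rng[2] > 100)
      stop("fat-fraction values must lie in [0, 100] percent (got range ",
           signif(rng[1], 4), "..", signif(rng[2], 4), ")", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing,
         slice_axis = slice_axis, value_kind = value_kind),
    class = "ff_volume"
  )
}

#' @export
print.ff_volume <- function(x, ...) {
  cat("<ff_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, slice axis ", x$slice_axis, ", ", x$value_kind, "\n", sep = "")
  invisible(x)
}

#' @export
dim.ff_volume <- function(x) dim(x$values)

#' Construct a segmentation mask
#'
#' An integer label volume on the same grid as its paired image volumes,
#' distinguishing the four rotator cuff muscles, scapula, humerus and
#' background. Every voxel code must appear in `label_map` and each role has
#' exactly one code.
#'
#' @param labels Integer 3D array of label codes.
#' @param spacing Numeric vector of 3 positive voxel spacings (mm).
#' @param label_map Named integer vector mapping roles to codes; see
#'   [default_label_map()].
#' @param slice_axis Axis index (1--3) of the slice stack direction.
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(labels, spacing, label_map = default_label_map(),
                     slice_axis = 1L) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  slice_axis <- as.integer(slice_axis)
  if (length(slice_axis) != 1L || slice_axis < 1L || slice_axis > 3L)
    stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  label_map <- validate_label_map(label_map)
  codes <- sort(unique(as.vector(labels)))
  unknown <- setdiff(codes, unname(label_map))
  if (length(unknown))
    stop("mask contains label code(s) absent from label_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(
    list(labels = labels, spacing = spacing,
         slice_axis = slice_axis, label_map = label_map),
    class = "seg_mask"
  )
}

validate_label_map <- function(label_map) {
  label_map <- vapply(label_map, as.integer, integer(1))
  if (!setequal(names(label_map), label_roles))
    stop("label_map must name exactly the roles: ",
         paste(label_roles, collapse = ", "), call. = FALSE)
  if (anyDuplicated(label_map))
    stop("label_map codes must be unique", call. = FALSE)
  if (label_map[["background"]] != 0L)
    stop("background code must be 0", call. = FALSE)
  label_map[label_roles]
}

#' @export
print.seg_mask <- function(x, ...) {
  cat("<seg_mask> ", paste(dim(x$labels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, slice axis ", x$slice_axis, "\n", sep = "")
  counts <- table(factor(x$labels, levels = unname(x$label_map),
                         labels = names(x$label_map)))
  cat("  ", paste(names(counts), counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.seg_mask <- function(x) dim(x$labels)

#' Look up the integer code of a role in a mask
#' @param mask A [seg_mask()].
#' @param role One of the roles in the mask's label map.
#' @return Integer code.
#' @export
label_code <- function(mask, role) {
  if (!role %in% names(mask$label_map))
    stop("unknown role: ", role, call. = FALSE)
  unname(mask$label_map[[role]])
}

#' Logical array of voxels carrying a given role's label
#' @inheritParams label_code
#' @return Logical array with the mask's dimensions.
#' @export
role_voxels <- function(mask, role) {
  mask$labels == label_code(mask, role)
}

#' Logical array of voxels in the union of the four muscle labels
#' @param mask A [seg_mask()].
#' @return Logical array with the mask's dimensions.
#' @export
muscle_voxels <- function(mask) {
  codes <- unname(mask$label_map[rc_muscles])
  array(mask$labels %in% codes, dim = dim(mask$labels))
}

check_same_grid <- function(vol, mask, tol = 1e-3) {
  if (!identical(dim(vol)[1:3], dim(mask)[1:3]))
    stop("grid shape mismatch: ", paste(dim(vol), collapse = "x"), " vs ",
         paste(dim(mask), collapse = "x"), call. = FALSE)
  if (max(abs(vol$spacing - mask$spacing)) > tol)
    stop("voxel spacing mismatch beyond ", tol, " mm", call. = FALSE)
  invisible(TRUE)
}

#' Zero out all voxels outside the rotator cuff muscles
#'
#' Packaging step applied before feeding volumes to the predictor or writing
#' masked images: voxels outside the union of the four muscle labels are set
#' to zero, voxels inside are unchanged. The segmentation mask remains the
#' authority for muscle membership downstream -- a muscle voxel whose fat
#' fraction happens to be 0 still counts in every mean.
#'
#' @param vol An [ff_volume()] (T1 or fat fraction).
#' @param mask A [seg_mask()] on the same grid.
#' @return An [ff_volume()] with non-muscle voxels zeroed.
#' @export
mask_to_muscle <- function(vol, mask) {
  check_same_grid(vol, mask)
  values <- vol$values
  values[!muscle_voxels(mask)] <- 0
  ff_volume(values, vol$spacing, value_kind = vol$value_kind,
            slice_axis = vol$slice_axis)
}

#' Bundle co-registered volumes into a shoulder case
#'
#' A case holds the co-registered T1-like volume, the quantitative
#' fat-fraction volume, the segmentation mask, the acquisition orientation,
#' and (optionally) per-muscle Goutallier grades. All three grids must share
#' shape and spacing.
#'
#' @param case_id Character identifier.
#' @param t1 [ff_volume()] with `value_kind = "t1_intensity"`.
#' @param ff [ff_volume()] with `value_kind = "fat_fraction_percent"`.
#' @param mask [seg_mask()] on the same grid.
#' @param orientation `"sagittal"` or `"coronal"`.
#' @param gg Optional named integer vector of Goutallier grades (0--4), one
#'   per muscle in [rc_muscles].
#' @return An object of class `shoulder_case`.
#' @export
shoulder_case <- function(case_id, t1, ff, mask,
                          orientation = c("sagittal", "coronal"), gg = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(t1, "ff_volume"), inherits(ff, "ff_volume"),
            inherits(mask, "seg_mask"))
  if (t1$value_kind != "t1_intensity")
    stop("`t1` must have value_kind t1_intensity", call. = FALSE)
  if (ff$value_kind != "fat_fraction_percent")
    stop("`ff` must have value_kind fat_fraction_percent", call. = FALSE)
  check_same_grid(t1, mask)
  check_same_grid(ff, mask)
  if (t1$slice_axis != ff$slice_axis || t1$slice_axis != mask$slice_axis)
    stop("slice_axis differs between volumes", call. = FALSE)
  if (!is.null(gg)) {
    gg <- vapply(gg, as.integer, integer(1))
    if (!all(names(gg) %in% rc_muscles) || any(gg < 0L) || any(gg > 4L))
      stop("`gg` must be named by muscle with integer grades in 0..4",
           call. = FALSE)
  }
  structure(
    list(case_id = as.character(case_id), t1 = t1, ff = ff, mask = mask,
         orientation = orientation, gg = gg),
    class = "shoulder_case"
  )
}

#' @export
print.shoulder_case <- function(x, ...) {
  cat("<shoulder_case> ", x$case_id, " (", x$orientation, "), ",
      paste(dim(x$mask), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

slice_indices <- function(x) seq_len(dim(x)[x$slice_axis])

# Extract slice i (a matrix) orthogonal to `axis` from a 3D array.
get_slice <- function(arr, axis, i) {
  switch(axis,
         arr[i, , , drop = TRUE],
         arr[, i, , drop = TRUE],
         arr[, , i, drop = TRUE])
}

# In-plane pixel area in mm^2 (product of the two non-slice spacings).
pixel_area <- function(x) prod(x$spacing[-x$slice_axis])
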