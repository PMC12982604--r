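muscle_summary <- function(case_id, muscle, method, mean_ff, voxel_count) {
  tibble::tibble(case_id = case_id, muscle = muscle, method = method,
                 mean_ff = mean_ff, voxel_count = as.integer(voxel_count))
}

resolve_muscles <- function(muscle) {
  if (is.null(muscle)) rc_muscles else {
    bad <- setdiff(muscle, rc_muscles)
    if (length(bad))
      stop("unknown muscle(s): ", paste(bad, collapse = ", "), call. = FALSE)
    muscle
  }
}

#' Whole-muscle quantitative fat fraction
#'
#' The mean fat fraction over all voxels carrying a muscle's label --- the
#' reference whole-volume measure. Membership comes from the segmentation
#' mask alone, so muscle voxels with 0 % fat count toward the mean.
#'
#' @param ff [ff_volume()] of kind `fat_fraction_percent`.
#' @param mask [seg_mask()] on the same grid.
#' @param muscle Muscle role(s); default all four rotator cuff muscles.
#' @param case_id Identifier copied into the output.
#' @return Tibble with one row per muscle: `case_id`, `muscle`,
#'   `method = "quantitative"`, `mean_ff` (percent), `voxel_count`.
#' @export
whole_muscle_ff <- function(ff, mask, muscle = NULL, case_id = NA_character_) {
  stopifnot(inherits(ff, "ff_volume"), ff$value_kind == "fat_fraction_percent")
  check_same_grid(ff, mask)
  muscles <- resolve_muscles(muscle)
  purrr::map_dfr(muscles, function(m) {
    vox <- role_voxels(mask, m)
    n <- sum(vox)
    if (n == 0L) stop("muscle ", m, " has no voxels", call. = FALSE)
    muscle_summary(case_id, m, "quantitative", mean(ff$values[vox]), n)
  })
}

#' Binary-threshold fat fraction baseline
#'
#' The traditional binary fat/muscle separation: voxels with fat fraction
#' strictly above `threshold` count as 100 % fat, all other muscle voxels as
#' 0 % fat, and the muscle fat fraction is the percentage of fat voxels
#' among the muscle's voxels. With the conventional 40 % threshold this
#' measure structurally underestimates the quantitative mean, because all
#' sub-threshold intramuscular fat is discarded.
#'
#' @inheritParams whole_muscle_ff
#' @param threshold Fat-fraction cut in percent, strict inequality
#'   (default 40).
#' @return Tibble as for [whole_muscle_ff()] with `method = "binary"`.
#' @export
binary_ff <- function(ff, mask, muscle = NULL, threshold = 40,
                      case_id = NA_character_) {
  stopifnot(inherits(ff, "ff_volume"), ff$value_kind == "fat_fraction_percent")
  if (threshold <= 0 || threshold >= 100)
    stop("threshold must be in (0, 100)", call. = FALSE)
  check_same_grid(ff, mask)
  muscles <- resolve_muscles(muscle)
  purrr::map_dfr(muscles, function(m) {
    vox <- role_voxels(mask, m)
    n <- sum(vox)
    if (n == 0L) stop("muscle ", m, " has no voxels", call. = FALSE)
    fat <- sum(ff$values[vox] > threshold)
    muscle_summary(case_id, m, "binary", 100 * fat / n, n)
  })
}

#' Class-derived whole-muscle fat fraction
#'
#' The muscle mean of the per-voxel representative fat fractions of a
#' fat-fraction-class mask --- the quantitative measure recovered from a
#' (predicted or ground-truth) class mask.
#'
#' @param classes An `ff_class_mask`.
#' @param mask [seg_mask()] on the same grid.
#' @param muscle Muscle role(s); default all four.
#' @param scheme Scheme supplying representatives; defaults to the mask's.
#' @param case_id Identifier copied into the output.
#' @return Tibble as for [whole_muscle_ff()] with `method = "class_derived"`.
#' @export
class_derived_ff <- function(classes, mask, muscle = NULL,
                             scheme = classes$scheme,
                             case_id = NA_character_) {
  stopifnot(inherits(classes, "ff_class_mask"))
  if (!identical(dim(classes), dim(mask)))
    stop("grid shape mismatch", call. = FALSE)
  muscles <- resolve_muscles(muscle)
  purrr::map_dfr(muscles, function(m) {
    vox <- role_voxels(mask, m)
    n <- sum(vox)
    if (n == 0L) stop("muscle ", m, " has no voxels", call. = FALSE)
    cls <- classes$classes[vox]
    if (any(cls < 0L))
      stop("sentinel class inside muscle ", m, call. = FALSE)
    muscle_summary(case_id, m, "class_derived",
                   mean(scheme$representatives[cls + 1L]), n)
  })
}

#' Measure one case with all three whole-muscle methods
#'
#' @param case A [shoulder_case()].
#' @param methods Subset of `"quantitative"`, `"binary"`, `"class_derived"`.
#' @param classes Class mask for the class-derived method; defaults to the
#'   ground-truth quantization of the case's own FF volume.
#' @param scheme [class_scheme()] used when quantizing.
#' @param threshold Binary threshold in percent.
#' @return Tibble with one row per muscle and method.
#' @export
measure_case <- function(case,
                         methods = c("quantitative", "binary",
                                     "class_derived"),
                         classes = NULL, scheme = class_scheme(),
                         threshold = 40) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- list()
  if ("quantitative" %in% methods)
    out$q <- whole_muscle_ff(case$ff, case$mask, case_id = case$case_id)
  if ("binary" %in% methods)
    out$b <- binary_ff(case$ff, case$mask, threshold = threshold,
                       case_id = case$case_id)
  if ("class_derived" %in% methods) {
    if (is.null(classes))
      classes <- ff_quantize(case$ff, case$mask, scheme)
    out$c <- class_derived_ff(classes, case$mask, case_id = case$case_id)
  }
  dplyr::bind_rows(out)
}
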