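#' Read one co-registered shoulder case from NIfTI files
#'
#' Reads the T1-like intensity volume, the quantitative fat-fraction volume
#' (0--100 percent) and the integer segmentation mask, validates that the
#' three grids share shape and spacing (tolerance 1e-3 mm), and returns a
#' [shoulder_case()]. Grids must be axis-aligned: a NIfTI orientation matrix
#' whose rotation part is not a signed axis permutation is rejected, since
#' resampling between oblique orientations is out of scope.
#'
#' @param t1_path,ff_path,mask_path Paths to `.nii` / `.nii.gz` files.
#' @param case_id Identifier; defaults to the T1 file name stem.
#' @param label_map Named integer role-to-code map, see [default_label_map()].
#' @param orientation `"sagittal"` or `"coronal"`.
#' @param slice_axis Axis index (1--3) of the slice stack direction.
#' @param gg Optional named per-muscle Goutallier grades (0--4).
#' @return A [shoulder_case()].
#' @export
read_case <- function(t1_path, ff_path, mask_path,
                      case_id = NULL, label_map = default_label_map(),
                      orientation = c("sagittal", "coronal"),
                      slice_axis = 1L, gg = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(t1_path))
  t1r <- read_nifti_grid(t1_path)
  ffr <- read_nifti_grid(ff_path)
  mkr <- read_nifti_grid(mask_path)
  t1 <- ff_volume(t1r$values, t1r$spacing, "t1_intensity", slice_axis)
  ff <- ff_volume(ffr$values, ffr$spacing, "fat_fraction_percent", slice_axis)
  mask <- seg_mask(round(mkr$values), mkr$spacing, label_map, slice_axis)
  shoulder_case(case_id, t1, ff, mask, orientation, gg)
}

read_nifti_grid <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(path, ": expected a 3D volume, got ", length(d), " dimensions",
         call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  check_axis_aligned(img, path)
  list(values = array(as.numeric(img), dim = d), spacing = spacing)
}

# Reject volumes whose orientation matrix is not a signed axis permutation
# (up to voxel scaling): the package treats grids as pre-registered and
# axis-aligned, and does no oblique resampling.
check_axis_aligned <- function(img, path, tol = 1e-3) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error")) return(invisible(TRUE))
  rot <- xf[1:3, 1:3]
  sp <- RNifti::pixdim(img)[1:3]
  perm <- abs(rot) %*% diag(1 / sp)
  ok <- all(abs(perm[perm > 0.5] - 1) < tol) &&
    all(perm[perm <= 0.5] < tol) &&
    all(colSums(perm > 0.5) == 1) && all(rowSums(perm > 0.5) == 1)
  if (!ok)
    stop(path, ": orientation matrix is not an axis permutation; ",
         "oblique grids are not supported", call. = FALSE)
  invisible(TRUE)
}

#' Write a shoulder case to NIfTI files
#'
#' Writes `t1.nii.gz`, `ff.nii.gz` and `mask.nii.gz` into `dir`, plus a
#' `case.json` sidecar holding the case id, orientation, label map, slice
#' axis and any Goutallier grades. Masks are written as 32-bit integers so
#' label codes round-trip bit for bit.
#'
#' @param case A [shoulder_case()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(t1 = file.path(dir, "t1.nii.gz"),
             ff = file.path(dir, "ff.nii.gz"),
             mask = file.path(dir, "mask.nii.gz"),
             meta = file.path(dir, "case.json"))
  write_volume_nifti(case$t1$values, case$t1$spacing, paths[["t1"]])
  write_volume_nifti(case$ff$values, case$ff$spacing, paths[["ff"]])
  write_volume_nifti(case$mask$labels, case$mask$spacing, paths[["mask"]],
                     datatype = "int32")
  meta <- list(case_id = case$case_id, orientation = case$orientation,
               slice_axis = case$mask$slice_axis,
               label_map = as.list(case$mask$label_map))
  if (!is.null(case$gg)) meta$gg <- as.list(case$gg)
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

write_volume_nifti <- function(values, spacing, path, datatype = "auto") {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read back a case written by [write_case()]
#' @param dir Directory holding `t1.nii.gz`, `ff.nii.gz`, `mask.nii.gz` and
#'   `case.json`.
#' @return A [shoulder_case()].
#' @export
read_case_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "case.json"))
  gg <- if (!is.null(meta$gg)) unlist(meta$gg) else NULL
  read_case(file.path(dir, "t1.nii.gz"), file.path(dir, "ff.nii.gz"),
            file.path(dir, "mask.nii.gz"),
            case_id = meta$case_id,
            label_map = unlist(meta$label_map),
            orientation = meta$orientation,
            slice_axis = as.integer(meta$slice_axis), gg = gg)
}
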