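#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable constant of the analysis with its conventional
#' default: the five-class boundaries 15/30/45/60 %, the 40 % binary
#' threshold, the 50 mm^2 slice-area filter, the 5 mm profile resampling
#' step, and the minimum of 20 contributing cases per cohort-profile
#' position.
#'
#' @param n_cases Cohort size to simulate (default 24, the evaluation
#'   cohort size).
#' @param scheme A [class_scheme()].
#' @param binary_threshold Binary fat threshold in percent.
#' @param min_area_mm2 Slice-area filter in mm^2.
#' @param step_mm Profile resampling step in mm.
#' @param min_n Minimum contributing cases per cohort position.
#' @param predictor `"oracle"`, `"calibrated_threshold"` or `"mini_cnn"`.
#' @param n_train Training phantoms for trainable predictors.
#' @param severity_range Range the cohort severities are drawn from.
#' @param shape,spacing Phantom grid.
#' @param seed Master seed; all stage randomness derives from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_cases = 24L, scheme = class_scheme(),
                       binary_threshold = 40, min_area_mm2 = 50,
                       step_mm = 5, min_n = 20L,
                       predictor = c("oracle", "calibrated_threshold",
                                     "mini_cnn"),
                       n_train = 8L, severity_range = c(0, 1),
                       shape = c(16L, 32L, 32L), spacing = c(3.5, 1, 1),
                       seed = 1L) {
  predictor <- match.arg(predictor)
  structure(
    list(n_cases = as.integer(n_cases), scheme = scheme,
         binary_threshold = binary_threshold, min_area_mm2 = min_area_mm2,
         step_mm = step_mm, min_n = as.integer(min_n),
         predictor = predictor, n_train = as.integer(n_train),
         severity_range = severity_range, shape = shape, spacing = spacing,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full phantom-cohort pipeline
#'
#' Orchestrates simulate -> predict/quantize -> measure -> Y-slice ->
#' profile -> cohort -> evaluate on a synthetic cohort: generates
#' `n_cases` phantoms, obtains class masks from the configured predictor,
#' measures each muscle with the quantitative, class-derived and binary
#' methods, detects the Y-slice, builds slice profiles and the cohort
#' profile, and summarises errors of both the class-derived and binary
#' measurements against the quantitative ground truth, including the
#' Wilcoxon signed-rank comparison of their absolute errors. Deterministic
#' under the config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, CSV tables and a
#'   `manifest.json` with MD5 checksums are written there.
#' @return A list with `measurements`, `y_slices`, `profiles` (per-case
#'   resampled), `cohort_profile`, `errors_class`, `errors_binary`,
#'   `comparison` (class `ff_method_comparison`), `per_class`,
#'   and `manifest` (tibble, empty when nothing is written).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$n_cases, seed = config$seed,
                            severity_range = config$severity_range,
                            shape = config$shape, spacing = config$spacing)
  predictor <- switch(
    config$predictor,
    oracle = oracle_predictor(config$scheme),
    calibrated_threshold = ,
    mini_cnn = {
      train <- generate_cohort(config$n_train,
                               seed = config$seed + 10000L,
                               severity_range = config$severity_range,
                               shape = config$shape,
                               spacing = config$spacing)
      train_cases <- purrr::map(train, "case")
      if (config$predictor == "mini_cnn")
        train_mini_cnn(train_cases, config$scheme,
                       seed = config$seed + 20000L)
      else calibrate_threshold(train_cases, config$scheme)
    })

  measurements <- list(); y_slices <- list(); profiles <- list()
  per_class <- list()
  for (ph in cohort) {
    cs <- ph$case
    classes <- withCallingHandlers(
      predict(predictor, cs),
      error = function(e) stop("stage predict failed for case ", cs$case_id,
                               ": ", conditionMessage(e), call. = FALSE))
    measurements[[cs$case_id]] <-
      measure_case(cs, classes = classes, scheme = config$scheme,
                   threshold = config$binary_threshold)
    y <- detect_y_slice(cs$mask)
    y_slices[[cs$case_id]] <- tibble::tibble(
      case_id = cs$case_id, y_slice = y$slice_index,
      lateral_direction = y$lateral_direction,
      y_slice_true = ph$truth$y_slice)
    profiles[[cs$case_id]] <- purrr::map_dfr(rc_muscles, function(m) {
      sp <- slice_profile(cs$ff, cs$mask, m, y,
                          min_area_mm2 = config$min_area_mm2,
                          case_id = cs$case_id)
      resample_profile(sp, step = config$step_mm)
    })
    per_class[[cs$case_id]] <-
      per_class_error(ff_dequantize(classes), cs$ff,
                      ff_quantize(cs$ff, cs$mask, config$scheme), cs$mask) |>
      dplyr::mutate(case_id = cs$case_id)
  }
  measurements <- dplyr::bind_rows(measurements)
  y_slices <- dplyr::bind_rows(y_slices)
  profile_tbl <- dplyr::bind_rows(profiles)
  cohort_prof <- aggregate_cohort(profile_tbl, min_n = config$min_n)
  if (!nrow(cohort_prof))
    warning("cohort profile is empty: fewer than min_n = ", config$min_n,
            " contributing cases at every position", call. = FALSE)

  truth_tbl <- dplyr::filter(measurements, .data$method == "quantitative")
  class_tbl <- dplyr::filter(measurements, .data$method == "class_derived")
  binary_tbl <- dplyr::filter(measurements, .data$method == "binary")
  errors_class <- error_summary(class_tbl, truth_tbl)
  errors_binary <- error_summary(binary_tbl, truth_tbl)
  comparison <- compare_methods(
    abs(attr(errors_class, "errors")$error),
    abs(attr(errors_binary, "errors")$error))

  result <- list(measurements = measurements, y_slices = y_slices,
                 profiles = profile_tbl, cohort_profile = cohort_prof,
                 errors_class = errors_class, errors_binary = errors_binary,
                 comparison = comparison,
                 per_class = dplyr::bind_rows(per_class),
                 manifest = tibble::tibble(file = character(),
                                           md5 = character()))
  if (!is.null(out_dir)) result$manifest <- write_outputs(result, out_dir)
  result
}

write_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(measurements = result$measurements,
                 y_slices = result$y_slices,
                 profiles = result$profiles,
                 cohort_profile = result$cohort_profile,
                 errors_class = result$errors_class,
                 errors_binary = result$errors_binary,
                 per_class = result$per_class,
                 comparison = tidy(result$comparison))
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths[nm] <- p
  }
  manifest <- tibble::tibble(file = basename(paths),
                             md5 = unname(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE)
  manifest
}
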