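# End-to-end orchestration: import -> preprocess -> segment -> postprocess
# -> report.

#' Run the full segmentation pipeline
#'
#' Executes the stages in order: import (unless an already-loaded volume is
#' given), gap check, preprocessing, referential-slice selection,
#' segmentation with the chosen algorithm, and postprocessing. Identical
#' configuration and input give identical output.
#'
#' @param input a DICOM folder path or a [layered_volume()].
#' @param series series number to load when `input` is a folder.
#' @param algo `"rg"` (region growing), `"at"` (adaptive threshold) or
#'   `"ac"` (active contours).
#' @param seed voxel `c(x, y, z)` seeding region growing; `NULL` uses
#'   [auto_seed()] (median-intensity pixel of the referential segment).
#' @param preprocess a [preprocess_config()].
#' @param rg a [region_growing_params()].
#' @param at an [adaptive_threshold_params()].
#' @param gvf a [gvf_params()].
#' @param coeffs an [energy_coefficients()].
#' @param post a [postprocess_params()], or `NULL` to skip postprocessing
#'   and inspect the raw segmentation.
#' @param reference optional reference mask (3D logical array); when given,
#'   a [case_similarity()] report is included.
#' @param verbose log stage progress via `message()`.
#' @return List of class `"PipelineResult"`: `mask` (final
#'   `SegmentationMask`), `raw_mask` (before postprocessing), `z_ref`,
#'   `volume` (the preprocessed [layered_volume()]), `seed` (the voxel used,
#'   region growing only), and `report` (a `SimilarityReport` or `NULL`).
#' @export
run_pipeline <- function(input, series = NULL, algo = c("rg", "at", "ac"),
                         seed = NULL, preprocess = preprocess_config(),
                         rg = region_growing_params(),
                         at = adaptive_threshold_params(),
                         gvf = gvf_params(), coeffs = energy_coefficients(),
                         post = postprocess_params(), reference = NULL,
                         verbose = FALSE) {
  algo <- match.arg(algo)
  say <- function(...) if (verbose) message("[liverseg] ", ...)
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  volume <- if (inherits(input, "LayeredVolume")) input
  else stage("import", check_gaps(load_series(input, series)))
  if (!"preprocessed" %in% names(volume$layers))
    volume <- stage("preprocess", preprocess_volume(volume, preprocess))
  z_ref <- referential_index(volume$z_max, at$referential$z_fraction)
  say("referential slice Z = ", z_ref)

  raw <- switch(algo,
    rg = stage("region growing", {
      if (is.null(seed)) seed <- auto_seed(volume, z_ref, at$referential)
      grow(volume, seed, rg)
    }),
    at = stage("adaptive threshold",
               segment_adaptive_threshold(volume, z_ref, at)),
    ac = stage("active contours",
               segment_active_contours(volume, z_ref, gvf, coeffs, at)))

  final <- if (is.null(post)) raw
  else stage("postprocess", postprocess_volume(raw, z_ref, post))
  report <- if (!is.null(reference))
    stage("validate", case_similarity(final, reference)) else NULL
  structure(list(mask = final, raw_mask = raw, z_ref = z_ref,
                 volume = volume, seed = seed, report = report, algo = algo),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult (%s): %d voxels segmented, z_ref = %d\n",
              x$algo, sum(x$mask), x$z_ref))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}
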