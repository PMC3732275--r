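# Slice-wise similarity validation and grid-search parameter optimization.

#' Slice-wise similarity between two binary masks
#'
#' Zero-shift normalized cross-correlation clamped to `[0, 1]`, with the
#' validation conventions: exactly one empty mask scores 0 (even a few-pixel
#' spurious segment zeroes its slice), both empty score 1.
#'
#' @param a,b logical matrices of identical shape.
#' @return Similarity in `[0, 1]`.
#' @export
slice_similarity <- function(a, b) {
  stop_if_not_mask_pair(a, b)
  ncc_masks(a, b)
}

#' Compare a candidate segmentation against a reference, slice by slice
#'
#' Computes [slice_similarity()] for every slice `1..z_max` (slices where
#' both masks are empty count as 1) and aggregates mean, median and standard
#' deviation over all slices.
#'
#' @param candidate,reference 3D logical arrays of identical geometry.
#' @return A list of class `"SimilarityReport"`: `per_slice` (data frame
#'   with `z`, `similarity`), `mean`, `median`, `std`.
#' @export
case_similarity <- function(candidate, reference) {
  if (!identical(dim(candidate), dim(reference)))
    stop("volume geometries do not match")
  z_max <- dim(candidate)[3]
  sims <- vapply(seq_len(z_max), function(z)
    slice_similarity(candidate[, , z], reference[, , z]), numeric(1))
  structure(list(per_slice = data.frame(z = seq_len(z_max),
                                        similarity = sims),
                 mean = mean(sims), median = stats::median(sims),
                 std = stats::sd(sims)),
            class = "SimilarityReport")
}

#' @export
print.SimilarityReport <- function(x, ...) {
  cat(sprintf(
    "SimilarityReport over %d slices: mean %.3f, median %.3f, std %.3f\n",
    nrow(x$per_slice), x$mean, x$median, x$std))
  invisible(x)
}

#' Exhaustive grid search of segmentation parameters
#'
#' Evaluates `segment_fn` at every point of the parameter grid on every
#' case, scoring each run by the chosen objective (mean or median of the
#' slice similarities against the case's reference). Reports the per-case
#' optima (case-specific parameters, objective `S_C`) and the single grid
#' point maximizing the cross-case mean objective (globally-optimized
#' parameters, `S_G`). Ties break toward the lexicographically first grid
#' point, and results are invariant to case ordering. A segmentation failure
#' at a grid point scores 0 for that case (with a warning).
#'
#' @param cases list of cases, each a list with `volume` (a preprocessed
#'   [layered_volume()]), `reference` (3D logical array), and optionally
#'   extras such as a fixed `seed` that `segment_fn` may use.
#' @param segment_fn `function(volume, params, case)` returning a 3D logical
#'   mask; `params` is one row of the grid as a named list.
#' @param grid named list of parameter value vectors; the grid is their full
#'   cross product, ordered lexicographically (last parameter varying
#'   slowest).
#' @param objective `"mean"` or `"median"` slice similarity.
#' @return A list of class `"GridSearchResult"`: `per_case_best` (data frame
#'   of each case's best grid point and objective `S_C`), `global_best`
#'   (named list of parameters), `global_objective` (`S_G`), and `results`
#'   (the full score table, one row per grid point x case).
#' @export
grid_search <- function(cases, segment_fn, grid,
                        objective = c("mean", "median")) {
  objective <- match.arg(objective)
  stopifnot(length(cases) >= 1, length(grid) >= 1,
            all(lengths(grid) >= 1))
  points <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  n_pts <- nrow(points)
  scores <- matrix(NA_real_, n_pts, length(cases))
  for (p in seq_len(n_pts)) {
    params <- as.list(points[p, , drop = FALSE])
    for (ci in seq_along(cases)) {
      scores[p, ci] <- tryCatch({
        m <- segment_fn(cases[[ci]]$volume, params, cases[[ci]])
        rep_ <- case_similarity(m, cases[[ci]]$reference)
        if (objective == "mean") rep_$mean else rep_$median
      }, error = function(e) {
        warning("grid point ", p, ", case ", ci, " failed: ",
                conditionMessage(e), call. = FALSE)
        0
      })
    }
  }
  per_case_idx <- apply(scores, 2, which.max)  # first max: lexicographic tie
  per_case_best <- cbind(case = seq_along(cases),
                         points[per_case_idx, , drop = FALSE],
                         S_C = scores[cbind(per_case_idx,
                                            seq_along(cases))])
  rownames(per_case_best) <- NULL
  cross_case <- rowMeans(scores)
  g <- which.max(cross_case)
  results <- cbind(points[rep(seq_len(n_pts), times = length(cases)), ,
                          drop = FALSE],
                   case = rep(seq_along(cases), each = n_pts),
                   score = as.vector(scores))
  rownames(results) <- NULL
  structure(list(per_case_best = per_case_best,
                 global_best = as.list(points[g, , drop = FALSE]),
                 global_objective = cross_case[g],
                 global_per_case = scores[g, ],
                 results = results, objective = objective),
            class = "GridSearchResult")
}

#' @export
print.GridSearchResult <- function(x, ...) {
  cat("Grid search (", x$objective, " slice similarity)\n", sep = "")
  cat("Globally-optimized parameters (S_G = ",
      sprintf("%.3f", x$global_objective), "):\n", sep = "")
  utils::str(x$global_best, give.attr = FALSE)
  cat("Per-case optima:\n")
  print(x$per_case_best)
  invisible(x)
}
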