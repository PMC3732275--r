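# Adaptive threshold: per-slice exhaustive threshold sweep maximizing NCC
# to the neighboring already-segmented slice, propagated bidirectionally
# from the referential slice.

#' Adaptive-threshold parameters
#'
#' @param similarity_stop when the best similarity a sweep can reach on a
#'   slice falls below this value (default 0.70), the organ is considered to
#'   have ended: that slice and all further slices in the current direction
#'   are emptied.
#' @param sweep_levels thresholds tried per slice (default 64).
#' @param referential a [referential_config()].
#' @return A list of class `"AdaptiveThresholdParams"`.
#' @export
adaptive_threshold_params <- function(similarity_stop = 0.70,
                                      sweep_levels = 64,
                                      referential = referential_config()) {
  if (similarity_stop <= 0 || similarity_stop >= 1)
    stop("similarity_stop must be in (0, 1)")
  structure(list(similarity_stop = similarity_stop,
                 sweep_levels = as.integer(sweep_levels),
                 referential = referential),
            class = "AdaptiveThresholdParams")
}

#' Threshold sweep against a reference mask
#'
#' Binarizes the slice at `sweep_levels` thresholds spanning its intensity
#' range (cleanup identical to the referential sweep), scores each cleaned
#' mask by NCC against `reference_mask`, and returns the argmax (ties break
#' to the lowest, most inclusive threshold).
#'
#' @param slice preprocessed 2D intensity matrix.
#' @param reference_mask non-empty logical matrix (the neighboring slice's
#'   segmentation).
#' @param sweep_levels number of thresholds.
#' @return List with `threshold`, `similarity`, `mask`. A constant slice
#'   yields similarity 0 and an empty mask.
#' @export
sweep_threshold <- function(slice, reference_mask, sweep_levels = 64) {
  stop_if_not_mask_pair(slice, reference_mask)
  if (!any(reference_mask)) stop("reference_mask is empty")
  res <- threshold_sweep(slice, sweep_levels,
                         function(mask) ncc_masks(mask, reference_mask))
  if (is.null(res))
    return(list(threshold = NA_real_, similarity = 0,
                mask = matrix(FALSE, nrow(slice), ncol(slice))))
  res
}

#' Segment a volume by adaptive thresholding
#'
#' The referential slice is segmented by preset matching
#' ([segment_referential()]); segmentation then propagates forward
#' (`z_ref+1 .. z_max`) and backward (`z_ref-1 .. 1`), each slice swept
#' against its already-segmented neighbor. The two passes are independent.
#' In either direction, once the best attainable similarity drops below
#' `similarity_stop` the organ is deemed ended: the current and all further
#' slices in that direction stay empty (errors of this propagation are
#' cumulative by construction, hence the hard stop).
#'
#' @param volume a preprocessed [layered_volume()].
#' @param z_ref referential slice index (default [referential_index()]).
#' @param params an [adaptive_threshold_params()].
#' @param presets optional preset list for the referential slice.
#' @return 3D logical array of class `"SegmentationMask"`, with attributes
#'   `similarities` (per-slice best NCC, NA where never attempted) and
#'   `z_ref`.
#' @export
segment_adaptive_threshold <- function(volume, z_ref = NULL,
                                       params = adaptive_threshold_params(),
                                       presets = NULL) {
  stopifnot(inherits(volume, "LayeredVolume"))
  if (is.null(z_ref))
    z_ref <- referential_index(volume$z_max, params$referential$z_fraction)
  slices <- get_layer(volume, "preprocessed")
  d <- dim(slices[[1]])
  zmax <- volume$z_max
  mask <- array(FALSE, c(d, zmax))
  sims <- rep(NA_real_, zmax)

  ref <- segment_referential(slices[[z_ref]], presets = presets,
                             cfg = params$referential)
  mask[, , z_ref] <- ref$mask
  sims[z_ref] <- ref$similarity

  propagate <- function(zs) {
    prev <- ref$mask
    for (z in zs) {
      if (!any(prev)) break
      r <- sweep_threshold(slices[[z]], prev, params$sweep_levels)
      sims[z] <<- r$similarity
      if (r$similarity < params$similarity_stop) break  # organ has ended
      mask[, , z] <<- r$mask
      prev <- r$mask
    }
  }
  if (z_ref < zmax) propagate((z_ref + 1):zmax)
  if (z_ref > 1) propagate((z_ref - 1):1)

  structure(mask, class = "SegmentationMask", similarities = sims,
            z_ref = z_ref)
}
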