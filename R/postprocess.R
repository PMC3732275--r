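# Postprocessing: leakage and redundant-segment elimination by morphology
# and per-segment NCC against neighboring slices.

#' Postprocessing parameters
#'
#' @param ncc_threshold a segment on a slice survives only if its NCC
#'   against its template (the segment intersected with the finalized
#'   neighboring slice) strictly exceeds this value (default 0.65).
#' @return A list of class `"PostprocessParams"`.
#' @export
postprocess_params <- function(ncc_threshold = 0.65) {
  if (ncc_threshold <= 0 || ncc_threshold >= 1)
    stop("ncc_threshold must be in (0, 1)")
  structure(list(ncc_threshold = ncc_threshold,
                 structuring_element = disk3()),
            class = "PostprocessParams")
}

#' Keep only the largest connected component of a slice mask
#'
#' Components are labeled with in-plane 4-connectivity (erosion has already
#' cut thin bonds, and 4-connectivity maximizes separation of leakage).
#' Area ties break to the component whose anchor (its smallest `(row, col)`
#' position in lexicographic order) is smallest.
#'
#' @param mask logical matrix.
#' @return Logical matrix with at most one component (empty in, empty out).
#' @export
keep_largest <- function(mask) {
  lab <- label4(mask)
  k <- max(lab)
  if (k <= 1) return(mask & TRUE)
  areas <- tabulate(lab[lab > 0], nbins = k)
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    anchor <- vapply(best, function(b) {
      rc <- which(lab == b, arr.ind = TRUE)
      rc <- rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
      rc[1, 1] * (ncol(mask) + 1) + rc[1, 2]
    }, numeric(1))
    best <- best[which.min(anchor)]
  }
  lab == best
}

#' Filter the segments of one slice against a finalized neighbor
#'
#' For each connected segment `S` on `current_mask`, the comparison template
#' is `S` intersected with the finalized neighboring slice; `S` is kept iff
#' `NCC(S, template) > ncc_threshold`. Comparing per segment (rather than
#' whole slices) lets multiple true segments survive while leakage segments,
#' which have no counterpart on the neighbor, are discarded.
#'
#' @param current_mask logical matrix being filtered.
#' @param neighbor_final finalized neighboring slice mask.
#' @param params a [postprocess_params()].
#' @return Logical matrix: the union of the surviving segments.
#' @export
filter_slice <- function(current_mask, neighbor_final,
                         params = postprocess_params()) {
  stop_if_not_mask_pair(current_mask, neighbor_final)
  lab <- label4(current_mask)
  k <- max(lab)
  if (k == 0) return(current_mask & FALSE)
  out <- matrix(FALSE, nrow(current_mask), ncol(current_mask))
  for (i in seq_len(k)) {
    seg <- lab == i
    template <- seg & neighbor_final
    if (ncc_masks(seg, template) > params$ncc_threshold) out <- out | seg
  }
  out
}

#' Postprocess a segmentation mask volume
#'
#' The full leakage-removal procedure: (1) erode every slice with the 3x3
#' disk (cutting thin bonds to neighboring organs); (2) keep only the
#' largest segment on the referential slice; (3) sweep outward in both Z
#' directions, filtering each slice's segments against its already-finalized
#' inner neighbor with [filter_slice()]; (4) dilate every slice with the 3x3
#' disk. The two directional sweeps are independent of each other.
#'
#' @param mask 3D logical array (`SegmentationMask`).
#' @param z_ref referential slice index.
#' @param params a [postprocess_params()].
#' @return Postprocessed 3D logical `"SegmentationMask"`.
#' @export
postprocess_volume <- function(mask, z_ref, params = postprocess_params()) {
  d <- dim(mask)
  stopifnot(length(d) == 3, z_ref >= 1, z_ref <= d[3])
  se <- params$structuring_element
  slices <- lapply(seq_len(d[3]), function(z)
    matrix(EBImage::erode(mask[, , z] * 1, se) > 0.5, d[1]))
  if (!any(slices[[z_ref]])) {
    warning("referential slice empty after erosion; postprocessing left the ",
            "mask unchanged", call. = FALSE)
    return(structure(mask & TRUE, class = "SegmentationMask", z_ref = z_ref))
  }
  slices[[z_ref]] <- keep_largest(slices[[z_ref]])
  sweep_dir <- function(zs) {
    prev <- slices[[z_ref]]
    for (z in zs) {
      slices[[z]] <<- filter_slice(slices[[z]], prev, params)
      prev <- slices[[z]]
    }
  }
  if (z_ref < d[3]) sweep_dir((z_ref + 1):d[3])
  if (z_ref > 1) sweep_dir((z_ref - 1):1)
  out <- vapply(slices, function(s)
    matrix(EBImage::dilate(s * 1, se) > 0.5, d[1]), matrix(TRUE, d[1], d[2]))
  structure(array(out, d), class = "SegmentationMask", z_ref = z_ref)
}
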