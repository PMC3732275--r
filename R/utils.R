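# Shared helpers: mask similarity, morphology wrappers, RNG scoping.

#' Normalized cross-correlation between two binary masks
#'
#' Zero-shift NCC between two registered binary masks, computed as the Pearson
#' correlation of the mask images. Degenerate cases follow the conventions
#' used throughout the pipeline: both masks empty gives 1, exactly one empty
#' gives 0, and a mask that covers the whole frame (constant, so correlation
#' is undefined) falls back to the Dice overlap.
#'
#' @param a,b logical matrices of identical shape.
#' @return A number in `[0, 1]` (negative correlations are clamped to 0).
#' @export
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:6, 3:6] <- TRUE
#' ncc_masks(m, m)  # 1
ncc_masks <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  ea <- any(a); eb <- any(b)
  if (!ea && !eb) return(1)
  if (xor(ea, eb)) return(0)
  if (all(a) || all(b)) return(dice(a, b))
  r <- stats::cor(as.numeric(a), as.numeric(b))
  if (is.na(r)) return(0)
  max(0, min(1, r))
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b logical arrays of identical shape (2D or 3D).
#' @return `2|a n b| / (|a| + |b|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

# 3x3 disk structuring element used by every morphology step
disk3 <- function() EBImage::makeBrush(3, shape = "disc")

# hole filling + opening used before every mask-vs-mask NCC so that the
# comparison is not dominated by thresholding speckle
clean_mask <- function(mask) {
  m <- EBImage::fillHull(mask * 1)
  m <- EBImage::erode(m, disk3())
  m <- EBImage::dilate(m, disk3())
  matrix(m > 0.5, nrow = nrow(mask))
}

# Evaluate `expr` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# connected-component labels (2D, 4-connectivity)
label4 <- function(mask) label4_cpp(matrix(as.logical(mask), nrow = nrow(mask)))

stop_if_not_mask_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes do not match")
}
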