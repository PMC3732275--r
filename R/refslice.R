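# Referential slice selection and the initial liver segment on it.

#' Referential-slice configuration
#'
#' @param z_fraction fraction of the stack at which the referential slice
#'   sits (default 0.65, found empirically on abdominal MRI: that slice very
#'   likely shows a large liver cross-section).
#' @param size_coefficient scales the target size of the liver presets used
#'   to pick the initial threshold (the knob optimized by [grid_search()] for
#'   the adaptive-threshold algorithm).
#' @param n_presets number of liver-shape presets (default 6).
#' @param sweep_levels number of thresholds tried across the intensity range.
#' @return A list of class `"ReferentialConfig"`.
#' @export
referential_config <- function(z_fraction = 0.65, size_coefficient = 1,
                               n_presets = 6, sweep_levels = 64) {
  stopifnot(z_fraction > 0, z_fraction < 1, size_coefficient > 0,
            sweep_levels >= 2)
  structure(list(z_fraction = z_fraction,
                 size_coefficient = size_coefficient,
                 n_presets = as.integer(n_presets),
                 sweep_levels = as.integer(sweep_levels)),
            class = "ReferentialConfig")
}

#' Index of the referential slice
#'
#' `z_ref = round(z_fraction * z_max)` (half-up), clamped to `[1, z_max]`.
#' For a typical abdominal acquisition this lands on a slice with a large
#' liver cross-section; every segmentation algorithm starts there.
#'
#' @param z_max number of slices (>= 1).
#' @param z_fraction stack fraction, default 0.65.
#' @return Integer slice index.
#' @export
#' @examples
#' referential_index(72)  # 47
referential_index <- function(z_max, z_fraction = 0.65) {
  if (z_max < 1) stop("z_max must be >= 1")
  min(max(as.integer(floor(z_fraction * z_max + 0.5)), 1L), as.integer(z_max))
}

# filled, possibly indented superellipse on a pixel grid
superellipse_mask <- function(height, width, cy, cx, ry, rx, expo, theta,
                              notch = NULL) {
  yy <- matrix(seq_len(height), height, width) - cy
  xx <- matrix(seq_len(width), height, width, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  inside <- (abs(u) / rx)^expo + (abs(v) / ry)^expo <= 1
  if (!is.null(notch)) {
    nu <- u - notch$du; nv <- v - notch$dv
    inside <- inside & (abs(nu) / notch$rx)^2 + (abs(nv) / notch$ry)^2 > 1
  }
  inside
}

#' Generate the liver-shape presets for the referential slice
#'
#' Six deterministic, connected, hole-free binary masks of liver-like
#' cross-sections (ovals, beans and crescents at differing sizes and
#' orientations). Each covers between 5% and 45% of the slice area; the area
#' scales linearly with `size_coefficient` within those caps. These stand in
#' for manually curated liver outlines: only their count, rough shape and
#' size matter, and users can substitute their own cohort-specific masks.
#'
#' @param height,width slice size in pixels (>= 32).
#' @param size_coefficient multiplies each preset's target area.
#' @return List of 6 logical matrices.
#' @export
generate_presets <- function(height, width, size_coefficient = 1) {
  stopifnot(height >= 32, width >= 32, size_coefficient > 0)
  fracs <- pmin(pmax(c(0.09, 0.13, 0.18, 0.24, 0.30, 0.38) *
                       size_coefficient, 0.05), 0.45)
  aspect <- c(1.5, 1.1, 1.8, 1.3, 1.6, 1.2)   # ry/rx
  expo <- c(2, 2.5, 2, 3, 2.5, 2)
  theta <- c(0, 0.4, -0.5, 0.2, -0.3, 0.7)
  notched <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  lapply(seq_len(6), function(i) {
    area <- fracs[i] * height * width
    # exact superellipse area: 4 rx ry Gamma(1+1/p)^2 / Gamma(1+2/p)
    ac <- 4 * gamma(1 + 1 / expo[i])^2 / gamma(1 + 2 / expo[i])
    rx <- sqrt(area / (ac * aspect[i]))
    ry <- rx * aspect[i]
    # if a radius would leave the frame, trade aspect for area so the
    # target area (and hence the size_coefficient scaling) is preserved
    if (ry > height * 0.47) { ry <- height * 0.47; rx <- area / (ac * ry) }
    if (rx > width * 0.47) { rx <- width * 0.47; ry <- area / (ac * rx) }
    notch <- if (notched[i])
      list(du = rx * 0.95, dv = 0, rx = rx * 0.55, ry = ry * 0.75)
    superellipse_mask(height, width, height / 2, width / 2, ry, rx,
                      expo[i], theta[i], notch)
  })
}

# Threshold sweep shared by the referential slice and adaptive threshold:
# binarize at `sweep_levels` thresholds spanning the slice's intensity range
# (keeping pixels >= t), clean the mask (hole fill + 3x3 opening), score it
# with `score_fn`, and return the argmax (ties -> lowest threshold).
threshold_sweep <- function(slice, sweep_levels, score_fn) {
  rng <- range(slice)
  if (diff(rng) == 0) return(NULL)
  thresholds <- seq(rng[1], rng[2], length.out = sweep_levels + 1)[-1]
  best <- list(similarity = -Inf)
  for (t in thresholds) {
    mask <- clean_mask(slice >= t)
    s <- score_fn(mask)
    if (s > best$similarity)
      best <- list(threshold = t, similarity = s, mask = mask)
  }
  best
}

#' Segment the liver on the referential slice by preset matching
#'
#' Sweeps `sweep_levels` thresholds over the slice's intensity range; for
#' each threshold the cleaned binarization is compared by NCC against every
#' preset, and the threshold whose best preset match is maximal wins.
#'
#' @param slice preprocessed 2D intensity matrix.
#' @param presets list of binary masks from [generate_presets()] (defaults to
#'   the built-in six at the slice's size).
#' @param cfg a [referential_config()].
#' @return List with `mask` (logical matrix), `threshold`, `similarity`, and
#'   `preset` (index of the best-matching preset).
#' @export
segment_referential <- function(slice, presets = NULL,
                                cfg = referential_config()) {
  if (is.null(presets))
    presets <- generate_presets(nrow(slice), ncol(slice),
                                cfg$size_coefficient)
  stopifnot(all(vapply(presets, function(p)
    identical(dim(p), dim(slice)), logical(1))))
  best_preset <- NA_integer_
  res <- threshold_sweep(slice, cfg$sweep_levels, function(mask) {
    sims <- vapply(presets, function(p) ncc_masks(mask, p), numeric(1))
    max(sims)
  })
  if (is.null(res)) stop("no structure on referential slice (constant image)")
  sims <- vapply(presets, function(p) ncc_masks(res$mask, p), numeric(1))
  res$preset <- which.max(sims)
  res
}
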