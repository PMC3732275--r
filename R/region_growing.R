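# Seeded 3D region growing with 26-connectivity.

#' Region-growing parameters
#'
#' @param deviation relative intensity tolerance (default 0.20): a neighbor
#'   with intensity `v` is accepted iff `I (1 - deviation) < v <
#'   I (1 + deviation)` (open interval), `I` being the anchor intensity.
#' @param reference_mode what anchors the acceptance interval: `"seed"`
#'   (default; the interval is fixed by the seed intensity, so the grown
#'   region cannot drift) or `"current"` (the interval follows the voxel
#'   being expanded, the literal reading of comparing each neighbor to the
#'   current voxel; results then depend on queue order).
#' @param max_voxels safety cap on the region size; `Inf` disables it.
#' @return A list of class `"RegionGrowingParams"`.
#' @export
region_growing_params <- function(deviation = 0.20,
                                  reference_mode = c("seed", "current"),
                                  max_voxels = Inf) {
  if (deviation <= 0 || deviation >= 1)
    stop("deviation must be in (0, 1)")
  structure(list(deviation = deviation,
                 reference_mode = match.arg(reference_mode),
                 max_voxels = max_voxels),
            class = "RegionGrowingParams")
}

#' Grow a 3D region from a seed voxel
#'
#' Breadth-first expansion from the seed under 26-connectivity: each queued
#' voxel's 26 neighbors are accepted when their intensity falls in the open
#' interval `(I (1 - deviation), I (1 + deviation))`; every voxel is enqueued
#' at most once. The result is a single 26-connected component containing
#' the seed.
#'
#' @param volume preprocessed 3D numeric array `(rows, cols, z)`, or a
#'   [layered_volume()] (its `"preprocessed"` layer is used).
#' @param seed integer voxel `c(x, y, z)` = (column, row, slice).
#' @param params a [region_growing_params()].
#' @return 3D logical array of class `"SegmentationMask"`.
#' @export
#' @examples
#' v <- array(1000, c(8, 8, 4)); v[5:8, , ] <- 2000
#' m <- grow(v, c(1, 1, 1))  # only the 1000-intensity rows
grow <- function(volume, seed, params = region_growing_params()) {
  if (inherits(volume, "LayeredVolume"))
    volume <- get_layer(volume, "preprocessed", as_array = TRUE)
  stopifnot(length(dim(volume)) == 3, length(seed) == 3)
  d <- dim(volume)
  x <- as.integer(seed[1]); y <- as.integer(seed[2]); z <- as.integer(seed[3])
  if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3])
    stop("seed outside volume")
  if (volume[y, x, z] == 0)
    stop("seed lies on zero padding (empty voxel)")
  mask <- region_grow_cpp(volume, d, c(y, x, z) - 1L, params$deviation,
                          if (params$reference_mode == "seed") 0L else 1L,
                          params$max_voxels)
  if (sum(mask) > 0.5 * length(mask))
    warning("region covers more than half the volume; check the seed and ",
            "deviation", call. = FALSE)
  structure(mask, class = "SegmentationMask")
}

#' Automatic seed on the referential slice
#'
#' Segments the referential slice with [segment_referential()] and returns
#' the in-segment pixel whose intensity is nearest the segment's median
#' intensity. Picking the median avoids seeding inside vessels or nodules,
#' whose intensities are outliers within the liver segment. Ties break to
#' the lowest linear (column-major) index, so the choice is deterministic.
#'
#' @param volume a preprocessed [layered_volume()].
#' @param z_ref referential slice index (default from [referential_index()]).
#' @param cfg a [referential_config()].
#' @return Integer voxel `c(x, y, z)`.
#' @export
auto_seed <- function(volume, z_ref = NULL, cfg = referential_config()) {
  stopifnot(inherits(volume, "LayeredVolume"))
  if (is.null(z_ref)) z_ref <- referential_index(volume$z_max, cfg$z_fraction)
  slice <- get_layer(volume, "preprocessed")[[z_ref]]
  seg <- segment_referential(slice, cfg = cfg)
  idx <- which(seg$mask)
  if (!length(idx)) stop("empty referential segment; cannot place a seed")
  vals <- slice[idx]
  med <- stats::median(vals)
  dev <- abs(vals - med)
  tied <- idx[dev == min(dev)]
  # deterministic tie-break: of all median-intensity pixels, take the one
  # nearest the segment centroid (an interior pixel, away from the edge),
  # then the lowest linear index
  rc <- arrayInd(tied, dim(slice))
  ctr <- colMeans(arrayInd(idx, dim(slice)))
  d2 <- (rc[, 1] - ctr[1])^2 + (rc[, 2] - ctr[2])^2
  pick <- rc[order(d2, tied)[1], ]
  c(x = pick[2], y = pick[1], z = z_ref)
}
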