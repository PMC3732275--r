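# Per-slice preprocessing: sigmoid VOI transform, de-biasing, denoising,
# fixed-VOI contrast redistribution. Every stage is stored in its own layer.

#' Sigmoid VOI transformation parameters
#'
#' @param wc window center (intensity units).
#' @param ww window width (intensity units, must be positive).
#' @param output_range maximum output intensity.
#' @return A list of class `"SigmoidParams"`.
#' @export
sigmoid_params <- function(wc, ww, output_range) {
  if (!is.finite(ww) || ww <= 0) stop("window width (ww) must be positive")
  if (output_range <= 0) stop("output_range must be positive")
  structure(list(wc = wc, ww = ww, output_range = output_range),
            class = "SigmoidParams")
}

#' Preprocessing configuration
#'
#' Defaults follow the pipeline's standard settings: a 3x3 average filter
#' followed by a 3x3 Gaussian filter (sigma 0.5), and a fixed VOI of
#' WC = 20000, WW = 100, output range 2^16 that redistributes contrast over
#' the whole 16-bit range so that liver tissue lands in a predictable
#' intensity band regardless of the source range.
#'
#' @param filter_mask_size odd window size of the denoising filters (pixels).
#' @param gaussian_sigma sigma of the Gaussian stage (pixels).
#' @param fixed_voi [sigmoid_params()] of the final contrast redistribution.
#' @param bias_sigma smoothing scale of bias estimation in pixels; `NULL`
#'   means a quarter of the image width.
#' @return A list of class `"PreprocessConfig"`.
#' @export
preprocess_config <- function(filter_mask_size = 3, gaussian_sigma = 0.5,
                              fixed_voi = sigmoid_params(20000, 100, 2^16),
                              bias_sigma = NULL) {
  if (filter_mask_size < 1 || filter_mask_size %% 2 != 1)
    stop("filter_mask_size must be odd and >= 1")
  structure(list(filter_mask_size = as.integer(filter_mask_size),
                 gaussian_sigma = gaussian_sigma, fixed_voi = fixed_voi,
                 bias_sigma = bias_sigma),
            class = "PreprocessConfig")
}

#' Sigmoid VOI transform of an intensity image
#'
#' The DICOM-standard sigmoid value-of-interest mapping
#' `out(x) = output_range / (1 + exp(-4 (x - WC) / WW))`. Small `WW`
#' approximates a step (thresholding at `WC`); `WW` larger than the intensity
#' range approximates a linear rescale. Strictly monotone and bounded in
#' `(0, output_range)`.
#'
#' @param image numeric matrix.
#' @param params a [sigmoid_params()].
#' @return Transformed matrix, same shape.
#' @export
#' @examples
#' sigmoid_transform(matrix(512), sigmoid_params(512, 1, 100))  # midpoint: 50
sigmoid_transform <- function(image, params) {
  if (!inherits(params, "SigmoidParams"))
    params <- do.call(sigmoid_params, as.list(params))
  params$output_range / (1 + exp(-4 * (image - params$wc) / params$ww))
}

#' Reduce smooth multiplicative intensity inhomogeneity
#'
#' Homomorphic bias correction with foreground weighting: the bias field is
#' estimated as a heavily Gaussian-smoothed copy of the slice (scale
#' `bias_sigma`, default a quarter of the image width), where the smoothing
#' average is taken over the bright (tissue) pixels only, so that dark
#' background does not drag the estimate down near organ edges. The field is
#' normalized to unit mean and divided out; the output is rescaled so the
#' slice mean is preserved. MR inhomogeneity in-plane is slowly varying,
#' which is what the large smoothing scale encodes; residual through-slice
#' (Z) inhomogeneity is not addressed here and is handled downstream by the
#' segmentation algorithms' tolerance parameters.
#'
#' @param image non-negative numeric matrix.
#' @param bias_sigma smoothing scale in pixels.
#' @return Corrected matrix with (approximately) the same mean.
#' @export
correct_bias <- function(image, bias_sigma = ncol(image) / 4) {
  if (min(image) < 0) stop("image must be non-negative")
  m0 <- mean(image)
  if (m0 == 0) return(image)
  # bright (tissue) pixels carry the bias signal; half the near-maximum
  # separates tissue from background yet keeps a constant image all-tissue
  w <- (image > 0.5 * stats::quantile(image, 0.99)) * 1
  if (sum(w) < 16) return(image)
  ksize <- 2 * ceiling(2 * bias_sigma) + 1
  kmax <- min(dim(image))
  if (kmax %% 2 == 0) kmax <- kmax - 1
  ksize <- min(ksize, kmax)
  num <- filter_gaussian(image * w, ksize, bias_sigma)
  den <- filter_gaussian(w, ksize, bias_sigma)
  mfg <- mean(image[w > 0])
  # regularized weighted average: far from any foreground the field decays
  # to the foreground mean, making the correction neutral there
  field <- (num + 0.01 * mfg) / (den + 0.01)
  field <- field / mean(field)
  out <- image / field
  out * (m0 / mean(out))
}

#' Noise-eliminating filter: average then Gaussian
#'
#' Applies a `filter_mask_size` square box (average) filter followed by a
#' Gaussian filter with the same window, run sequentially. Both kernels have
#' unit mass, so constants are preserved and the output stays within the
#' input range.
#'
#' @param image numeric matrix.
#' @param filter_mask_size odd window size in pixels (default 3).
#' @param gaussian_sigma Gaussian sigma in pixels (default 0.5).
#' @return Filtered matrix.
#' @export
denoise <- function(image, filter_mask_size = 3, gaussian_sigma = 0.5) {
  if (filter_mask_size %% 2 != 1) stop("filter_mask_size must be odd")
  avg <- filter_average(image, filter_mask_size)
  filter_gaussian(avg, filter_mask_size, gaussian_sigma)
}

filter_average <- function(image, size) {
  if (size == 1) return(image)
  k <- matrix(1 / size^2, size, size)
  as.matrix(EBImage::filter2(image, k, boundary = "replicate"))
}

filter_gaussian <- function(image, size, sigma) {
  if (size == 1) return(image)
  half <- (size - 1) / 2
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(image, k, boundary = "replicate"))
}

#' Run the full preprocessing chain over a volume
#'
#' Populates four layers on top of `"source"`, mirroring the stages of the
#' pipeline:
#' * `"original"` - per-slice sigmoid transform using that slice's own
#'   WC/WW metadata and an output range of `2^bits_allocated - 1`;
#' * `"debiased"` - [correct_bias()] of the original slices;
#' * `"filtered"` - [denoise()] of the debiased slices;
#' * `"preprocessed"` - sigmoid transform with the fixed VOI
#'   (`cfg$fixed_voi`), redistributing contrast over the full 16-bit range.
#'
#' Slices are processed independently of one another, so the result does not
#' depend on processing order; `"source"` is never mutated.
#'
#' @param volume a [layered_volume()] with a `"source"` layer.
#' @param cfg a [preprocess_config()].
#' @return The volume with layers `original`, `debiased`, `filtered`,
#'   `preprocessed` appended.
#' @export
preprocess_volume <- function(volume, cfg = preprocess_config()) {
  stopifnot(inherits(volume, "LayeredVolume"))
  src <- get_layer(volume, "source")
  orig <- vector("list", volume$z_max)
  deb <- vector("list", volume$z_max)
  fil <- vector("list", volume$z_max)
  pre <- vector("list", volume$z_max)
  for (z in seq_len(volume$z_max)) {
    m <- volume$metadata[[z]]
    if (is.null(m) || is.null(m$window_center) || is.na(m$window_center))
      stop("missing metadata for slice Z = ", z)
    vp <- sigmoid_params(m$window_center, m$window_width,
                         2^m$bits_allocated - 1)
    orig[[z]] <- sigmoid_transform(src[[z]], vp)
    bs <- if (is.null(cfg$bias_sigma)) ncol(src[[z]]) / 4 else cfg$bias_sigma
    deb[[z]] <- correct_bias(orig[[z]], bs)
    fil[[z]] <- denoise(deb[[z]], cfg$filter_mask_size, cfg$gaussian_sigma)
    pre[[z]] <- sigmoid_transform(fil[[z]], cfg$fixed_voi)
  }
  volume <- add_layer(volume, "original", orig)
  volume <- add_layer(volume, "debiased", deb)
  volume <- add_layer(volume, "filtered", fil)
  add_layer(volume, "preprocessed", pre)
}
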