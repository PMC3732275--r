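# Sigmoid VOI transform, bias correction, denoising, layer bookkeeping.

test_that("sigmoid transform: midpoint, monotonicity, bounds", {
  p <- sigmoid_params(512, 100, 1000)
  expect_equal(sigmoid_transform(matrix(512), p)[1], 500)
  x <- matrix(seq(0, 1024, by = 8), nrow = 1)
  y <- sigmoid_transform(x, p)
  expect_true(all(diff(as.numeric(y)) >= 0))
  expect_true(all(y > 0 & y < 1000))
  expect_error(sigmoid_params(512, 0, 1000), "positive")
})

test_that("narrow window approximates a step function", {
  p <- sigmoid_params(512, 1, 2^16)
  lo <- sigmoid_transform(matrix(510), p)[1]
  hi <- sigmoid_transform(matrix(514), p)[1]
  expect_lt(lo, 0.001 * 2^16)
  expect_gt(hi, 0.999 * 2^16)
})

test_that("wide window approximates a linear transform within 2% of range", {
  p <- sigmoid_params(512, 2048, 2^16)
  x <- seq(0, 1024, by = 4)
  y <- as.numeric(sigmoid_transform(matrix(x, nrow = 1), p))
  fit <- lm(y ~ x)
  expect_lt(max(abs(residuals(fit))), 0.02 * 2^16)
})

test_that("repeated fixed-VOI sigmoid is idempotent in saturated regions", {
  p <- sigmoid_params(20000, 100, 2^16)
  x <- matrix(c(1000, 60000), nrow = 1)  # far below / above the window
  once <- sigmoid_transform(x, p)
  twice <- sigmoid_transform(once, p)
  expect_equal(as.numeric(twice), as.numeric(once), tolerance = 1e-6)
})

test_that("bias correction: constant image unchanged, ramp bias reduced", {
  const <- matrix(500, 64, 64)
  out <- correct_bias(const)
  expect_true(all(abs(out - const) / 500 < 0.01))
  expect_identical(correct_bias(matrix(0, 8, 8)), matrix(0, 8, 8))

  ramp <- matrix(rep(seq(1, 1.4, length.out = 64), each = 64), 64, 64)
  img <- 1000 * ramp
  corrected <- correct_bias(img)
  cv <- function(m) sd(m) / mean(m)
  expect_lt(cv(corrected), cv(img) / 2)
  expect_lt(abs(mean(corrected) - mean(img)) / mean(img), 0.01)
})

test_that("bias correction reduces in-tissue variation on a phantom slice", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, bias_amplitude = 0.3,
                                    seed = 3))
  z <- 14
  src <- get_layer(ph$volume, "source")[[z]]
  lv <- ph$labels$liver[, , z] & !ph$labels$vessels[, , z] &
    !ph$labels$nodules[, , z]
  cv <- function(m) sd(m[lv]) / mean(m[lv])
  corrected <- correct_bias(src)
  expect_lt(cv(corrected), cv(src))
})

test_that("denoise: constants preserved, impulse spread, noise reduced", {
  const <- matrix(7, 16, 16)
  expect_equal(denoise(const), const)

  imp <- matrix(0, 15, 15); imp[8, 8] <- 900
  avg <- liverseg:::filter_average(imp, 3)
  expect_equal(avg[8, 8], 100)  # box filter splits the impulse 9 ways
  expect_equal(sum(avg), 900)

  ph <- generate_phantom(small_spec(noise_sigma = 0))
  clean <- get_layer(ph$volume, "source")[[12]]
  noisy <- clean
  set.seed(9)
  idx <- sample(length(noisy), round(0.1 * length(noisy)))
  noisy[idx] <- ifelse(seq_along(idx) %% 2 == 0, 0, 65535)
  expect_lt(mean(abs(denoise(noisy) - clean)), mean(abs(noisy - clean)))
  # unit-mass kernels cannot leave the input range
  out <- denoise(noisy)
  expect_true(all(out >= min(noisy) & out <= max(noisy)))
})

test_that("preprocess_volume populates the five layers with right ranges", {
  v <- small_phantom()$volume
  expect_setequal(names(v$layers),
                  c("source", "original", "debiased", "filtered",
                    "preprocessed"))
  expect_length(get_layer(v, "preprocessed"), v$z_max)
  pre <- get_layer(v, "preprocessed", as_array = TRUE)
  expect_true(all(pre >= 0 & pre <= 2^16))
  orig <- get_layer(v, "original", as_array = TRUE)
  expect_true(all(orig >= 0 & orig <= 2^16 - 1))
})

test_that("preprocessing is per-slice independent and keeps source intact", {
  ph <- generate_phantom(small_spec(seed = 6))
  fwd <- preprocess_volume(ph$volume)
  # reverse the slice order, preprocess, reverse back: identical output
  rev_src <- rev(get_layer(ph$volume, "source"))
  rev_meta <- rev(ph$volume$metadata)
  vr <- preprocess_volume(layered_volume(rev_src, rev_meta))
  expect_equal(rev(get_layer(vr, "preprocessed")),
               get_layer(fwd, "preprocessed"))
  expect_identical(get_layer(fwd, "source"), get_layer(ph$volume, "source"))
})

test_that("preprocess_volume validates its inputs", {
  ph <- generate_phantom(small_spec())
  broken <- ph$volume
  broken$metadata[[3]]$window_center <- NA_real_
  expect_error(preprocess_volume(broken), "slice Z = 3")
  expect_error(preprocess_config(filter_mask_size = 4), "odd")
})
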