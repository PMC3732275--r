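# Independent oracles and shared fixtures for the test suite.

# ---- brute-force oracles (kept deliberately naive and separate from the
# ---- package's implementations) -------------------------------------------

# Connected component of {v : lo < v < hi} containing the seed, under
# 26-connectivity, by plain R flood fill over an explicit visit stack.
oracle_region <- function(vol, seed_yxz, lo, hi) {
  d <- dim(vol)
  ok <- vol > lo & vol < hi
  out <- array(FALSE, d)
  if (!ok[seed_yxz[1], seed_yxz[2], seed_yxz[3]]) {
    out[seed_yxz[1], seed_yxz[2], seed_yxz[3]] <- TRUE  # seed always in
    return(out)
  }
  stack <- matrix(seed_yxz, ncol = 3)
  out[seed_yxz[1], seed_yxz[2], seed_yxz[3]] <- TRUE
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (nrow(stack) > 0) {
    p <- stack[nrow(stack), ]
    stack <- stack[-nrow(stack), , drop = FALSE]
    nb <- sweep(offs, 2, p, "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[keep, , drop = FALSE]
    for (i in seq_len(nrow(nb))) {
      y <- nb[i, 1]; x <- nb[i, 2]; z <- nb[i, 3]
      if (ok[y, x, z] && !out[y, x, z]) {
        out[y, x, z] <- TRUE
        stack <- rbind(stack, c(y, x, z))
      }
    }
  }
  out
}

# Pearson correlation of two binary images from raw pixel sums.
oracle_pearson <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  sa <- sum(a); sb <- sum(b); sab <- sum(a * b)
  num <- n * sab - sa * sb
  den <- sqrt(n * sum(a^2) - sa^2) * sqrt(n * sum(b^2) - sb^2)
  num / den
}

# ---- shared fixtures, built once per test run -----------------------------

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small, fast phantom used by most unit tests (24 slices of 64x64);
# its decoy overlaps the liver's upper slices so the leakage bond exists
small_spec <- function(...) {
  args <- list(...)
  if (is.null(args$shape)) args$shape <- c(24, 64, 64)
  nz <- args$shape[1]
  if (is.null(args$liver_z_range))
    args$liver_z_range <- c(max(1, round(0.15 * nz)), round(0.92 * nz))
  if (is.null(args$decoy_z_range))
    args$decoy_z_range <- c(round(0.72 * nz), nz)
  do.call(phantom_spec, args)
}

small_phantom <- function() fixture("small_phantom", function() {
  ph <- generate_phantom(small_spec(noise_sigma = 0))
  ph$volume <- preprocess_volume(ph$volume)
  ph
})

# a disk-shaped mask, used by contour and GVF geometry tests
disk_mask <- function(n, cy, cx, r) {
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}
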