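# Edge maps, Gradient Vector Flow, contour tracing, snake energies and
# greedy evolution.

test_that("edge map: constant slice is zero, step edge peaks on the edge", {
  expect_true(all(edge_map(matrix(7, 16, 16)) == 0))
  step <- matrix(0, 16, 16); step[, 9:16] <- 100
  e <- edge_map(step)
  expect_true(all(e[, 8:9] == 1))
  expect_true(all(e[, c(1:6, 11:16)] < 1e-9))
})

test_that("phantom edge pixels lie on the true organ boundaries", {
  ph <- small_phantom()
  zr <- referential_index(ph$volume$z_max)
  e <- edge_map(get_layer(ph$volume, "preprocessed")[[zr]])
  top <- e >= quantile(e[e > 0], 0.9)
  # every labeled structure (organ outline, vessels, nodules) is a true
  # intensity boundary on this slice
  inner_edge <- function(m) m & !(EBImage::erode(m * 1,
                                  EBImage::makeBrush(3, "box")) > 0.5)
  boundary <- inner_edge(ph$truth[, , zr] | ph$labels$decoy[, , zr]) |
    inner_edge(ph$labels$vessels[, , zr]) |
    inner_edge(ph$labels$nodules[, , zr])
  dmap <- EBImage::distmap(1 - boundary)
  expect_gte(mean(dmap[top] <= 2), 0.9)
})

test_that("GVF of a zero edge map is zero; divergence is caught", {
  g <- compute_gvf(matrix(0, 16, 16), gvf_params(iterations = 10))
  expect_true(all(g$u == 0) && all(g$v == 0))
  expect_error(gvf_params(mu = 0.2, dt = 10), "stability")
})

test_that("GVF points toward a disk boundary from outside", {
  n <- 96; cy <- 48; cx <- 48; r <- 25
  edge <- edge_map(disk_mask(n, cy, cx, r) * 1000)
  g <- compute_gvf(edge, gvf_params(mu = 0.2, iterations = 1000))
  yy <- matrix(seq_len(n), n, n); xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  d <- sqrt((yy - cy)^2 + (xx - cx)^2)
  ring <- d > r + 1 & d <= r + 10
  inward_y <- (cy - yy) / d; inward_x <- (cx - xx) / d
  dot <- g$u[ring] * inward_x[ring] + g$v[ring] * inward_y[ring]
  expect_gte(mean(dot > 0), 0.95)
})

test_that("GVF converges: doubling iterations changes the field little", {
  # a frame 1000 iterations can fully relax: < 1% RMS change on doubling
  edge <- edge_map(disk_mask(32, 16, 16, 10) * 1000)
  g1 <- compute_gvf(edge, gvf_params(iterations = 1000))
  g2 <- compute_gvf(edge, gvf_params(iterations = 2000))
  rms <- function(a, b) sqrt(mean((a - b)^2))
  scale <- sqrt(mean(g1$u^2 + g1$v^2))
  expect_lt((rms(g1$u, g2$u) + rms(g1$v, g2$v)) / 2, 0.01 * scale)
  expect_lt(g2$residual, g1$residual + 1e-12)

  # on a larger frame the far field keeps strengthening for long, but the
  # direction field the snake follows is already settled near the edge
  edge64 <- edge_map(disk_mask(64, 32, 32, 16) * 1000)
  h1 <- compute_gvf(edge64, gvf_params(iterations = 1000))
  h2 <- compute_gvf(edge64, gvf_params(iterations = 2000))
  yy <- matrix(1:64, 64, 64); xx <- t(yy)
  band <- abs(sqrt((yy - 32)^2 + (xx - 32)^2) - 16) <= 10
  da <- abs(atan2(h1$v, h1$u) - atan2(h2$v, h2$u))
  da <- pmin(da, 2 * pi - da)
  expect_lt(mean(da[band]), 1 * pi / 180)
})

test_that("contour tracing: point count, ordering, round trip", {
  sq <- matrix(FALSE, 64, 64); sq[13:52, 13:52] <- TRUE  # perimeter 156
  ct <- contour_from_mask(sq, 8)
  expect_true(nrow(ct) %in% c(19, 20))

  dk <- disk_mask(64, 32, 32, 20)
  cd <- contour_from_mask(dk, 8)
  ang <- atan2(cd[, 1] - 32, cd[, 2] - 32)
  # monotone in polar angle: after unwrapping, all steps share one sign
  dd <- diff(ang)
  dd <- dd - 2 * pi * round(dd / (2 * pi))
  expect_true(all(dd > 0) || all(dd < 0))
  expect_gte(dice(contour_to_mask(cd, c(64, 64)), dk), 0.95)
  expect_gte(dice(contour_to_mask(ct, c(64, 64)), sq), 0.95)

  expect_error(contour_from_mask(matrix(FALSE, 8, 8)), "empty")
  two <- matrix(FALSE, 32, 32); two[2:8, 2:8] <- TRUE; two[20:26, 20:26] <- TRUE
  expect_error(contour_from_mask(two), "2 connected components")
})

test_that("point energies: collinear minimum, degenerate field, magnitude", {
  # straight contour: the center (collinear) candidate minimizes curvature
  pts <- structure(cbind(c(10, 10, 10, 10), c(4, 8, 12, 16)),
                   class = "ActiveContour")
  zero_field <- structure(list(u = matrix(0, 24, 24), v = matrix(0, 24, 24),
                               magnitude = matrix(0, 24, 24)),
                          class = "GVFField")
  e <- point_energies(pts, 2, zero_field, energy_coefficients(0, 1, 0, 0))
  expect_equal(e[2, 2], min(e))
  # zero field: direction energy is uniformly 1
  ed <- point_energies(pts, 2, zero_field, energy_coefficients(0, 0, 0, 1))
  expect_true(all(ed == 1))
  # magnitude-only: the candidate with the strongest field wins
  mag <- matrix(0, 24, 24); mag[11, 8] <- 1  # below point 2 at (10, 8)
  field <- structure(list(u = matrix(0, 24, 24), v = matrix(0, 24, 24),
                          magnitude = mag), class = "GVFField")
  em <- point_energies(pts, 2, field, energy_coefficients(0, 0, 1, 0))
  expect_equal(which.min(em), 6L)  # (dr = +1, dc = 0) in column-major order
  expect_true(all(em >= 0 & em <= 1))
})

test_that("direction energy is zero only at the field-pointed neighbor", {
  u <- matrix(0, 24, 24); v <- matrix(0, 24, 24)
  u[10, 8] <- 1  # field at the current point (10, 8) points to +x
  field <- structure(list(u = u, v = v, magnitude = matrix(0.5, 24, 24)),
                     class = "GVFField")
  pts <- structure(cbind(c(10, 10, 10, 10), c(4, 8, 12, 16)),
                   class = "ActiveContour")
  ed <- point_energies(pts, 2, field, energy_coefficients(0, 0, 0, 1))
  expect_equal(ed[2, 3], 0)           # dr = 0, dc = +1
  expect_equal(sum(ed == 0), 1)
  expect_equal(sum(ed == 1), 8)
})

test_that("evolution: zero coefficients are the identity, edges are fixed points", {
  dk <- disk_mask(64, 32, 32, 18)
  ct <- contour_from_mask(dk, 8)
  field <- compute_gvf(edge_map(dk * 1000), gvf_params(iterations = 400))
  none <- evolve_contour(ct, field, energy_coefficients(0, 0, 0, 0), 10)
  expect_equal(unclass(none), unclass(ct))
  # a contour lying exactly on a strong closed edge ridge is a fixed point
  sq <- matrix(FALSE, 64, 64); sq[13:52, 13:52] <- TRUE
  ring <- sq & !(EBImage::erode(sq * 1, EBImage::makeBrush(3, "box")) > 0.5)
  csq <- contour_from_mask(sq, 8)
  ridge <- structure(list(u = matrix(0, 64, 64), v = matrix(0, 64, 64),
                          magnitude = ring * 1), class = "GVFField")
  pinned <- evolve_contour(csq, ridge, energy_coefficients(0, 0, 9, 0), 50)
  expect_equal(unclass(pinned), unclass(csq))
})

test_that("a circle outside a disk converges onto its boundary", {
  n <- 80; cy <- 40; cx <- 40; r <- 18
  dk <- disk_mask(n, cy, cx, r)
  init <- contour_from_mask(disk_mask(n, cy, cx, r + 5), 8)
  field <- compute_gvf(edge_map(dk * 1000), gvf_params(iterations = 1000))
  out <- evolve_contour(init, field, energy_coefficients(), 100)
  d <- abs(sqrt((out[, 1] - cy)^2 + (out[, 2] - cx)^2) - r)
  expect_lt(mean(d), 1.5)
})

test_that("active-contour volume segmentation recovers the phantom liver", {
  ph <- generate_phantom(small_spec(noise_sigma = 0, seed = 13))
  ph$volume <- preprocess_volume(ph$volume)
  zr <- referential_index(ph$volume$z_max)
  m <- segment_active_contours(ph$volume, zr,
                               gvf = gvf_params(iterations = 400))
  zs <- which(apply(ph$truth, 3, any))
  mid <- zs[zs >= quantile(zs, 0.25) & zs <= quantile(zs, 0.75)]
  dices <- vapply(mid, function(z) dice(m[, , z], ph$truth[, , z]),
                  numeric(1))
  expect_true(all(dices >= 0.8))

  # single-slice volume: one evolve call, non-empty result
  one <- layered_volume(get_layer(ph$volume, "source")[zr],
                        ph$volume$metadata[zr])
  one <- preprocess_volume(one)
  m1 <- segment_active_contours(one, 1, gvf = gvf_params(iterations = 200))
  expect_true(any(m1))
})
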