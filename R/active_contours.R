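# Greedy active contours (snakes) driven by Gradient Vector Flow.

#' GVF computation parameters
#'
#' @param mu regularization weight of the GVF functional (default 0.2).
#' @param iterations diffusion iterations (default 1000).
#' @param dt explicit-scheme time step; `NULL` picks 0.9x the stability
#'   bound for the given `mu`.
#' @return A list of class `"GVFParams"`.
#' @export
gvf_params <- function(mu = 0.2, iterations = 1000, dt = NULL) {
  stopifnot(mu > 0, iterations >= 1)
  # the data-fidelity term is treated implicitly, so only the explicit
  # diffusion term bounds the time step
  bound <- 1 / (4 * mu)
  if (is.null(dt)) dt <- 0.9 * bound
  if (dt <= 0 || dt > bound)
    stop("dt outside the explicit-scheme stability bound for this mu")
  structure(list(mu = mu, iterations = as.integer(iterations), dt = dt),
            class = "GVFParams")
}

#' Energy-contribution weights of the greedy snake
#'
#' Defaults 1, 3, 9, 3 for elasticity, curvature, GVF magnitude and GVF
#' direction: the external (edge-attraction) terms dominate, with curvature
#' and direction keeping the contour smooth and moving with the field.
#'
#' @param elasticity,curvature,gvf_magnitude,gvf_direction non-negative
#'   weights.
#' @return A list of class `"EnergyCoefficients"`.
#' @export
energy_coefficients <- function(elasticity = 1, curvature = 3,
                                gvf_magnitude = 9, gvf_direction = 3) {
  w <- c(elasticity, curvature, gvf_magnitude, gvf_direction)
  if (any(w < 0)) stop("energy coefficients must be >= 0")
  structure(list(elasticity = elasticity, curvature = curvature,
                 gvf_magnitude = gvf_magnitude,
                 gvf_direction = gvf_direction),
            class = "EnergyCoefficients")
}

grad_xy <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  fx <- (f[, c(2:nc, nc)] - f[, c(1, 1:(nc - 1))]) / 2  # along columns (x)
  fy <- (f[c(2:nr, nr), ] - f[c(1, 1:(nr - 1)), ]) / 2  # along rows (y)
  list(fx = fx, fy = fy)
}

#' Edge map of a preprocessed slice
#'
#' Gradient-magnitude map (central differences) normalized to `[0, 1]`.
#'
#' @param slice 2D intensity matrix.
#' @return Non-negative matrix with maximum 1 (all-zero for a constant
#'   slice).
#' @export
edge_map <- function(slice) {
  g <- grad_xy(slice)
  e <- sqrt(g$fx^2 + g$fy^2)
  mx <- max(e)
  if (mx > 0) e / mx else e
}

#' Gradient Vector Flow of an edge map
#'
#' Iterative diffusion of the edge-gradient field minimizing the GVF
#' functional: smoothness weighted by `mu` against data fidelity weighted by
#' the squared edge-gradient magnitude. The returned field extends edge
#' attraction far from the edges, which is what lets a contour initialized
#' at a distance find the organ boundary.
#'
#' @param edge edge map in `[0, 1]` (from [edge_map()]).
#' @param params a [gvf_params()].
#' @return List of class `"GVFField"` with components `u`, `v` (vector
#'   field, x = columns / y = rows), `magnitude` (norm normalized to
#'   `[0, 1]`), and `residual` (mean RMS update over the final 10% of
#'   iterations, a convergence diagnostic).
#' @export
compute_gvf <- function(edge, params = gvf_params()) {
  g <- grad_xy(edge)
  r <- gvf_cpp(g$fx, g$fy, params$mu, params$iterations, params$dt)
  mag <- sqrt(r$u^2 + r$v^2)
  mx <- max(mag)
  structure(list(u = r$u, v = r$v,
                 magnitude = if (mx > 0) mag / mx else mag,
                 residual = r$residual),
            class = "GVFField")
}

#' Closed contour from a binary mask
#'
#' Traces the boundary of the (single) connected component in consistent
#' orientation and keeps every `spacing`-th boundary pixel (decimation).
#' If decimation would leave fewer than 4 points the spacing is reduced so
#' the contour stays valid.
#'
#' @param mask logical matrix with exactly one connected component.
#' @param spacing circumference pixels between retained points (default 8).
#' @return Matrix of class `"ActiveContour"`, n x 2, columns `(row, col)`,
#'   ordered along the circumference (closed implicitly: last connects to
#'   first).
#' @export
contour_from_mask <- function(mask, spacing = 8) {
  if (!any(mask)) stop("cannot trace an empty mask")
  lab <- label4(mask)
  if (max(lab) > 1)
    stop("mask has ", max(lab), " connected components; expected exactly 1")
  oc <- EBImage::ocontour(matrix(as.integer(mask), nrow(mask)))[[1]] + 1L
  n <- nrow(oc)
  spacing <- max(1L, min(as.integer(spacing), n %/% 4L))
  pts <- oc[seq(1, n, by = spacing), , drop = FALSE]
  if (nrow(pts) < 4) stop("contour collapse: fewer than 4 points")
  structure(pts, class = "ActiveContour", spacing = spacing)
}

#' Fill a closed contour back into a mask
#'
#' Rasterizes the polygon spanned by the contour points (even-odd rule,
#' pixel centers) and adds the contour pixels themselves.
#'
#' @param contour an [contour_from_mask()] result (n x 2, `(row, col)`).
#' @param dim target `c(rows, cols)`.
#' @return Logical matrix.
#' @export
contour_to_mask <- function(contour, dim) {
  pts <- unclass(contour)
  n <- nrow(pts)
  yy <- matrix(seq_len(dim[1]), dim[1], dim[2])
  xx <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  crossings <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- pts[i, 1]; x1 <- pts[i, 2]; y2 <- pts[j, 1]; x2 <- pts[j, 2]
    if (y1 == y2) next
    # horizontal ray to +x, edge crossing test at pixel centers
    cond <- ((y1 > yy) != (y2 > yy)) &
      (xx < (x2 - x1) * (yy - y1) / (y2 - y1) + x1)
    crossings <- crossings + cond
  }
  m <- crossings %% 2L == 1L
  m[cbind(pmin(pmax(round(pts[, 1]), 1), dim[1]),
          pmin(pmax(round(pts[, 2]), 1), dim[2]))] <- TRUE
  m
}

snap_dir <- function(u, v) {
  # snap a field vector to the nearest of the 8 neighbor directions
  k <- round(atan2(v, u) / (pi / 4)) %% 8
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)[k + 1]
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)[k + 1]
  c(drow, dcol)
}

minmax01 <- function(e) {
  rng <- range(e)
  if (diff(rng) == 0) return(e * 0)
  (e - rng[1]) / diff(rng)
}

#' Total snake energies on the 3x3 candidate grid of one contour point
#'
#' For the current pixel and its 8 neighbors, computes the weighted total
#' `w_e E_elast + w_c E_curv + w_m E_mag + w_d E_dir`:
#' * elasticity: deviation of the candidate's distance to the previous point
#'   from the contour's mean inter-point spacing;
#' * curvature: squared second difference `|P_prev - 2 P + P_next|^2`;
#' * magnitude: low where the GVF magnitude is high (edge-attracting);
#' * direction: 0 only at the neighbor nearest the direction of the GVF
#'   vector at the current pixel, 1 elsewhere (all 1 when the field there
#'   is negligible).
#'
#' Elasticity, curvature and magnitude are min-max normalized to `[0, 1]`
#' over the nine candidates; direction is already binary.
#'
#' @param contour an `ActiveContour`.
#' @param index point index.
#' @param gvf a [compute_gvf()] field.
#' @param coeffs an [energy_coefficients()].
#' @param mean_spacing optionally precomputed mean inter-point spacing.
#' @return 3x3 numeric matrix of total energies; `[2, 2]` is "stay".
#' @export
point_energies <- function(contour, index, gvf, coeffs = energy_coefficients(),
                           mean_spacing = NULL) {
  pts <- unclass(contour)
  n <- nrow(pts)
  stopifnot(index >= 1, index <= n)
  d <- dim(gvf$magnitude)
  cur <- pts[index, ]
  prv <- pts[if (index == 1) n else index - 1, ]
  nxt <- pts[if (index == n) 1 else index + 1, ]
  if (is.null(mean_spacing)) mean_spacing <- contour_mean_spacing(pts)

  offs <- expand.grid(dr = -1:1, dc = -1:1)
  cy <- pmin(pmax(cur[1] + offs$dr, 1), d[1])
  cx <- pmin(pmax(cur[2] + offs$dc, 1), d[2])
  e_el <- abs(mean_spacing - sqrt((cy - prv[1])^2 + (cx - prv[2])^2))
  e_cv <- (prv[1] - 2 * cy + nxt[1])^2 + (prv[2] - 2 * cx + nxt[2])^2
  e_mg <- 1 - gvf$magnitude[cbind(cy, cx)]

  e_dir <- rep(1, 9)
  u0 <- gvf$u[cur[1], cur[2]]; v0 <- gvf$v[cur[1], cur[2]]
  if (sqrt(u0^2 + v0^2) >= 1e-6) {
    dd <- snap_dir(u0, v0)
    hit <- which(offs$dr == dd[1] & offs$dc == dd[2])
    e_dir[hit] <- 0
  }
  tot <- coeffs$elasticity * minmax01(e_el) +
    coeffs$curvature * minmax01(e_cv) +
    coeffs$gvf_magnitude * minmax01(e_mg) +
    coeffs$gvf_direction * e_dir
  matrix(tot, 3, 3)  # rows = dr -1:1, cols = dc -1:1
}

contour_mean_spacing <- function(pts) {
  n <- nrow(pts)
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  mean(sqrt(rowSums((nxt - pts)^2)))
}

#' Greedy evolution of an active contour
#'
#' Per iteration, every point moves to the argmin of its 3x3 candidate
#' energies (staying is allowed and wins ties); elasticity and curvature are
#' recomputed every iteration since they depend on the moving points. Stops
#' after `max_iterations` or as soon as no point moved.
#'
#' @param contour an `ActiveContour`.
#' @param gvf a [compute_gvf()] field of the slice.
#' @param coeffs an [energy_coefficients()].
#' @param max_iterations iteration cap (default 100).
#' @return The evolved `ActiveContour`.
#' @export
evolve_contour <- function(contour, gvf, coeffs = energy_coefficients(),
                           max_iterations = 100) {
  pts <- unclass(contour)
  d <- dim(gvf$magnitude)
  for (it in seq_len(max_iterations)) {
    ms <- contour_mean_spacing(pts)
    moved <- FALSE
    new_pts <- pts
    cur_contour <- structure(pts, class = "ActiveContour")
    for (i in seq_len(nrow(pts))) {
      e <- point_energies(cur_contour, i, gvf, coeffs, mean_spacing = ms)
      if (e[2, 2] <= min(e)) next  # staying put wins ties
      k <- which.min(e)  # column-major: deterministic tie-break
      dr <- (k - 1) %% 3 - 1
      dc <- (k - 1) %/% 3 - 1
      new_pts[i, ] <- c(pmin(pmax(pts[i, 1] + dr, 1), d[1]),
                        pmin(pmax(pts[i, 2] + dc, 1), d[2]))
      moved <- TRUE
    }
    pts <- new_pts
    if (!moved) break
  }
  if (nrow(unique(pts)) < 4) stop("contour collapse: fewer than 4 distinct points")
  structure(pts, class = "ActiveContour", spacing = attr(contour, "spacing"))
}

#' Segment a volume with GVF active contours
#'
#' The initial contour on the referential slice comes from the
#' adaptive-threshold referential segmentation (largest segment, traced and
#' decimated). On each slice the edge map and its GVF are computed and the
#' contour evolved greedily; propagation is bidirectional from `z_ref`, each
#' slice initialized with the neighboring slice's final contour (liver shape
#' changes little between adjacent slices). Self-intersections are repaired
#' by re-tracing the filled polygon's outer boundary. A direction terminates
#' when the filled contour area drops below `min_area_fraction` of the
#' referential segment area.
#'
#' @param volume a preprocessed [layered_volume()].
#' @param z_ref referential slice (default [referential_index()]).
#' @param gvf a [gvf_params()].
#' @param coeffs an [energy_coefficients()].
#' @param at_params an [adaptive_threshold_params()] for the referential
#'   segmentation.
#' @param max_iterations snake move iterations per slice (default 100).
#' @param spacing contour decimation spacing in pixels (default 8).
#' @param min_area_fraction per-direction stop: minimum contour area as a
#'   fraction of the referential segment area (default 0.1).
#' @return 3D logical `"SegmentationMask"` with attribute `z_ref`.
#' @export
segment_active_contours <- function(volume, z_ref = NULL,
                                    gvf = gvf_params(),
                                    coeffs = energy_coefficients(),
                                    at_params = adaptive_threshold_params(),
                                    max_iterations = 100, spacing = 8,
                                    min_area_fraction = 0.1) {
  stopifnot(inherits(volume, "LayeredVolume"))
  if (is.null(z_ref))
    z_ref <- referential_index(volume$z_max, at_params$referential$z_fraction)
  slices <- get_layer(volume, "preprocessed")
  d <- dim(slices[[1]])
  zmax <- volume$z_max
  mask <- array(FALSE, c(d, zmax))

  ref <- segment_referential(slices[[z_ref]], cfg = at_params$referential)
  ref_mask <- keep_largest(ref$mask)
  ref_mask <- matrix(EBImage::fillHull(ref_mask * 1) > 0.5, d[1])
  ref_area <- sum(ref_mask)
  if (ref_area == 0) stop("empty referential segment")
  min_area <- min_area_fraction * ref_area

  evolve_slice <- function(z, init) {
    field <- compute_gvf(edge_map(slices[[z]]), gvf)
    out <- evolve_contour(init, field, coeffs, max_iterations)
    m <- contour_to_mask(out, d)
    # repair potential self-intersection: retrace the filled outer boundary
    m1 <- keep_largest(matrix(EBImage::fillHull(m * 1) > 0.5, d[1]))
    list(contour = out, mask = m1)
  }

  init0 <- contour_from_mask(ref_mask, spacing)
  r0 <- evolve_slice(z_ref, init0)
  mask[, , z_ref] <- r0$mask

  propagate <- function(zs) {
    ct <- r0$contour
    for (z in zs) {
      r <- evolve_slice(z, ct)
      if (sum(r$mask) < min_area) break  # organ has ended
      mask[, , z] <<- r$mask
      ct <- tryCatch(contour_from_mask(r$mask, spacing),
                     error = function(e) r$contour)
    }
  }
  if (z_ref < zmax) propagate((z_ref + 1):zmax)
  if (z_ref > 1) propagate((z_ref - 1):1)
  structure(mask, class = "SegmentationMask", z_ref = z_ref)
}
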