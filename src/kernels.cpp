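// Numerical kernels: 3D seeded region growing, GVF diffusion, 2D labeling.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Breadth-first 3D region growing under 26-connectivity.
// vol: numeric array dim (ny, nx, nz); seed0: 0-based (row, col, z).
// Acceptance: lo < v < hi with the bounds anchored either at the seed
// intensity (mode 0) or recomputed from the enqueuing voxel (mode 1).
// [[Rcpp::export]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dim,
                              IntegerVector seed0, double deviation,
                              int reference_mode, double max_voxels) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  LogicalVector mask(n);
  std::vector<signed char> seen(n, 0);

  auto idx = [&](int y, int x, int z) -> R_xlen_t {
    return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
  };

  const int sy = seed0[0], sx = seed0[1], sz = seed0[2];
  const R_xlen_t s = idx(sy, sx, sz);
  const double iseed = vol[s];

  std::queue<R_xlen_t> q;
  q.push(s);
  seen[s] = 1;
  mask[s] = true;
  double accepted = 1;

  while (!q.empty()) {
    const R_xlen_t cur = q.front();
    q.pop();
    const int cz = (int)(cur / ((R_xlen_t)ny * nx));
    const int rem = (int)(cur % ((R_xlen_t)ny * nx));
    const int cx = rem / ny, cy = rem % ny;
    const double anchor = (reference_mode == 0) ? iseed : vol[cur];
    const double lo = anchor * (1.0 - deviation);
    const double hi = anchor * (1.0 + deviation);
    for (int dz = -1; dz <= 1; ++dz) {
      const int z = cz + dz;
      if (z < 0 || z >= nz) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        const int x = cx + dx;
        if (x < 0 || x >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          if (dy == 0 && dx == 0 && dz == 0) continue;
          const int y = cy + dy;
          if (y < 0 || y >= ny) continue;
          const R_xlen_t nb = idx(y, x, z);
          if (seen[nb]) continue;
          const double v = vol[nb];
          if (v > lo && v < hi) {
            seen[nb] = 1;
            mask[nb] = true;
            q.push(nb);
            if (++accepted > max_voxels)
              stop("runaway growth: region exceeded max_voxels");
          } else if (reference_mode == 0) {
            // seed-anchored bounds never change: rejection is final
            seen[nb] = 1;
          }
        }
      }
    }
  }
  mask.attr("dim") = dim;
  return mask;
}

// Gradient Vector Flow by explicit diffusion (Xu & Prince functional):
// u_t = mu * lap(u) - (fx^2 + fy^2) * (u - fx), same for v with fy.
// Returns list(u, v, residual) where residual tracks the RMS update over
// the final 10% of iterations (convergence diagnostic).
// [[Rcpp::export]]
List gvf_cpp(arma::mat fx, arma::mat fy, double mu, int iterations, double dt) {
  arma::mat u = fx, v = fy;
  const arma::mat b = arma::square(fx) + arma::square(fy);
  const arma::mat c1 = b % fx, c2 = b % fy;
  const arma::uword nr = fx.n_rows, nc = fx.n_cols;
  arma::mat lap(nr, nc);
  const int tail_from = iterations - std::max(1, iterations / 10);
  double res = 0.0;
  int res_n = 0;

  auto laplacian = [&](const arma::mat &m) {
    // 5-point Laplacian with replicated borders
    lap.zeros();
    lap.rows(1, nr - 1) += m.rows(0, nr - 2);
    lap.row(0) += m.row(0);
    lap.rows(0, nr - 2) += m.rows(1, nr - 1);
    lap.row(nr - 1) += m.row(nr - 1);
    lap.cols(1, nc - 1) += m.cols(0, nc - 2);
    lap.col(0) += m.col(0);
    lap.cols(0, nc - 2) += m.cols(1, nc - 1);
    lap.col(nc - 1) += m.col(nc - 1);
    lap -= 4.0 * m;
  };

  // diffusion explicit, data term implicit: unconditionally stable in b,
  // so dt is bounded by the diffusion term alone (dt <= 1/(4 mu))
  const arma::mat denom = 1.0 + dt * b;
  for (int it = 0; it < iterations; ++it) {
    laplacian(u);
    arma::mat du = (u + dt * (mu * lap + c1)) / denom - u;
    u += du;
    laplacian(v);
    arma::mat dv = (v + dt * (mu * lap + c2)) / denom - v;
    v += dv;
    if (it >= tail_from) {
      res += std::sqrt(arma::accu(arma::square(du) + arma::square(dv)) /
                       (2.0 * nr * nc));
      ++res_n;
    }
    if (!u.is_finite() || !v.is_finite())
      stop("GVF diverged (non-finite values): dt too large");
  }
  return List::create(_["u"] = u, _["v"] = v,
                      _["residual"] = res_n ? res / res_n : 0.0);
}

// 4-connected labeling of a binary 2D image; labels 1..k in scan order
// (column-major, so the component containing the smallest (row, col) in
// column-major order gets the smallest label).
// [[Rcpp::export]]
IntegerMatrix label4_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int>> q;
  for (int x = 0; x < nc; ++x) {
    for (int y = 0; y < nr; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      lab(y, x) = ++next;
      q.push({y, x});
      while (!q.empty()) {
        auto [cy, cx] = q.front();
        q.pop();
        const int ny_[4] = {cy - 1, cy + 1, cy, cy};
        const int nx_[4] = {cx, cx, cx - 1, cx + 1};
        for (int k = 0; k < 4; ++k) {
          const int yy = ny_[k], xx = nx_[k];
          if (yy < 0 || yy >= nr || xx < 0 || xx >= nc) continue;
          if (mask(yy, xx) && !lab(yy, xx)) {
            lab(yy, xx) = next;
            q.push({yy, xx});
          }
        }
      }
    }
  }
  return lab;
}
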