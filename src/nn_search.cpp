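#include <Rcpp.h>
using namespace Rcpp;

// Exact nearest target point for every query point (brute-force scan).
// Ties resolved to the lowest target index via strict '<'.
// [[Rcpp::export]]
List cpp_nn1(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow(), nt = target.nrow();
  if (target.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have 3 columns");
  if (nt == 0) stop("target is empty");
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<double> tx(nt), ty(nt), tz(nt);
  for (int j = 0; j < nt; ++j) {
    tx[j] = target(j, 0); ty[j] = target(j, 1); tz[j] = target(j, 2);
  }
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < nt; ++j) {
      const double dx = tx[j] - qx, dy = ty[j] - qy, dz = tz[j] - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Exact nearest-neighbour search accelerated by a uniform spatial hash
// grid. Candidate cells are pruned by exact box distances and rings are
// expanded until no unscanned cell can beat the current best, so results
// are identical to the brute-force scan (including lowest-index tie
// resolution).
// [[Rcpp::export]]
List cpp_nn1_grid(NumericMatrix query, NumericMatrix target) {
  const int nq = query.nrow(), nt = target.nrow();
  if (target.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have 3 columns");
  if (nt == 0) stop("target is empty");
  std::vector<double> tx(nt), ty(nt), tz(nt);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int j = 0; j < nt; ++j) {
    tx[j] = target(j, 0); ty[j] = target(j, 1); tz[j] = target(j, 2);
    lo[0] = std::min(lo[0], tx[j]); hi[0] = std::max(hi[0], tx[j]);
    lo[1] = std::min(lo[1], ty[j]); hi[1] = std::max(hi[1], ty[j]);
    lo[2] = std::min(lo[2], tz[j]); hi[2] = std::max(hi[2], tz[j]);
  }
  const double vol = std::max(hi[0] - lo[0], 1e-9) *
                     std::max(hi[1] - lo[1], 1e-9) *
                     std::max(hi[2] - lo[2], 1e-9);
  double h = std::cbrt(vol * 4.0 / nt);
  if (!(h > 0) || !R_finite(h)) h = 1.0;
  int nc[3];
  for (int d = 0; d < 3; ++d) {
    nc[d] = std::max(1, (int)std::floor((hi[d] - lo[d]) / h) + 1);
    nc[d] = std::min(nc[d], 256);
  }
  // recompute the effective cell size per axis so the grid covers the box
  double hs[3];
  for (int d = 0; d < 3; ++d)
    hs[d] = std::max((hi[d] - lo[d]) / nc[d], 1e-12);
  const double hmin = std::min(hs[0], std::min(hs[1], hs[2]));
  const int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> count(ncell + 1, 0), cell(nt);
  auto cell_of = [&](double x, double y, double z) {
    int ix = std::min(nc[0] - 1, std::max(0, (int)((x - lo[0]) / hs[0])));
    int iy = std::min(nc[1] - 1, std::max(0, (int)((y - lo[1]) / hs[1])));
    int iz = std::min(nc[2] - 1, std::max(0, (int)((z - lo[2]) / hs[2])));
    return (ix * nc[1] + iy) * nc[2] + iz;
  };
  for (int j = 0; j < nt; ++j) {
    cell[j] = cell_of(tx[j], ty[j], tz[j]);
    ++count[cell[j] + 1];
  }
  for (int c = 0; c < ncell; ++c) count[c + 1] += count[c];
  std::vector<int> bucket(nt), fill(count.begin(), count.end() - 1);
  for (int j = 0; j < nt; ++j) bucket[fill[cell[j]]++] = j;

  IntegerVector idx(nq);
  NumericVector dist(nq);
  const int rmax = std::max(nc[0], std::max(nc[1], nc[2]));
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int bx = std::min(nc[0] - 1, std::max(0, (int)((qx - lo[0]) / hs[0])));
    int by = std::min(nc[1] - 1, std::max(0, (int)((qy - lo[1]) / hs[1])));
    int bz = std::min(nc[2] - 1, std::max(0, (int)((qz - lo[2]) / hs[2])));
    double best = R_PosInf;
    int bj = 0;
    for (int r = 0; r < rmax; ++r) {
      if (r >= 1) {
        const double bound = (r - 1) * hmin;
        if (best < bound * bound) break;
      }
      for (int ix = std::max(0, bx - r); ix <= std::min(nc[0] - 1, bx + r);
           ++ix) {
        for (int iy = std::max(0, by - r); iy <= std::min(nc[1] - 1, by + r);
             ++iy) {
          for (int iz = std::max(0, bz - r);
               iz <= std::min(nc[2] - 1, bz + r); ++iz) {
            const int cr = std::max(std::abs(ix - bx),
                           std::max(std::abs(iy - by), std::abs(iz - bz)));
            if (cr != r) continue; // only the new ring
            // exact distance from the query to the cell box
            double dx = std::max(std::max(lo[0] + ix * hs[0] - qx,
                                          qx - (lo[0] + (ix + 1) * hs[0])),
                                 0.0);
            double dy = std::max(std::max(lo[1] + iy * hs[1] - qy,
                                          qy - (lo[1] + (iy + 1) * hs[1])),
                                 0.0);
            double dz = std::max(std::max(lo[2] + iz * hs[2] - qz,
                                          qz - (lo[2] + (iz + 1) * hs[2])),
                                 0.0);
            if (dx * dx + dy * dy + dz * dz > best) continue;
            const int c = (ix * nc[1] + iy) * nc[2] + iz;
            for (int p = count[c]; p < count[c + 1]; ++p) {
              const int j = bucket[p];
              const double ddx = tx[j] - qx, ddy = ty[j] - qy,
                           ddz = tz[j] - qz;
              const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best || (d2 == best && j < bj)) { best = d2; bj = j; }
            }
          }
        }
      }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Indices of the k nearest neighbours of each point, excluding the point
// itself. Row i holds the neighbours of point i ordered by distance
// (ties by lower index).
// [[Rcpp::export]]
IntegerMatrix cpp_knn(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < number of points");
  IntegerMatrix out(n, k);
  std::vector<double> x(n), y(n), z(n);
  for (int j = 0; j < n; ++j) {
    x[j] = pts(j, 0); y[j] = pts(j, 1); z[j] = pts(j, 2);
  }
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (int i = 0; i < n; ++i) {
    int filled = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (filled < k) {
        int p = filled++;
        while (p > 0 && bd[p - 1] > d2) {
          bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
        }
        bd[p] = d2; bi[p] = j;
      } else if (d2 < bd[k - 1]) {
        int p = k - 1;
        while (p > 0 && bd[p - 1] > d2) {
          bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
        }
        bd[p] = d2; bi[p] = j;
      }
    }
    for (int p = 0; p < k; ++p) out(i, p) = bi[p] + 1;
  }
  return out;
}
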