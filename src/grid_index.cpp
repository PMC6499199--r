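// Uniform-grid spatial hashing for 3D neighbor queries.
//
// All exported routines are deterministic and RNG-free; randomized orderings
// (e.g. the dart-throwing permutation) are drawn in R and passed in.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline int64_t cell_key(int64_t ix, int64_t iy, int64_t iz) {
  // Multiplicative hash of the integer cell triple. Collisions are harmless:
  // they only add candidates that the exact distance test then rejects.
  return ix * INT64_C(0x9E3779B97F4A7C15) ^
         iy * INT64_C(0xC2B2AE3D27D4EB4F) ^
         iz * INT64_C(0x165667B19E3779F9);
}

struct GridIndex {
  double h;                       // cell edge length (m)
  std::unordered_map<int64_t, std::vector<int> > cells;
  const double *x, *y, *z;
  int n;

  GridIndex(const NumericMatrix& pts, double cell)
      : h(cell), x(&pts(0, 0)), n(pts.nrow()) {
    y = x + n;
    z = y + n;
    cells.reserve(static_cast<size_t>(n));
  }

  inline int64_t ci(double v) const {
    return static_cast<int64_t>(std::floor(v / h));
  }

  void insert(int i) {
    cells[cell_key(ci(x[i]), ci(y[i]), ci(z[i]))].push_back(i);
  }

  void insert_all() {
    for (int i = 0; i < n; ++i) insert(i);
  }
};

inline double sqdist(const double* x, const double* y, const double* z,
                     int i, double qx, double qy, double qz) {
  const double dx = x[i] - qx, dy = y[i] - qy, dz = z[i] - qz;
  return dx * dx + dy * dy + dz * dz;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_radius_count(NumericMatrix pts, double radius) {
  const int n = pts.nrow();
  IntegerVector out(n);
  if (n == 0 || radius <= 0) return out;

  GridIndex g(pts, radius);
  g.insert_all();
  const double r2 = radius * radius;

  int64_t keys[27];
  for (int i = 0; i < n; ++i) {
    const double qx = g.x[i], qy = g.y[i], qz = g.z[i];
    const int64_t cx = g.ci(qx), cy = g.ci(qy), cz = g.ci(qz);
    int cnt = 0, nk = 0;
    for (int64_t ax = cx - 1; ax <= cx + 1; ++ax)
      for (int64_t ay = cy - 1; ay <= cy + 1; ++ay)
        for (int64_t az = cz - 1; az <= cz + 1; ++az) {
          const int64_t key = cell_key(ax, ay, az);
          // distinct cells can hash-collide onto one bucket; visiting a
          // bucket twice would double-count its points
          bool seen = false;
          for (int k = 0; k < nk; ++k) if (keys[k] == key) { seen = true; break; }
          if (seen) continue;
          keys[nk++] = key;
          auto it = g.cells.find(key);
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            if (sqdist(g.x, g.y, g.z, j, qx, qy, qz) <= r2) ++cnt;
          }
        }
    out[i] = cnt;
  }
  return out;
}

// Nearest reference point for each query point (1-based index).
// Ties in exact squared distance resolve to the lowest reference index.
// [[Rcpp::export]]
IntegerVector cpp_nn1(NumericMatrix ref, NumericMatrix query) {
  const int m = ref.nrow(), nq = query.nrow();
  if (m == 0) stop("reference point set is empty");
  IntegerVector out(nq);
  if (nq == 0) return out;

  // Cell size targeting a handful of points per occupied cell. Point clouds
  // are surface samples with highly nonuniform density, so the bounding-box
  // guess is refined against the actual occupied-cell occupancy.
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) {
    lo[d] = R_PosInf;
    hi[d] = R_NegInf;
    for (int i = 0; i < m; ++i) {
      const double v = ref(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  const double vol = std::max((hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]), 0.0);
  double h = (vol > 0) ? 2.0 * std::cbrt(vol / m) : 1.0;
  const double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                                (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                                (hi[2] - lo[2]) * (hi[2] - lo[2]));
  if (!(h > 0) || !R_finite(h)) h = 1.0;

  for (int pass = 0; pass < 4; ++pass) {
    std::unordered_map<int64_t, int> occ;
    occ.reserve(static_cast<size_t>(m));
    const double inv = 1.0 / h;
    for (int i = 0; i < m; ++i) {
      ++occ[cell_key(static_cast<int64_t>(std::floor(ref(i, 0) * inv)),
                     static_cast<int64_t>(std::floor(ref(i, 1) * inv)),
                     static_cast<int64_t>(std::floor(ref(i, 2) * inv)))];
    }
    const double avg = static_cast<double>(m) / occ.size();
    if (avg <= 8.0) break;
    // occupancy grows ~h^2 on surface-sampled data
    h *= std::sqrt(6.0 / avg);
  }

  GridIndex g(ref, h);
  g.insert_all();

  // A ring bound large enough to always reach the populated region.
  const int64_t ring_cap = static_cast<int64_t>(std::ceil(diag / h)) + 3;

  for (int q = 0; q < nq; ++q) {
    const double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    const int64_t cx = g.ci(qx), cy = g.ci(qy), cz = g.ci(qz);

    // Distance (in cells) from the query cell to the reference bounding box,
    // so queries far outside the cloud start scanning at a useful ring.
    int64_t start = 0;
    {
      int64_t dx = 0, dy = 0, dz = 0;
      if (cx < g.ci(lo[0])) dx = g.ci(lo[0]) - cx; else if (cx > g.ci(hi[0])) dx = cx - g.ci(hi[0]);
      if (cy < g.ci(lo[1])) dy = g.ci(lo[1]) - cy; else if (cy > g.ci(hi[1])) dy = cy - g.ci(hi[1]);
      if (cz < g.ci(lo[2])) dz = g.ci(lo[2]) - cz; else if (cz > g.ci(hi[2])) dz = cz - g.ci(hi[2]);
      start = std::max(dx, std::max(dy, dz));
      if (start > 0) --start;
    }

    double best_d2 = R_PosInf;
    int best_i = -1;

    for (int64_t ring = start; ring <= start + ring_cap; ++ring) {
      // Any point in a cell at Chebyshev ring r is at least (r-1)*h away.
      if (best_i >= 0) {
        const double bound = (ring - 1) > 0 ? (ring - 1) * h : 0.0;
        if (best_d2 <= bound * bound) break;
      }
      for (int64_t ax = cx - ring; ax <= cx + ring; ++ax)
        for (int64_t ay = cy - ring; ay <= cy + ring; ++ay) {
          const bool face_xy = (ax == cx - ring || ax == cx + ring ||
                                ay == cy - ring || ay == cy + ring);
          const int64_t zstep = (face_xy || ring == 0) ? 1 : 2 * ring;
          for (int64_t az = cz - ring; az <= cz + ring; az += (zstep > 0 ? zstep : 1)) {
            auto it = g.cells.find(cell_key(ax, ay, az));
            if (it == g.cells.end()) continue;
            for (int j : it->second) {
              const double d2 = sqdist(g.x, g.y, g.z, j, qx, qy, qz);
              if (d2 < best_d2 || (d2 == best_d2 && j < best_i)) {
                best_d2 = d2;
                best_i = j;
              }
            }
          }
        }
    }
    out[q] = best_i + 1;
  }
  return out;
}

// Dart-throwing Poisson-disk selection. `order` is a 1-based visiting
// permutation drawn by the caller; a visited point is accepted as a seed iff
// no previously accepted seed lies within distance <= dmin of it.
// Returns accepted point indices (1-based) in acceptance order.
// [[Rcpp::export]]
IntegerVector cpp_poisson_disk(NumericMatrix pts, IntegerVector order, double dmin) {
  const int n = pts.nrow();
  if (n == 0) stop("empty point set");
  if (order.size() != n) stop("order must be a permutation of the point indices");
  if (!(dmin > 0)) stop("dmin must be positive");

  GridIndex g(pts, dmin);
  const double r2 = dmin * dmin;
  std::vector<int> seeds;
  seeds.reserve(64);

  for (int k = 0; k < n; ++k) {
    const int i = order[k] - 1;
    const double qx = g.x[i], qy = g.y[i], qz = g.z[i];
    const int64_t cx = g.ci(qx), cy = g.ci(qy), cz = g.ci(qz);
    bool blocked = false;
    for (int64_t ax = cx - 1; ax <= cx + 1 && !blocked; ++ax)
      for (int64_t ay = cy - 1; ay <= cy + 1 && !blocked; ++ay)
        for (int64_t az = cz - 1; az <= cz + 1 && !blocked; ++az) {
          auto it = g.cells.find(cell_key(ax, ay, az));
          if (it == g.cells.end()) continue;
          for (int j : it->second) {
            if (sqdist(g.x, g.y, g.z, j, qx, qy, qz) <= r2) {
              blocked = true;
              break;
            }
          }
        }
    if (!blocked) {
      g.insert(i);
      seeds.push_back(i + 1);
    }
  }
  return wrap(seeds);
}
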