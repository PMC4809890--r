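// Core 3D image operators: grayscale reconstruction by dilation (hybrid
// raster/queue algorithm), marker-controlled watershed by priority flood,
// connected-component labeling, separable 1D convolution, and brute-force
// boundary distances. Neighborhoods are passed in as explicit offset
// matrices so R-side oracles can share the exact enumeration order.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

struct Off { int dx, dy, dz; long long dlin; };

static std::vector<Off> makeOffsets(const IntegerMatrix& offsets,
                                    int nx, int ny) {
  std::vector<Off> out;
  out.reserve(offsets.nrow());
  for (int r = 0; r < offsets.nrow(); ++r) {
    Off o;
    o.dx = offsets(r, 0); o.dy = offsets(r, 1); o.dz = offsets(r, 2);
    o.dlin = (long long)o.dx + (long long)nx * (o.dy + (long long)ny * o.dz);
    out.push_back(o);
  }
  return out;
}

static inline bool inGrid(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
}

// ---------------------------------------------------------------------------
// Grayscale reconstruction by dilation (Vincent-style hybrid algorithm).
// marker must be <= mask voxelwise (enforced by the R wrapper).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector mask,
                              IntegerVector dims, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out = clone(marker);
  std::vector<Off> offs = makeOffsets(offsets, nx, ny);
  std::vector<Off> neg, pos;
  for (const Off& o : offs) (o.dlin < 0 ? neg : pos).push_back(o);

  // forward raster scan
  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        double m = out[idx];
        for (const Off& o : neg) {
          int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
          if (inGrid(X, Y, Z, nx, ny, nz)) {
            double v = out[idx + o.dlin];
            if (v > m) m = v;
          }
        }
        double mk = mask[idx];
        out[idx] = m < mk ? m : mk;
      }

  // backward raster scan + queue seeding
  std::queue<R_xlen_t> fifo;
  idx = n - 1;
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x, --idx) {
        double m = out[idx];
        for (const Off& o : pos) {
          int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
          if (inGrid(X, Y, Z, nx, ny, nz)) {
            double v = out[idx + o.dlin];
            if (v > m) m = v;
          }
        }
        double mk = mask[idx];
        out[idx] = m < mk ? m : mk;
        for (const Off& o : pos) {
          int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
          if (inGrid(X, Y, Z, nx, ny, nz)) {
            R_xlen_t q = idx + o.dlin;
            if (out[q] < out[idx] && out[q] < mask[q]) { fifo.push(idx); break; }
          }
        }
      }

  // queue propagation
  while (!fifo.empty()) {
    R_xlen_t p = fifo.front(); fifo.pop();
    int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
    for (const Off& o : offs) {
      int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
      if (!inGrid(X, Y, Z, nx, ny, nz)) continue;
      R_xlen_t q = p + o.dlin;
      if (out[q] < out[p] && mask[q] != out[q]) {
        double v = out[p] < mask[q] ? out[p] : mask[q];
        if (v > out[q]) { out[q] = v; fifo.push(q); }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marker-controlled watershed: priority flood producing a complete
// partition (no watershed lines). Deterministic: min-heap ordered by
// (control value, insertion counter); seeds pushed in label order then
// linear-index order; neighbors enumerated in offset-row order.
// ---------------------------------------------------------------------------

struct QEntry {
  double prio;
  uint64_t counter;
  R_xlen_t idx;
  int label;
};
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // min-heap on priority
    return a.counter > b.counter;                   // FIFO among equals
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector control, IntegerVector seeds,
                            IntegerVector dims, IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<Off> offs = makeOffsets(offsets, nx, ny);
  IntegerVector out(n, 0);
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> pq;
  uint64_t counter = 0;

  std::vector<int> labels;
  for (R_xlen_t i = 0; i < n; ++i)
    if (seeds[i] > 0) labels.push_back(seeds[i]);
  std::sort(labels.begin(), labels.end());
  labels.erase(std::unique(labels.begin(), labels.end()), labels.end());
  if (labels.empty()) stop("empty marker set: at least one labeled voxel required");

  for (int lab : labels)
    for (R_xlen_t i = 0; i < n; ++i)
      if (seeds[i] == lab) pq.push({control[i], counter++, i, lab});

  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    if (out[e.idx] != 0) continue;
    out[e.idx] = e.label;
    int x = (int)(e.idx % nx), y = (int)((e.idx / nx) % ny),
        z = (int)(e.idx / ((R_xlen_t)nx * ny));
    for (const Off& o : offs) {
      int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
      if (!inGrid(X, Y, Z, nx, ny, nz)) continue;
      R_xlen_t q = e.idx + o.dlin;
      if (out[q] == 0) pq.push({control[q], counter++, q, e.label});
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labeling of a binary mask (BFS, labels assigned in
// linear-index order of the first voxel of each component).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<Off> offs = makeOffsets(offsets, nx, ny);
  IntegerVector out(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || out[i] != 0) continue;
    ++next;
    out[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int x = (int)(p % nx), y = (int)((p / nx) % ny),
          z = (int)(p / ((R_xlen_t)nx * ny));
      for (const Off& o : offs) {
        int X = x + o.dx, Y = y + o.dy, Z = z + o.dz;
        if (!inGrid(X, Y, Z, nx, ny, nz)) continue;
        R_xlen_t q = p + o.dlin;
        if (mask[q] && out[q] == 0) { out[q] = next; stack.push_back(q); }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis with replicate boundary.
// kernel has odd length; axis is 0 (x), 1 (y) or 2 (z).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_conv1d(NumericVector data, IntegerVector dims,
                         NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size(), r = klen / 2;
  NumericVector out((R_xlen_t)nx * ny * nz);
  const int nAxis = dims[axis];
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const R_xlen_t stride = strides[axis];

  R_xlen_t idx = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x, ++idx) {
        const int pos = (axis == 0) ? x : (axis == 1 ? y : z);
        double acc = 0;
        for (int t = -r; t <= r; ++t) {
          int pp = pos + t;
          if (pp < 0) pp = 0;
          if (pp >= nAxis) pp = nAxis - 1;
          acc += kernel[t + r] * data[idx + (R_xlen_t)(pp - pos) * stride];
        }
        out[idx] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Directed minimum distances between two point sets (mm coordinates).
// Returns, for each row of A, the distance to the nearest row of B.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_directed_min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
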