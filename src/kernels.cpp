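// Low-level 3D image kernels used by the foci-counting protocols and the
// synthetic stack generator. Arrays are column-major with dims (n1, n2, n3)
// = (rows/y, cols/x, planes/z), matching R's array layout.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int n1, int n2) {
  return (R_xlen_t)i + (R_xlen_t)n1 * ((R_xlen_t)j + (R_xlen_t)n2 * k);
}

// neighbour offset table for 6- or 26-connectivity
static void neighbour_offsets(int conn, std::vector<std::array<int, 3>> &off) {
  off.clear();
  if (conn == 6) {
    off = {{{-1, 0, 0}}, {{1, 0, 0}}, {{0, -1, 0}},
           {{0, 1, 0}},  {{0, 0, -1}}, {{0, 0, 1}}};
  } else {
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          off.push_back({{di, dj, dk}});
        }
  }
}

// [[Rcpp::export]]
NumericVector cpp_mean_filter_disk(NumericVector x, IntegerVector dims,
                                   double radius) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(x.size());
  // disk offsets: di^2 + dj^2 <= r^2 (ImageJ "Mean..." disk support)
  std::vector<std::pair<int, int>> disk;
  const int r = (int)std::floor(radius);
  for (int dj = -r; dj <= r; ++dj)
    for (int di = -r; di <= r; ++di)
      if ((double)(di * di + dj * dj) <= radius * radius + 1e-12)
        disk.push_back({di, dj});
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        double s = 0.0;
        int cnt = 0;
        for (auto &d : disk) {
          const int ii = i + d.first, jj = j + d.second;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2) continue;
          s += x[idx3(ii, jj, k, n1, n2)];
          ++cnt;
        }
        out[idx3(i, j, k, n1, n2)] = s / cnt;
      }
  return out;
}

// Slice-wise local maxima with prominence tolerance, following the ImageJ
// "Find Maxima" logic: candidates (>= all 8 neighbours, > at least one) are
// processed in decreasing intensity; each floods the region above
// (value - tolerance); candidates whose region touches the claimed region of
// a higher maximum are merged into it; accepted maxima are marked with a
// single voxel. Candidates must additionally rise more than `floor_` above
// the stack minimum, which suppresses pure-noise maxima in object-free
// slices. Deterministic: ties broken by linear index.
// [[Rcpp::export]]
IntegerVector cpp_find_maxima_2d(NumericVector x, IntegerVector dims,
                                 double tol, double floor_) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  IntegerVector out(x.size());
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  std::vector<int> cand;
  std::vector<char> visited((size_t)n1 * n2);
  std::vector<int> stack_;

  for (int k = 0; k < n3; ++k) {
    const R_xlen_t base = (R_xlen_t)n1 * n2 * k;
    cand.clear();
    std::fill(visited.begin(), visited.end(), 0);
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const double v = x[base + i + (R_xlen_t)n1 * j];
        bool ge_all = true, gt_one = false;
        for (int t = 0; t < 8; ++t) {
          const int ii = i + di8[t], jj = j + dj8[t];
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2) continue;
          const double w = x[base + ii + (R_xlen_t)n1 * jj];
          if (w > v) { ge_all = false; break; }
          if (w < v) gt_one = true;
        }
        if (ge_all && gt_one && v > floor_) cand.push_back(i + n1 * j);
      }
    std::stable_sort(cand.begin(), cand.end(), [&](int a, int b) {
      const double va = x[base + a], vb = x[base + b];
      if (va != vb) return va > vb;
      return a < b;
    });
    for (int c : cand) {
      if (visited[c]) continue;
      const double cv = x[base + c];
      bool merged = false;
      stack_.clear();
      stack_.push_back(c);
      std::vector<int> region;
      visited[c] = 1;
      region.push_back(c);
      while (!stack_.empty()) {
        const int p = stack_.back();
        stack_.pop_back();
        const int pi = p % n1, pj = p / n1;
        for (int t = 0; t < 8; ++t) {
          const int ii = pi + di8[t], jj = pj + dj8[t];
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2) continue;
          const int q = ii + n1 * jj;
          const double w = x[base + q];
          if (w <= cv - tol) continue;
          if (visited[q] == 2) { merged = true; continue; }
          if (visited[q]) continue;
          visited[q] = 1;
          region.push_back(q);
          stack_.push_back(q);
        }
      }
      for (int q : region) visited[q] = 2; // claimed
      if (!merged) out[base + c] = 1;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, IntegerVector dims,
                                double s1, double s2, double s3) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector a = clone(x);
  const double sig[3] = {s1, s2, s3};
  const int n[3] = {n1, n2, n3};
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sig[ax];
    if (s <= 0) continue;
    const int hw = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> ker(2 * hw + 1);
    for (int t = -hw; t <= hw; ++t)
      ker[t + hw] = std::exp(-0.5 * t * t / (s * s));
    NumericVector b(a.size());
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          const int pos[3] = {i, j, k};
          double num = 0.0, den = 0.0;
          for (int t = -hw; t <= hw; ++t) {
            const int p = pos[ax] + t;
            if (p < 0 || p >= n[ax]) continue;
            int ii = i, jj = j, kk = k;
            if (ax == 0) ii = p; else if (ax == 1) jj = p; else kk = p;
            const double w = ker[t + hw];
            num += w * a[idx3(ii, jj, kk, n1, n2)];
            den += w;
          }
          b[idx3(i, j, k, n1, n2)] = num / den;
        }
    a = b;
  }
  return a;
}

// Render anisotropic Gaussian point sources (centres and sigmas in voxel
// units, 0-based) additively into a stack. Each source integrates to
// approximately its amplitude times the analytic Gaussian volume.
// [[Rcpp::export]]
NumericVector cpp_add_gaussians(IntegerVector dims, NumericVector c1,
                                NumericVector c2, NumericVector c3,
                                double s1, double s2, double s3,
                                NumericVector amp) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  const int h1 = std::max(1, (int)std::ceil(4.0 * s1));
  const int h2 = std::max(1, (int)std::ceil(4.0 * s2));
  const int h3 = std::max(1, (int)std::ceil(4.0 * s3));
  for (R_xlen_t f = 0; f < c1.size(); ++f) {
    const double y = c1[f], xx = c2[f], z = c3[f], A = amp[f];
    const int i0 = std::max(0, (int)std::floor(y) - h1);
    const int i1 = std::min(n1 - 1, (int)std::ceil(y) + h1);
    const int j0 = std::max(0, (int)std::floor(xx) - h2);
    const int j1 = std::min(n2 - 1, (int)std::ceil(xx) + h2);
    const int k0 = std::max(0, (int)std::floor(z) - h3);
    const int k1 = std::min(n3 - 1, (int)std::ceil(z) + h3);
    for (int k = k0; k <= k1; ++k) {
      const double ez = std::exp(-0.5 * (k - z) * (k - z) / (s3 * s3));
      for (int j = j0; j <= j1; ++j) {
        const double ex = std::exp(-0.5 * (j - xx) * (j - xx) / (s2 * s2));
        for (int i = i0; i <= i1; ++i) {
          const double ey = std::exp(-0.5 * (i - y) * (i - y) / (s1 * s1));
          out[idx3(i, j, k, n1, n2)] += A * ey * ex * ez;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int conn) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(conn, off);
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<R_xlen_t> stack_;
  for (R_xlen_t p = 0; p < mask.size(); ++p) {
    if (!mask[p] || lab[p]) continue;
    lab[p] = ++next;
    stack_.clear();
    stack_.push_back(p);
    while (!stack_.empty()) {
      const R_xlen_t q = stack_.back();
      stack_.pop_back();
      const int i = (int)(q % n1);
      const int j = (int)((q / n1) % n2);
      const int k = (int)(q / ((R_xlen_t)n1 * n2));
      for (auto &d : off) {
        const int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
        if (mask[r] && !lab[r]) {
          lab[r] = next;
          stack_.push_back(r);
        }
      }
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation of `marker` under `mask`
// (marker <= mask pointwise), queue-based.
// [[Rcpp::export]]
NumericVector cpp_reconstruct_dilation(NumericVector marker,
                                       NumericVector mask, IntegerVector dims,
                                       int conn) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(conn, off);
  NumericVector J = clone(marker);
  for (R_xlen_t p = 0; p < J.size(); ++p)
    if (J[p] > mask[p]) J[p] = mask[p];
  std::queue<R_xlen_t> q;
  for (R_xlen_t p = 0; p < J.size(); ++p) q.push(p);
  while (!q.empty()) {
    const R_xlen_t p = q.front();
    q.pop();
    const int i = (int)(p % n1);
    const int j = (int)((p / n1) % n2);
    const int k = (int)(p / ((R_xlen_t)n1 * n2));
    const double vp = J[p];
    for (auto &d : off) {
      const int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
      const double cand = std::min(vp, mask[r]);
      if (cand > J[r]) {
        J[r] = cand;
        q.push(r);
      }
    }
  }
  return J;
}

// Label connected plateaus with no strictly higher neighbour (regional
// maxima), restricted to mask > 0.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector x, IntegerVector mask,
                                  IntegerVector dims, int conn) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(conn, off);
  IntegerVector lab(x.size());
  std::vector<char> done(x.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> stack_, plateau;
  for (R_xlen_t p = 0; p < x.size(); ++p) {
    if (done[p] || !mask[p]) continue;
    const double v = x[p];
    bool is_max = true;
    plateau.clear();
    stack_.clear();
    stack_.push_back(p);
    done[p] = 1;
    plateau.push_back(p);
    while (!stack_.empty()) {
      const R_xlen_t q2 = stack_.back();
      stack_.pop_back();
      const int i = (int)(q2 % n1);
      const int j = (int)((q2 / n1) % n2);
      const int k = (int)(q2 / ((R_xlen_t)n1 * n2));
      for (auto &d : off) {
        const int ii = i + d[0], jj = j + d[1], kk = k + d[2];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
        if (!mask[r]) continue;
        if (x[r] > v) is_max = false;
        else if (x[r] == v && !done[r]) {
          done[r] = 1;
          plateau.push_back(r);
          stack_.push_back(r);
        }
      }
    }
    if (is_max) {
      ++next;
      for (R_xlen_t q2 : plateau) lab[q2] = next;
    }
  }
  return lab;
}

struct WsNode {
  double h;
  R_xlen_t seq;
  R_xlen_t idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.h != b.h) return a.h > b.h; // min-heap on height
    return a.seq > b.seq;             // FIFO tie-break -> deterministic
  }
};

// Marker-controlled watershed: flood `height` ascending from labelled
// markers within mask; every masked voxel joins the basin that reaches it
// first.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector markers,
                            IntegerVector mask, IntegerVector dims,
                            int conn) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(conn, off);
  IntegerVector lab(height.size());
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t seq = 0;
  for (R_xlen_t p = 0; p < height.size(); ++p)
    if (markers[p] && mask[p]) {
      lab[p] = markers[p];
      pq.push({height[p], seq++, p, markers[p]});
    }
  while (!pq.empty()) {
    const WsNode nd = pq.top();
    pq.pop();
    const R_xlen_t p = nd.idx;
    const int i = (int)(p % n1);
    const int j = (int)((p / n1) % n2);
    const int k = (int)(p / ((R_xlen_t)n1 * n2));
    for (auto &d : off) {
      const int ii = i + d[0], jj = j + d[1], kk = k + d[2];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      const R_xlen_t r = idx3(ii, jj, kk, n1, n2);
      if (!mask[r] || lab[r]) continue;
      lab[r] = nd.lab;
      pq.push({height[r], seq++, r, nd.lab});
    }
  }
  return lab;
}
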