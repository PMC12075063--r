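// 3D voxel kernels backing the segmentation and tracing stages.
// All volumes are passed as flat vectors with dims (n1, n2, n3) in
// column-major (R) order: linear index = i1 + n1*(i2 + n2*i3).

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

struct Dims {
  int n1, n2, n3;
  R_xlen_t n;
  Dims(IntegerVector d) : n1(d[0]), n2(d[1]), n3(d[2]) {
    n = (R_xlen_t)n1 * n2 * n3;
  }
  inline R_xlen_t id(int i1, int i2, int i3) const {
    return (R_xlen_t)i1 + (R_xlen_t)n1 * ((R_xlen_t)i2 + (R_xlen_t)n2 * i3);
  }
};

// 26- or 6-neighbourhood offsets as (d1,d2,d3) triples.
static std::vector<std::array<int,3> > neighbour_offsets(int conn) {
  std::vector<std::array<int,3> > off;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && nz != 1) continue;
        off.push_back({{a, b, c}});
      }
  return off;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector x, IntegerVector dim, IntegerVector r) {
  Dims d(dim);
  int r1 = r[0], r2 = r[1], r3 = r[2];
  NumericVector out(d.n);
  std::vector<double> buf((2*r1+1)*(2*r2+1)*(2*r3+1));
  for (int i3 = 0; i3 < d.n3; ++i3)
    for (int i2 = 0; i2 < d.n2; ++i2)
      for (int i1 = 0; i1 < d.n1; ++i1) {
        size_t k = 0;
        for (int a = -r3; a <= r3; ++a) {
          int j3 = clampi(i3 + a, 0, d.n3 - 1);
          for (int b = -r2; b <= r2; ++b) {
            int j2 = clampi(i2 + b, 0, d.n2 - 1);
            for (int c = -r1; c <= r1; ++c) {
              int j1 = clampi(i1 + c, 0, d.n1 - 1);
              buf[k++] = x[d.id(j1, j2, j3)];
            }
          }
        }
        size_t mid = k / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + k);
        double m = buf[mid];
        if (k % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + mid);
          m = 0.5 * (m + lo);
        }
        out[d.id(i1, i2, i3)] = m;
      }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_maxfilter3d(NumericVector x, IntegerVector dim, IntegerVector r) {
  Dims d(dim);
  int r1 = r[0], r2 = r[1], r3 = r[2];
  NumericVector out(d.n);
  for (int i3 = 0; i3 < d.n3; ++i3)
    for (int i2 = 0; i2 < d.n2; ++i2)
      for (int i1 = 0; i1 < d.n1; ++i1) {
        double m = -std::numeric_limits<double>::infinity();
        for (int a = -r3; a <= r3; ++a) {
          int j3 = clampi(i3 + a, 0, d.n3 - 1);
          for (int b = -r2; b <= r2; ++b) {
            int j2 = clampi(i2 + b, 0, d.n2 - 1);
            for (int c = -r1; c <= r1; ++c) {
              int j1 = clampi(i1 + c, 0, d.n1 - 1);
              double v = x[d.id(j1, j2, j3)];
              if (v > m) m = v;
            }
          }
        }
        out[d.id(i1, i2, i3)] = m;
      }
  return out;
}

// Connected-component labelling of a boolean volume.
// [[Rcpp::export]]
IntegerVector cpp_conncomp3d(LogicalVector mask, IntegerVector dim, int conn) {
  Dims d(dim);
  std::vector<std::array<int,3> > off = neighbour_offsets(conn);
  IntegerVector lab(d.n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int i3 = 0; i3 < d.n3; ++i3)
    for (int i2 = 0; i2 < d.n2; ++i2)
      for (int i1 = 0; i1 < d.n1; ++i1) {
        R_xlen_t p = d.id(i1, i2, i3);
        if (!mask[p] || lab[p] != 0) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back(); stack.pop_back();
          int q3 = (int)(q / ((R_xlen_t)d.n1 * d.n2));
          int rem = (int)(q % ((R_xlen_t)d.n1 * d.n2));
          int q2 = rem / d.n1, q1 = rem % d.n1;
          for (size_t k = 0; k < off.size(); ++k) {
            int j1 = q1 + off[k][0], j2 = q2 + off[k][1], j3 = q3 + off[k][2];
            if (j1 < 0 || j1 >= d.n1 || j2 < 0 || j2 >= d.n2 || j3 < 0 || j3 >= d.n3)
              continue;
            R_xlen_t u = d.id(j1, j2, j3);
            if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
          }
        }
      }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher), grid step s.
static void dt1d(std::vector<double> &f, std::vector<double> &out, double s) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double fq = f[q];
    while (true) {
      int p = v[k];
      double sden = 2.0 * s2 * (q - p);
      double sp = (fq + s2 * q * q - (f[p] + s2 * p * p)) / sden;
      if (sp <= z[k]) { --k; continue; }
      ++k; v[k] = q; z[k] = sp; z[k + 1] = std::numeric_limits<double>::infinity();
      break;
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]) * s;
    out[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (um) from each foreground voxel to nearest background,
// with anisotropic spacing (one value per axis, same order as dims).
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  Dims d(dim);
  const double INF = 1e30;
  NumericVector g(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) g[i] = mask[i] ? INF : 0.0;
  // pass along axis 1
  {
    std::vector<double> f(d.n1), o(d.n1);
    for (int i3 = 0; i3 < d.n3; ++i3)
      for (int i2 = 0; i2 < d.n2; ++i2) {
        for (int i1 = 0; i1 < d.n1; ++i1) f[i1] = g[d.id(i1, i2, i3)];
        dt1d(f, o, spacing[0]);
        for (int i1 = 0; i1 < d.n1; ++i1) g[d.id(i1, i2, i3)] = o[i1];
      }
  }
  // axis 2
  {
    std::vector<double> f(d.n2), o(d.n2);
    for (int i3 = 0; i3 < d.n3; ++i3)
      for (int i1 = 0; i1 < d.n1; ++i1) {
        for (int i2 = 0; i2 < d.n2; ++i2) f[i2] = g[d.id(i1, i2, i3)];
        dt1d(f, o, spacing[1]);
        for (int i2 = 0; i2 < d.n2; ++i2) g[d.id(i1, i2, i3)] = o[i2];
      }
  }
  // axis 3
  {
    std::vector<double> f(d.n3), o(d.n3);
    for (int i2 = 0; i2 < d.n2; ++i2)
      for (int i1 = 0; i1 < d.n1; ++i1) {
        for (int i3 = 0; i3 < d.n3; ++i3) f[i3] = g[d.id(i1, i2, i3)];
        dt1d(f, o, spacing[2]);
        for (int i3 = 0; i3 < d.n3; ++i3) g[d.id(i1, i2, i3)] = o[i3];
      }
  }
  for (R_xlen_t i = 0; i < d.n; ++i) g[i] = std::sqrt(g[i]);
  return g;
}

struct QItem {
  double elev;
  unsigned long order;
  R_xlen_t idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order; // FIFO among equal elevations
  }
};

// Marker-based watershed by priority flooding of `elev`, restricted to mask.
// Flood front uses 6-connectivity. Voxels in mask components that no seed can
// reach keep label 0 (resolved by the caller).
// [[Rcpp::export]]
IntegerVector cpp_watershed3d(NumericVector elev, IntegerVector markers,
                              LogicalVector mask, IntegerVector dim) {
  Dims d(dim);
  std::vector<std::array<int,3> > off = neighbour_offsets(6);
  IntegerVector lab(d.n);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  unsigned long counter = 0;
  for (R_xlen_t i = 0; i < d.n; ++i) {
    lab[i] = (mask[i] && markers[i] > 0) ? markers[i] : 0;
    if (lab[i] > 0) pq.push(QItem{elev[i], counter++, i});
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    R_xlen_t q = it.idx;
    int q3 = (int)(q / ((R_xlen_t)d.n1 * d.n2));
    int rem = (int)(q % ((R_xlen_t)d.n1 * d.n2));
    int q2 = rem / d.n1, q1 = rem % d.n1;
    int lq = lab[q];
    for (size_t k = 0; k < off.size(); ++k) {
      int j1 = q1 + off[k][0], j2 = q2 + off[k][1], j3 = q3 + off[k][2];
      if (j1 < 0 || j1 >= d.n1 || j2 < 0 || j2 >= d.n2 || j3 < 0 || j3 >= d.n3)
        continue;
      R_xlen_t u = d.id(j1, j2, j3);
      if (mask[u] && lab[u] == 0) {
        lab[u] = lq;
        pq.push(QItem{elev[u], counter++, u});
      }
    }
  }
  return lab;
}

// Grayscale reconstruction by dilation of `marker` under `ceiling`
// (Vincent's hybrid raster/FIFO algorithm, 6-connectivity).
// [[Rcpp::export]]
NumericVector cpp_reconstruct3d(NumericVector marker, NumericVector ceiling,
                                IntegerVector dim) {
  Dims d(dim);
  NumericVector J = clone(marker);
  // forward raster scan
  for (int i3 = 0; i3 < d.n3; ++i3)
    for (int i2 = 0; i2 < d.n2; ++i2)
      for (int i1 = 0; i1 < d.n1; ++i1) {
        R_xlen_t p = d.id(i1, i2, i3);
        double m = J[p];
        if (i1 > 0) m = std::max(m, J[d.id(i1 - 1, i2, i3)]);
        if (i2 > 0) m = std::max(m, J[d.id(i1, i2 - 1, i3)]);
        if (i3 > 0) m = std::max(m, J[d.id(i1, i2, i3 - 1)]);
        J[p] = std::min(m, ceiling[p]);
      }
  // backward raster scan; queue boundary pixels
  std::queue<R_xlen_t> fifo;
  for (int i3 = d.n3 - 1; i3 >= 0; --i3)
    for (int i2 = d.n2 - 1; i2 >= 0; --i2)
      for (int i1 = d.n1 - 1; i1 >= 0; --i1) {
        R_xlen_t p = d.id(i1, i2, i3);
        double m = J[p];
        if (i1 < d.n1 - 1) m = std::max(m, J[d.id(i1 + 1, i2, i3)]);
        if (i2 < d.n2 - 1) m = std::max(m, J[d.id(i1, i2 + 1, i3)]);
        if (i3 < d.n3 - 1) m = std::max(m, J[d.id(i1, i2, i3 + 1)]);
        J[p] = std::min(m, ceiling[p]);
        bool push = false;
        if (i1 < d.n1 - 1) { R_xlen_t u = d.id(i1 + 1, i2, i3);
          if (J[u] < J[p] && J[u] < ceiling[u]) push = true; }
        if (!push && i2 < d.n2 - 1) { R_xlen_t u = d.id(i1, i2 + 1, i3);
          if (J[u] < J[p] && J[u] < ceiling[u]) push = true; }
        if (!push && i3 < d.n3 - 1) { R_xlen_t u = d.id(i1, i2, i3 + 1);
          if (J[u] < J[p] && J[u] < ceiling[u]) push = true; }
        if (push) fifo.push(p);
      }
  std::vector<std::array<int,3> > off = neighbour_offsets(6);
  while (!fifo.empty()) {
    R_xlen_t q = fifo.front(); fifo.pop();
    int q3 = (int)(q / ((R_xlen_t)d.n1 * d.n2));
    int rem = (int)(q % ((R_xlen_t)d.n1 * d.n2));
    int q2 = rem / d.n1, q1 = rem % d.n1;
    double Jq = J[q];
    for (size_t k = 0; k < off.size(); ++k) {
      int j1 = q1 + off[k][0], j2 = q2 + off[k][1], j3 = q3 + off[k][2];
      if (j1 < 0 || j1 >= d.n1 || j2 < 0 || j2 >= d.n2 || j3 < 0 || j3 >= d.n3)
        continue;
      R_xlen_t u = d.id(j1, j2, j3);
      if (J[u] < Jq && J[u] < ceiling[u]) {
        J[u] = std::min(Jq, ceiling[u]);
        fifo.push(u);
      }
    }
  }
  return J;
}

// Separable 1D convolution along one axis (1, 2 or 3), replicate border.
// Kernel centre at floor(len/2).
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector x, IntegerVector dim,
                                NumericVector kernel, int axis) {
  Dims d(dim);
  int K = kernel.size();
  int c = K / 2;
  NumericVector out(d.n);
  int nA = axis == 1 ? d.n1 : (axis == 2 ? d.n2 : d.n3);
  std::vector<double> line(nA), res(nA);
  int nB, nC;
  if (axis == 1)      { nB = d.n2; nC = d.n3; }
  else if (axis == 2) { nB = d.n1; nC = d.n3; }
  else                { nB = d.n1; nC = d.n2; }
  for (int ic = 0; ic < nC; ++ic)
    for (int ib = 0; ib < nB; ++ib) {
      for (int ia = 0; ia < nA; ++ia) {
        R_xlen_t p = axis == 1 ? d.id(ia, ib, ic)
                   : axis == 2 ? d.id(ib, ia, ic)
                               : d.id(ib, ic, ia);
        line[ia] = x[p];
      }
      for (int ia = 0; ia < nA; ++ia) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          int j = clampi(ia + k - c, 0, nA - 1);
          s += kernel[k] * line[j];
        }
        res[ia] = s;
      }
      for (int ia = 0; ia < nA; ++ia) {
        R_xlen_t p = axis == 1 ? d.id(ia, ib, ic)
                   : axis == 2 ? d.id(ib, ia, ic)
                               : d.id(ib, ic, ia);
        out[p] = res[ia];
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Topological thinning (curve skeleton).
// Simple-point characterisation (Malandain & Bertrand): a foreground voxel is
// simple iff (a) its 26-neighbourhood contains exactly one 26-connected
// foreground component adjacent to it, and (b) its 18-neighbourhood contains
// exactly one 6-connected background component 6-adjacent to the centre.

namespace thin {

static bool tables_ready = false;
static std::vector<std::vector<int> > adj26; // within 3x3x3, 26-adjacency
static std::vector<std::vector<int> > adj6;  // within 3x3x3, 6-adjacency
static bool in18[27];                        // 18-neighbourhood member
static bool face6[27];                       // 6-adjacent to centre

static inline int cube_id(int a, int b, int c) { return (a+1) + 3*((b+1) + 3*(c+1)); }

static void build_tables() {
  adj26.assign(27, std::vector<int>());
  adj6.assign(27, std::vector<int>());
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        int i = cube_id(a, b, c);
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        in18[i] = (nz >= 1 && nz <= 2);
        face6[i] = (nz == 1);
        for (int f = -1; f <= 1; ++f)
          for (int e = -1; e <= 1; ++e)
            for (int d2 = -1; d2 <= 1; ++d2) {
              if (d2 == a && e == b && f == c) continue;
              if (std::abs(d2 - a) > 1 || std::abs(e - b) > 1 || std::abs(f - c) > 1)
                continue;
              int j = cube_id(d2, e, f);
              int dd = std::abs(d2 - a) + std::abs(e - b) + std::abs(f - c);
              adj26[i].push_back(j);
              if (dd == 1) adj6[i].push_back(j);
            }
      }
  tables_ready = true;
}

// nb[27]: foreground flags of the 3x3x3 cube (centre index 13).
static bool is_simple(const bool nb[27]) {
  if (!tables_ready) build_tables();
  // (a) exactly one 26-component of foreground among the 26 neighbours
  bool seen[27] = {false};
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    std::vector<int> st; st.push_back(i); seen[i] = true;
    while (!st.empty()) {
      int q = st.back(); st.pop_back();
      for (size_t k = 0; k < adj26[q].size(); ++k) {
        int u = adj26[q][k];
        if (u != 13 && nb[u] && !seen[u]) { seen[u] = true; st.push_back(u); }
      }
    }
  }
  if (ncomp_fg != 1) return false;
  // (b) exactly one 6-component of background within the 18-neighbourhood
  //     that touches a face neighbour of the centre
  bool seenb[27] = {false};
  int ncomp_bg = 0;
  for (int i = 0; i < 27; ++i) {
    if (!in18[i] || nb[i] || seenb[i] || !face6[i]) continue;
    // grow the component from a face-neighbour seed
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    std::vector<int> st; st.push_back(i); seenb[i] = true;
    while (!st.empty()) {
      int q = st.back(); st.pop_back();
      for (size_t k = 0; k < adj6[q].size(); ++k) {
        int u = adj6[q][k];
        if (in18[u] && !nb[u] && !seenb[u]) { seenb[u] = true; st.push_back(u); }
      }
    }
  }
  return ncomp_bg == 1;
}

} // namespace thin

// Sequential directional thinning to a curve skeleton with endpoint
// preservation. Returns the skeleton as a logical vector.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  Dims d(dim);
  std::vector<char> fg(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) fg[i] = mask[i] ? 1 : 0;
  const int dir[6][3] = {
    {0,0,1}, {0,0,-1}, {0,1,0}, {0,-1,0}, {1,0,0}, {-1,0,0}
  };
  std::vector<R_xlen_t> cand;
  bool nb[27];
  auto load_nb = [&](int i1, int i2, int i3) {
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a) {
          int j1 = i1 + a, j2 = i2 + b, j3 = i3 + c;
          bool v = false;
          if (j1 >= 0 && j1 < d.n1 && j2 >= 0 && j2 < d.n2 && j3 >= 0 && j3 < d.n3)
            v = fg[d.id(j1, j2, j3)] != 0;
          nb[(a+1) + 3*((b+1) + 3*(c+1))] = v;
        }
  };
  auto count_fg26 = [&]() {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int s = 0; s < 6; ++s) {
      // candidates from the pass snapshot: border voxels that are not
      // endpoints *now*; the endpoint test is not re-evaluated during the
      // sequential deletions, so voxels that only become tips mid-pass
      // (the spur mechanism) can still be removed. Topology stays safe
      // because simplicity is re-checked at deletion time.
      cand.clear();
      for (int i3 = 0; i3 < d.n3; ++i3)
        for (int i2 = 0; i2 < d.n2; ++i2)
          for (int i1 = 0; i1 < d.n1; ++i1) {
            R_xlen_t p = d.id(i1, i2, i3);
            if (!fg[p]) continue;
            int j1 = i1 + dir[s][0], j2 = i2 + dir[s][1], j3 = i3 + dir[s][2];
            bool border = !(j1 >= 0 && j1 < d.n1 && j2 >= 0 && j2 < d.n2 &&
                            j3 >= 0 && j3 < d.n3 && fg[d.id(j1, j2, j3)]);
            if (!border) continue;
            load_nb(i1, i2, i3);
            if (count_fg26() < 2) continue;  // endpoint or isolated: keep
            cand.push_back(p);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        R_xlen_t p = cand[k];
        if (!fg[p]) continue;
        int q3 = (int)(p / ((R_xlen_t)d.n1 * d.n2));
        int rem = (int)(p % ((R_xlen_t)d.n1 * d.n2));
        int q2 = rem / d.n1, q1 = rem % d.n1;
        load_nb(q1, q2, q3);
        if (count_fg26() == 0) continue;   // lone voxel: keep the component
        if (!thin::is_simple(nb)) continue;
        fg[p] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(d.n);
  for (R_xlen_t i = 0; i < d.n; ++i) out[i] = fg[i] != 0;
  return out;
}

// Trilinear resampling onto an isotropic-or-otherwise new grid. Voxel i sits
// at physical coordinate i*spacing along each axis (0-based).
// [[Rcpp::export]]
List cpp_resample3d(NumericVector x, IntegerVector dim, NumericVector spacing,
                    NumericVector new_spacing) {
  Dims d(dim);
  int m1 = (int)std::floor((d.n1 - 1) * spacing[0] / new_spacing[0]) + 1;
  int m2 = (int)std::floor((d.n2 - 1) * spacing[1] / new_spacing[1]) + 1;
  int m3 = (int)std::floor((d.n3 - 1) * spacing[2] / new_spacing[2]) + 1;
  NumericVector out((R_xlen_t)m1 * m2 * m3);
  for (int i3 = 0; i3 < m3; ++i3) {
    double z = i3 * new_spacing[2] / spacing[2];
    int z0 = clampi((int)std::floor(z), 0, d.n3 - 1);
    int z1 = clampi(z0 + 1, 0, d.n3 - 1);
    double fz = z - std::floor(z);
    for (int i2 = 0; i2 < m2; ++i2) {
      double y = i2 * new_spacing[1] / spacing[1];
      int y0 = clampi((int)std::floor(y), 0, d.n2 - 1);
      int y1 = clampi(y0 + 1, 0, d.n2 - 1);
      double fy = y - std::floor(y);
      for (int i1 = 0; i1 < m1; ++i1) {
        double xx = i1 * new_spacing[0] / spacing[0];
        int x0 = clampi((int)std::floor(xx), 0, d.n1 - 1);
        int x1 = clampi(x0 + 1, 0, d.n1 - 1);
        double fx = xx - std::floor(xx);
        double v000 = x[d.id(x0, y0, z0)], v100 = x[d.id(x1, y0, z0)];
        double v010 = x[d.id(x0, y1, z0)], v110 = x[d.id(x1, y1, z0)];
        double v001 = x[d.id(x0, y0, z1)], v101 = x[d.id(x1, y0, z1)];
        double v011 = x[d.id(x0, y1, z1)], v111 = x[d.id(x1, y1, z1)];
        double v =
          (1-fz) * ((1-fy) * ((1-fx)*v000 + fx*v100) + fy * ((1-fx)*v010 + fx*v110)) +
             fz  * ((1-fy) * ((1-fx)*v001 + fx*v101) + fy * ((1-fx)*v011 + fx*v111));
        out[(R_xlen_t)i1 + (R_xlen_t)m1 * ((R_xlen_t)i2 + (R_xlen_t)m2 * i3)] = v;
      }
    }
  }
  return List::create(_["data"] = out,
                      _["dim"] = IntegerVector::create(m1, m2, m3));
}
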