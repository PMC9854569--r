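#include <Rcpp.h>
#include <cmath>
#include <map>
#include <queue>
#include <vector>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = R_NegInf; z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance to the nearest background (zero) pixel.
// The image border counts as background: the transform runs on a grid
// padded with one ring of zeros.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const IntegerMatrix& labels) {
  const int H = labels.nrow(), W = labels.ncol();
  const int Hp = H + 2, Wp = W + 2;
  const double INF = 1e18;
  std::vector<double> g(Hp * Wp, 0.0);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j)
      g[(i + 1) + (j + 1) * Hp] = labels(i, j) > 0 ? INF : 0.0;
  std::vector<double> f(std::max(Hp, Wp)), d(std::max(Hp, Wp));
  for (int j = 0; j < Wp; ++j) {           // columns
    f.assign(g.begin() + j * Hp, g.begin() + (j + 1) * Hp);
    f.resize(Hp); d.resize(Hp);
    dt1d(f, d);
    for (int i = 0; i < Hp; ++i) g[i + j * Hp] = d[i];
  }
  std::vector<double> fr(Wp), dr(Wp);
  NumericMatrix out(H, W);
  for (int i = 0; i < Hp; ++i) {           // rows
    for (int j = 0; j < Wp; ++j) fr[j] = g[i + j * Hp];
    dt1d(fr, dr);
    if (i >= 1 && i <= H)
      for (int j = 1; j <= W; ++j) out(i - 1, j - 1) = std::sqrt(dr[j]);
  }
  return out;
}

// Fill interior holes: background components not connected to the image
// border (4-connectivity) are assigned the instance id that surrounds
// them (majority over adjacent positive pixels).
// [[Rcpp::export]]
IntegerMatrix cpp_fill_holes(const IntegerMatrix& labels) {
  const int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix out = clone(labels);
  std::vector<char> reach(H * W, 0);
  std::queue<int> q;
  auto push_bg = [&](int i, int j) {
    int id = i + j * H;
    if (labels(i, j) == 0 && !reach[id]) { reach[id] = 1; q.push(id); }
  };
  for (int j = 0; j < W; ++j) { push_bg(0, j); push_bg(H - 1, j); }
  for (int i = 0; i < H; ++i) { push_bg(i, 0); push_bg(i, W - 1); }
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    int id = q.front(); q.pop();
    int i = id % H, j = id / H;
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii >= 0 && ii < H && jj >= 0 && jj < W) push_bg(ii, jj);
    }
  }
  std::vector<char> seen(H * W, 0);
  for (int j0 = 0; j0 < W; ++j0) {
    for (int i0 = 0; i0 < H; ++i0) {
      int id0 = i0 + j0 * H;
      if (labels(i0, j0) != 0 || reach[id0] || seen[id0]) continue;
      // collect one hole component and its bordering instance ids
      std::vector<int> comp;
      std::map<int, int> border;
      std::queue<int> qq;
      qq.push(id0); seen[id0] = 1;
      while (!qq.empty()) {
        int id = qq.front(); qq.pop();
        comp.push_back(id);
        int i = id % H, j = id / H;
        for (int k = 0; k < 4; ++k) {
          int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          int lab = labels(ii, jj);
          int nid = ii + jj * H;
          if (lab == 0) {
            if (!seen[nid] && !reach[nid]) { seen[nid] = 1; qq.push(nid); }
          } else {
            border[lab]++;
          }
        }
      }
      int best = 0, bestn = -1;
      for (auto& kv : border)
        if (kv.second > bestn) { bestn = kv.second; best = kv.first; }
      if (best > 0)
        for (int id : comp) out(id % H, id / H) = best;
    }
  }
  return out;
}

// Radial star-convex distances: from each foreground pixel march along
// each ray in unit steps; the boundary is the first sampled position
// whose nearest pixel is not the same instance (or lies outside the
// image), refined to `refine` resolution on the final step.
// [[Rcpp::export]]
NumericVector cpp_radial_dist(const IntegerMatrix& labels,
                              const NumericMatrix& dirs,
                              double refine) {
  const int H = labels.nrow(), W = labels.ncol();
  const int m = dirs.nrow();
  NumericVector out(Dimension(H, W, m));
  const double maxlen = std::sqrt((double)H * H + (double)W * W) + 2.0;
  auto same = [&](double r, double c, int id) {
    int ri = (int)std::lround(r), ci = (int)std::lround(c);
    if (ri < 0 || ri >= H || ci < 0 || ci >= W) return false;
    return labels(ri, ci) == id;
  };
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int id = labels(i, j);
      if (id <= 0) continue;
      for (int k = 0; k < m; ++k) {
        double dr = dirs(k, 0), dc = dirs(k, 1);
        double t = 1.0;
        while (t <= maxlen && same(i + t * dr, j + t * dc, id)) t += 1.0;
        double lo = t - 1.0, hi = std::min(t, maxlen);
        double s = lo + refine;
        while (s < hi && same(i + s * dr, j + s * dc, id)) s += refine;
        out[i + j * H + k * H * W] = std::min(s, hi);
      }
    }
  }
  return out;
}
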