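#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Vertices are n x 2 matrices in (row, col) order, 0-based continuous
// pixel coordinates, pixel centers at integers.

static double shoelace_signed(const std::vector<double>& r,
                              const std::vector<double>& c) {
  const int n = (int)r.size();
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += c[j] * r[i] - c[i] * r[j];
  return 0.5 * a;
}

// [[Rcpp::export]]
double cpp_polygon_area(const NumericMatrix& verts) {
  const int n = verts.nrow();
  std::vector<double> r(n), c(n);
  for (int i = 0; i < n; ++i) { r[i] = verts(i, 0); c[i] = verts(i, 1); }
  return std::fabs(shoelace_signed(r, c));
}

// Even-odd scanline fill: pixel (i,j) set iff its center lies inside.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(const NumericMatrix& verts, int H, int W) {
  IntegerMatrix out(H, W);
  const int n = verts.nrow();
  if (n < 3) return out;
  double rmin = R_PosInf, rmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    rmin = std::min(rmin, verts(i, 0));
    rmax = std::max(rmax, verts(i, 0));
  }
  int i0 = std::max(0, (int)std::ceil(rmin));
  int i1 = std::min(H - 1, (int)std::floor(rmax));
  std::vector<double> xs;
  for (int i = i0; i <= i1; ++i) {
    xs.clear();
    double y = (double)i;
    for (int a = 0, b = n - 1; a < n; b = a++) {
      double r1 = verts(b, 0), c1 = verts(b, 1);
      double r2 = verts(a, 0), c2 = verts(a, 1);
      if ((r1 > y) != (r2 > y))
        xs.push_back(c1 + (y - r1) * (c2 - c1) / (r2 - r1));
    }
    std::sort(xs.begin(), xs.end());
    for (size_t k = 0; k + 1 < xs.size(); k += 2) {
      int j0 = std::max(0, (int)std::ceil(xs[k]));
      int j1 = std::min(W - 1, (int)std::ceil(xs[k + 1]) - 1);
      for (int j = j0; j <= j1; ++j) out(i, j) = 1;
    }
  }
  return out;
}

static bool point_in_poly(double pr, double pc, const NumericMatrix& v) {
  const int n = v.nrow();
  bool in = false;
  for (int a = 0, b = n - 1; a < n; b = a++) {
    double r1 = v(b, 0), c1 = v(b, 1), r2 = v(a, 0), c2 = v(a, 1);
    if ((r1 > pr) != (r2 > pr) &&
        pc < c1 + (pr - r1) * (c2 - c1) / (r2 - r1))
      in = !in;
  }
  return in;
}

// Supersampled IoU over the union bounding box; the reference oracle.
// [[Rcpp::export]]
double cpp_raster_iou(const NumericMatrix& va, const NumericMatrix& vb,
                      double grid) {
  double rmin = R_PosInf, rmax = R_NegInf, cmin = R_PosInf, cmax = R_NegInf;
  for (int i = 0; i < va.nrow(); ++i) {
    rmin = std::min(rmin, va(i, 0)); rmax = std::max(rmax, va(i, 0));
    cmin = std::min(cmin, va(i, 1)); cmax = std::max(cmax, va(i, 1));
  }
  for (int i = 0; i < vb.nrow(); ++i) {
    rmin = std::min(rmin, vb(i, 0)); rmax = std::max(rmax, vb(i, 0));
    cmin = std::min(cmin, vb(i, 1)); cmax = std::max(cmax, vb(i, 1));
  }
  if (!(rmax > rmin) || !(cmax > cmin)) return 0.0;
  long long na = 0, nb = 0, nab = 0;
  for (double r = rmin + grid / 2; r < rmax; r += grid) {
    for (double c = cmin + grid / 2; c < cmax; c += grid) {
      bool ia = point_in_poly(r, c, va);
      bool ib = point_in_poly(r, c, vb);
      na += ia; nb += ib; nab += (ia && ib);
    }
  }
  long long un = na + nb - nab;
  return un > 0 ? (double)nab / (double)un : 0.0;
}

// Clip polygon (r,c lists) against half-plane left of directed edge
// (ar,ac)->(br,bc); Sutherland-Hodgman step.  Signed area stays exact
// for simple (possibly non-convex) subjects when the clip is convex.
static void clip_halfplane(std::vector<double>& r, std::vector<double>& c,
                           double ar, double ac, double br, double bc,
                           std::vector<double>& nr, std::vector<double>& nc) {
  nr.clear(); nc.clear();
  const int n = (int)r.size();
  if (n == 0) return;
  double er = br - ar, ec = bc - ac;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    double sj = ec * (r[j] - ar) - er * (c[j] - ac);
    double si = ec * (r[i] - ar) - er * (c[i] - ac);
    bool inj = sj >= 0, ini = si >= 0;
    if (inj != ini) {
      double t = sj / (sj - si);
      nr.push_back(r[j] + t * (r[i] - r[j]));
      nc.push_back(c[j] + t * (c[i] - c[j]));
    }
    if (ini) { nr.push_back(r[i]); nc.push_back(c[i]); }
  }
}

// Exact area of A intersect B where B is star-shaped about centerB:
// decompose B into its triangle fan and sum area(A ∩ triangle).
static double clip_intersection_area(const NumericMatrix& va,
                                     const NumericMatrix& vb,
                                     double cbr, double cbc) {
  const int na = va.nrow(), nb = vb.nrow();
  double armin = R_PosInf, armax = R_NegInf, acmin = R_PosInf, acmax = R_NegInf;
  std::vector<double> ar(na), ac(na);
  for (int i = 0; i < na; ++i) {
    ar[i] = va(i, 0); ac[i] = va(i, 1);
    armin = std::min(armin, ar[i]); armax = std::max(armax, ar[i]);
    acmin = std::min(acmin, ac[i]); acmax = std::max(acmax, ac[i]);
  }
  double total = 0.0;
  std::vector<double> r0, c0, r1, c1;
  for (int k = 0; k < nb; ++k) {
    int k2 = (k + 1) % nb;
    double t1r = vb(k, 0), t1c = vb(k, 1);
    double t2r = vb(k2, 0), t2c = vb(k2, 1);
    // bbox cull against A
    double trmin = std::min({cbr, t1r, t2r}), trmax = std::max({cbr, t1r, t2r});
    double tcmin = std::min({cbc, t1c, t2c}), tcmax = std::max({cbc, t1c, t2c});
    if (trmin > armax || trmax < armin || tcmin > acmax || tcmax < acmin)
      continue;
    // orient triangle counter-clockwise in (c, r) algebra
    double s = (t1c - cbc) * (t2r - cbr) - (t2c - cbc) * (t1r - cbr);
    if (std::fabs(s) < 1e-12) continue;
    double p1r = t1r, p1c = t1c, p2r = t2r, p2c = t2c;
    if (s < 0) { std::swap(p1r, p2r); std::swap(p1c, p2c); }
    r0 = ar; c0 = ac;
    clip_halfplane(r0, c0, cbr, cbc, p1r, p1c, r1, c1);
    clip_halfplane(r1, c1, p1r, p1c, p2r, p2c, r0, c0);
    clip_halfplane(r0, c0, p2r, p2c, cbr, cbc, r1, c1);
    if (r1.size() >= 3) total += std::fabs(shoelace_signed(r1, c1));
  }
  return total;
}

// [[Rcpp::export]]
double cpp_clip_iou(const NumericMatrix& va, const NumericMatrix& vb,
                    double car, double cac, double cbr, double cbc) {
  double area_a = cpp_polygon_area(va);
  double area_b = cpp_polygon_area(vb);
  if (area_a <= 0 && area_b <= 0) return 0.0;
  double inter = clip_intersection_area(va, vb, cbr, cbc);
  double un = area_a + area_b - inter;
  if (un <= 0) return 0.0;
  double iou = inter / un;
  return std::min(1.0, std::max(0.0, iou));
}

// Pairwise IoU matrix for a proposal set (shared ray directions).
// centers: n x 2, dists: n x m, dirs: m x 2 (row, col unit vectors).
// Entry (i, j) is computed exactly as polygon_iou(a = i, b = j), i.e.
// with the triangle fan of j, so that the matrix is bit-identical to
// per-pair calls (density ties in adaptive NMS sit on exact-equality
// comparisons).  Pairs whose bounding circles do not intersect are
// provably zero and skipped.
// [[Rcpp::export]]
NumericMatrix cpp_iou_matrix(const NumericMatrix& centers,
                             const NumericMatrix& dists,
                             const NumericMatrix& dirs) {
  const int n = centers.nrow(), m = dists.ncol();
  std::vector<NumericMatrix> verts;
  std::vector<double> rmax(n), area(n);
  verts.reserve(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix v(m, 2);
    double mx = 0;
    for (int k = 0; k < m; ++k) {
      v(k, 0) = centers(i, 0) + dists(i, k) * dirs(k, 0);
      v(k, 1) = centers(i, 1) + dists(i, k) * dirs(k, 1);
      mx = std::max(mx, dists(i, k));
    }
    verts.push_back(v);
    rmax[i] = mx;
    area[i] = cpp_polygon_area(v);
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double dr = centers(i, 0) - centers(j, 0);
      double dc = centers(i, 1) - centers(j, 1);
      double d2 = dr * dr + dc * dc;
      double rs = rmax[i] + rmax[j];
      if (d2 >= rs * rs) continue;
      if (area[i] <= 0 && area[j] <= 0) continue;
      double inter = clip_intersection_area(verts[i], verts[j],
                                            centers(j, 0), centers(j, 1));
      double un = area[i] + area[j] - inter;
      out(i, j) = un > 0 ? std::min(1.0, std::max(0.0, inter / un)) : 0.0;
    }
  }
  return out;
}
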