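// Brute-force mesh queries with AABB rejection. Meshes in this package are
// small (10^2-10^3 faces) so a spatial index would be overkill; the AABB
// pre-test keeps the inner loop cheap enough for the FDK inner iterations.
#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Moller-Trumbore ray/triangle intersection. Returns t >= 0 or -1.
static inline double ray_tri(const double *o, const double *d,
                             const double *a, const double *b, const double *c,
                             double *ndot) {
  double e1[3], e2[3], p[3], q[3], s[3];
  for (int k = 0; k < 3; ++k) { e1[k] = b[k] - a[k]; e2[k] = c[k] - a[k]; }
  p[0] = d[1] * e2[2] - d[2] * e2[1];
  p[1] = d[2] * e2[0] - d[0] * e2[2];
  p[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < 1e-14) return -1.0;
  double inv = 1.0 / det;
  for (int k = 0; k < 3; ++k) s[k] = o[k] - a[k];
  double u = (s[0] * p[0] + s[1] * p[1] + s[2] * p[2]) * inv;
  if (u < -1e-9 || u > 1.0 + 1e-9) return -1.0;
  q[0] = s[1] * e1[2] - s[2] * e1[1];
  q[1] = s[2] * e1[0] - s[0] * e1[2];
  q[2] = s[0] * e1[1] - s[1] * e1[0];
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < -1e-9 || u + v > 1.0 + 1e-9) return -1.0;
  double t = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  if (t < 0.0) return -1.0;
  // sign of (triangle normal) . (ray dir): caller decides front/back facing
  double n0 = e1[1] * e2[2] - e1[2] * e2[1];
  double n1 = e1[2] * e2[0] - e1[0] * e2[2];
  double n2 = e1[0] * e2[1] - e1[1] * e2[0];
  *ndot = n0 * d[0] + n1 * d[1] + n2 * d[2];
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_ray_depths(NumericMatrix pts, NumericMatrix dirs,
                             NumericMatrix V, IntegerMatrix F,
                             double max_depth) {
  int np = pts.nrow(), nf = F.nrow();
  NumericVector out(np);
  // per-face AABB
  std::vector<double> lo(3 * nf), hi(3 * nf);
  for (int i = 0; i < nf; ++i) {
    int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
    for (int k = 0; k < 3; ++k) {
      double a = V(ia, k), b = V(ib, k), c = V(ic, k);
      double mn = a < b ? a : b; mn = mn < c ? mn : c;
      double mx = a > b ? a : b; mx = mx > c ? mx : c;
      lo[3 * i + k] = mn; hi[3 * i + k] = mx;
    }
  }
  for (int p = 0; p < np; ++p) {
    double o[3] = { pts(p, 0), pts(p, 1), pts(p, 2) };
    double d[3] = { dirs(p, 0), dirs(p, 1), dirs(p, 2) };
    double best = -1.0;
    for (int i = 0; i < nf; ++i) {
      // AABB reject: segment [o, o + max_depth*d] vs box (slab test)
      bool skip = false;
      for (int k = 0; k < 3 && !skip; ++k) {
        double a = o[k], b = o[k] + max_depth * d[k];
        double mn = a < b ? a : b, mx = a > b ? a : b;
        if (mx < lo[3 * i + k] - 1e-9 || mn > hi[3 * i + k] + 1e-9) skip = true;
      }
      if (skip) continue;
      int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
      double A[3] = { V(ia, 0), V(ia, 1), V(ia, 2) };
      double B[3] = { V(ib, 0), V(ib, 1), V(ib, 2) };
      double C[3] = { V(ic, 0), V(ic, 1), V(ic, 2) };
      double ndot;
      double t = ray_tri(o, d, A, B, C, &ndot);
      // a penetrated vertex lies beyond the master surface, so its inward
      // ray exits through the master's back side: outward normal . dir > 0
      if (t >= 0.0 && t <= max_depth && ndot > 0.0)
        if (best < 0.0 || t < best) best = t;
    }
    out[p] = best > 0.0 ? best : 0.0;
  }
  return out;
}

static inline void closest_on_tri(const double *p, const double *a,
                                  const double *b, const double *c,
                                  double *out) {
  // Ericson, Real-Time Collision Detection, closest point on triangle
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k] = b[k] - a[k]; ac[k] = c[k] - a[k]; ap[k] = p[k] - a[k]; }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0 && d2 <= 0) { for (int k = 0; k < 3; ++k) out[k] = a[k]; return; }
  double bp[3]; for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0 && d4 <= d3) { for (int k = 0; k < 3; ++k) out[k] = b[k]; return; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    return;
  }
  double cp[3]; for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0 && d5 <= d6) { for (int k = 0; k < 3; ++k) out[k] = c[k]; return; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
}

// Signed closest-point depth: distance to the master surface where the
// query point lies behind the nearest facet's outward normal (inside the
// master body), else 0. Continuous in the query point within smooth
// regions, unlike ray-cast depth which jumps at grazing incidence.
// [[Rcpp::export]]
NumericVector cpp_signed_depths(NumericMatrix P, NumericMatrix V,
                                IntegerMatrix F, double max_depth) {
  int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double q[3] = { P(p, 0), P(p, 1), P(p, 2) };
    double best = DBL_MAX, bn[3] = { 0, 0, 0 }, bp[3] = { 0, 0, 0 };
    for (int i = 0; i < nf; ++i) {
      int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
      double A[3] = { V(ia, 0), V(ia, 1), V(ia, 2) };
      double B[3] = { V(ib, 0), V(ib, 1), V(ib, 2) };
      double C[3] = { V(ic, 0), V(ic, 1), V(ic, 2) };
      double d2box = 0.0;
      for (int k = 0; k < 3; ++k) {
        double mn = A[k] < B[k] ? A[k] : B[k]; mn = mn < C[k] ? mn : C[k];
        double mx = A[k] > B[k] ? A[k] : B[k]; mx = mx > C[k] ? mx : C[k];
        double d = q[k] < mn ? mn - q[k] : (q[k] > mx ? q[k] - mx : 0.0);
        d2box += d * d;
      }
      if (d2box >= best) continue;
      double r[3];
      closest_on_tri(q, A, B, C, r);
      double d2 = (r[0] - q[0]) * (r[0] - q[0]) + (r[1] - q[1]) * (r[1] - q[1]) +
                  (r[2] - q[2]) * (r[2] - q[2]);
      if (d2 < best) {
        best = d2;
        bp[0] = r[0]; bp[1] = r[1]; bp[2] = r[2];
        double e1[3], e2[3];
        for (int k = 0; k < 3; ++k) { e1[k] = B[k] - A[k]; e2[k] = C[k] - A[k]; }
        bn[0] = e1[1] * e2[2] - e1[2] * e2[1];
        bn[1] = e1[2] * e2[0] - e1[0] * e2[2];
        bn[2] = e1[0] * e2[1] - e1[1] * e2[0];
      }
    }
    double dist = std::sqrt(best);
    double dot = bn[0] * (q[0] - bp[0]) + bn[1] * (q[1] - bp[1]) +
                 bn[2] * (q[2] - bp[2]);
    double d = (dot < 0.0) ? dist : 0.0;
    out[p] = d > max_depth ? max_depth : d;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_closest_points(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nf = F.nrow();
  NumericMatrix out(np, 3);
  for (int p = 0; p < np; ++p) {
    double q[3] = { P(p, 0), P(p, 1), P(p, 2) };
    double best = DBL_MAX, bp[3] = { q[0], q[1], q[2] };
    for (int i = 0; i < nf; ++i) {
      int ia = F(i, 0) - 1, ib = F(i, 1) - 1, ic = F(i, 2) - 1;
      double A[3] = { V(ia, 0), V(ia, 1), V(ia, 2) };
      double B[3] = { V(ib, 0), V(ib, 1), V(ib, 2) };
      double C[3] = { V(ic, 0), V(ic, 1), V(ic, 2) };
      // quick reject on squared AABB distance
      double d2box = 0.0;
      for (int k = 0; k < 3; ++k) {
        double mn = A[k] < B[k] ? A[k] : B[k]; mn = mn < C[k] ? mn : C[k];
        double mx = A[k] > B[k] ? A[k] : B[k]; mx = mx > C[k] ? mx : C[k];
        double d = q[k] < mn ? mn - q[k] : (q[k] > mx ? q[k] - mx : 0.0);
        d2box += d * d;
      }
      if (d2box >= best) continue;
      double r[3];
      closest_on_tri(q, A, B, C, r);
      double d2 = (r[0] - q[0]) * (r[0] - q[0]) + (r[1] - q[1]) * (r[1] - q[1]) +
                  (r[2] - q[2]) * (r[2] - q[2]);
      if (d2 < best) { best = d2; bp[0] = r[0]; bp[1] = r[1]; bp[2] = r[2]; }
    }
    out(p, 0) = bp[0]; out(p, 1) = bp[1]; out(p, 2) = bp[2];
  }
  return out;
}
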