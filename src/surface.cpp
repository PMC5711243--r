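#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Squared distance from point p to triangle (a, b, c), Eberly's
// region-based closest-point algorithm.
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double E0[3], E1[3], D[3];
  for (int i = 0; i < 3; ++i) {
    E0[i] = b[i] - a[i];
    E1[i] = c[i] - a[i];
    D[i] = a[i] - p[i];
  }
  double a00 = E0[0]*E0[0] + E0[1]*E0[1] + E0[2]*E0[2];
  double a01 = E0[0]*E1[0] + E0[1]*E1[1] + E0[2]*E1[2];
  double a11 = E1[0]*E1[0] + E1[1]*E1[1] + E1[2]*E1[2];
  double b0 = E0[0]*D[0] + E0[1]*D[1] + E0[2]*D[2];
  double b1 = E1[0]*D[0] + E1[1]*D[1] + E1[2]*D[2];
  double det = std::fabs(a00 * a11 - a01 * a01);
  double s = a01 * b1 - a11 * b0;
  double t = a01 * b0 - a00 * b1;

  if (s + t <= det) {
    if (s < 0) {
      if (t < 0) {  // region 4
        if (b0 < 0) { t = 0; s = (-b0 >= a00 ? 1 : -b0 / a00); }
        else { s = 0; t = (b1 >= 0 ? 0 : (-b1 >= a11 ? 1 : -b1 / a11)); }
      } else {      // region 3
        s = 0; t = (b1 >= 0 ? 0 : (-b1 >= a11 ? 1 : -b1 / a11));
      }
    } else if (t < 0) {  // region 5
      t = 0; s = (b0 >= 0 ? 0 : (-b0 >= a00 ? 1 : -b0 / a00));
    } else {             // region 0
      double inv = 1 / det; s *= inv; t *= inv;
    }
  } else {
    if (s < 0) {  // region 2
      double tmp0 = a01 + b0, tmp1 = a11 + b1;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a00 - 2 * a01 + a11;
        s = (numer >= denom ? 1 : numer / denom); t = 1 - s;
      } else {
        s = 0; t = (tmp1 <= 0 ? 1 : (b1 >= 0 ? 0 : -b1 / a11));
      }
    } else if (t < 0) {  // region 6
      double tmp0 = a01 + b1, tmp1 = a00 + b0;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0, denom = a00 - 2 * a01 + a11;
        t = (numer >= denom ? 1 : numer / denom); s = 1 - t;
      } else {
        t = 0; s = (tmp1 <= 0 ? 1 : (b0 >= 0 ? 0 : -b0 / a00));
      }
    } else {  // region 1
      double numer = a11 + b1 - a01 - b0;
      if (numer <= 0) s = 0;
      else {
        double denom = a00 - 2 * a01 + a11;
        s = (numer >= denom ? 1 : numer / denom);
      }
      t = 1 - s;
    }
  }
  double q[3];
  for (int i = 0; i < 3; ++i) q[i] = a[i] + s * E0[i] + t * E1[i] - p[i];
  return q[0]*q[0] + q[1]*q[1] + q[2]*q[2];
}

// Minimum distance from each sample point to a triangle soup, with a
// per-triangle bounding-sphere prune against the current best distance.
// [[Rcpp::export(name = ".point_mesh_distance_cpp")]]
NumericVector point_mesh_distance_cpp(NumericMatrix points,
                                      NumericMatrix vertices,
                                      IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow();
  NumericVector out(np);

  // triangle centroids and bounding radii
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<double> A(3 * nf), B(3 * nf), C(3 * nf);
  for (int f = 0; f < nf; ++f) {
    int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
    for (int d = 0; d < 3; ++d) {
      A[3*f+d] = vertices(ia, d);
      B[3*f+d] = vertices(ib, d);
      C[3*f+d] = vertices(ic, d);
    }
    cx[f] = (A[3*f] + B[3*f] + C[3*f]) / 3;
    cy[f] = (A[3*f+1] + B[3*f+1] + C[3*f+1]) / 3;
    cz[f] = (A[3*f+2] + B[3*f+2] + C[3*f+2]) / 3;
    double r2 = 0;
    const double *vs[3] = {&A[3*f], &B[3*f], &C[3*f]};
    for (int v = 0; v < 3; ++v) {
      double dx = vs[v][0] - cx[f], dy = vs[v][1] - cy[f],
             dz = vs[v][2] - cz[f];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }

  for (int p = 0; p < np; ++p) {
    double pt[3] = {points(p, 0), points(p, 1), points(p, 2)};
    double best = std::numeric_limits<double>::infinity();
    double best_d = std::numeric_limits<double>::infinity();  // sqrt of best
    for (int f = 0; f < nf; ++f) {
      double dx = pt[0] - cx[f], dy = pt[1] - cy[f], dz = pt[2] - cz[f];
      double cd = std::sqrt(dx*dx + dy*dy + dz*dz) - rad[f];
      if (cd > best_d) continue;
      double d2 = point_tri_dist2(pt, &A[3*f], &B[3*f], &C[3*f]);
      if (d2 < best) { best = d2; best_d = std::sqrt(d2); }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
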