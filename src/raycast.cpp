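// Per-pixel ray casting against a triangle mesh (Moller-Trumbore, nearest
// hit). Replaces GPU cube-mapping with an equivalent CPU projection.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ray_cast_cpp(NumericVector origin, NumericMatrix dirs,
                  NumericMatrix verts, IntegerMatrix faces) {
  const int nr = dirs.nrow();
  const int nf = faces.nrow();
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  // precompute triangle vertices and edges
  std::vector<double> ax(nf), ay(nf), az(nf), e1x(nf), e1y(nf), e1z(nf),
      e2x(nf), e2y(nf), e2z(nf);
  for (int f = 0; f < nf; ++f) {
    int i0 = faces(f, 0), i1 = faces(f, 1), i2 = faces(f, 2);
    ax[f] = verts(i0, 0); ay[f] = verts(i0, 1); az[f] = verts(i0, 2);
    e1x[f] = verts(i1, 0) - ax[f]; e1y[f] = verts(i1, 1) - ay[f];
    e1z[f] = verts(i1, 2) - az[f];
    e2x[f] = verts(i2, 0) - ax[f]; e2y[f] = verts(i2, 1) - ay[f];
    e2z[f] = verts(i2, 2) - az[f];
  }

  NumericVector tout(nr, NA_REAL);
  IntegerVector fout(nr, NA_INTEGER);
  for (int r = 0; r < nr; ++r) {
    double dx = dirs(r, 0), dy = dirs(r, 1), dz = dirs(r, 2);
    if (!std::isfinite(dx)) continue;
    double tbest = R_PosInf;
    int fbest = -1;
    for (int f = 0; f < nf; ++f) {
      // h = d x e2
      double hx = dy * e2z[f] - dz * e2y[f];
      double hy = dz * e2x[f] - dx * e2z[f];
      double hz = dx * e2y[f] - dy * e2x[f];
      double det = e1x[f] * hx + e1y[f] * hy + e1z[f] * hz;
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double sx = ox - ax[f], sy = oy - ay[f], sz = oz - az[f];
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < -1e-9 || u > 1 + 1e-9) continue;
      // q = s x e1
      double qx = sy * e1z[f] - sz * e1y[f];
      double qy = sz * e1x[f] - sx * e1z[f];
      double qz = sx * e1y[f] - sy * e1x[f];
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1 + 1e-9) continue;
      double t = (e2x[f] * qx + e2y[f] * qy + e2z[f] * qz) * inv;
      if (t > 1e-9 && t < tbest) { tbest = t; fbest = f; }
    }
    if (fbest >= 0) { tout[r] = tbest; fout[r] = fbest + 1; }
  }
  return List::create(_["t"] = tout, _["face"] = fout);
}
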