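// Ray tracing through the schematic mouse eye: analytic Snell refraction at
// spherical surfaces and step-wise propagation through the GRIN lens lattice.
// All lengths in micrometers. The optical axis is +z, light enters at z = 0.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 operator+(Vec3 a, Vec3 b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator-(Vec3 a, Vec3 b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator*(double s, Vec3 a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }
inline Vec3 unit(Vec3 a) { double n = norm(a); return {a.x / n, a.y / n, a.z / n}; }

// Geometry slots (see R/eye_model.R eye_geom_vector)
enum { G_CZ_AC = 0, G_R_AC, G_CZ_PC, G_R_PC, G_CZ_AL, G_R_AL, G_CZ_PL, G_R_PL,
       G_CZ_RET, G_R_RET, G_PUPIL_Z, G_PUPIL_R, G_N_COR, G_N_AQ, G_N_VIT,
       G_APERTURE };

// Intersect ray p + t d with a sphere centered on the axis at (0,0,cz),
// radius R. cap_sign selects the cap: hits must satisfy
// sign(hit.z - cz) == cap_sign. Returns smallest positive t on that cap with
// radial distance from the axis <= max_rad, or -1.
double intersect_sphere(const Vec3& p, const Vec3& d, double cz, double R,
                        int cap_sign, double max_rad) {
  Vec3 oc = {p.x, p.y, p.z - cz};
  double b = dot(d, oc);
  double c = dot(oc, oc) - R * R;
  double disc = b * b - c;
  if (disc < 0) return -1.0;
  double sq = std::sqrt(disc);
  double roots[2] = {-b - sq, -b + sq};
  for (int k = 0; k < 2; ++k) {
    double t = roots[k];
    if (t < 1e-9) continue;
    Vec3 h = p + t * d;
    if (cap_sign > 0 && h.z - cz <= 0) continue;
    if (cap_sign < 0 && h.z - cz >= 0) continue;
    if (std::sqrt(h.x * h.x + h.y * h.y) > max_rad) continue;
    return t;
  }
  return -1.0;
}

// Snell refraction. normal need not be oriented; it is flipped to face the
// incoming ray. Returns false on total internal reflection.
bool refract_dir(const Vec3& d, Vec3 n, double n1, double n2, Vec3& out) {
  double ci = -dot(d, n);
  if (ci < 0) { n = -1.0 * n; ci = -ci; }
  double eta = n1 / n2;
  double st2 = eta * eta * (1.0 - ci * ci);
  if (st2 > 1.0) return false;
  double ct = std::sqrt(1.0 - st2);
  out = unit(eta * d + (eta * ci - ct) * n);
  return true;
}

struct Lattice {
  const double* v;     // index values, filled on all nodes
  double ox, oy, oz;   // node 0 position
  double h;            // node spacing
  int nx, ny, nz;
  std::vector<double> lx, ly, lz;  // gradient of log(v) per node
};

inline int idx(const Lattice& L, int i, int j, int k) {
  return i + L.nx * (j + L.ny * k);
}

void build_log_gradient(Lattice& L) {
  int n = L.nx * L.ny * L.nz;
  std::vector<double> lg(n);
  for (int i = 0; i < n; ++i) lg[i] = std::log(L.v[i]);
  L.lx.assign(n, 0.0); L.ly.assign(n, 0.0); L.lz.assign(n, 0.0);
  for (int k = 0; k < L.nz; ++k)
    for (int j = 0; j < L.ny; ++j)
      for (int i = 0; i < L.nx; ++i) {
        int c = idx(L, i, j, k);
        int ip = (i + 1 < L.nx) ? i + 1 : i, im = (i > 0) ? i - 1 : i;
        int jp = (j + 1 < L.ny) ? j + 1 : j, jm = (j > 0) ? j - 1 : j;
        int kp = (k + 1 < L.nz) ? k + 1 : k, km = (k > 0) ? k - 1 : k;
        L.lx[c] = (lg[idx(L, ip, j, k)] - lg[idx(L, im, j, k)]) / ((ip - im) * L.h);
        L.ly[c] = (lg[idx(L, i, jp, k)] - lg[idx(L, i, jm, k)]) / ((jp - jm) * L.h);
        L.lz[c] = (lg[idx(L, i, j, kp)] - lg[idx(L, i, j, km)]) / ((kp - km) * L.h);
      }
}

// Fused trilinear interpolation of the three log-gradient components.
Vec3 trilin_grad(const Lattice& L, const Vec3& p) {
  double fx = (p.x - L.ox) / L.h, fy = (p.y - L.oy) / L.h, fz = (p.z - L.oz) / L.h;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  if (i < 0) i = 0; if (i > L.nx - 2) i = L.nx - 2;
  if (j < 0) j = 0; if (j > L.ny - 2) j = L.ny - 2;
  if (k < 0) k = 0; if (k > L.nz - 2) k = L.nz - 2;
  double wx = fx - i, wy = fy - j, wz = fz - k;
  wx = wx < 0 ? 0 : (wx > 1 ? 1 : wx);
  wy = wy < 0 ? 0 : (wy > 1 ? 1 : wy);
  wz = wz < 0 ? 0 : (wz > 1 ? 1 : wz);
  Vec3 out = {0, 0, 0};
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
        int c = idx(L, i + di, j + dj, k + dk);
        out.x += w * L.lx[c];
        out.y += w * L.ly[c];
        out.z += w * L.lz[c];
      }
  return out;
}

// Trilinear interpolation of a per-node field at position p.
double trilin(const Lattice& L, const std::vector<double>& f, const Vec3& p) {
  double fx = (p.x - L.ox) / L.h, fy = (p.y - L.oy) / L.h, fz = (p.z - L.oz) / L.h;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  if (i < 0) i = 0; if (i > L.nx - 2) i = L.nx - 2;
  if (j < 0) j = 0; if (j > L.ny - 2) j = L.ny - 2;
  if (k < 0) k = 0; if (k > L.nz - 2) k = L.nz - 2;
  double wx = fx - i, wy = fy - j, wz = fz - k;
  wx = wx < 0 ? 0 : (wx > 1 ? 1 : wx);
  wy = wy < 0 ? 0 : (wy > 1 ? 1 : wy);
  wz = wz < 0 ? 0 : (wz > 1 ? 1 : wz);
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
        out += w * f[idx(L, i + di, j + dj, k + dk)];
      }
  return out;
}

double trilin_vals(const Lattice& L, const Vec3& p) {
  double fx = (p.x - L.ox) / L.h, fy = (p.y - L.oy) / L.h, fz = (p.z - L.oz) / L.h;
  int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
  if (i < 0) i = 0; if (i > L.nx - 2) i = L.nx - 2;
  if (j < 0) j = 0; if (j > L.ny - 2) j = L.ny - 2;
  if (k < 0) k = 0; if (k > L.nz - 2) k = L.nz - 2;
  double wx = fx - i, wy = fy - j, wz = fz - k;
  wx = wx < 0 ? 0 : (wx > 1 ? 1 : wx);
  wy = wy < 0 ? 0 : (wy > 1 ? 1 : wy);
  wz = wz < 0 ? 0 : (wz > 1 ? 1 : wz);
  double out = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        double w = (di ? wx : 1 - wx) * (dj ? wy : 1 - wy) * (dk ? wz : 1 - wz);
        out += w * L.v[idx(L, i + di, j + dj, k + dk)];
      }
  return out;
}

inline bool in_lens(const NumericVector& g, const Vec3& p) {
  Vec3 ca = {0, 0, g[G_CZ_AL]}, cp = {0, 0, g[G_CZ_PL]};
  return norm(p - ca) <= g[G_R_AL] && norm(p - cp) <= g[G_R_PL];
}

// Step-wise GRIN propagation from a point inside the lens; stops when the ray
// leaves the lens body. On return p/d hold the boundary point and direction;
// returns +1 for posterior exit, -1 for anterior exit, 0 if lost.
int grin_transit(const NumericVector& g, const Lattice& L, double step,
                 Vec3& p, Vec3& d, int max_steps = 6000) {
  for (int it = 0; it < max_steps; ++it) {
    Vec3 p_prev = p, d_prev = d;
    p = p + step * d;
    Vec3 grad = trilin_grad(L, p);
    d = unit(d + step * grad);
    if (!in_lens(g, p)) {
      // bisect the last segment to the boundary
      Vec3 a = p_prev, b = p;
      for (int bi = 0; bi < 30; ++bi) {
        Vec3 m = 0.5 * (a + b);
        if (in_lens(g, m)) a = m; else b = m;
      }
      p = b;
      d = d_prev;  // direction on the segment that crossed
      Vec3 cpost = {0, 0, g[G_CZ_PL]};
      if (norm(p - cpost) >= g[G_R_PL] - 1e-6) return 1;
      return -1;
    }
  }
  return 0;
}

// status codes shared with R: 0 ok, 1 miss, 2 pupil-blocked, 3 TIR,
// 4 side-exit, 5 lost
const int OK = 0, MISS = 1, BLOCKED = 2, TIR = 3, SIDE = 4, LOST = 5;

bool pupil_pass(const NumericVector& g, Vec3& p, const Vec3& d) {
  // advance to the pupil plane and test the stop; p is updated to the plane
  if (std::fabs(d.z) < 1e-12) return false;
  double t = (g[G_PUPIL_Z] - p.z) / d.z;
  if (t < -1e-6) return true;  // plane already passed (shouldn't happen)
  Vec3 h = p + t * d;
  if (std::sqrt(h.x * h.x + h.y * h.y) > g[G_PUPIL_R]) return false;
  p = h;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List trace_rays_cpp(NumericMatrix origin, NumericMatrix dir, NumericVector geom,
                    int lens_type, double n_const, NumericVector lat_vals,
                    NumericVector lat_origin, double lat_h,
                    IntegerVector lat_dim, double step, bool backward) {
  int n = origin.nrow();
  IntegerVector status(n);
  NumericMatrix exit_pos(n, 3), exit_dir(n, 3), retina_pos(n, 3);
  std::fill(retina_pos.begin(), retina_pos.end(), NA_REAL);

  Lattice L;
  if (lens_type == 1) {
    L.v = REAL(lat_vals);
    L.ox = lat_origin[0]; L.oy = lat_origin[1]; L.oz = lat_origin[2];
    L.h = lat_h; L.nx = lat_dim[0]; L.ny = lat_dim[1]; L.nz = lat_dim[2];
    build_log_gradient(L);
  }

  const NumericVector& g = geom;
  for (int r = 0; r < n; ++r) {
    Vec3 p = {origin(r, 0), origin(r, 1), origin(r, 2)};
    Vec3 d = unit({dir(r, 0), dir(r, 1), dir(r, 2)});
    int st = OK;

    if (!backward) {
      // air -> anterior cornea
      double t = intersect_sphere(p, d, g[G_CZ_AC], g[G_R_AC], -1, g[G_APERTURE]);
      if (t < 0) { status[r] = MISS; continue; }
      p = p + t * d;
      Vec3 nrm = unit(p - Vec3{0, 0, g[G_CZ_AC]});
      if (!refract_dir(d, nrm, 1.0, g[G_N_COR], d)) { status[r] = TIR; continue; }
      // cornea -> aqueous
      t = intersect_sphere(p, d, g[G_CZ_PC], g[G_R_PC], -1, g[G_APERTURE]);
      if (t < 0) { status[r] = MISS; continue; }
      p = p + t * d;
      nrm = unit(p - Vec3{0, 0, g[G_CZ_PC]});
      if (!refract_dir(d, nrm, g[G_N_COR], g[G_N_AQ], d)) { status[r] = TIR; continue; }
      // pupil stop
      if (!pupil_pass(g, p, d)) { status[r] = BLOCKED; continue; }
      // aqueous -> lens
      t = intersect_sphere(p, d, g[G_CZ_AL], g[G_R_AL], -1, g[G_R_AL] * 2);
      if (t < 0) { status[r] = MISS; continue; }
      p = p + t * d;
      nrm = unit(p - Vec3{0, 0, g[G_CZ_AL]});
      double n_in = (lens_type == 0) ? n_const : trilin_vals(L, p);
      if (!refract_dir(d, nrm, g[G_N_AQ], n_in, d)) { status[r] = TIR; continue; }
      // transit
      double n_exit = n_in;
      if (lens_type == 0) {
        t = intersect_sphere(p, d, g[G_CZ_PL], g[G_R_PL], 1, g[G_R_PL] * 2);
        if (t < 0) { status[r] = SIDE; continue; }
        p = p + t * d;
      } else {
        // nudge inside, then step
        p = p + 1e-3 * d;
        int ex = grin_transit(g, L, step, p, d);
        if (ex == 0) { status[r] = LOST; continue; }
        if (ex < 0) { status[r] = SIDE; continue; }
        n_exit = trilin_vals(L, p);
      }
      nrm = unit(p - Vec3{0, 0, g[G_CZ_PL]});
      if (!refract_dir(d, nrm, n_exit, g[G_N_VIT], d)) { status[r] = TIR; continue; }
      exit_pos(r, 0) = p.x; exit_pos(r, 1) = p.y; exit_pos(r, 2) = p.z;
      exit_dir(r, 0) = d.x; exit_dir(r, 1) = d.y; exit_dir(r, 2) = d.z;
      // vitreous -> retina
      t = intersect_sphere(p, d, g[G_CZ_RET], g[G_R_RET], 1, g[G_R_RET] * 2);
      if (t >= 0) {
        Vec3 h = p + t * d;
        retina_pos(r, 0) = h.x; retina_pos(r, 1) = h.y; retina_pos(r, 2) = h.z;
      }
      status[r] = st;
    } else {
      // back-trace: retina -> posterior lens
      double t = intersect_sphere(p, d, g[G_CZ_PL], g[G_R_PL], 1, g[G_R_PL] * 2);
      if (t < 0) { status[r] = MISS; continue; }
      p = p + t * d;
      Vec3 nrm = unit(p - Vec3{0, 0, g[G_CZ_PL]});
      double n_in = (lens_type == 0) ? n_const : trilin_vals(L, p);
      if (!refract_dir(d, nrm, g[G_N_VIT], n_in, d)) { status[r] = TIR; continue; }
      double n_exit = n_in;
      if (lens_type == 0) {
        t = intersect_sphere(p, d, g[G_CZ_AL], g[G_R_AL], -1, g[G_R_AL] * 2);
        if (t < 0) { status[r] = SIDE; continue; }
        p = p + t * d;
      } else {
        p = p + 1e-3 * d;
        int ex = grin_transit(g, L, step, p, d);
        if (ex == 0) { status[r] = LOST; continue; }
        if (ex > 0) { status[r] = SIDE; continue; }
        n_exit = trilin_vals(L, p);
      }
      nrm = unit(p - Vec3{0, 0, g[G_CZ_AL]});
      if (!refract_dir(d, nrm, n_exit, g[G_N_AQ], d)) { status[r] = TIR; continue; }
      // pupil stop (traveling -z)
      if (!pupil_pass(g, p, d)) { status[r] = BLOCKED; continue; }
      // aqueous -> cornea
      t = intersect_sphere(p, d, g[G_CZ_PC], g[G_R_PC], -1, g[G_APERTURE]);
      if (t < 0) { status[r] = MISS; continue; }
      p = p + t * d;
      nrm = unit(p - Vec3{0, 0, g[G_CZ_PC]});
      if (!refract_dir(d, nrm, g[G_N_AQ], g[G_N_COR], d)) { status[r] = TIR; continue; }
      // cornea -> air
      t = intersect_sphere(p, d, g[G_CZ_AC], g[G_R_AC], -1, g[G_APERTURE]);
      if (t < 0) { status[r] = MISS; continue; }
      p = p + t * d;
      nrm = unit(p - Vec3{0, 0, g[G_CZ_AC]});
      if (!refract_dir(d, nrm, g[G_N_COR], 1.0, d)) { status[r] = TIR; continue; }
      exit_pos(r, 0) = p.x; exit_pos(r, 1) = p.y; exit_pos(r, 2) = p.z;
      exit_dir(r, 0) = d.x; exit_dir(r, 1) = d.y; exit_dir(r, 2) = d.z;
      status[r] = OK;
    }
  }
  return List::create(_["status"] = status, _["exit_pos"] = exit_pos,
                      _["exit_dir"] = exit_dir, _["retina_pos"] = retina_pos);
}

// Single-ray GRIN path for convergence and reversibility checks. The ray
// starts inside the lens; the path (including the boundary point) is returned.
// [[Rcpp::export]]
List grin_path_cpp(NumericVector origin, NumericVector dir, NumericVector geom,
                   NumericVector lat_vals, NumericVector lat_origin,
                   double lat_h, IntegerVector lat_dim, double step,
                   int max_steps) {
  Lattice L;
  L.v = REAL(lat_vals);
  L.ox = lat_origin[0]; L.oy = lat_origin[1]; L.oz = lat_origin[2];
  L.h = lat_h; L.nx = lat_dim[0]; L.ny = lat_dim[1]; L.nz = lat_dim[2];
  build_log_gradient(L);
  Vec3 p = {origin[0], origin[1], origin[2]};
  Vec3 d = unit({dir[0], dir[1], dir[2]});
  std::vector<double> path;
  path.push_back(p.x); path.push_back(p.y); path.push_back(p.z);
  int exit_code = 0;
  for (int it = 0; it < max_steps; ++it) {
    Vec3 p_prev = p, d_prev = d;
    p = p + step * d;
    Vec3 grad = trilin_grad(L, p);
    d = unit(d + step * grad);
    if (!in_lens(geom, p)) {
      Vec3 a = p_prev, b = p;
      for (int bi = 0; bi < 30; ++bi) {
        Vec3 m = 0.5 * (a + b);
        if (in_lens(geom, m)) a = m; else b = m;
      }
      p = b; d = d_prev;
      Vec3 cpost = {0, 0, geom[G_CZ_PL]};
      exit_code = (norm(p - cpost) >= geom[G_R_PL] - 1e-6) ? 1 : -1;
      path.push_back(p.x); path.push_back(p.y); path.push_back(p.z);
      break;
    }
    path.push_back(p.x); path.push_back(p.y); path.push_back(p.z);
  }
  int np = path.size() / 3;
  NumericMatrix pm(np, 3);
  for (int i = 0; i < np; ++i) {
    pm(i, 0) = path[3 * i]; pm(i, 1) = path[3 * i + 1]; pm(i, 2) = path[3 * i + 2];
  }
  return List::create(_["path"] = pm, _["exit_code"] = exit_code,
                      _["dir"] = NumericVector::create(d.x, d.y, d.z));
}
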