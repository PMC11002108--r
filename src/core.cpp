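#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cubic B-spline basis
// ---------------------------------------------------------------------------

static inline void bspline_w(double u, double* w) {
  const double v = 1.0 - u;
  w[0] = v * v * v / 6.0;
  w[1] = (3.0 * u * u * u - 6.0 * u * u + 4.0) / 6.0;
  w[2] = (-3.0 * u * u * u + 3.0 * u * u + 3.0 * u + 1.0) / 6.0;
  w[3] = u * u * u / 6.0;
}

static inline void bspline_dw(double u, double* w) {
  const double v = 1.0 - u;
  w[0] = -v * v / 2.0;
  w[1] = (3.0 * u * u - 4.0 * u) / 2.0;
  w[2] = (-3.0 * u * u + 2.0 * u + 1.0) / 2.0;
  w[3] = u * u / 2.0;
}

// Periodic temporal basis: weight of each of nt control points at time t,
// period F frames.  CP k peaks at t = k * F / nt.
static void temporal_weights(double t, double F, int nt, std::vector<double>& w) {
  std::fill(w.begin(), w.end(), 0.0);
  double s = t * nt / F;
  double fs = std::floor(s);
  double u = s - fs;
  int ib = (int)fs;
  double b[4];
  bspline_w(u, b);
  for (int j = 0; j < 4; ++j) {
    int k = ib - 1 + j;
    k %= nt; if (k < 0) k += nt;
    w[k] += b[j];
  }
}

// ---------------------------------------------------------------------------
// Lattice level handling
// ---------------------------------------------------------------------------

struct Level {
  double org[3], sp[3];
  int dm[3];
  int nt;
  int ncp;
  const double* coef;         // [cp + ncp*(k + nt*comp)]
  std::vector<double> ceff;   // collapsed [cp*3] for current frame pair (t,0)
  std::vector<double> wt;     // wt_eff per temporal CP for current frame
};

static void parse_levels(List levels, std::vector<Level>& L) {
  int nl = levels.size();
  L.resize(nl);
  for (int l = 0; l < nl; ++l) {
    List lv = levels[l];
    NumericVector org = lv["origin"], sp = lv["spacing"];
    IntegerVector dm = lv["dims"];
    NumericVector cf = lv["coef"];
    for (int a = 0; a < 3; ++a) { L[l].org[a] = org[a]; L[l].sp[a] = sp[a]; L[l].dm[a] = dm[a]; }
    L[l].nt = as<int>(lv["n_temporal"]);
    L[l].ncp = dm[0] * dm[1] * dm[2];
    L[l].coef = REAL(cf);
  }
}

// Collapse temporal coefficients for time t (with reference-frame subtraction
// of t = 0), storing wt_eff and ceff in the level.
static void collapse_level(Level& lv, double t, double F) {
  int nt = lv.nt, ncp = lv.ncp;
  std::vector<double> w0(nt), wt(nt);
  temporal_weights(0.0, F, nt, w0);
  temporal_weights(t, F, nt, wt);
  lv.wt.resize(nt);
  for (int k = 0; k < nt; ++k) lv.wt[k] = wt[k] - w0[k];
  lv.ceff.assign((size_t)ncp * 3, 0.0);
  for (int comp = 0; comp < 3; ++comp) {
    for (int k = 0; k < nt; ++k) {
      double wk = lv.wt[k];
      if (wk == 0.0) continue;
      const double* c = lv.coef + (size_t)ncp * (k + (size_t)nt * comp);
      double* o = lv.ceff.data() + (size_t)ncp * comp;
      for (int cp = 0; cp < ncp; ++cp) o[cp] += wk * c[cp];
    }
  }
}

// Spatial support weights at point x: fills 64 (or fewer in 2D) weights and
// control-point indices; returns false if x outside the lattice support.
struct SpatialW {
  int idx[64];
  double w[64];
  int n;
};

static bool spatial_weights(const Level& lv, const double* x, SpatialW& sw) {
  double wx[3][4];
  int base[3], nb[3];
  for (int a = 0; a < 3; ++a) {
    if (lv.dm[a] == 1) { base[a] = 0; nb[a] = 1; wx[a][0] = 1.0; continue; }
    double s = (x[a] - lv.org[a]) / lv.sp[a];
    if (s < -1e-9 || s > lv.dm[a] - 3 + 1e-9) return false;
    if (s < 0) s = 0;
    double fs = std::floor(s);
    int ib = (int)fs;
    if (ib > lv.dm[a] - 4) ib = lv.dm[a] - 4;
    double u = s - ib;
    bspline_w(u, wx[a]);
    base[a] = ib;
    nb[a] = 4;
  }
  int n = 0;
  int nx = lv.dm[0], ny = lv.dm[1];
  for (int k = 0; k < nb[2]; ++k)
    for (int j = 0; j < nb[1]; ++j) {
      double wjk = wx[1][j] * wx[2][k];
      int off = (base[2] + k) * nx * ny + (base[1] + j) * nx + base[0];
      for (int i = 0; i < nb[0]; ++i) {
        sw.idx[n] = off + i;
        sw.w[n] = wx[0][i] * wjk;
        ++n;
      }
    }
  sw.n = n;
  return true;
}

// Displacement at x from all (collapsed) levels. Returns false if outside
// every level's support.
static bool disp_at(std::vector<Level>& L, const double* x, double* u) {
  u[0] = u[1] = u[2] = 0.0;
  bool any = false;
  SpatialW sw;
  for (size_t l = 0; l < L.size(); ++l) {
    if (!spatial_weights(L[l], x, sw)) continue;
    any = true;
    const double* c0 = L[l].ceff.data();
    const double* c1 = c0 + L[l].ncp;
    const double* c2 = c1 + L[l].ncp;
    double a = 0, b = 0, c = 0;
    for (int m = 0; m < sw.n; ++m) {
      double w = sw.w[m]; int id = sw.idx[m];
      a += w * c0[id]; b += w * c1[id]; c += w * c2[id];
    }
    u[0] += a; u[1] += b; u[2] += c;
  }
  return any;
}

// [[Rcpp::export]]
List eval_displacement_cpp(List levels, NumericMatrix pts, double t, double F) {
  std::vector<Level> L;
  parse_levels(levels, L);
  for (size_t l = 0; l < L.size(); ++l) collapse_level(L[l], t, F);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  LogicalVector outside(n);
  double x[3], u[3];
  for (int i = 0; i < n; ++i) {
    x[0] = pts(i, 0); x[1] = pts(i, 1); x[2] = pts(i, 2);
    bool in = disp_at(L, x, u);
    out(i, 0) = u[0]; out(i, 1) = u[1]; out(i, 2) = u[2];
    outside[i] = !in;
  }
  return List::create(_["u"] = out, _["outside"] = outside);
}

// [[Rcpp::export]]
NumericVector temporal_weights_cpp(double t, double F, int nt) {
  std::vector<double> w(nt);
  temporal_weights(t, F, nt, w);
  return NumericVector(w.begin(), w.end());
}

// ---------------------------------------------------------------------------
// Image sampling
// ---------------------------------------------------------------------------

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample of a volume (voxel-index coordinates, clamped).
static double trilerp(const double* img, const int* dm, double ix, double iy, double iz) {
  ix = clampd(ix, 0.0, dm[0] - 1.0);
  iy = clampd(iy, 0.0, dm[1] - 1.0);
  iz = clampd(iz, 0.0, dm[2] - 1.0);
  int x0 = (int)ix, y0 = (int)iy, z0 = (int)iz;
  if (x0 > dm[0] - 2) x0 = std::max(dm[0] - 2, 0);
  if (y0 > dm[1] - 2) y0 = std::max(dm[1] - 2, 0);
  if (z0 > dm[2] - 2) z0 = std::max(dm[2] - 2, 0);
  double fx = ix - x0, fy = iy - y0, fz = iz - z0;
  int x1 = std::min(x0 + 1, dm[0] - 1);
  int y1 = std::min(y0 + 1, dm[1] - 1);
  int z1 = std::min(z0 + 1, dm[2] - 1);
  size_t nxy = (size_t)dm[0] * dm[1];
#define VOX(i, j, k) img[(size_t)(k) * nxy + (size_t)(j) * dm[0] + (i)]
  double c00 = VOX(x0, y0, z0) * (1 - fx) + VOX(x1, y0, z0) * fx;
  double c10 = VOX(x0, y1, z0) * (1 - fx) + VOX(x1, y1, z0) * fx;
  double c01 = VOX(x0, y0, z1) * (1 - fx) + VOX(x1, y0, z1) * fx;
  double c11 = VOX(x0, y1, z1) * (1 - fx) + VOX(x1, y1, z1) * fx;
#undef VOX
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Central-difference gradient volumes (per mm).
static void grad_volumes(const double* img, const int* dm, const double* sp,
                         std::vector<double>& gx, std::vector<double>& gy,
                         std::vector<double>& gz) {
  size_t n = (size_t)dm[0] * dm[1] * dm[2];
  gx.assign(n, 0.0); gy.assign(n, 0.0); gz.assign(n, 0.0);
  size_t nxy = (size_t)dm[0] * dm[1];
  for (int z = 0; z < dm[2]; ++z)
    for (int y = 0; y < dm[1]; ++y)
      for (int x = 0; x < dm[0]; ++x) {
        size_t id = (size_t)z * nxy + (size_t)y * dm[0] + x;
        int xp = std::min(x + 1, dm[0] - 1), xm = std::max(x - 1, 0);
        int yp = std::min(y + 1, dm[1] - 1), ym = std::max(y - 1, 0);
        int zp = std::min(z + 1, dm[2] - 1), zm = std::max(z - 1, 0);
        gx[id] = (img[(size_t)z * nxy + (size_t)y * dm[0] + xp] -
                  img[(size_t)z * nxy + (size_t)y * dm[0] + xm]) / ((xp - xm) * sp[0]);
        gy[id] = (img[(size_t)z * nxy + (size_t)yp * dm[0] + x] -
                  img[(size_t)z * nxy + (size_t)ym * dm[0] + x]) / ((yp - ym) * sp[1]);
        if (dm[2] > 1)
          gz[id] = (img[(size_t)zp * nxy + (size_t)y * dm[0] + x] -
                    img[(size_t)zm * nxy + (size_t)y * dm[0] + x]) / ((zp - zm) * sp[2]);
      }
}

// [[Rcpp::export]]
NumericVector warp_image_cpp(NumericVector img, IntegerVector dims,
                             NumericVector origin, NumericVector spacing,
                             List levels, double t, double F) {
  std::vector<Level> L;
  parse_levels(levels, L);
  for (size_t l = 0; l < L.size(); ++l) collapse_level(L[l], t, F);
  int dm[3] = { dims[0], dims[1], dims[2] };
  size_t n = (size_t)dm[0] * dm[1] * dm[2];
  NumericVector out(n);
  const double* im = REAL(img);
  double x[3], u[3];
  size_t id = 0;
  for (int z = 0; z < dm[2]; ++z)
    for (int y = 0; y < dm[1]; ++y)
      for (int xx = 0; xx < dm[0]; ++xx, ++id) {
        x[0] = origin[0] + xx * spacing[0];
        x[1] = origin[1] + y * spacing[1];
        x[2] = origin[2] + z * spacing[2];
        disp_at(L, x, u);
        out[id] = trilerp(im, dm,
                          (x[0] - u[0] - origin[0]) / spacing[0],
                          (x[1] - u[1] - origin[1]) / spacing[1],
                          dm[2] == 1 ? 0.0 : (x[2] - u[2] - origin[2]) / spacing[2]);
      }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Regularisers: bending energy (squared second differences of the CP grids,
// per temporal CP and component) and smoothed L1 sparsity.
// ---------------------------------------------------------------------------

static double bending_level(const Level& lv, double* grad) {
  int nx = lv.dm[0], ny = lv.dm[1], nz = lv.dm[2];
  double hx = lv.sp[0], hy = lv.sp[1], hz = lv.sp[2];
  double cell = hx * hy * (nz > 1 ? hz : 1.0);
  double e = 0.0;
  int ncp = lv.ncp, nt = lv.nt;
  bool d3 = nz > 1;
  for (int comp = 0; comp < 3; ++comp)
    for (int k = 0; k < nt; ++k) {
      const double* c = lv.coef + (size_t)ncp * (k + (size_t)nt * comp);
      double* g = grad ? grad + (size_t)ncp * (k + (size_t)nt * comp) : 0;
#define C(i, j, l) c[(l) * nx * ny + (j) * nx + (i)]
#define G(i, j, l) g[(l) * nx * ny + (j) * nx + (i)]
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            // second differences, one-sided boundaries skipped
            if (x >= 1 && x <= nx - 2) {
              double d = (C(x - 1, y, z) - 2 * C(x, y, z) + C(x + 1, y, z)) / (hx * hx);
              e += cell * d * d;
              if (g) {
                double f = 2.0 * cell * d / (hx * hx);
                G(x - 1, y, z) += f; G(x, y, z) -= 2 * f; G(x + 1, y, z) += f;
              }
            }
            if (y >= 1 && y <= ny - 2) {
              double d = (C(x, y - 1, z) - 2 * C(x, y, z) + C(x, y + 1, z)) / (hy * hy);
              e += cell * d * d;
              if (g) {
                double f = 2.0 * cell * d / (hy * hy);
                G(x, y - 1, z) += f; G(x, y, z) -= 2 * f; G(x, y + 1, z) += f;
              }
            }
            if (d3 && z >= 1 && z <= nz - 2) {
              double d = (C(x, y, z - 1) - 2 * C(x, y, z) + C(x, y, z + 1)) / (hz * hz);
              e += cell * d * d;
              if (g) {
                double f = 2.0 * cell * d / (hz * hz);
                G(x, y, z - 1) += f; G(x, y, z) -= 2 * f; G(x, y, z + 1) += f;
              }
            }
            if (x >= 1 && x <= nx - 2 && y >= 1 && y <= ny - 2) {
              double d = (C(x + 1, y + 1, z) - C(x + 1, y - 1, z) -
                          C(x - 1, y + 1, z) + C(x - 1, y - 1, z)) / (4 * hx * hy);
              e += 2.0 * cell * d * d;
              if (g) {
                double f = 4.0 * cell * d / (4 * hx * hy);
                G(x + 1, y + 1, z) += f; G(x + 1, y - 1, z) -= f;
                G(x - 1, y + 1, z) -= f; G(x - 1, y - 1, z) += f;
              }
            }
            if (d3 && x >= 1 && x <= nx - 2 && z >= 1 && z <= nz - 2) {
              double d = (C(x + 1, y, z + 1) - C(x + 1, y, z - 1) -
                          C(x - 1, y, z + 1) + C(x - 1, y, z - 1)) / (4 * hx * hz);
              e += 2.0 * cell * d * d;
              if (g) {
                double f = 4.0 * cell * d / (4 * hx * hz);
                G(x + 1, y, z + 1) += f; G(x + 1, y, z - 1) -= f;
                G(x - 1, y, z + 1) -= f; G(x - 1, y, z - 1) += f;
              }
            }
            if (d3 && y >= 1 && y <= ny - 2 && z >= 1 && z <= nz - 2) {
              double d = (C(x, y + 1, z + 1) - C(x, y + 1, z - 1) -
                          C(x, y - 1, z + 1) + C(x, y - 1, z - 1)) / (4 * hy * hz);
              e += 2.0 * cell * d * d;
              if (g) {
                double f = 4.0 * cell * d / (4 * hy * hz);
                G(x, y + 1, z + 1) += f; G(x, y + 1, z - 1) -= f;
                G(x, y - 1, z + 1) -= f; G(x, y - 1, z - 1) += f;
              }
            }
          }
#undef C
#undef G
    }
  return e;
}

static double sparsity_level(const Level& lv, double eps, double* grad) {
  size_t n = (size_t)lv.ncp * lv.nt * 3;
  double s = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double c = lv.coef[i];
    double r = std::sqrt(c * c + eps * eps);
    s += r - eps;
    if (grad) grad[i] += c / r;
  }
  return s;
}

// [[Rcpp::export]]
List regularisers_cpp(List levels, double eps) {
  std::vector<Level> L;
  parse_levels(levels, L);
  double be = 0.0, sp = 0.0;
  for (size_t l = 0; l < L.size(); ++l) {
    be += bending_level(L[l], 0);
    sp += sparsity_level(L[l], eps, 0);
  }
  return List::create(_["bending_energy"] = be, _["sparsity"] = sp);
}

// ---------------------------------------------------------------------------
// Registration objective: sum over frames of -NMI(warped ED, frame_t)
// (Parzen-window joint histogram, cubic kernel on the moving axis) plus
// bending-energy and sparsity penalties.  Analytic gradient for one level.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List ffd_objective_cpp(List levels, NumericVector moving, IntegerVector dims,
                       NumericVector origin, NumericVector spacing,
                       List fixed_frames, NumericVector tvals, double F,
                       int bins, double sw_w, double be_w, double eps,
                       int active_level, double grad_thresh) {
  std::vector<Level> L;
  parse_levels(levels, L);
  int dm[3] = { dims[0], dims[1], dims[2] };
  size_t nvox = (size_t)dm[0] * dm[1] * dm[2];
  const double* mov = REAL(moving);
  double sp[3] = { spacing[0], spacing[1], spacing[2] };

  double mmin = mov[0], mmax = mov[0];
  for (size_t i = 1; i < nvox; ++i) {
    if (mov[i] < mmin) mmin = mov[i];
    if (mov[i] > mmax) mmax = mov[i];
  }
  bool mconst = (mmax - mmin) < 1e-12;
  double binw = mconst ? 1.0 : (mmax - mmin) / bins;

  std::vector<double> gx, gy, gz;
  bool want_grad = active_level >= 0;
  if (want_grad) grad_volumes(mov, dm, sp, gx, gy, gz);

  int nf = fixed_frames.size();
  NumericVector nmi_out(nf);

  // gradient accumulator for the active level
  NumericVector grad_out;
  double* grad = 0;
  Level* AL = 0;
  if (want_grad) {
    AL = &L[active_level];
    grad_out = NumericVector((size_t)AL->ncp * AL->nt * 3);
    grad = REAL(grad_out);
  }

  // per-voxel scratch for one frame
  std::vector<double> wv(nvox), mgx(nvox), mgy(nvox), mgz(nvox);
  std::vector<int> fb(nvox);
  std::vector<double> hist((size_t)bins * bins);
  std::vector<double> dndp((size_t)bins * bins);
  std::vector<double> Gt;

  double total = 0.0;

  for (int f = 0; f < nf; ++f) {
    NumericVector fx = fixed_frames[f];
    const double* fix = REAL(fx);
    double t = tvals[f];
    for (size_t l = 0; l < L.size(); ++l) collapse_level(L[l], t, F);

    double fmin = fix[0], fmax = fix[0];
    for (size_t i = 1; i < nvox; ++i) {
      if (fix[i] < fmin) fmin = fix[i];
      if (fix[i] > fmax) fmax = fix[i];
    }
    bool fconst = (fmax - fmin) < 1e-12;
    double fbinw = fconst ? 1.0 : (fmax - fmin) / bins;

    std::fill(hist.begin(), hist.end(), 0.0);

    // pass 1: warp, sample, histogram
    size_t id = 0;
    double x[3], u[3];
    for (int z = 0; z < dm[2]; ++z)
      for (int y = 0; y < dm[1]; ++y)
        for (int xx = 0; xx < dm[0]; ++xx, ++id) {
          x[0] = origin[0] + xx * sp[0];
          x[1] = origin[1] + y * sp[1];
          x[2] = origin[2] + z * sp[2];
          disp_at(L, x, u);
          double px = (x[0] - u[0] - origin[0]) / sp[0];
          double py = (x[1] - u[1] - origin[1]) / sp[1];
          double pz = dm[2] == 1 ? 0.0 : (x[2] - u[2] - origin[2]) / sp[2];
          double w = trilerp(mov, dm, px, py, pz);
          wv[id] = w;
          if (want_grad) {
            mgx[id] = trilerp(gx.data(), dm, px, py, pz);
            mgy[id] = trilerp(gy.data(), dm, px, py, pz);
            mgz[id] = dm[2] == 1 ? 0.0 : trilerp(gz.data(), dm, px, py, pz);
          }
          int fbin = fconst ? 0 : (int)((fix[id] - fmin) / fbinw);
          if (fbin > bins - 1) fbin = bins - 1;
          fb[id] = fbin;
          double mc = mconst ? 1.5 : (w - mmin) / binw;
          mc = clampd(mc, 1.0, bins - 2.0 - 1e-9);
          int base = (int)std::floor(mc) - 1;
          double uu = mc - std::floor(mc);
          double bw[4];
          bspline_w(uu, bw);
          double* h = hist.data() + (size_t)fbin * bins;
          h[base] += bw[0]; h[base + 1] += bw[1];
          h[base + 2] += bw[2]; h[base + 3] += bw[3];
        }

    // entropies
    double N = (double)nvox;
    double Hj = 0.0, Hm = 0.0, Hf = 0.0;
    std::vector<double> pm(bins, 0.0), pf(bins, 0.0);
    for (int j = 0; j < bins; ++j)
      for (int i = 0; i < bins; ++i) {
        double p = hist[(size_t)j * bins + i] / N;
        hist[(size_t)j * bins + i] = p;
        pm[i] += p; pf[j] += p;
        if (p > 0) Hj -= p * std::log(p);
      }
    for (int i = 0; i < bins; ++i) {
      if (pm[i] > 0) Hm -= pm[i] * std::log(pm[i]);
      if (pf[i] > 0) Hf -= pf[i] * std::log(pf[i]);
    }
    double nmi;
    if (Hj < 1e-12 || mconst || fconst) nmi = 1.0;
    else nmi = (Hm + Hf) / Hj;
    nmi_out[f] = nmi;
    total += -nmi;

    if (!want_grad || mconst || fconst || Hj < 1e-12) continue;

    // dNMI/dp table
    for (int j = 0; j < bins; ++j)
      for (int i = 0; i < bins; ++i) {
        double p = hist[(size_t)j * bins + i];
        double lp = p > 0 ? std::log(p) : 0.0;
        double lpm = pm[i] > 0 ? std::log(pm[i]) : 0.0;
        dndp[(size_t)j * bins + i] = (-(1.0 + lpm)) / Hj + nmi * (1.0 + lp) / Hj;
      }

    // pass 2: scatter to collapsed gradient of the active level, then expand
    Gt.assign((size_t)AL->ncp * 3, 0.0);
    id = 0;
    SpatialW swt;
    for (int z = 0; z < dm[2]; ++z)
      for (int y = 0; y < dm[1]; ++y)
        for (int xx = 0; xx < dm[0]; ++xx, ++id) {
          double gxl = mgx[id], gyl = mgy[id], gzl = mgz[id];
          if (std::fabs(gxl) < grad_thresh && std::fabs(gyl) < grad_thresh &&
              std::fabs(gzl) < grad_thresh) continue;
          double mc = (wv[id] - mmin) / binw;
          mc = clampd(mc, 1.0, bins - 2.0 - 1e-9);
          int base = (int)std::floor(mc) - 1;
          double uu = mc - std::floor(mc);
          double dbw[4];
          bspline_dw(uu, dbw);
          const double* dn = dndp.data() + (size_t)fb[id] * bins;
          double alpha = dn[base] * dbw[0] + dn[base + 1] * dbw[1] +
                         dn[base + 2] * dbw[2] + dn[base + 3] * dbw[3];
          double s = alpha / (N * binw);
          if (s == 0.0) continue;
          x[0] = origin[0] + xx * sp[0];
          x[1] = origin[1] + y * sp[1];
          x[2] = origin[2] + z * sp[2];
          if (!spatial_weights(*AL, x, swt)) continue;
          double g0 = s * gxl, g1 = s * gyl, g2 = s * gzl;
          double* G0 = Gt.data();
          double* G1 = G0 + AL->ncp;
          double* G2 = G1 + AL->ncp;
          for (int m = 0; m < swt.n; ++m) {
            double w = swt.w[m]; int cp = swt.idx[m];
            G0[cp] += w * g0; G1[cp] += w * g1; G2[cp] += w * g2;
          }
        }
    // expand over temporal CPs
    for (int comp = 0; comp < 3; ++comp) {
      const double* Gc = Gt.data() + (size_t)AL->ncp * comp;
      for (int k = 0; k < AL->nt; ++k) {
        double wk = AL->wt[k];
        if (wk == 0.0) continue;
        double* gr = grad + (size_t)AL->ncp * (k + (size_t)AL->nt * comp);
        for (int cp = 0; cp < AL->ncp; ++cp) gr[cp] += wk * Gc[cp];
      }
    }
  }

  // regularisers
  double be = 0.0, spv = 0.0;
  for (size_t l = 0; l < L.size(); ++l) {
    bool act = want_grad && (int)l == active_level;
    // temporary gradient buffers added directly into grad (scaled after)
    if (act) {
      size_t n = (size_t)L[l].ncp * L[l].nt * 3;
      std::vector<double> gb(n, 0.0), gs(n, 0.0);
      be += bending_level(L[l], gb.data());
      spv += sparsity_level(L[l], eps, gs.data());
      for (size_t i = 0; i < n; ++i) grad[i] += be_w * gb[i] + sw_w * gs[i];
    } else {
      be += bending_level(L[l], 0);
      spv += sparsity_level(L[l], eps, 0);
    }
  }
  total += be_w * be + sw_w * spv;

  List out = List::create(_["value"] = total, _["nmi"] = nmi_out,
                          _["bending_energy"] = be, _["sparsity"] = spv);
  if (want_grad) out["grad"] = grad_out;
  return out;
}

// ---------------------------------------------------------------------------
// Rasterisation: parity fill along x-rays through a closed triangle mesh.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector rasterize_mesh_cpp(NumericMatrix V, IntegerMatrix Tr,
                                 IntegerVector dims, NumericVector origin,
                                 NumericVector spacing, double inside_val,
                                 double outside_val) {
  int dm[3] = { dims[0], dims[1], dims[2] };
  size_t nvox = (size_t)dm[0] * dm[1] * dm[2];
  NumericVector out(nvox, outside_val);
  int ntri = Tr.nrow();
  // crossing lists per (y, z) ray
  std::vector<std::vector<double> > cross((size_t)dm[1] * dm[2]);
  const double jit = 1e-7;  // dodge exact edge hits (voxel units)
  for (int tr = 0; tr < ntri; ++tr) {
    double ax = V(Tr(tr, 0), 0), ay = V(Tr(tr, 0), 1), az = V(Tr(tr, 0), 2);
    double bx = V(Tr(tr, 1), 0), by = V(Tr(tr, 1), 1), bz = V(Tr(tr, 1), 2);
    double cx = V(Tr(tr, 2), 0), cy = V(Tr(tr, 2), 1), cz = V(Tr(tr, 2), 2);
    double ymin = std::min(ay, std::min(by, cy)), ymax = std::max(ay, std::max(by, cy));
    double zmin = std::min(az, std::min(bz, cz)), zmax = std::max(az, std::max(bz, cz));
    int j0 = std::max(0, (int)std::ceil((ymin - origin[1]) / spacing[1] - jit));
    int j1 = std::min(dm[1] - 1, (int)std::floor((ymax - origin[1]) / spacing[1] + jit));
    int k0 = std::max(0, (int)std::ceil((zmin - origin[2]) / spacing[2] - jit));
    int k1 = std::min(dm[2] - 1, (int)std::floor((zmax - origin[2]) / spacing[2] + jit));
    for (int k = k0; k <= k1; ++k) {
      double rz = origin[2] + k * spacing[2] + jit * spacing[2];
      for (int j = j0; j <= j1; ++j) {
        double ry = origin[1] + j * spacing[1] + jit * spacing[1];
        // solve barycentric in (y, z)
        double d = (by - ay) * (cz - az) - (bz - az) * (cy - ay);
        if (std::fabs(d) < 1e-14) continue;
        double l1 = ((ry - ay) * (cz - az) - (rz - az) * (cy - ay)) / d;
        double l2 = ((by - ay) * (rz - az) - (bz - az) * (ry - ay)) / d;
        if (l1 < 0 || l2 < 0 || l1 + l2 > 1) continue;
        double xh = ax + l1 * (bx - ax) + l2 * (cx - ax);
        cross[(size_t)k * dm[1] + j].push_back(xh);
      }
    }
  }
  size_t nxy = (size_t)dm[0] * dm[1];
  for (int k = 0; k < dm[2]; ++k)
    for (int j = 0; j < dm[1]; ++j) {
      std::vector<double>& cs = cross[(size_t)k * dm[1] + j];
      if (cs.empty()) continue;
      std::sort(cs.begin(), cs.end());
      size_t np = cs.size() / 2 * 2;  // drop unmatched tangential hit if odd
      for (size_t p = 0; p + 1 < np; p += 2) {
        int i0 = std::max(0, (int)std::ceil((cs[p] - origin[0]) / spacing[0]));
        int i1 = std::min(dm[0] - 1, (int)std::floor((cs[p + 1] - origin[0]) / spacing[0]));
        for (int i = i0; i <= i1; ++i)
          out[(size_t)k * nxy + (size_t)j * dm[0] + i] = inside_val;
      }
    }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector gaussian_blur3_cpp(NumericVector img, IntegerVector dims, double sigma_vox) {
  int dm[3] = { dims[0], dims[1], dims[2] };
  size_t n = (size_t)dm[0] * dm[1] * dm[2];
  if (sigma_vox <= 0) return clone(img);
  int r = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma_vox * sigma_vox)); s += k[i + r]; }
  for (int i = 0; i <= 2 * r; ++i) k[i] /= s;
  std::vector<double> a(REAL(img), REAL(img) + n), b(n);
  size_t nxy = (size_t)dm[0] * dm[1];
  // along each axis
  for (int axis = 0; axis < 3; ++axis) {
    if (dm[axis] == 1) continue;
    for (int z = 0; z < dm[2]; ++z)
      for (int y = 0; y < dm[1]; ++y)
        for (int x = 0; x < dm[0]; ++x) {
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int xi = x, yi = y, zi = z;
            if (axis == 0) xi = std::min(std::max(x + i, 0), dm[0] - 1);
            if (axis == 1) yi = std::min(std::max(y + i, 0), dm[1] - 1);
            if (axis == 2) zi = std::min(std::max(z + i, 0), dm[2] - 1);
            acc += k[i + r] * a[(size_t)zi * nxy + (size_t)yi * dm[0] + xi];
          }
          b[(size_t)z * nxy + (size_t)y * dm[0] + x] = acc;
        }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Point-to-triangle-mesh distances.
// ---------------------------------------------------------------------------

static double pt_seg_dist2(const double* p, const double* a, const double* b) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double denom = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
  double t = denom > 0 ? (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / denom : 0.0;
  t = clampd(t, 0.0, 1.0);
  double d0 = ap[0] - t * ab[0], d1 = ap[1] - t * ab[1], d2 = ap[2] - t * ab[2];
  return d0 * d0 + d1 * d1 + d2 * d2;
}

static double pt_tri_dist2(const double* p, const double* a, const double* b, const double* c) {
  double ab[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double ac[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double n[3] = { ab[1] * ac[2] - ab[2] * ac[1],
                  ab[2] * ac[0] - ab[0] * ac[2],
                  ab[0] * ac[1] - ab[1] * ac[0] };
  double nn = n[0] * n[0] + n[1] * n[1] + n[2] * n[2];
  if (nn > 1e-30) {
    double ap[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
    double dist = (ap[0] * n[0] + ap[1] * n[1] + ap[2] * n[2]) / std::sqrt(nn);
    double q[3] = { p[0] - dist * n[0] / std::sqrt(nn),
                    p[1] - dist * n[1] / std::sqrt(nn),
                    p[2] - dist * n[2] / std::sqrt(nn) };
    // barycentric test of projection q
    double aq[3] = { q[0] - a[0], q[1] - a[1], q[2] - a[2] };
    double d00 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
    double d01 = ab[0] * ac[0] + ab[1] * ac[1] + ab[2] * ac[2];
    double d11 = ac[0] * ac[0] + ac[1] * ac[1] + ac[2] * ac[2];
    double d20 = aq[0] * ab[0] + aq[1] * ab[1] + aq[2] * ab[2];
    double d21 = aq[0] * ac[0] + aq[1] * ac[1] + aq[2] * ac[2];
    double den = d00 * d11 - d01 * d01;
    if (den > 1e-30) {
      double v = (d11 * d20 - d01 * d21) / den;
      double w = (d00 * d21 - d01 * d20) / den;
      if (v >= 0 && w >= 0 && v + w <= 1) return dist * dist;
    }
  }
  double d = pt_seg_dist2(p, a, b);
  d = std::min(d, pt_seg_dist2(p, b, c));
  d = std::min(d, pt_seg_dist2(p, a, c));
  return d;
}

// [[Rcpp::export]]
NumericVector point_mesh_distance_cpp(NumericMatrix P, NumericMatrix V, IntegerMatrix Tr) {
  int np = P.nrow(), nt = Tr.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = { P(i, 0), P(i, 1), P(i, 2) };
    double best = R_PosInf;
    for (int t = 0; t < nt; ++t) {
      double a[3] = { V(Tr(t, 0), 0), V(Tr(t, 0), 1), V(Tr(t, 0), 2) };
      double b[3] = { V(Tr(t, 1), 0), V(Tr(t, 1), 1), V(Tr(t, 1), 2) };
      double c[3] = { V(Tr(t, 2), 0), V(Tr(t, 2), 1), V(Tr(t, 2), 2) };
      double d = pt_tri_dist2(p, a, b, c);
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Iso-level edge-crossing points (lightweight surface extraction).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix isosurface_points_cpp(NumericVector img, IntegerVector dims,
                                    NumericVector origin, NumericVector spacing,
                                    double level) {
  int dm[3] = { dims[0], dims[1], dims[2] };
  const double* im = REAL(img);
  size_t nxy = (size_t)dm[0] * dm[1];
  std::vector<double> pts;
  for (int z = 0; z < dm[2]; ++z)
    for (int y = 0; y < dm[1]; ++y)
      for (int x = 0; x < dm[0]; ++x) {
        double v0 = im[(size_t)z * nxy + (size_t)y * dm[0] + x];
        for (int axis = 0; axis < 3; ++axis) {
          int xi = x + (axis == 0), yi = y + (axis == 1), zi = z + (axis == 2);
          if (xi >= dm[0] || yi >= dm[1] || zi >= dm[2]) continue;
          double v1 = im[(size_t)zi * nxy + (size_t)yi * dm[0] + xi];
          if ((v0 - level) * (v1 - level) < 0) {
            double f = (level - v0) / (v1 - v0);
            double px = origin[0] + (x + f * (xi - x)) * spacing[0];
            double py = origin[1] + (y + f * (yi - y)) * spacing[1];
            double pz = origin[2] + (z + f * (zi - z)) * spacing[2];
            pts.push_back(px); pts.push_back(py); pts.push_back(pz);
          }
        }
      }
  int n = pts.size() / 3;
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = pts[3 * i];
    out(i, 1) = pts[3 * i + 1];
    out(i, 2) = pts[3 * i + 2];
  }
  return out;
}
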