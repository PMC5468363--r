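#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Compact molecular-mechanics energy + analytic gradient.
//
// Terms:
//   bonds:    harmonic,                E = k (r - r0)^2
//   angles:   cosine-harmonic,         E = k (cos t - cos t0)^2
//             (smooth at linearity, minima at +-t0)
//   torsions: periodic,                E = v (1 + cos(n phi + p))
//   vdW:      Lennard-Jones 12-6,      E = s d ((x/r)^12 - 2 (x/r)^6)
//   restraint (optional): per-atom flat-bottom positional well,
//             E = 0.5 k (d - radius)^2 for d > radius, else 0
//
// The restraint energy is accumulated separately so callers can report
// force-field energies that exclude the biasing term.

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// [[Rcpp::export(name = ".ff_eval")]]
List ff_eval(NumericMatrix coords,
             IntegerMatrix bonds, NumericVector b_r0, NumericVector b_k,
             IntegerMatrix angles, NumericVector a_cos0, NumericVector a_k,
             IntegerMatrix torsions, NumericVector t_v, NumericVector t_n,
             NumericVector t_p,
             IntegerMatrix vdw, NumericVector v_x, NumericVector v_d,
             NumericVector v_s,
             bool use_restraint, NumericMatrix ref, double radius,
             double rk) {
  const int n = coords.nrow();
  double e_ff = 0.0, e_res = 0.0;
  NumericMatrix grad(n, 3);
  const double EPS = 1e-12;

  // bonds
  for (int t = 0; t < bonds.nrow(); ++t) {
    int i = bonds(t, 0) - 1, j = bonds(t, 1) - 1;
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = coords(i, c) - coords(j, c); r2 += d[c] * d[c]; }
    double r = std::sqrt(r2 > EPS ? r2 : EPS);
    double dr = r - b_r0[t];
    e_ff += b_k[t] * dr * dr;
    double f = 2.0 * b_k[t] * dr / r;
    for (int c = 0; c < 3; ++c) { grad(i, c) += f * d[c]; grad(j, c) -= f * d[c]; }
  }

  // angles (i - j - k, j central)
  for (int t = 0; t < angles.nrow(); ++t) {
    int i = angles(t, 0) - 1, j = angles(t, 1) - 1, k = angles(t, 2) - 1;
    double u[3], v[3];
    double nu2 = 0.0, nv2 = 0.0;
    for (int c = 0; c < 3; ++c) {
      u[c] = coords(i, c) - coords(j, c);
      v[c] = coords(k, c) - coords(j, c);
      nu2 += u[c] * u[c]; nv2 += v[c] * v[c];
    }
    double nu = std::sqrt(nu2 > EPS ? nu2 : EPS);
    double nv = std::sqrt(nv2 > EPS ? nv2 : EPS);
    double ct = dot3(u, v) / (nu * nv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double diff = ct - a_cos0[t];
    e_ff += a_k[t] * diff * diff;
    double pref = 2.0 * a_k[t] * diff;
    for (int c = 0; c < 3; ++c) {
      double dcdi = v[c] / (nu * nv) - ct * u[c] / (nu * nu);
      double dcdk = u[c] / (nu * nv) - ct * v[c] / (nv * nv);
      grad(i, c) += pref * dcdi;
      grad(k, c) += pref * dcdk;
      grad(j, c) -= pref * (dcdi + dcdk);
    }
  }

  // torsions (i - j - k - l about bond j-k)
  for (int t = 0; t < torsions.nrow(); ++t) {
    int i = torsions(t, 0) - 1, j = torsions(t, 1) - 1;
    int k = torsions(t, 2) - 1, l = torsions(t, 3) - 1;
    double b1[3], b2[3], b3[3];
    for (int c = 0; c < 3; ++c) {
      b1[c] = coords(j, c) - coords(i, c);
      b2[c] = coords(k, c) - coords(j, c);
      b3[c] = coords(l, c) - coords(k, c);
    }
    double n1[3], n2[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    if (n1sq < EPS || n2sq < EPS) continue;  // collinear: torsion undefined
    double nb2 = std::sqrt(dot3(b2, b2));
    double m[3];
    cross3(n1, b2, m);
    double x = dot3(n1, n2);
    double y = dot3(m, n2) / nb2;
    double phi = std::atan2(y, x);
    double arg = t_n[t] * phi + t_p[t];
    e_ff += t_v[t] * (1.0 + std::cos(arg));
    double dEdphi = -t_v[t] * t_n[t] * std::sin(arg);
    // standard analytic dphi/dr (validated against finite differences)
    double dphidr1[3], dphidr4[3];
    for (int c = 0; c < 3; ++c) {
      dphidr1[c] = nb2 / n1sq * n1[c];
      dphidr4[c] = -nb2 / n2sq * n2[c];
    }
    double s12 = dot3(b1, b2) / (nb2 * nb2);
    double s32 = dot3(b3, b2) / (nb2 * nb2);
    for (int c = 0; c < 3; ++c) {
      double g1 = dphidr1[c];
      double g4 = dphidr4[c];
      double g2 = -(1.0 + s12) * g1 + s32 * g4;
      double g3 = s12 * g1 - (1.0 + s32) * g4;
      grad(i, c) += dEdphi * g1;
      grad(j, c) += dEdphi * g2;
      grad(k, c) += dEdphi * g3;
      grad(l, c) += dEdphi * g4;
    }
  }

  // van der Waals
  for (int t = 0; t < vdw.nrow(); ++t) {
    int i = vdw(t, 0) - 1, j = vdw(t, 1) - 1;
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = coords(i, c) - coords(j, c); r2 += d[c] * d[c]; }
    double r = std::sqrt(r2 > EPS ? r2 : EPS);
    double q = v_x[t] / r;
    double q6 = q * q * q; q6 = q6 * q6;
    double q12 = q6 * q6;
    double sd = v_s[t] * v_d[t];
    e_ff += sd * (q12 - 2.0 * q6);
    double dEdr = sd * (-12.0 * q12 + 12.0 * q6) / r;
    double f = dEdr / r;
    for (int c = 0; c < 3; ++c) { grad(i, c) += f * d[c]; grad(j, c) -= f * d[c]; }
  }

  // flat-bottom positional restraint
  if (use_restraint) {
    for (int i = 0; i < n; ++i) {
      double d[3], r2 = 0.0;
      for (int c = 0; c < 3; ++c) { d[c] = coords(i, c) - ref(i, c); r2 += d[c] * d[c]; }
      double r = std::sqrt(r2);
      if (r > radius) {
        double excess = r - radius;
        e_res += 0.5 * rk * excess * excess;
        double f = rk * excess / (r > EPS ? r : EPS);
        for (int c = 0; c < 3; ++c) grad(i, c) += f * d[c];
      }
    }
  }

  return List::create(_["energy"] = e_ff, _["restraint"] = e_res,
                      _["gradient"] = grad);
}
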