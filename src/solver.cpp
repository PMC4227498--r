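// Explicit central-difference solver over linear tetrahedra.
//
// Constant-strain tets, lumped mass, small-strain kinematics with an
// optional corotational frame (polar decomposition per element), linear
// elastic and one-term Prony viscoelastic stress updates (exact
// exponential recursion for the deviatoric memory), nodal volumetric-
// strain averaging against near-incompressible locking, surface-based
// hydrostatic fluid-cavity coupling (exact volume-gradient forces),
// prescribed force-pulse loading, rigid penalty-contact impactors
// (sphere or plane face), mass-proportional damping for relaxation runs,
// and a running energy audit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double det3(const double m[9]) {
  return m[0] * (m[4] * m[8] - m[5] * m[7])
       - m[1] * (m[3] * m[8] - m[5] * m[6])
       + m[2] * (m[3] * m[7] - m[4] * m[6]);
}

static bool inv3(const double m[9], double out[9]) {
  double d = det3(m);
  if (d == 0.0) return false;
  double id = 1.0 / d;
  out[0] = (m[4] * m[8] - m[5] * m[7]) * id;
  out[1] = (m[2] * m[7] - m[1] * m[8]) * id;
  out[2] = (m[1] * m[5] - m[2] * m[4]) * id;
  out[3] = (m[5] * m[6] - m[3] * m[8]) * id;
  out[4] = (m[0] * m[8] - m[2] * m[6]) * id;
  out[5] = (m[2] * m[3] - m[0] * m[5]) * id;
  out[6] = (m[3] * m[7] - m[4] * m[6]) * id;
  out[7] = (m[1] * m[6] - m[0] * m[7]) * id;
  out[8] = (m[0] * m[4] - m[1] * m[3]) * id;
  return true;
}

// Polar rotation factor of F by Higham iteration R <- (R + R^-T)/2.
static void polar_rotation(const double F[9], double R[9]) {
  for (int i = 0; i < 9; ++i) R[i] = F[i];
  double Ri[9], RiT[9];
  for (int it = 0; it < 12; ++it) {
    if (!inv3(R, Ri)) break;
    RiT[0] = Ri[0]; RiT[1] = Ri[3]; RiT[2] = Ri[6];
    RiT[3] = Ri[1]; RiT[4] = Ri[4]; RiT[5] = Ri[7];
    RiT[6] = Ri[2]; RiT[7] = Ri[5]; RiT[8] = Ri[8];
    double diff = 0.0;
    for (int i = 0; i < 9; ++i) {
      double nv = 0.5 * (R[i] + RiT[i]);
      diff += std::fabs(nv - R[i]);
      R[i] = nv;
    }
    if (diff < 1e-12) break;
  }
}

// Max principal value of a symmetric tensor in Voigt order
// (xx, yy, zz, xy, yz, xz).
static double max_principal_voigt(const double s[6]) {
  double p1 = s[3] * s[3] + s[4] * s[4] + s[5] * s[5];
  double q = (s[0] + s[1] + s[2]) / 3.0;
  if (p1 < 1e-300) {
    double m = s[0];
    if (s[1] > m) m = s[1];
    if (s[2] > m) m = s[2];
    return m;
  }
  double p2 = (s[0] - q) * (s[0] - q) + (s[1] - q) * (s[1] - q) +
              (s[2] - q) * (s[2] - q) + 2.0 * p1;
  double p = std::sqrt(p2 / 6.0);
  double B[9] = {(s[0] - q) / p, s[3] / p, s[5] / p,
                 s[3] / p, (s[1] - q) / p, s[4] / p,
                 s[5] / p, s[4] / p, (s[2] - q) / p};
  double r = det3(B) / 2.0;
  if (r < -1.0) r = -1.0;
  if (r > 1.0) r = 1.0;
  double phi = std::acos(r) / 3.0;
  return q + 2.0 * p * std::cos(phi);
}

static double von_mises_voigt(const double s[6]) {
  double m = (s[0] + s[1] + s[2]) / 3.0;
  double d0 = s[0] - m, d1 = s[1] - m, d2 = s[2] - m;
  return std::sqrt(1.5 * (d0 * d0 + d1 * d1 + d2 * d2) +
                   3.0 * (s[3] * s[3] + s[4] * s[4] + s[5] * s[5]));
}

// Per-element critical time step 2/omega_max with the element's own
// lumped mass (Irons' element eigenvalue theorem gives a rigorous bound
// on the assembled system's highest frequency). Power iteration on the
// 12x12 mass-normalised stiffness.
// [[Rcpp::export]]
NumericVector elem_critical_dt(NumericMatrix nodes, IntegerMatrix elems,
                               NumericVector lam, NumericVector mu,
                               NumericVector rho) {
  const int m = elems.nrow();
  NumericVector out(m);
  std::vector<double> K(144), z(12), zn(12);
  for (int e = 0; e < m; ++e) {
    double D[9];
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d)
        D[3 * d + k] = nodes(elems(e, k + 1), d) - nodes(elems(e, 0), d);
    double V = det3(D) / 6.0;
    double Di[9];
    inv3(D, Di);
    double g[12];
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) g[3 * (k + 1) + d] = Di[3 * k + d];
    for (int d = 0; d < 3; ++d) g[d] = -(g[3 + d] + g[6 + d] + g[9 + d]);
    // K[(k,i),(l,j)] = V (lam g_ki g_lj + mu g_kj g_li + mu dij g_k.g_l)
    for (int k = 0; k < 4; ++k)
      for (int l = 0; l < 4; ++l) {
        double gg = g[3 * k] * g[3 * l] + g[3 * k + 1] * g[3 * l + 1] +
                    g[3 * k + 2] * g[3 * l + 2];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            K[(3 * k + i) * 12 + (3 * l + j)] =
              V * (lam[e] * g[3 * k + i] * g[3 * l + j] +
                   mu[e] * g[3 * k + j] * g[3 * l + i] +
                   (i == j ? mu[e] * gg : 0.0));
      }
    double minv = 4.0 / (rho[e] * V);   // 1/(rho V / 4)
    for (int i = 0; i < 12; ++i) z[i] = 1.0 / (1.0 + i);
    double lam_max = 0.0;
    for (int it = 0; it < 60; ++it) {
      double nrm = 0.0;
      for (int i = 0; i < 12; ++i) {
        double s = 0.0;
        for (int j = 0; j < 12; ++j) s += K[i * 12 + j] * z[j];
        zn[i] = minv * s;               // M^-1 K z
        nrm += zn[i] * zn[i];
      }
      nrm = std::sqrt(nrm);
      if (nrm < 1e-300) { lam_max = 0.0; break; }
      double prev = lam_max;
      lam_max = nrm;
      for (int i = 0; i < 12; ++i) z[i] = zn[i] / nrm;
      if (it > 5 && std::fabs(lam_max - prev) < 1e-10 * lam_max) break;
    }
    out[e] = lam_max > 0 ? 2.0 / std::sqrt(1.02 * lam_max) : R_PosInf;
  }
  return out;
}

// [[Rcpp::export]]
List fe_explicit_run(NumericMatrix nodes0, IntegerMatrix elems,
                     IntegerVector etype, NumericMatrix eprops,
                     NumericVector mass,
                     IntegerMatrix cavtris, double cavV0, double cavKf,
                     IntegerVector lnodes, NumericVector lw,
                     NumericVector ldir, NumericVector pulse,
                     NumericVector bodyacc, double damping,
                     IntegerVector fixed, LogicalVector avg_el,
                     int vol_average, int corotational,
                     int imp_type, NumericVector imp_par,
                     NumericVector imp_x0, NumericVector imp_v0,
                     NumericVector imp_axis, IntegerVector contact_nodes,
                     LogicalVector brain_el, LogicalVector skull_el,
                     IntegerVector probe_el,
                     IntegerVector ndt_el, NumericMatrix ndt_bary,
                     IntegerVector track_nodes,
                     double dt, int nsteps, int out_every) {
  const int n = nodes0.nrow(), m = elems.nrow();
  const int np = probe_el.size(), nm = ndt_el.size(), nt = track_nodes.size();
  const int tc = cavtris.nrow();
  const bool has_cavity = tc > 0;

  // --- precompute element geometry ---
  std::vector<double> X0(3 * n), x(3 * n), v(3 * n, 0.0), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) X0[3 * i + d] = x[3 * i + d] = nodes0(i, d);

  std::vector<int> en(4 * m);
  for (int e = 0; e < m; ++e)
    for (int k = 0; k < 4; ++k) en[4 * e + k] = elems(e, k);

  std::vector<double> grad(12 * m), vol(m);
  for (int e = 0; e < m; ++e) {
    const int* nd = &en[4 * e];
    double D[9];
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d)
        D[3 * d + k] = X0[3 * nd[k + 1] + d] - X0[3 * nd[0] + d];
    double Dv = det3(D);
    vol[e] = Dv / 6.0;
    if (vol[e] <= 0.0) stop("element %d has non-positive volume", e + 1);
    double Di[9];
    inv3(D, Di);
    // grad N_k (k=1..3) = row k-1 of D^{-1}; grad N_0 = -sum
    double* g = &grad[12 * e];
    for (int k = 0; k < 3; ++k)
      for (int d = 0; d < 3; ++d) g[3 * (k + 1) + d] = Di[3 * k + d];
    for (int d = 0; d < 3; ++d)
      g[d] = -(g[3 + d] + g[6 + d] + g[9 + d]);
  }

  // per-element material constants
  std::vector<double> pa(m), pb(m);  // prony recursion factors
  for (int e = 0; e < m; ++e) {
    if (etype[e] == 1) {
      double beta = eprops(e, 4);
      double ex = std::exp(-beta * dt);
      pa[e] = ex;
      pb[e] = 2.0 * (eprops(e, 2) - eprops(e, 3)) * (1.0 - ex) / (beta * dt);
    }
  }

  std::vector<double> fcav(3 * n, 0.0);
  // deferred trapezoidal work accumulation
  std::vector<double> fint_prev(3 * n, 0.0), fext_prev(3 * n, 0.0),
      dx_prev(3 * n, 0.0);
  bool have_prev = false;
  std::vector<double> sig(6 * m, 0.0), strain(6 * m, 0.0);
  std::vector<double> hvar(6 * m, 0.0), eprev(6 * m, 0.0);
  std::vector<double> Rrot(corotational ? 9 * m : 0);
  std::vector<double> nv_num(n), nv_den(n);
  std::vector<char> isfixed(n, 0);
  for (int i = 0; i < fixed.size(); ++i) isfixed[fixed[i]] = 1;

  double Mtot = 0.0;
  for (int i = 0; i < n; ++i) Mtot += mass[i];

  // impactor state
  double impX[3] = {0, 0, 0}, impV[3] = {0, 0, 0};
  double impR = 0, impM = 1, impK = 0, axis[3] = {0, 0, 1};
  if (imp_type >= 0) {
    impR = imp_par[0]; impM = imp_par[1]; impK = imp_par[2];
    for (int d = 0; d < 3; ++d) {
      impX[d] = imp_x0[d]; impV[d] = imp_v0[d]; axis[d] = imp_axis[d];
    }
  }

  // energy bookkeeping
  double Wext = 0.0, Wint = 0.0, Wdamp = 0.0;
  double KE0 = 0.0;
  if (imp_type >= 0)
    KE0 = 0.5 * impM * (impV[0] * impV[0] + impV[1] * impV[1] + impV[2] * impV[2]);

  // output allocation
  int nout = nsteps / out_every + 1 + ((nsteps % out_every) ? 1 : 0);
  NumericVector t_out(nout), force_out(nout);
  NumericMatrix acc_out(nout, 4), en_out(nout, 6), cav_out(nout, 2);
  NumericMatrix probe_out(nout, np > 0 ? np : 1);
  NumericMatrix ndt_out(nout, nm > 0 ? 3 * nm : 1);
  NumericMatrix trk_out(nout, nt > 0 ? 3 * nt : 1);
  NumericMatrix imp_out(nout, 6);
  double vm_peak = 0, vm_time = 0; int vm_elem = -1;
  double ps_peak = -1e300, ps_time = 0; int ps_elem = -1;
  bool any_brain = false, any_skull = false;
  for (int e = 0; e < m; ++e) {
    if (brain_el[e]) any_brain = true;
    if (skull_el[e]) any_skull = true;
  }
  int orow = 0;

  std::vector<double> acc(3 * n, 0.0), fext(3 * n);

  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    // --- internal forces ---
    std::fill(f.begin(), f.end(), 0.0);
    std::fill(fext.begin(), fext.end(), 0.0);
    if (vol_average) {
      std::fill(nv_num.begin(), nv_num.end(), 0.0);
      std::fill(nv_den.begin(), nv_den.end(), 0.0);
    }

    // pass 1: strains
    for (int e = 0; e < m; ++e) {
      const int* nd = &en[4 * e];
      const double* g = &grad[12 * e];
      double H[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
      for (int k = 0; k < 4; ++k) {
        const double ux = x[3 * nd[k]] - X0[3 * nd[k]];
        const double uy = x[3 * nd[k] + 1] - X0[3 * nd[k] + 1];
        const double uz = x[3 * nd[k] + 2] - X0[3 * nd[k] + 2];
        H[0] += ux * g[3 * k]; H[1] += ux * g[3 * k + 1]; H[2] += ux * g[3 * k + 2];
        H[3] += uy * g[3 * k]; H[4] += uy * g[3 * k + 1]; H[5] += uy * g[3 * k + 2];
        H[6] += uz * g[3 * k]; H[7] += uz * g[3 * k + 1]; H[8] += uz * g[3 * k + 2];
      }
      double* eps = &strain[6 * e];
      if (corotational) {
        double F[9] = {H[0] + 1, H[1], H[2], H[3], H[4] + 1, H[5],
                       H[6], H[7], H[8] + 1};
        if (det3(F) <= 0.0)
          stop("element %d inverted at t = %g s", e + 1, t);
        double* R = &Rrot[9 * e];
        polar_rotation(F, R);
        // U = R^T F; strain = sym(U) - I
        double U[9];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double s = 0;
            for (int k = 0; k < 3; ++k) s += R[3 * k + i] * F[3 * k + j];
            U[3 * i + j] = s;
          }
        eps[0] = U[0] - 1; eps[1] = U[4] - 1; eps[2] = U[8] - 1;
        eps[3] = 0.5 * (U[1] + U[3]);
        eps[4] = 0.5 * (U[5] + U[7]);
        eps[5] = 0.5 * (U[2] + U[6]);
      } else {
        eps[0] = H[0]; eps[1] = H[4]; eps[2] = H[8];
        eps[3] = 0.5 * (H[1] + H[3]);
        eps[4] = 0.5 * (H[5] + H[7]);
        eps[5] = 0.5 * (H[2] + H[6]);
      }
      if (vol_average && avg_el[e]) {
        double ev = eps[0] + eps[1] + eps[2];
        for (int k = 0; k < 4; ++k) {
          nv_num[nd[k]] += vol[e] * ev;
          nv_den[nd[k]] += vol[e];
        }
      }
    }

    // pass 2: stress + internal force
    for (int e = 0; e < m; ++e) {
      const int* nd = &en[4 * e];
      const double* g = &grad[12 * e];
      double* eps = &strain[6 * e];
      double ev = eps[0] + eps[1] + eps[2];
      double evbar = ev;
      if (vol_average && avg_el[e]) {
        evbar = 0.0;
        for (int k = 0; k < 4; ++k)
          evbar += (nv_den[nd[k]] > 0.0) ? nv_num[nd[k]] / nv_den[nd[k]] : ev;
        evbar *= 0.25;
      }
      double s[6];
      if (etype[e] == 0) {             // elastic: lambda, mu
        double lam = eprops(e, 1), mu = eprops(e, 2);
        double lv = lam * evbar;
        s[0] = lv + 2.0 * mu * (eps[0] + (evbar - ev) / 3.0);
        s[1] = lv + 2.0 * mu * (eps[1] + (evbar - ev) / 3.0);
        s[2] = lv + 2.0 * mu * (eps[2] + (evbar - ev) / 3.0);
        s[3] = 2.0 * mu * eps[3];
        s[4] = 2.0 * mu * eps[4];
        s[5] = 2.0 * mu * eps[5];
      } else {                         // prony: K, G0, Ginf, beta
        double K = eprops(e, 1), Ginf = eprops(e, 3);
        double ed[6] = {eps[0] - ev / 3.0, eps[1] - ev / 3.0,
                        eps[2] - ev / 3.0, eps[3], eps[4], eps[5]};
        double* h = &hvar[6 * e];
        double* ep = &eprev[6 * e];
        for (int c = 0; c < 6; ++c) {
          h[c] = pa[e] * h[c] + pb[e] * (ed[c] - ep[c]);
          ep[c] = ed[c];
          s[c] = 2.0 * Ginf * ed[c] + h[c];
        }
        s[0] += K * evbar; s[1] += K * evbar; s[2] += K * evbar;
      }
      if (corotational) {
        const double* R = &Rrot[9 * e];
        double S[9] = {s[0], s[3], s[5], s[3], s[1], s[4], s[5], s[4], s[2]};
        double RS[9];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double a = 0;
            for (int k = 0; k < 3; ++k) a += R[3 * i + k] * S[3 * k + j];
            RS[3 * i + j] = a;
          }
        double G[9];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            double a = 0;
            for (int k = 0; k < 3; ++k) a += RS[3 * i + k] * R[3 * j + k];
            G[3 * i + j] = a;
          }
        s[0] = G[0]; s[1] = G[4]; s[2] = G[8];
        s[3] = 0.5 * (G[1] + G[3]);
        s[4] = 0.5 * (G[5] + G[7]);
        s[5] = 0.5 * (G[2] + G[6]);
      }
      double* se = &sig[6 * e];
      for (int c = 0; c < 6; ++c) se[c] = s[c];
      const double Ve = vol[e];
      for (int k = 0; k < 4; ++k) {
        const double gx = g[3 * k], gy = g[3 * k + 1], gz = g[3 * k + 2];
        f[3 * nd[k]]     -= Ve * (s[0] * gx + s[3] * gy + s[5] * gz);
        f[3 * nd[k] + 1] -= Ve * (s[3] * gx + s[1] * gy + s[4] * gz);
        f[3 * nd[k] + 2] -= Ve * (s[5] * gx + s[4] * gy + s[2] * gz);
      }
    }

    // --- cavity (forces kept separate; cavity energy is tracked via its
    // exact potential, not accumulated work) ---
    double cavV = 0.0, cavP = 0.0;
    std::fill(fcav.begin(), fcav.end(), 0.0);
    if (has_cavity) {
      for (int tI = 0; tI < tc; ++tI) {
        const double* x1 = &x[3 * cavtris(tI, 0)];
        const double* x2 = &x[3 * cavtris(tI, 1)];
        const double* x3 = &x[3 * cavtris(tI, 2)];
        double c23[3];
        cross3(x2, x3, c23);
        cavV += (x1[0] * c23[0] + x1[1] * c23[1] + x1[2] * c23[2]) / 6.0;
      }
      cavP = cavKf * (cavV0 - cavV) / cavV0;
      for (int tI = 0; tI < tc; ++tI) {
        const int i1 = cavtris(tI, 0), i2 = cavtris(tI, 1), i3 = cavtris(tI, 2);
        const double* x1 = &x[3 * i1];
        const double* x2 = &x[3 * i2];
        const double* x3 = &x[3 * i3];
        double c1[3], c2[3], c3[3];
        cross3(x2, x3, c1);
        cross3(x3, x1, c2);
        cross3(x1, x2, c3);
        for (int d = 0; d < 3; ++d) {
          fcav[3 * i1 + d] += cavP * c1[d] / 6.0;
          fcav[3 * i2 + d] += cavP * c2[d] / 6.0;
          fcav[3 * i3 + d] += cavP * c3[d] / 6.0;
        }
      }
    }

    // --- external forces ---
    double Fpulse = (step < pulse.size()) ? pulse[step] : 0.0;
    for (int i = 0; i < lnodes.size(); ++i)
      for (int d = 0; d < 3; ++d)
        fext[3 * lnodes[i] + d] += Fpulse * lw[i] * ldir[d];
    if (bodyacc[0] != 0 || bodyacc[1] != 0 || bodyacc[2] != 0)
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d)
          fext[3 * i + d] += mass[i] * bodyacc[d];

    // impactor penalty contact
    double Fcontact = 0.0, Econtact = 0.0, fimp[3] = {0, 0, 0};
    if (imp_type >= 0) {
      for (int ci = 0; ci < contact_nodes.size(); ++ci) {
        const int i = contact_nodes[ci];
        const double* xi = &x[3 * i];
        double pen = 0.0, nrm[3] = {0, 0, 0};
        if (imp_type == 0) {           // sphere
          double d0 = xi[0] - impX[0], d1 = xi[1] - impX[1], d2 = xi[2] - impX[2];
          double dist = std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
          if (dist < impR && dist > 1e-12) {
            pen = impR - dist;
            nrm[0] = d0 / dist; nrm[1] = d1 / dist; nrm[2] = d2 / dist;
          }
        } else {                       // plane face, travel axis points at head
          double r0 = xi[0] - impX[0], r1 = xi[1] - impX[1], r2 = xi[2] - impX[2];
          double along = r0 * axis[0] + r1 * axis[1] + r2 * axis[2];
          if (along < 0.0) {
            double l0 = r0 - along * axis[0], l1 = r1 - along * axis[1],
                   l2 = r2 - along * axis[2];
            if (std::sqrt(l0 * l0 + l1 * l1 + l2 * l2) <= impR) {
              pen = -along;
              nrm[0] = axis[0]; nrm[1] = axis[1]; nrm[2] = axis[2];
            }
          }
        }
        if (pen > 0.0) {
          double fc = impK * pen;
          Fcontact += fc;
          Econtact += 0.5 * impK * pen * pen;
          for (int d = 0; d < 3; ++d) {
            fext[3 * i + d] += fc * nrm[d];
            fimp[d] -= fc * nrm[d];
          }
        }
      }
    }

    double Ftot = (imp_type >= 0) ? Fcontact : std::fabs(Fpulse);

    // trapezoidal work increments over the step just completed
    if (have_prev) {
      for (int i = 0; i < 3 * n; ++i) {
        Wint += -0.5 * (fint_prev[i] + f[i]) * dx_prev[i];
        Wext += 0.5 * (fext_prev[i] + fext[i]) * dx_prev[i];
      }
    }

    // --- totals, record, integrate ---
    double atot[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        double fi = f[3 * i + d] + fcav[3 * i + d] + fext[3 * i + d]
                  - damping * mass[i] * v[3 * i + d];
        if (isfixed[i]) fi = 0.0;
        acc[3 * i + d] = fi / mass[i];
        atot[d] += fi;
      }
    }
    for (int d = 0; d < 3; ++d) atot[d] /= Mtot;

    bool record = (step % out_every == 0) || step == nsteps;
    if (record) {
      double KE = 0.0;
      for (int i = 0; i < n; ++i)
        KE += 0.5 * mass[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                               v[3 * i + 2] * v[3 * i + 2]);
      double impKE = 0.0;
      if (imp_type >= 0)
        impKE = 0.5 * impM * (impV[0] * impV[0] + impV[1] * impV[1] +
                              impV[2] * impV[2]);
      double Ecav = has_cavity ? cavKf * (cavV0 - cavV) * (cavV0 - cavV) / (2 * cavV0) : 0.0;
      double bal_num = (KE + impKE - KE0) + Wint + Ecav + Econtact - Wext - Wdamp;
      if (!std::isfinite(KE))
        stop("solver diverged (non-finite kinetic energy) at t = %g s, step %d",
             t, step);
      t_out[orow] = t;
      force_out[orow] = Ftot;
      for (int d = 0; d < 3; ++d) acc_out(orow, d) = atot[d];
      acc_out(orow, 3) = std::sqrt(atot[0] * atot[0] + atot[1] * atot[1] +
                                   atot[2] * atot[2]);
      en_out(orow, 0) = KE + impKE;
      en_out(orow, 1) = Wint;
      en_out(orow, 2) = Ecav;
      en_out(orow, 3) = Wext;
      en_out(orow, 4) = bal_num;   // raw joules; normalised by the caller
      en_out(orow, 5) = Wdamp;
      cav_out(orow, 0) = cavV;
      cav_out(orow, 1) = cavP;
      for (int p = 0; p < np; ++p) {
        const double* se = &sig[6 * probe_el[p]];
        probe_out(orow, p) = -(se[0] + se[1] + se[2]) / 3.0;
      }
      for (int mk = 0; mk < nm; ++mk) {
        const int* nd = &en[4 * ndt_el[mk]];
        for (int d = 0; d < 3; ++d) {
          double pos = 0.0;
          for (int k = 0; k < 4; ++k)
            pos += ndt_bary(mk, k) * x[3 * nd[k] + d];
          ndt_out(orow, 3 * mk + d) = pos;
        }
      }
      for (int ti = 0; ti < nt; ++ti)
        for (int d = 0; d < 3; ++d)
          trk_out(orow, 3 * ti + d) = x[3 * track_nodes[ti] + d];
      for (int d = 0; d < 3; ++d) {
        imp_out(orow, d) = impX[d];
        imp_out(orow, 3 + d) = impV[d];
      }
      if (any_brain || any_skull) {
        for (int e = 0; e < m; ++e) {
          if (brain_el[e]) {
            double vm = von_mises_voigt(&sig[6 * e]);
            if (vm > vm_peak) { vm_peak = vm; vm_time = t; vm_elem = e; }
          }
          if (skull_el[e]) {
            double ps = max_principal_voigt(&sig[6 * e]);
            if (ps > ps_peak) { ps_peak = ps; ps_time = t; ps_elem = e; }
          }
        }
      }
      ++orow;
    }

    if (step == nsteps) break;

    // velocity / position update (central difference)
    for (int i = 0; i < n; ++i) {
      if (isfixed[i]) {
        for (int d = 0; d < 3; ++d) dx_prev[3 * i + d] = 0.0;
        continue;
      }
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] += acc[3 * i + d] * dt;
        double dx = v[3 * i + d] * dt;
        x[3 * i + d] += dx;
        dx_prev[3 * i + d] = dx;
        Wdamp += -damping * mass[i] * v[3 * i + d] * dx;
      }
    }
    std::copy(f.begin(), f.end(), fint_prev.begin());
    std::copy(fext.begin(), fext.end(), fext_prev.begin());
    have_prev = true;
    if (imp_type >= 0) {
      for (int d = 0; d < 3; ++d) {
        impV[d] += fimp[d] / impM * dt;
        impX[d] += impV[d] * dt;
      }
    }
  }

  NumericMatrix final_stress(m, 6);
  for (int e = 0; e < m; ++e)
    for (int c = 0; c < 6; ++c) final_stress(e, c) = sig[6 * e + c];

  return List::create(
    _["time"] = t_out, _["force"] = force_out, _["acc"] = acc_out,
    _["energy"] = en_out, _["cavity"] = cav_out, _["probes"] = probe_out,
    _["ndt"] = ndt_out, _["track"] = trk_out, _["impactor"] = imp_out,
    _["vm_peak"] = vm_peak, _["vm_time"] = vm_time, _["vm_elem"] = vm_elem + 1,
    _["ps_peak"] = (any_skull ? ps_peak : 0.0), _["ps_time"] = ps_time,
    _["ps_elem"] = ps_elem + 1,
    _["final_stress"] = final_stress, _["dt"] = dt, _["nsteps"] = nsteps);
}
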