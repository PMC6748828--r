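// Element-level kernels for the large-deformation FE solver.
// Material points use the fiber-reinforced hyperelastic composite:
//   Psi = K/2 (ln J)^2 + ((1-theta_f) mu_m + mu_c)/2 (I1_iso - 3)
//         + theta_f mu_f/2 (I4* - 1)^2,   I4* = tr(H C_iso)
// Trilinear hexahedra with an energy-consistent F-bar treatment (the
// centroid volumetric correction enters the element strain energy and the
// internal force is its exact gradient), which mitigates volumetric
// locking at K/mu ~ 10^2-10^3. The follower turgor pressure derives from
// the enclosed-volume potential -p V(u) of the closed lumen surface, so
// the discrete problem is a genuine potential minimisation and the solver
// can use energy line searches. Element stiffness is obtained by central
// finite differences of the gradient, hence consistent with both the
// F-bar coupling and the follower load.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct MatPar {
  double K, mu_m, mu_f, mu_c, theta_f, fa;
  vec3 a0;
};

static MatPar row_par(const mat& P, uword e) {
  MatPar p;
  p.K = P(e, 0); p.mu_m = P(e, 1); p.mu_f = P(e, 2); p.mu_c = P(e, 3);
  p.theta_f = P(e, 4);
  p.a0 = {P(e, 5), P(e, 6), P(e, 7)};
  p.fa = P(e, 8);
  return p;
}

// Cauchy stress at one material point. Returns false if det(F) <= 0.
static bool point_stress(const mat33& F, const MatPar& p, bool tension_only,
                         mat33& sig) {
  double J = det(F);
  if (!(J > 0.0)) return false;
  double Jm23 = std::pow(J, -2.0 / 3.0);
  mat33 I(fill::eye);
  mat33 bbar = Jm23 * (F * F.t());
  mat33 H = p.fa * (p.a0 * p.a0.t()) + ((1.0 - p.fa) / 3.0) * I;
  mat33 A = Jm23 * (F * H * F.t());
  double I4 = trace(A);
  double mubar = (1.0 - p.theta_f) * p.mu_m + p.mu_c;
  sig = (p.K * std::log(J) / J) * I
      + (mubar / J) * (bbar - (trace(bbar) / 3.0) * I);
  if (!(tension_only && I4 < 1.0)) {
    double g = 2.0 * p.theta_f * p.mu_f * (I4 - 1.0);
    sig += (g / J) * (A - (I4 / 3.0) * I);
  }
  return true;
}

static double point_energy(const mat33& F, const MatPar& p,
                           bool tension_only) {
  double J = det(F);
  if (!(J > 0.0)) Rcpp::stop("invalid deformation: det(F) <= 0");
  double Jm23 = std::pow(J, -2.0 / 3.0);
  mat33 I(fill::eye);
  double I1bar = Jm23 * trace(F * F.t());
  mat33 H = p.fa * (p.a0 * p.a0.t()) + ((1.0 - p.fa) / 3.0) * I;
  double I4 = Jm23 * trace(F * H * F.t());
  double mubar = (1.0 - p.theta_f) * p.mu_m + p.mu_c;
  double psi = 0.5 * p.K * std::pow(std::log(J), 2)
             + 0.5 * mubar * (I1bar - 3.0);
  if (!(tension_only && I4 < 1.0))
    psi += 0.5 * p.theta_f * p.mu_f * std::pow(I4 - 1.0, 2);
  return psi;
}

// [[Rcpp::export(name = ".cpp_cauchy_stress")]]
arma::mat cpp_cauchy_stress(const arma::mat& F, const arma::rowvec& par,
                            bool tension_only) {
  mat P(1, 9);
  P.row(0) = par;
  MatPar p = row_par(P, 0);
  mat33 sig;
  mat33 Ff = F;
  if (!point_stress(Ff, p, tension_only, sig))
    Rcpp::stop("invalid deformation: det(F) <= 0");
  return mat(sig);
}

// [[Rcpp::export(name = ".cpp_strain_energy")]]
double cpp_strain_energy(const arma::mat& F, const arma::rowvec& par,
                         bool tension_only) {
  mat P(1, 9);
  P.row(0) = par;
  mat33 Ff = F;
  return point_energy(Ff, row_par(P, 0), tension_only);
}

// ---- hex8 shape machinery ------------------------------------------------

static const double XI[8]  = {-1,  1,  1, -1, -1,  1,  1, -1};
static const double ETA[8] = {-1, -1,  1,  1, -1, -1,  1,  1};
static const double ZET[8] = {-1, -1, -1, -1,  1,  1,  1,  1};

// dN (8x3) in natural coordinates at (xi, eta, zeta)
static void hex_dN(double xi, double eta, double zeta, mat& dN) {
  for (int a = 0; a < 8; ++a) {
    dN(a, 0) = 0.125 * XI[a] * (1 + ETA[a] * eta) * (1 + ZET[a] * zeta);
    dN(a, 1) = 0.125 * (1 + XI[a] * xi) * ETA[a] * (1 + ZET[a] * zeta);
    dN(a, 2) = 0.125 * (1 + XI[a] * xi) * (1 + ETA[a] * eta) * ZET[a];
  }
}

// Deformation gradient and reference-Jacobian determinant at one point.
static bool kin_at(const mat& X, const mat& U, double xi, double eta,
                   double zeta, mat33& F, mat& dNdX, double& detJref) {
  mat dN(8, 3);
  hex_dN(xi, eta, zeta, dN);
  mat33 Jac = X.t() * dN;     // dX_i/dxi_j
  detJref = det(Jac);
  if (!(detJref > 0.0)) return false;
  dNdX = dN * inv(Jac);       // dN_a/dX_i
  F = eye(3, 3) + (U.t() * dNdX);
  return true;
}

// Reference-configuration data of one element: shape-function gradients and
// Jacobian determinants at the 8 Gauss points and the centroid. Depends on
// X only, so it is computed once per element and reused across the
// finite-difference stiffness perturbations.
struct ElemRef {
  mat dNdX[8];
  double dJ[8];
  mat dNdX0;
  bool ok;
};

static ElemRef elem_ref(const mat& X) {
  ElemRef r;
  r.ok = true;
  const double g = 1.0 / std::sqrt(3.0);
  mat dN(8, 3);
  for (int q = 0; q < 8; ++q) {
    hex_dN(g * XI[q], g * ETA[q], g * ZET[q], dN);
    mat33 Jac = X.t() * dN;
    r.dJ[q] = det(Jac);
    if (!(r.dJ[q] > 0.0)) { r.ok = false; return r; }
    r.dNdX[q] = dN * inv(Jac);
  }
  hex_dN(0, 0, 0, dN);
  mat33 Jac0 = X.t() * dN;
  if (!(det(Jac0) > 0.0)) { r.ok = false; return r; }
  r.dNdX0 = dN * inv(Jac0);
  return r;
}

// Element strain energy with the F-bar centroid correction.
static bool elem_energy(const ElemRef& r, const mat& U, const MatPar& p,
                        bool fbar, bool tension_only, double& E) {
  E = 0.0;
  double J0 = 1.0;
  if (fbar) {
    mat33 F0 = eye(3, 3) + U.t() * r.dNdX0;
    J0 = det(F0);
    if (!(J0 > 0.0)) return false;
  }
  for (int q = 0; q < 8; ++q) {
    mat33 F = eye(3, 3) + U.t() * r.dNdX[q];
    double J = det(F);
    if (!(J > 0.0)) return false;
    mat33 Fb = fbar ? std::pow(J0 / J, 1.0 / 3.0) * F : F;
    E += r.dJ[q] * point_energy(Fb, p, tension_only);
  }
  return true;
}

// Internal force: exact gradient of elem_energy. With F-bar,
//   dPsi(Fb) = [c Pb - (c/3)(Pb:F) F^-T] : dF + (c/3)(Pb:F) F0^-T : dF0
// where c = (J0/J)^(1/3) and Pb is the first Piola-Kirchhoff stress at Fb.
static bool elem_fint(const ElemRef& r, const mat& U, const MatPar& p,
                      bool fbar, bool tension_only, vec& f) {
  f.zeros(24);
  double J0 = 1.0;
  mat33 F0inv_t;
  if (fbar) {
    mat33 F0 = eye(3, 3) + U.t() * r.dNdX0;
    J0 = det(F0);
    if (!(J0 > 0.0)) return false;
    F0inv_t = inv(F0).t();
  }
  double c0acc = 0.0;   // accumulates w (c/3)(Pb : F) for the centroid term
  for (int q = 0; q < 8; ++q) {
    const mat& dNdX = r.dNdX[q];
    mat33 F = eye(3, 3) + U.t() * dNdX;
    double J = det(F);
    if (!(J > 0.0)) return false;
    mat33 M;   // contraction matrix against dF at this point
    if (fbar) {
      double c = std::pow(J0 / J, 1.0 / 3.0);
      mat33 Fb = c * F;
      mat33 sig;
      if (!point_stress(Fb, p, tension_only, sig)) return false;
      mat33 Pb = J0 * sig * inv(Fb).t();   // det(Fb) = J0
      double pf = accu(Pb % F);
      M = c * Pb - (c / 3.0) * pf * inv(F).t();
      c0acc += r.dJ[q] * (c / 3.0) * pf;
    } else {
      mat33 sig;
      if (!point_stress(F, p, tension_only, sig)) return false;
      M = J * sig * inv(F).t();
    }
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        f(3 * a + i) += r.dJ[q] * (M(i, 0) * dNdX(a, 0) +
                                   M(i, 1) * dNdX(a, 1) +
                                   M(i, 2) * dNdX(a, 2));
  }
  if (fbar) {
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        f(3 * a + i) += c0acc * (F0inv_t(i, 0) * r.dNdX0(a, 0) +
                                 F0inv_t(i, 1) * r.dNdX0(a, 1) +
                                 F0inv_t(i, 2) * r.dNdX0(a, 2));
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_assemble")]]
Rcpp::List cpp_assemble(const arma::mat& nodes, const arma::imat& elems,
                        const arma::mat& P, const arma::vec& u,
                        bool fbar, bool tension_only, bool want_K) {
  const uword ne = elems.n_rows, nn = nodes.n_rows;
  vec fint(3 * nn, fill::zeros);
  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  if (want_K) { Ki.reserve(ne * 576); Kj.reserve(ne * 576); Kx.reserve(ne * 576); }
  mat X(8, 3), U(8, 3);
  vec f(24), fp(24), fm(24);
  for (uword e = 0; e < ne; ++e) {
    MatPar p = row_par(P, e);
    uvec conn(8);
    for (int a = 0; a < 8; ++a) {
      conn(a) = (uword)elems(e, a);
      X.row(a) = nodes.row(conn(a));
      for (int i = 0; i < 3; ++i) U(a, i) = u(3 * conn(a) + i);
    }
    ElemRef r = elem_ref(X);
    if (!r.ok)
      Rcpp::stop("degenerate reference geometry in element %d", (int)(e + 1));
    if (!elem_fint(r, U, p, fbar, tension_only, f))
      Rcpp::stop("element inversion in element %d", (int)(e + 1));
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        fint(3 * conn(a) + i) += f(3 * a + i);
    if (want_K) {
      // forward differences of the gradient, reusing the base gradient f;
      // the exact Hessian is symmetric (potential formulation), so the
      // solver symmetrises and factorises with Cholesky
      double vol = r.dJ[0] + r.dJ[1] + r.dJ[2] + r.dJ[3] +
                   r.dJ[4] + r.dJ[5] + r.dJ[6] + r.dJ[7];
      double h = 1e-6 * std::cbrt(vol);        // strain perturbation ~1e-6
      mat Ue = U;
      for (int d = 0; d < 24; ++d) {
        int a = d / 3, i = d % 3;
        Ue(a, i) = U(a, i) + h;
        bool okp = elem_fint(r, Ue, p, fbar, tension_only, fp);
        if (!okp) {
          Ue(a, i) = U(a, i) - h;   // fall back to a backward step
          okp = elem_fint(r, Ue, p, fbar, tension_only, fp);
          if (!okp)
            Rcpp::stop("element inversion during linearisation in element %d",
                       (int)(e + 1));
          fp = 2.0 * f - fp;
        }
        Ue(a, i) = U(a, i);
        for (int b = 0; b < 24; ++b) {
          double kv = (fp(b) - f(b)) / h;
          if (kv != 0.0) {
            Ki.push_back(3 * conn(b / 3) + b % 3 + 1);
            Kj.push_back(3 * conn(a) + i + 1);
            Kx.push_back(kv);
          }
        }
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("fint") = fint,
      Rcpp::Named("Ki") = Ki, Rcpp::Named("Kj") = Kj,
      Rcpp::Named("Kx") = Kx);
}

// [[Rcpp::export(name = ".cpp_internal_energy")]]
double cpp_internal_energy(const arma::mat& nodes, const arma::imat& elems,
                           const arma::mat& P, const arma::vec& u,
                           bool fbar, bool tension_only) {
  const uword ne = elems.n_rows;
  mat X(8, 3), U(8, 3);
  double E = 0.0, Ee;
  for (uword e = 0; e < ne; ++e) {
    MatPar p = row_par(P, e);
    for (int a = 0; a < 8; ++a) {
      uword n = (uword)elems(e, a);
      X.row(a) = nodes.row(n);
      for (int i = 0; i < 3; ++i) U(a, i) = u(3 * n + i);
    }
    ElemRef r = elem_ref(X);
    if (!r.ok)
      Rcpp::stop("degenerate reference geometry in element %d", (int)(e + 1));
    if (!elem_energy(r, U, p, fbar, tension_only, Ee))
      Rcpp::stop("element inversion in element %d", (int)(e + 1));
    E += Ee;
  }
  return E;
}

// ---- follower pressure via the enclosed-volume potential -----------------

// facet contribution to the enclosed volume: (1/3) sum_gp x . (x_xi x x_eta)
static double facet_volume(const mat& x) {
  const double g = 1.0 / std::sqrt(3.0);
  const double QXI[4] = {-1, 1, 1, -1}, QETA[4] = {-1, -1, 1, 1};
  double V = 0.0;
  for (int q = 0; q < 4; ++q) {
    double xi = g * QXI[q], eta = g * QETA[q];
    vec4 N, Nxi, Neta;
    for (int a = 0; a < 4; ++a) {
      N(a)   = 0.25 * (1 + QXI[a] * xi) * (1 + QETA[a] * eta);
      Nxi(a) = 0.25 * QXI[a] * (1 + QETA[a] * eta);
      Neta(a)= 0.25 * (1 + QXI[a] * xi) * QETA[a];
    }
    vec3 xg = x.t() * N, t1 = x.t() * Nxi, t2 = x.t() * Neta;
    V += dot(xg, cross(t1, t2)) / 3.0;
  }
  return V;
}

// exact gradient of facet_volume wrt facet node coordinates (12-vector)
static void facet_dvol(const mat& x, vec& f) {
  const double g = 1.0 / std::sqrt(3.0);
  const double QXI[4] = {-1, 1, 1, -1}, QETA[4] = {-1, -1, 1, 1};
  f.zeros(12);
  for (int q = 0; q < 4; ++q) {
    double xi = g * QXI[q], eta = g * QETA[q];
    vec4 N, Nxi, Neta;
    for (int a = 0; a < 4; ++a) {
      N(a)   = 0.25 * (1 + QXI[a] * xi) * (1 + QETA[a] * eta);
      Nxi(a) = 0.25 * QXI[a] * (1 + QETA[a] * eta);
      Neta(a)= 0.25 * (1 + QXI[a] * xi) * QETA[a];
    }
    vec3 xg = x.t() * N, t1 = x.t() * Nxi, t2 = x.t() * Neta;
    vec3 c12 = cross(t1, t2), c2x = cross(t2, xg), cx1 = cross(xg, t1);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        f(3 * a + i) += (N(a) * c12(i) + Nxi(a) * c2x(i) +
                         Neta(a) * cx1(i)) / 3.0;
  }
}

// [[Rcpp::export(name = ".cpp_enclosed_volume")]]
double cpp_enclosed_volume(const arma::mat& nodes, const arma::imat& facets,
                           const arma::vec& u) {
  const uword nf = facets.n_rows;
  mat x(4, 3);
  double V = 0.0;
  for (uword e = 0; e < nf; ++e) {
    for (int a = 0; a < 4; ++a) {
      uword n = (uword)facets(e, a);
      for (int i = 0; i < 3; ++i) x(a, i) = nodes(n, i) + u(3 * n + i);
    }
    V += facet_volume(x);
  }
  return V;
}

// [[Rcpp::export(name = ".cpp_pressure_load")]]
Rcpp::List cpp_pressure_load(const arma::mat& nodes, const arma::imat& facets,
                             const arma::vec& u, double p, bool want_K) {
  const uword nf = facets.n_rows, nn = nodes.n_rows;
  vec fext(3 * nn, fill::zeros);
  std::vector<int> Ki, Kj;
  std::vector<double> Kx;
  mat x(4, 3);
  vec f(12), fp(12), fm(12);
  for (uword e = 0; e < nf; ++e) {
    uvec conn(4);
    for (int a = 0; a < 4; ++a) {
      conn(a) = (uword)facets(e, a);
      for (int i = 0; i < 3; ++i)
        x(a, i) = nodes(conn(a), i) + u(3 * conn(a) + i);
    }
    facet_dvol(x, f);
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        fext(3 * conn(a) + i) += p * f(3 * a + i);
    if (want_K) {
      double h = 1e-6 * (1.0 + norm(x.row(0) - x.row(2), 2));
      mat xe = x;
      for (int d = 0; d < 12; ++d) {
        int a = d / 3, i = d % 3;
        xe(a, i) = x(a, i) + h;
        facet_dvol(xe, fp);
        xe(a, i) = x(a, i) - h;
        facet_dvol(xe, fm);
        xe(a, i) = x(a, i);
        for (int b = 0; b < 12; ++b) {
          double kv = p * (fp(b) - fm(b)) / (2.0 * h);
          if (kv != 0.0) {
            Ki.push_back(3 * conn(b / 3) + b % 3 + 1);
            Kj.push_back(3 * conn(a) + i + 1);
            Kx.push_back(kv);
          }
        }
      }
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("fext") = fext,
      Rcpp::Named("Ki") = Ki, Rcpp::Named("Kj") = Kj,
      Rcpp::Named("Kx") = Kx);
}

// Element-averaged Cauchy stress (xx, yy, zz, xy, yz, xz), von Mises and
// mean J, from quadrature-point stresses at the converged state.
// [[Rcpp::export(name = ".cpp_element_stress")]]
Rcpp::List cpp_element_stress(const arma::mat& nodes, const arma::imat& elems,
                              const arma::mat& P, const arma::vec& u,
                              bool fbar, bool tension_only) {
  const uword ne = elems.n_rows;
  mat S(ne, 6, fill::zeros);
  vec vm(ne, fill::zeros), Jel(ne, fill::zeros);
  const double g = 1.0 / std::sqrt(3.0);
  mat X(8, 3), U(8, 3);
  for (uword e = 0; e < ne; ++e) {
    MatPar p = row_par(P, e);
    for (int a = 0; a < 8; ++a) {
      uword n = (uword)elems(e, a);
      X.row(a) = nodes.row(n);
      for (int i = 0; i < 3; ++i) U(a, i) = u(3 * n + i);
    }
    double J0 = 1.0;
    if (fbar) {
      mat33 F0; mat dNdX(8, 3); double dJ;
      if (!kin_at(X, U, 0, 0, 0, F0, dNdX, dJ))
        Rcpp::stop("element inversion in element %d", (int)(e + 1));
      J0 = det(F0);
    }
    mat33 smean(fill::zeros);
    double jm = 0.0;
    for (int q = 0; q < 8; ++q) {
      mat33 F; mat dNdX(8, 3); double detJref;
      if (!kin_at(X, U, g * XI[q], g * ETA[q], g * ZET[q], F, dNdX, detJref))
        Rcpp::stop("element inversion in element %d", (int)(e + 1));
      double J = det(F);
      mat33 Fb = fbar ? std::pow(J0 / J, 1.0 / 3.0) * F : F;
      mat33 sig;
      if (!point_stress(Fb, p, tension_only, sig))
        Rcpp::stop("invalid deformation in element %d", (int)(e + 1));
      smean += sig;
      jm += J;
    }
    smean /= 8.0;
    jm /= 8.0;
    S(e, 0) = smean(0, 0); S(e, 1) = smean(1, 1); S(e, 2) = smean(2, 2);
    S(e, 3) = smean(0, 1); S(e, 4) = smean(1, 2); S(e, 5) = smean(0, 2);
    mat33 dev = smean - (trace(smean) / 3.0) * eye(3, 3);
    vm(e) = std::sqrt(1.5 * accu(dev % dev));
    Jel(e) = jm;
  }
  return Rcpp::List::create(Rcpp::Named("stress") = S,
                            Rcpp::Named("von_mises") = vm,
                            Rcpp::Named("J") = Jel);
}

// Connected components (26-connectivity) of `candidate`, keeping those that
// contain at least one `seed` voxel. Used by the hysteresis filter; works
// for 2D images as nz = 1.
// [[Rcpp::export(name = ".cpp_hysteresis_mask")]]
Rcpp::LogicalVector cpp_hysteresis_mask(Rcpp::LogicalVector candidate,
                                        Rcpp::LogicalVector seed,
                                        int nx, int ny, int nz) {
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (candidate.size() != n || seed.size() != n)
    Rcpp::stop("mask dimensions do not match");
  std::vector<int> comp(n, -1);
  std::vector<R_xlen_t> stack, members;
  Rcpp::LogicalVector out(n, false);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!candidate[s] || comp[s] != -1) continue;
    bool has_seed = false;
    stack.clear(); members.clear();
    stack.push_back(s);
    comp[s] = 1;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      members.push_back(v);
      if (seed[v]) has_seed = true;
      int i = v % nx, j = (v / nx) % ny, k = v / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (candidate[w] && comp[w] == -1) {
              comp[w] = 1;
              stack.push_back(w);
            }
          }
    }
    if (has_seed)
      for (R_xlen_t v : members) out[v] = true;
  }
  return out;
}
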