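// Compiled cores: analytic surrogate potentials, many-body descriptors
// (2-body, 3-body, SOAP-style power spectrum via the Legendre addition
// theorem) and sparse-GP kernel rows with analytic position gradients.
//
// Conventions: positions in A, energies in eV, forces in eV/A.
// Periodic cells are orthorhombic (asserted on the R side); the minimum
// image convention is applied per axis. All indices are 0-based here;
// R wrappers convert.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI_ = 3.141592653589793238462643383279502884;

struct Box {
  bool periodic[3];
  double L[3];
};

static Box make_box(const NumericVector &Ldiag, const LogicalVector &pbc) {
  Box b;
  for (int a = 0; a < 3; ++a) {
    b.periodic[a] = pbc[a];
    b.L[a] = Ldiag[a];
  }
  return b;
}

static inline void mic(const Box &b, double *d) {
  for (int a = 0; a < 3; ++a) {
    if (b.periodic[a]) d[a] -= b.L[a] * std::round(d[a] / b.L[a]);
  }
}

static inline void displacement(const NumericMatrix &pos, int i, int j,
                                const Box &b, double *d) {
  for (int a = 0; a < 3; ++a) d[a] = pos(j, a) - pos(i, a);
  mic(b, d);
}

static inline double fcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return 0.5 * (std::cos(PI_ * r / rc) + 1.0);
}
static inline double dfcut(double r, double rc) {
  if (r >= rc) return 0.0;
  return -0.5 * (PI_ / rc) * std::sin(PI_ * r / rc);
}

// C1 switching function: 1 below rs, 0 above rc, zero slope at both ends.
static inline double sw(double r, double rs, double rc) {
  if (r <= rs) return 1.0;
  if (r >= rc) return 0.0;
  double t = (r - rs) / (rc - rs);
  return 1.0 + t * t * (2.0 * t - 3.0);
}
static inline double dsw(double r, double rs, double rc) {
  if (r <= rs || r >= rc) return 0.0;
  double t = (r - rs) / (rc - rs);
  return 6.0 * t * (t - 1.0) / (rc - rs);
}

// ---------------------------------------------------------------------------
// Toy water surrogate: harmonic bonds/angle (intra) + switched LJ on O pairs
// and switched Coulomb on all intermolecular pairs (inter).

// mol_id: molecule index per atom; o_idx/h1_idx/h2_idx: per-molecule atom rows.
// [[Rcpp::export]]
List cpp_toy_water(const NumericMatrix &pos, const IntegerVector &is_oxygen,
                   const IntegerVector &mol_id, const NumericVector &Ldiag,
                   const LogicalVector &pbc, const List &par) {
  const int n = pos.nrow();
  Box box = make_box(Ldiag, pbc);
  const double kb = par["k_b"], r0 = par["r0"], ka = par["k_a"], th0 = par["theta0"];
  const double eps = par["epsilon"], sig = par["sigma"];
  const double qO = par["q_O"], qH = par["q_H"], kc = par["k_coul"];
  const double rs = par["r_switch"], rc = par["r_cut"];

  NumericMatrix f_intra(n, 3), f_inter(n, 3);
  double e_intra = 0.0, e_inter = 0.0;

  // group atoms by molecule
  int nmol = 0;
  for (int i = 0; i < n; ++i) nmol = std::max(nmol, mol_id[i] + 1);
  std::vector<int> oat(nmol, -1), h1(nmol, -1), h2(nmol, -1);
  for (int i = 0; i < n; ++i) {
    int m = mol_id[i];
    if (is_oxygen[i]) {
      if (oat[m] != -1) stop("molecule with two oxygens is not water");
      oat[m] = i;
    } else if (h1[m] == -1) h1[m] = i;
    else if (h2[m] == -1) h2[m] = i;
    else stop("molecule with >2 hydrogens is not water");
  }
  for (int m = 0; m < nmol; ++m) {
    if (oat[m] < 0 || h1[m] < 0 || h2[m] < 0) stop("non-water molecule (need O+2H)");
  }

  // intramolecular terms
  for (int m = 0; m < nmol; ++m) {
    int O = oat[m], A = h1[m], B = h2[m];
    double u[3], v[3];
    displacement(pos, O, A, box, u);
    displacement(pos, O, B, box, v);
    double ru = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
    double rv = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
    // bonds
    e_intra += 0.5 * kb * (ru - r0) * (ru - r0);
    e_intra += 0.5 * kb * (rv - r0) * (rv - r0);
    for (int a = 0; a < 3; ++a) {
      double gA = kb * (ru - r0) * u[a] / ru;   // dE/d(pos A)
      double gB = kb * (rv - r0) * v[a] / rv;
      f_intra(A, a) -= gA; f_intra(O, a) += gA;
      f_intra(B, a) -= gB; f_intra(O, a) += gB;
    }
    // angle
    double dot = u[0]*v[0] + u[1]*v[1] + u[2]*v[2];
    double cth = dot / (ru * rv);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
    e_intra += 0.5 * ka * (th - th0) * (th - th0);
    double dEdth = ka * (th - th0);
    double pref = -dEdth / sth;  // dE/dcth
    for (int a = 0; a < 3; ++a) {
      double dcdu = v[a] / (ru * rv) - cth * u[a] / (ru * ru);
      double dcdv = u[a] / (ru * rv) - cth * v[a] / (rv * rv);
      f_intra(A, a) -= pref * dcdu;
      f_intra(B, a) -= pref * dcdv;
      f_intra(O, a) += pref * (dcdu + dcdv);
    }
  }

  // intermolecular terms
  for (int i = 0; i < n; ++i) {
    double qi = is_oxygen[i] ? qO : qH;
    for (int j = i + 1; j < n; ++j) {
      if (mol_id[i] == mol_id[j]) continue;
      double d[3];
      displacement(pos, i, j, box, d);
      double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2 >= rc * rc) continue;
      double r = std::sqrt(r2);
      double qj = is_oxygen[j] ? qO : qH;
      double S = sw(r, rs, rc), dS = dsw(r, rs, rc);
      double phi = kc * qi * qj / r;
      double dphi = -phi / r;
      if (is_oxygen[i] && is_oxygen[j]) {
        double sr6 = std::pow(sig / r, 6.0), sr12 = sr6 * sr6;
        phi += 4.0 * eps * (sr12 - sr6);
        dphi += 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r;
      }
      e_inter += phi * S;
      double dEdr = dphi * S + phi * dS;
      for (int a = 0; a < 3; ++a) {
        double g = dEdr * d[a] / r;  // dE/d(pos j)
        f_inter(j, a) -= g;
        f_inter(i, a) += g;
      }
    }
  }

  NumericMatrix forces(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) forces(i, a) = f_intra(i, a) + f_inter(i, a);
  return List::create(_["energy"] = e_intra + e_inter, _["forces"] = forces,
                      _["e_intra"] = e_intra, _["f_intra"] = f_intra,
                      _["e_inter"] = e_inter, _["f_inter"] = f_inter);
}

// ---------------------------------------------------------------------------
// Two-state empirical valence bond surface on a triatomic A-B-C.
// V1 = Morse_AB(r_AB) + C_rep exp(-r_BC/rho)
// V2 = Morse_BC(r_BC) + C_rep exp(-r_AB/rho)
// E  = (V1+V2)/2 - sqrt((V1-V2)^2 + 4 Delta^2)/2

static inline double morse(double r, double De, double a, double re, double *dEdr) {
  double ex = std::exp(-a * (r - re));
  *dEdr = 2.0 * De * a * ex * (1.0 - ex);
  return De * ((1.0 - ex) * (1.0 - ex) - 1.0);
}

// [[Rcpp::export]]
List cpp_evb(const NumericMatrix &pos, const List &par) {
  if (pos.nrow() != 3) stop("EVB surface is defined for exactly 3 atoms");
  const double De1 = par["De1"], a1 = par["a1"], re1 = par["re1"];
  const double De2 = par["De2"], a2 = par["a2"], re2 = par["re2"];
  const double Delta = par["delta"], Crep = par["C_rep"], rho = par["rho"];

  double dAB[3], dBC[3];
  for (int a = 0; a < 3; ++a) {
    dAB[a] = pos(1, a) - pos(0, a);
    dBC[a] = pos(2, a) - pos(1, a);
  }
  double rAB = std::sqrt(dAB[0]*dAB[0] + dAB[1]*dAB[1] + dAB[2]*dAB[2]);
  double rBC = std::sqrt(dBC[0]*dBC[0] + dBC[1]*dBC[1] + dBC[2]*dBC[2]);

  double dM1, dM2;
  double M1 = morse(rAB, De1, a1, re1, &dM1);
  double M2 = morse(rBC, De2, a2, re2, &dM2);
  double rep_BC = Crep * std::exp(-rBC / rho);
  double rep_AB = Crep * std::exp(-rAB / rho);
  double V1 = M1 + rep_BC, V2 = M2 + rep_AB;
  double dV = V1 - V2;
  double R = std::sqrt(dV * dV + 4.0 * Delta * Delta);
  double E = 0.5 * (V1 + V2) - 0.5 * R;
  double w1 = 0.5 * (1.0 - dV / R);   // dE/dV1
  double w2 = 0.5 * (1.0 + dV / R);   // dE/dV2

  // dE/drAB and dE/drBC
  double dEdrAB = w1 * dM1 + w2 * (-rep_AB / rho);
  double dEdrBC = w2 * dM2 + w1 * (-rep_BC / rho);

  NumericMatrix forces(3, 3);
  for (int a = 0; a < 3; ++a) {
    double gAB = dEdrAB * dAB[a] / rAB;  // dE/d(pos B) from AB
    double gBC = dEdrBC * dBC[a] / rBC;  // dE/d(pos C) from BC
    forces(0, a) += gAB;
    forces(1, a) -= gAB;
    forces(1, a) += gBC;
    forces(2, a) -= gBC;
  }
  return List::create(_["energy"] = E, _["forces"] = forces,
                      _["V1"] = V1, _["V2"] = V2);
}

// ---------------------------------------------------------------------------
// Neighbour list helper (O(N^2); systems here are small)

struct Nbr {
  int idx;      // atom index, or -1 for the centre's own density term (r=0)
  int z;        // species code 0..S-1
  double r;
  double u[3];  // unit vector (undefined for self term)
};

static std::vector<Nbr> neighbours(const NumericMatrix &pos,
                                   const IntegerVector &zcode, int c,
                                   const Box &box, double rc,
                                   bool include_self) {
  std::vector<Nbr> nb;
  const int n = pos.nrow();
  if (include_self) {
    Nbr s; s.idx = -1; s.z = zcode[c]; s.r = 0.0;
    s.u[0] = s.u[1] = s.u[2] = 0.0;
    nb.push_back(s);
  }
  for (int j = 0; j < n; ++j) {
    if (j == c) continue;
    double d[3];
    displacement(pos, c, j, box, d);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    if (r2 >= rc * rc || r2 < 1e-20) continue;
    Nbr s; s.idx = j; s.z = zcode[j]; s.r = std::sqrt(r2);
    for (int a = 0; a < 3; ++a) s.u[a] = d[a] / s.r;
    nb.push_back(s);
  }
  return nb;
}

// ---------------------------------------------------------------------------
// Two-body descriptor features and kernel rows

// [[Rcpp::export]]
List cpp_two_body_features(const NumericMatrix &pos, const IntegerVector &zcode,
                           const LogicalVector &center_mask,
                           const LogicalVector &nbr_mask,
                           const IntegerVector &group,
                           const NumericVector &Ldiag, const LogicalVector &pbc,
                           double rc) {
  Box box = make_box(Ldiag, pbc);
  std::vector<int> ci, ni;
  std::vector<double> rr, ww;
  for (int c = 0; c < pos.nrow(); ++c) {
    if (!center_mask[c]) continue;
    std::vector<Nbr> nb = neighbours(pos, zcode, c, box, rc, false);
    for (const Nbr &s : nb) {
      if (!nbr_mask[s.idx]) continue;
      if (group[c] >= 0 && group[s.idx] == group[c]) continue;
      ci.push_back(c); ni.push_back(s.idx);
      rr.push_back(s.r); ww.push_back(fcut(s.r, rc));
    }
  }
  return List::create(_["center"] = wrap(ci), _["neighbour"] = wrap(ni),
                      _["r"] = wrap(rr), _["w"] = wrap(ww));
}

// K: n_centers x n_sparse per-centre kernels; J: 3N x n_sparse gradient of
// column sums (d/dx of sum_c K[c,s]); kself: per-centre k(x,x).
// [[Rcpp::export]]
List cpp_kernel_2b(const NumericMatrix &pos, const IntegerVector &zcode,
                   const LogicalVector &center_mask,
                   const LogicalVector &nbr_mask, const IntegerVector &group,
                   const NumericVector &Ldiag,
                   const LogicalVector &pbc, double rc, double theta,
                   const NumericVector &r_s, const NumericVector &w_s,
                   bool want_grad) {
  Box box = make_box(Ldiag, pbc);
  const int n = pos.nrow(), ns = r_s.size();
  std::vector<int> centers;
  for (int c = 0; c < n; ++c) if (center_mask[c]) centers.push_back(c);
  const int nc = centers.size();

  NumericMatrix K(nc, ns), J;
  NumericVector kself(nc);
  if (want_grad) J = NumericMatrix(3 * n, ns);
  const double it2 = 1.0 / (2.0 * theta * theta);

  for (int cc = 0; cc < nc; ++cc) {
    int c = centers[cc];
    std::vector<Nbr> nb0 = neighbours(pos, zcode, c, box, rc, false);
    std::vector<Nbr> nb;
    for (const Nbr &s : nb0) {
      if (!nbr_mask[s.idx]) continue;
      if (group[c] >= 0 && group[s.idx] == group[c]) continue;
      nb.push_back(s);
    }
    std::vector<double> w(nb.size());
    for (size_t q = 0; q < nb.size(); ++q) w[q] = fcut(nb[q].r, rc);
    for (size_t q = 0; q < nb.size(); ++q) {
      const Nbr &s = nb[q];
      double fc = w[q], dfc = dfcut(s.r, rc);
      for (int m = 0; m < ns; ++m) {
        double e = std::exp(-(s.r - r_s[m]) * (s.r - r_s[m]) * it2);
        double val = fc * w_s[m] * e;
        K(cc, m) += val;
        if (want_grad) {
          double dvdr = dfc * w_s[m] * e - val * (s.r - r_s[m]) / (theta * theta);
          for (int a = 0; a < 3; ++a) {
            J(3 * s.idx + a, m) += dvdr * s.u[a];
            J(3 * c + a, m) -= dvdr * s.u[a];
          }
        }
      }
      for (size_t q2 = 0; q2 < nb.size(); ++q2) {
        double dr = s.r - nb[q2].r;
        kself[cc] += fc * w[q2] * std::exp(-dr * dr * it2);
      }
    }
  }
  return List::create(_["K"] = K, _["J"] = J, _["kself"] = kself,
                      _["centers"] = wrap(centers));
}

// ---------------------------------------------------------------------------
// Three-body descriptor features and kernel rows
// Feature per centre: (r1, r2, cos theta), symmetrised over r1<->r2; weight
// f_c(r1) f_c(r2). Squared-exponential kernel with length scales theta_r
// (both radial dims) and theta_c (cosine dim).

// [[Rcpp::export]]
List cpp_three_body_features(const NumericMatrix &pos, const IntegerVector &zcode,
                             const LogicalVector &center_mask,
                             const LogicalVector &nbr_mask,
                             const IntegerVector &group,
                             const NumericVector &Ldiag, const LogicalVector &pbc,
                             double rc) {
  Box box = make_box(Ldiag, pbc);
  std::vector<int> ci, j1, j2;
  std::vector<double> r1v, r2v, cv, wv;
  for (int c = 0; c < pos.nrow(); ++c) {
    if (!center_mask[c]) continue;
    std::vector<Nbr> nb0 = neighbours(pos, zcode, c, box, rc, false);
    std::vector<Nbr> nb;
    for (const Nbr &s : nb0) {
      if (!nbr_mask[s.idx]) continue;
      if (group[c] >= 0 && group[s.idx] == group[c]) continue;
      nb.push_back(s);
    }
    for (size_t a = 0; a < nb.size(); ++a) {
      for (size_t b = a + 1; b < nb.size(); ++b) {
        double cg = nb[a].u[0]*nb[b].u[0] + nb[a].u[1]*nb[b].u[1] + nb[a].u[2]*nb[b].u[2];
        double ra = nb[a].r, rb = nb[b].r;
        // canonical order r1 <= r2
        double rA = std::min(ra, rb), rB = std::max(ra, rb);
        ci.push_back(c);
        j1.push_back(ra <= rb ? nb[a].idx : nb[b].idx);
        j2.push_back(ra <= rb ? nb[b].idx : nb[a].idx);
        r1v.push_back(rA); r2v.push_back(rB); cv.push_back(cg);
        wv.push_back(fcut(ra, rc) * fcut(rb, rc));
      }
    }
  }
  return List::create(_["center"] = wrap(ci), _["n1"] = wrap(j1),
                      _["n2"] = wrap(j2), _["r1"] = wrap(r1v),
                      _["r2"] = wrap(r2v), _["cos"] = wrap(cv),
                      _["w"] = wrap(wv));
}

static inline double se3(double a, double b, double cg, double r1s, double r2s,
                         double cs, double itr, double itc) {
  double d1 = a - r1s, d2 = b - r2s, dc = cg - cs;
  return std::exp(-(d1 * d1 + d2 * d2) * itr - dc * dc * itc);
}

// [[Rcpp::export]]
List cpp_kernel_3b(const NumericMatrix &pos, const IntegerVector &zcode,
                   const LogicalVector &center_mask,
                   const LogicalVector &nbr_mask, const IntegerVector &group,
                   const NumericVector &Ldiag,
                   const LogicalVector &pbc, double rc, double theta_r,
                   double theta_c, const NumericMatrix &feat_s,
                   const NumericVector &w_s, bool want_grad) {
  Box box = make_box(Ldiag, pbc);
  const int n = pos.nrow(), ns = feat_s.nrow();
  std::vector<int> centers;
  for (int c = 0; c < n; ++c) if (center_mask[c]) centers.push_back(c);
  const int nc = centers.size();

  NumericMatrix K(nc, ns), J;
  NumericVector kself(nc);
  if (want_grad) J = NumericMatrix(3 * n, ns);
  const double itr = 1.0 / (2.0 * theta_r * theta_r);
  const double itc = 1.0 / (2.0 * theta_c * theta_c);

  for (int cc = 0; cc < nc; ++cc) {
    int c = centers[cc];
    std::vector<Nbr> nb0 = neighbours(pos, zcode, c, box, rc, false);
    std::vector<Nbr> nb;
    for (const Nbr &s : nb0) {
      if (!nbr_mask[s.idx]) continue;
      if (group[c] >= 0 && group[s.idx] == group[c]) continue;
      nb.push_back(s);
    }
    const int nn = nb.size();
    // collect triplets (a<b) with weights
    struct Tri { int a, b; double w, cg; };
    std::vector<Tri> tris;
    for (int a = 0; a < nn; ++a)
      for (int b = a + 1; b < nn; ++b) {
        Tri t; t.a = a; t.b = b;
        t.w = fcut(nb[a].r, rc) * fcut(nb[b].r, rc);
        t.cg = nb[a].u[0]*nb[b].u[0] + nb[a].u[1]*nb[b].u[1] + nb[a].u[2]*nb[b].u[2];
        tris.push_back(t);
      }

    for (const Tri &t : tris) {
      const Nbr &A = nb[t.a], &B = nb[t.b];
      double fa = fcut(A.r, rc), fb = fcut(B.r, rc);
      double dfa = dfcut(A.r, rc), dfb = dfcut(B.r, rc);
      for (int m = 0; m < ns; ++m) {
        double r1s = feat_s(m, 0), r2s = feat_s(m, 1), cs = feat_s(m, 2);
        double e1 = se3(A.r, B.r, t.cg, r1s, r2s, cs, itr, itc);
        double e2 = se3(B.r, A.r, t.cg, r1s, r2s, cs, itr, itc);
        double val = 0.5 * w_s[m] * t.w * (e1 + e2);
        K(cc, m) += val;
        if (want_grad) {
          // d/d rA
          double de_dra = 0.5 * w_s[m] * (
            t.w * (-(A.r - r1s) / (theta_r * theta_r) * e1
                   - (A.r - r2s) / (theta_r * theta_r) * e2)
            + dfa * fb * (e1 + e2));
          double de_drb = 0.5 * w_s[m] * (
            t.w * (-(B.r - r2s) / (theta_r * theta_r) * e1
                   - (B.r - r1s) / (theta_r * theta_r) * e2)
            + fa * dfb * (e1 + e2));
          double de_dcg = 0.5 * w_s[m] * t.w * (e1 + e2) *
            (-(t.cg - cs) / (theta_c * theta_c));
          for (int x = 0; x < 3; ++x) {
            // d rA/d(pos of A.idx) = u_A; d cg/d(d_A) = (u_B - cg u_A)/rA
            double gA = de_dra * A.u[x] + de_dcg * (B.u[x] - t.cg * A.u[x]) / A.r;
            double gB = de_drb * B.u[x] + de_dcg * (A.u[x] - t.cg * B.u[x]) / B.r;
            J(3 * A.idx + x, m) += gA;
            J(3 * B.idx + x, m) += gB;
            J(3 * c + x, m) -= gA + gB;
          }
        }
      }
      for (const Tri &t2 : tris) {
        const Nbr &A2 = nb[t2.a], &B2 = nb[t2.b];
        double e1 = se3(A.r, B.r, t.cg, A2.r, B2.r, t2.cg, itr, itc);
        double e2 = se3(B.r, A.r, t.cg, A2.r, B2.r, t2.cg, itr, itc);
        kself[cc] += 0.5 * t.w * t2.w * (e1 + e2);
      }
    }
  }
  return List::create(_["K"] = K, _["J"] = J, _["kself"] = kself,
                      _["centers"] = wrap(centers));
}

// ---------------------------------------------------------------------------
// SOAP-style power spectrum via the Legendre addition theorem.
//
// Gaussian radial basis g_n(r) = exp(-(r - mu_n)^2 / (2 sigma^2)) with mu_n
// equally spaced on [0, r_c], multiplied by the smooth cutoff f_c(r). Power
// spectrum entry for combined channels A=(z1,n1) <= B=(z2,n2) and degree l:
//   p_{AB,l} = fac * (2l+1)/(4 pi) * sum_{i in z1} sum_{j in z2}
//              G_{n1}(r_i) G_{n2}(r_j) P_l(cos gamma_ij)
// (fac = sqrt(2) off-diagonal), identical to the power spectrum of the
// species-resolved expansion in real spherical harmonics, with the centre
// atom contributing a pure l=0 self term. No explicit harmonics are needed
// and the gradients are pole-free.

struct SoapPar {
  double rc, sigma;
  int n_max, l_max, n_species;
  int M;    // n_species * n_max
  int D;    // M(M+1)/2 * (l_max+1)
};

static SoapPar soap_par(double rc, double sigma, int n_max, int l_max, int nsp) {
  SoapPar p;
  p.rc = rc; p.sigma = sigma; p.n_max = n_max; p.l_max = l_max; p.n_species = nsp;
  p.M = nsp * n_max;
  p.D = p.M * (p.M + 1) / 2 * (l_max + 1);
  return p;
}

// upper-triangle pair index for A <= B among M channels
static inline int tri_index(int A, int B, int M) {
  // row-major over pairs (A,B), A<=B
  return A * M - A * (A - 1) / 2 + (B - A);
}

static void legendre_all(double x, int lmax, double *P, double *dP) {
  P[0] = 1.0; if (dP) dP[0] = 0.0;
  if (lmax >= 1) { P[1] = x; if (dP) dP[1] = 1.0; }
  for (int l = 2; l <= lmax; ++l) {
    P[l] = ((2 * l - 1) * x * P[l - 1] - (l - 1) * P[l - 2]) / l;
    if (dP) dP[l] = dP[l - 2] + (2 * l - 1) * P[l - 1];
  }
}

// Per-centre data reused by all SOAP routines.
struct SoapCenter {
  int c;                       // centre atom index
  std::vector<Nbr> nb;         // includes self entry (idx = -1)
  arma::mat G;                 // nn x n_max: f_c(r) g_n(r)
  arma::mat dG;                // nn x n_max: d/dr of G (0 for self)
};

static SoapCenter soap_center(const NumericMatrix &pos, const IntegerVector &zcode,
                              int c, const Box &box, const SoapPar &sp) {
  SoapCenter sc;
  sc.c = c;
  sc.nb = neighbours(pos, zcode, c, box, sp.rc, true);
  const int nn = sc.nb.size();
  sc.G.set_size(nn, sp.n_max);
  sc.dG.set_size(nn, sp.n_max);
  double dmu = sp.n_max > 1 ? sp.rc / (sp.n_max - 1) : 0.0;
  for (int q = 0; q < nn; ++q) {
    double r = sc.nb[q].r;
    double fc = fcut(r, sp.rc), dfc = dfcut(r, sp.rc);
    for (int nn2 = 0; nn2 < sp.n_max; ++nn2) {
      double mu = nn2 * dmu;
      double g = std::exp(-(r - mu) * (r - mu) / (2.0 * sp.sigma * sp.sigma));
      sc.G(q, nn2) = fc * g;
      sc.dG(q, nn2) = sc.nb[q].idx < 0 ? 0.0
        : dfc * g - fc * g * (r - mu) / (sp.sigma * sp.sigma);
    }
  }
  return sc;
}

// power-spectrum vector for one centre (unnormalised)
static arma::vec soap_p(const SoapCenter &sc, const SoapPar &sp) {
  const int nn = sc.nb.size(), L = sp.l_max;
  arma::vec p(sp.D, arma::fill::zeros);
  std::vector<double> P(L + 1);
  const double sqrt2 = std::sqrt(2.0);
  for (int i = 0; i < nn; ++i) {
    for (int j = 0; j < nn; ++j) {
      bool selfpair = (sc.nb[i].idx < 0 || sc.nb[j].idx < 0);
      int lmax_ij;
      if (selfpair) { P[0] = 1.0; lmax_ij = 0; }
      else {
        double cg = sc.nb[i].u[0]*sc.nb[j].u[0] + sc.nb[i].u[1]*sc.nb[j].u[1] +
                    sc.nb[i].u[2]*sc.nb[j].u[2];
        legendre_all(cg, L, P.data(), nullptr);
        lmax_ij = L;
      }
      int zi = sc.nb[i].z, zj = sc.nb[j].z;
      for (int n1 = 0; n1 < sp.n_max; ++n1) {
        int A = zi * sp.n_max + n1;
        for (int n2 = 0; n2 < sp.n_max; ++n2) {
          int B = zj * sp.n_max + n2;
          if (A > B) continue;  // q is symmetric; count ordered pair once
          double fac = (A == B) ? 1.0 : sqrt2;
          double gg = sc.G(i, n1) * sc.G(j, n2);
          int base = tri_index(A, B, sp.M) * (L + 1);
          for (int l = 0; l <= lmax_ij; ++l) {
            p[base + l] += fac * (2 * l + 1) / (4.0 * PI_) * gg * P[l];
          }
        }
      }
    }
  }
  return p;
}

// [[Rcpp::export]]
List cpp_soap_vectors(const NumericMatrix &pos, const IntegerVector &zcode,
                      const LogicalVector &center_mask, const NumericVector &Ldiag,
                      const LogicalVector &pbc, double rc, double sigma,
                      int n_max, int l_max, int n_species) {
  Box box = make_box(Ldiag, pbc);
  SoapPar sp = soap_par(rc, sigma, n_max, l_max, n_species);
  std::vector<int> centers;
  for (int c = 0; c < pos.nrow(); ++c) if (center_mask[c]) centers.push_back(c);
  NumericMatrix out(centers.size(), sp.D);
  for (size_t k = 0; k < centers.size(); ++k) {
    SoapCenter sc = soap_center(pos, zcode, centers[k], box, sp);
    arma::vec p = soap_p(sc, sp);
    for (int d = 0; d < sp.D; ++d) out(k, d) = p[d];
  }
  return List::create(_["P"] = out, _["centers"] = wrap(centers), _["D"] = sp.D);
}

// Gradient of the (unnormalised) power spectrum of one centre with respect to
// the positions of all involved atoms; returned as dense D x 3n matrix
// accumulated over neighbour pairs. Used for kernel-row Jacobians at fit time.
static arma::mat soap_dp(const SoapCenter &sc, const SoapPar &sp, int natoms) {
  const int nn = sc.nb.size(), L = sp.l_max;
  arma::mat dp(sp.D, 3 * natoms, arma::fill::zeros);
  std::vector<double> P(L + 1), dP(L + 1);
  const double sqrt2 = std::sqrt(2.0);
  for (int i = 0; i < nn; ++i) {
    for (int j = 0; j < nn; ++j) {
      const Nbr &Ni = sc.nb[i], &Nj = sc.nb[j];
      bool selfpair = (Ni.idx < 0 || Nj.idx < 0);
      if (Ni.idx < 0 && Nj.idx < 0) {
        continue;  // self-self term is constant
      }
      double cg = 0.0;
      int lmax_ij = 0;
      if (!selfpair) {
        cg = Ni.u[0]*Nj.u[0] + Ni.u[1]*Nj.u[1] + Ni.u[2]*Nj.u[2];
        legendre_all(cg, L, P.data(), dP.data());
        lmax_ij = L;
      } else {
        P[0] = 1.0; dP[0] = 0.0;
      }
      int zi = Ni.z, zj = Nj.z;
      // position derivative building blocks
      // dr_i/dx(atom i) = u_i ; dcg/dd_i = (u_j - cg u_i)/r_i (if i not self)
      for (int n1 = 0; n1 < sp.n_max; ++n1) {
        int A = zi * sp.n_max + n1;
        for (int n2 = 0; n2 < sp.n_max; ++n2) {
          int B = zj * sp.n_max + n2;
          if (A > B) continue;
          double fac = (A == B) ? 1.0 : sqrt2;
          int base = tri_index(A, B, sp.M) * (L + 1);
          for (int l = 0; l <= lmax_ij; ++l) {
            double Cl = fac * (2 * l + 1) / (4.0 * PI_);
            double c1 = Cl * sc.dG(i, n1) * sc.G(j, n2) * P[l]; // via r_i
            double c2 = Cl * sc.G(i, n1) * sc.dG(j, n2) * P[l]; // via r_j
            double c3 = Cl * sc.G(i, n1) * sc.G(j, n2) * dP[l]; // via cg
            for (int x = 0; x < 3; ++x) {
              double gi = 0.0, gj = 0.0;
              if (Ni.idx >= 0) {
                gi += c1 * Ni.u[x];
                if (!selfpair)
                  gi += c3 * (Nj.u[x] - cg * Ni.u[x]) / Ni.r;
              }
              if (Nj.idx >= 0) {
                gj += c2 * Nj.u[x];
                if (!selfpair)
                  gj += c3 * (Ni.u[x] - cg * Nj.u[x]) / Nj.r;
              }
              if (Ni.idx >= 0) dp(base + l, 3 * Ni.idx + x) += gi;
              if (Nj.idx >= 0) dp(base + l, 3 * Nj.idx + x) += gj;
              dp(base + l, 3 * sc.c + x) -= gi + gj;
            }
          }
        }
      }
    }
  }
  return dp;
}

// dk/dp rows for all sparse environments of one centre.
// Phat rows are L2-normalised sparse vectors; k = (phat . phat_s)^zeta.
static void soap_dkdp(const arma::vec &p, const arma::mat &Phat, double zeta,
                      arma::vec &kout, arma::mat &dkdp) {
  double nrm = arma::norm(p);
  const int ns = Phat.n_rows;
  kout.set_size(ns);
  dkdp.set_size(ns, p.n_elem);
  if (nrm < 1e-300) { kout.zeros(); dkdp.zeros(); return; }
  arma::vec ph = p / nrm;
  arma::vec dots = Phat * ph;
  for (int s = 0; s < ns; ++s) {
    // k = d |d|^(zeta-1): equals d^zeta for d >= 0 (the usual case) and is
    // well defined for non-integer zeta; dk/dd = zeta |d|^(zeta-1).
    double d = dots[s];
    double amz = std::pow(std::abs(d), zeta - 1.0);
    kout[s] = d * amz;
    dkdp.row(s) = zeta * amz * (Phat.row(s) - d * ph.t()) / nrm;
  }
}

// [[Rcpp::export]]
List cpp_kernel_soap(const NumericMatrix &pos, const IntegerVector &zcode,
                     const LogicalVector &center_mask, const NumericVector &Ldiag,
                     const LogicalVector &pbc, double rc, double sigma,
                     int n_max, int l_max, int n_species,
                     const NumericMatrix &Phat_in, double zeta, bool want_grad) {
  Box box = make_box(Ldiag, pbc);
  SoapPar sp = soap_par(rc, sigma, n_max, l_max, n_species);
  const int n = pos.nrow();
  arma::mat Phat(Phat_in.begin(), Phat_in.nrow(), Phat_in.ncol());
  if ((int)Phat.n_cols != sp.D) stop("sparse matrix width does not match descriptor");
  std::vector<int> centers;
  for (int c = 0; c < n; ++c) if (center_mask[c]) centers.push_back(c);
  const int nc = centers.size(), ns = Phat.n_rows;

  NumericMatrix K(nc, ns), J;
  if (want_grad) J = NumericMatrix(3 * n, ns);
  arma::vec kout; arma::mat dkdp;
  for (int k = 0; k < nc; ++k) {
    SoapCenter sc = soap_center(pos, zcode, centers[k], box, sp);
    arma::vec p = soap_p(sc, sp);
    soap_dkdp(p, Phat, zeta, kout, dkdp);
    for (int s = 0; s < ns; ++s) K(k, s) = kout[s];
    if (want_grad) {
      arma::mat dp = soap_dp(sc, sp, n);       // D x 3n
      arma::mat Jc = dkdp * dp;                // ns x 3n
      for (int s = 0; s < ns; ++s)
        for (int x = 0; x < 3 * n; ++x) J(x, s) += Jc(s, x);
    }
  }
  return List::create(_["K"] = K, _["J"] = J, _["centers"] = wrap(centers));
}

// Fast prediction path: energy contribution sum_c sum_s w_s k(c, s) and its
// analytic forces via the adjoint lambda = sum_s w_s dk_s/dp per centre.
// [[Rcpp::export]]
List cpp_soap_energy_forces(const NumericMatrix &pos, const IntegerVector &zcode,
                            const LogicalVector &center_mask, const NumericVector &Ldiag,
                            const LogicalVector &pbc, double rc, double sigma,
                            int n_max, int l_max, int n_species,
                            const NumericMatrix &Phat_in, const NumericVector &w,
                            double zeta, bool want_forces) {
  Box box = make_box(Ldiag, pbc);
  SoapPar sp = soap_par(rc, sigma, n_max, l_max, n_species);
  const int n = pos.nrow();
  arma::mat Phat(Phat_in.begin(), Phat_in.nrow(), Phat_in.ncol());
  arma::vec wv(w.begin(), w.size());
  std::vector<int> centers;
  for (int c = 0; c < n; ++c) if (center_mask[c]) centers.push_back(c);

  double energy = 0.0;
  NumericMatrix forces(n, 3);
  NumericVector e_local(centers.size());
  arma::vec kout; arma::mat dkdp;
  const int L = sp.l_max;
  std::vector<double> P(L + 1), dP(L + 1);
  const double sqrt2 = std::sqrt(2.0);

  for (size_t kk = 0; kk < centers.size(); ++kk) {
    SoapCenter sc = soap_center(pos, zcode, centers[kk], box, sp);
    arma::vec p = soap_p(sc, sp);
    soap_dkdp(p, Phat, zeta, kout, dkdp);
    double eloc = arma::dot(kout, wv);
    e_local[kk] = eloc;
    energy += eloc;
    if (!want_forces) continue;
    arma::vec lam = dkdp.t() * wv;   // D adjoint
    // accumulate dE/dx = lam . dp/dx over neighbour pairs
    const int nn = sc.nb.size();
    for (int i = 0; i < nn; ++i) {
      for (int j = 0; j < nn; ++j) {
        const Nbr &Ni = sc.nb[i], &Nj = sc.nb[j];
        if (Ni.idx < 0 && Nj.idx < 0) continue;
        bool selfpair = (Ni.idx < 0 || Nj.idx < 0);
        double cg = 0.0; int lmax_ij = 0;
        if (!selfpair) {
          cg = Ni.u[0]*Nj.u[0] + Ni.u[1]*Nj.u[1] + Ni.u[2]*Nj.u[2];
          legendre_all(cg, L, P.data(), dP.data());
          lmax_ij = L;
        } else { P[0] = 1.0; dP[0] = 0.0; }
        double s_ri = 0.0, s_rj = 0.0, s_cg = 0.0;
        for (int n1 = 0; n1 < sp.n_max; ++n1) {
          int A = Ni.z * sp.n_max + n1;
          for (int n2 = 0; n2 < sp.n_max; ++n2) {
            int B = Nj.z * sp.n_max + n2;
            if (A > B) continue;
            double fac = (A == B) ? 1.0 : sqrt2;
            int base = tri_index(A, B, sp.M) * (L + 1);
            double a1 = 0.0, a2 = 0.0, a3 = 0.0;
            for (int l = 0; l <= lmax_ij; ++l) {
              double lC = lam[base + l] * fac * (2 * l + 1) / (4.0 * PI_);
              a1 += lC * P[l];
              a3 += lC * dP[l];
            }
            a2 = a1;
            s_ri += a1 * sc.dG(i, n1) * sc.G(j, n2);
            s_rj += a2 * sc.G(i, n1) * sc.dG(j, n2);
            s_cg += a3 * sc.G(i, n1) * sc.G(j, n2);
          }
        }
        for (int x = 0; x < 3; ++x) {
          double gi = 0.0, gj = 0.0;
          if (Ni.idx >= 0) {
            gi += s_ri * Ni.u[x];
            if (!selfpair) gi += s_cg * (Nj.u[x] - cg * Ni.u[x]) / Ni.r;
          }
          if (Nj.idx >= 0) {
            gj += s_rj * Nj.u[x];
            if (!selfpair) gj += s_cg * (Ni.u[x] - cg * Nj.u[x]) / Nj.r;
          }
          if (Ni.idx >= 0) forces(Ni.idx, x) -= gi;
          if (Nj.idx >= 0) forces(Nj.idx, x) -= gj;
          forces(sc.c, x) += gi + gj;
        }
      }
    }
  }
  return List::create(_["energy"] = energy, _["forces"] = forces,
                      _["e_local"] = e_local, _["centers"] = wrap(centers));
}
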