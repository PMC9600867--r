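// Element kernels for the plane-strain quasi-incompressible Yeoh model on
// 6-node isoparametric triangles, plus follower-pressure edge loads.
//
// Conventions: nodes in mm, stresses in Pa; the pair (Pa, mm) is a consistent
// per-unit-thickness 2D system, so nodal forces carry Pa*mm. Deformation
// gradients are the in-plane 2x2 block of a plane-strain motion (F33 = 1),
// stored row-major [F11, F12, F21, F22]. Connectivity is 1-based from R.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3-point interior quadrature on the reference triangle (degree 2, weight
// includes the 1/2 reference area). Standard reduced rule for T6 that avoids
// volumetric locking with a penalty formulation.
static const double QP[3][2] = {{1.0/6.0, 1.0/6.0}, {2.0/3.0, 1.0/6.0}, {1.0/6.0, 2.0/3.0}};
static const double QW = 1.0 / 6.0;

static void t6_shape(double xi, double eta, double *N, double *dN) {
  const double L1 = 1.0 - xi - eta, L2 = xi, L3 = eta;
  N[0] = L1 * (2.0 * L1 - 1.0);
  N[1] = L2 * (2.0 * L2 - 1.0);
  N[2] = L3 * (2.0 * L3 - 1.0);
  N[3] = 4.0 * L1 * L2;
  N[4] = 4.0 * L2 * L3;
  N[5] = 4.0 * L3 * L1;
  dN[0 * 2 + 0] = 1.0 - 4.0 * L1;  dN[0 * 2 + 1] = 1.0 - 4.0 * L1;
  dN[1 * 2 + 0] = 4.0 * L2 - 1.0;  dN[1 * 2 + 1] = 0.0;
  dN[2 * 2 + 0] = 0.0;             dN[2 * 2 + 1] = 4.0 * L3 - 1.0;
  dN[3 * 2 + 0] = 4.0 * (L1 - L2); dN[3 * 2 + 1] = -4.0 * L2;
  dN[4 * 2 + 0] = 4.0 * L3;        dN[4 * 2 + 1] = 4.0 * L2;
  dN[5 * 2 + 0] = -4.0 * L3;       dN[5 * 2 + 1] = 4.0 * (L1 - L3);
}

// First Piola-Kirchhoff stress and (optionally) the full material tangent
// A_{iJkL} = dP_{iJ}/dF_{kL} for W = c1 x + c2 x^2 + c3 x^3 + kap/2 (J-1)^2,
// x = Ib1 - 3, Ib1 = J^{-2/3} (tr C + 1). Returns false on J <= 0.
static bool yeoh_pk1(const double *F, double c1, double c2, double c3,
                     double kap, double *P, double *A, bool want_tangent,
                     double *Jout) {
  const double J = F[0] * F[3] - F[1] * F[2];
  if (Jout) *Jout = J;
  if (!(J > 0.0)) return false;
  double Fi[4];  // F^{-1}, row-major (indices F^{-1}_{Ji} = Fi[J*2+i])
  Fi[0] = F[3] / J; Fi[1] = -F[1] / J; Fi[2] = -F[2] / J; Fi[3] = F[0] / J;
  double FiT[4]; // F^{-T}_{iJ}
  FiT[0] = Fi[0]; FiT[1] = Fi[2]; FiT[2] = Fi[1]; FiT[3] = Fi[3];
  const double I1 = F[0] * F[0] + F[1] * F[1] + F[2] * F[2] + F[3] * F[3] + 1.0;
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  const double Ib1 = Jm23 * I1;
  const double x = Ib1 - 3.0;
  const double psi1 = c1 + 2.0 * c2 * x + 3.0 * c3 * x * x;
  const double psi2 = 2.0 * c2 + 6.0 * c3 * x;
  double G[4], H[4];
  for (int m = 0; m < 4; ++m) {
    G[m] = 2.0 * Jm23 * F[m] - (2.0 / 3.0) * Ib1 * FiT[m];
    H[m] = J * FiT[m];
    P[m] = psi1 * G[m] + kap * (J - 1.0) * H[m];
  }
  if (want_tangent) {
    for (int i = 0; i < 2; ++i) for (int Jd = 0; Jd < 2; ++Jd) {
      const int m = i * 2 + Jd;
      for (int k = 0; k < 2; ++k) for (int L = 0; L < 2; ++L) {
        const int n = k * 2 + L;
        const double del = (i == k && Jd == L) ? 1.0 : 0.0;
        const double FiJk = Fi[Jd * 2 + k], FiLi = Fi[L * 2 + i];
        double a = psi2 * G[m] * G[n];
        a += psi1 * (2.0 * Jm23 * del
                     - (4.0 / 3.0) * Jm23 * (F[m] * FiT[n] + F[n] * FiT[m])
                     + (4.0 / 9.0) * Ib1 * FiT[m] * FiT[n]
                     + (2.0 / 3.0) * Ib1 * FiJk * FiLi);
        a += kap * J * (2.0 * J - 1.0) * FiT[m] * FiT[n]
           - kap * (J - 1.0) * J * FiJk * FiLi;
        A[m * 4 + n] = a;
      }
    }
  }
  return true;
}

// Quadratic edge shape functions on xi in [-1, 1]; node order (end1, end2, mid).
static void edge_shape(double xi, double *M, double *dM) {
  M[0] = 0.5 * xi * (xi - 1.0);
  M[1] = 0.5 * xi * (xi + 1.0);
  M[2] = 1.0 - xi * xi;
  dM[0] = xi - 0.5;
  dM[1] = xi + 0.5;
  dM[2] = -2.0 * xi;
}
static const double EQP[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
static const double EQW[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};

// Assemble internal force, follower-pressure external force, and (optionally)
// the consistent tangent in triplet form. Edges traverse the lumen loop
// counterclockwise so the pressure resultant points from the lumen into the
// wall. Returns minJ <= 0 (with empty triplets) when an element inverts.
// [[Rcpp::export]]
List fem_assemble_cpp(NumericMatrix nodes, IntegerMatrix elems,
                      NumericMatrix matpar, NumericVector u, double pressure,
                      IntegerMatrix lumen_edges, bool want_tangent) {
  const int nn = nodes.nrow(), ne = elems.nrow(), nl = lumen_edges.nrow();
  NumericVector fint(2 * nn), fext(2 * nn);
  const R_xlen_t ntrip = want_tangent ? (R_xlen_t)ne * 144 + (R_xlen_t)nl * 36 : 0;
  IntegerVector ti(ntrip), tj(ntrip);
  NumericVector tx(ntrip);
  R_xlen_t pos = 0;
  double minJ = R_PosInf;

  double N[6], dN[12], dNdX[12], J0[4], J0i[4], F[4], P[4], A[16];
  for (int e = 0; e < ne; ++e) {
    const double c1 = matpar(e, 0), c2 = matpar(e, 1), c3 = matpar(e, 2),
                 kap = matpar(e, 3);
    int cn[6];
    double xe[12], ue[12];
    for (int a = 0; a < 6; ++a) {
      cn[a] = elems(e, a) - 1;
      xe[2 * a] = nodes(cn[a], 0); xe[2 * a + 1] = nodes(cn[a], 1);
      ue[2 * a] = u[2 * cn[a]];    ue[2 * a + 1] = u[2 * cn[a] + 1];
    }
    double Ke[144];
    if (want_tangent) std::fill(Ke, Ke + 144, 0.0);
    double fe[12] = {0};
    for (int q = 0; q < 3; ++q) {
      t6_shape(QP[q][0], QP[q][1], N, dN);
      J0[0] = J0[1] = J0[2] = J0[3] = 0.0;
      for (int a = 0; a < 6; ++a) {
        J0[0] += dN[2 * a] * xe[2 * a];      // dX/dxi
        J0[1] += dN[2 * a + 1] * xe[2 * a];  // dX/deta
        J0[2] += dN[2 * a] * xe[2 * a + 1];  // dY/dxi
        J0[3] += dN[2 * a + 1] * xe[2 * a + 1];
      }
      const double detJ0 = J0[0] * J0[3] - J0[1] * J0[2];
      if (!(detJ0 > 0.0)) { minJ = -1.0; break; }
      J0i[0] = J0[3] / detJ0; J0i[1] = -J0[1] / detJ0;
      J0i[2] = -J0[2] / detJ0; J0i[3] = J0[0] / detJ0;
      for (int a = 0; a < 6; ++a) {
        dNdX[2 * a]     = dN[2 * a] * J0i[0] + dN[2 * a + 1] * J0i[2];
        dNdX[2 * a + 1] = dN[2 * a] * J0i[1] + dN[2 * a + 1] * J0i[3];
      }
      F[0] = 1.0; F[1] = 0.0; F[2] = 0.0; F[3] = 1.0;
      for (int a = 0; a < 6; ++a) {
        F[0] += ue[2 * a] * dNdX[2 * a];
        F[1] += ue[2 * a] * dNdX[2 * a + 1];
        F[2] += ue[2 * a + 1] * dNdX[2 * a];
        F[3] += ue[2 * a + 1] * dNdX[2 * a + 1];
      }
      double Jdet;
      if (!yeoh_pk1(F, c1, c2, c3, kap, P, A, want_tangent, &Jdet)) {
        minJ = Jdet; break;
      }
      if (Jdet < minJ) minJ = Jdet;
      const double w = QW * detJ0;
      for (int a = 0; a < 6; ++a) {
        fe[2 * a]     += w * (P[0] * dNdX[2 * a] + P[1] * dNdX[2 * a + 1]);
        fe[2 * a + 1] += w * (P[2] * dNdX[2 * a] + P[3] * dNdX[2 * a + 1]);
      }
      if (want_tangent) {
        for (int a = 0; a < 6; ++a) for (int i = 0; i < 2; ++i) {
          for (int b = 0; b < 6; ++b) for (int k = 0; k < 2; ++k) {
            double s = 0.0;
            for (int Jd = 0; Jd < 2; ++Jd) for (int L = 0; L < 2; ++L)
              s += dNdX[2 * a + Jd] * A[(i * 2 + Jd) * 4 + (k * 2 + L)] * dNdX[2 * b + L];
            Ke[(2 * a + i) * 12 + (2 * b + k)] += w * s;
          }
        }
      }
    }
    if (!(minJ > 0.0)) {
      return List::create(_["ok"] = false, _["minJ"] = minJ, _["element"] = e + 1);
    }
    for (int a = 0; a < 6; ++a) {
      fint[2 * cn[a]]     += fe[2 * a];
      fint[2 * cn[a] + 1] += fe[2 * a + 1];
    }
    if (want_tangent) {
      for (int a = 0; a < 6; ++a) for (int i = 0; i < 2; ++i)
        for (int b = 0; b < 6; ++b) for (int k = 0; k < 2; ++k) {
          ti[pos] = 2 * cn[a] + i + 1;
          tj[pos] = 2 * cn[b] + k + 1;
          tx[pos] = Ke[(2 * a + i) * 12 + (2 * b + k)];
          ++pos;
        }
    }
  }

  // Follower pressure on the deformed lumen boundary: for a CCW loop the
  // force density per unit parameter is p * (t_y, -t_x), t = dy/dxi.
  double M[3], dM[3];
  for (int l = 0; l < nl; ++l) {
    int en[3];
    double ye[6];
    for (int a = 0; a < 3; ++a) {
      en[a] = lumen_edges(l, a) - 1;
      ye[2 * a]     = nodes(en[a], 0) + u[2 * en[a]];
      ye[2 * a + 1] = nodes(en[a], 1) + u[2 * en[a] + 1];
    }
    double fe[6] = {0}, Kl[36] = {0};
    for (int q = 0; q < 3; ++q) {
      edge_shape(EQP[q], M, dM);
      double tx_ = 0.0, ty_ = 0.0;
      for (int a = 0; a < 3; ++a) { tx_ += dM[a] * ye[2 * a]; ty_ += dM[a] * ye[2 * a + 1]; }
      for (int a = 0; a < 3; ++a) {
        fe[2 * a]     += EQW[q] * pressure * M[a] * ty_;
        fe[2 * a + 1] -= EQW[q] * pressure * M[a] * tx_;
      }
      if (want_tangent) {
        // d fext_a / d y_b = p * w * M_a * [[0, dM_b], [-dM_b, 0]]
        for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) {
          Kl[(2 * a) * 6 + (2 * b + 1)]     += EQW[q] * pressure * M[a] * dM[b];
          Kl[(2 * a + 1) * 6 + (2 * b)]     -= EQW[q] * pressure * M[a] * dM[b];
        }
      }
    }
    for (int a = 0; a < 3; ++a) {
      fext[2 * en[a]]     += fe[2 * a];
      fext[2 * en[a] + 1] += fe[2 * a + 1];
    }
    if (want_tangent) {
      for (int a = 0; a < 3; ++a) for (int i = 0; i < 2; ++i)
        for (int b = 0; b < 3; ++b) for (int k = 0; k < 2; ++k) {
          ti[pos] = 2 * en[a] + i + 1;
          tj[pos] = 2 * en[b] + k + 1;
          tx[pos] = -Kl[(2 * a + i) * 6 + (2 * b + k)];  // K = dR/du, R = fint - fext
          ++pos;
        }
    }
  }

  return List::create(_["ok"] = true, _["fint"] = fint, _["fext"] = fext,
                      _["i"] = ti, _["j"] = tj, _["x"] = tx, _["minJ"] = minJ);
}

// Per-element quadrature-averaged deformation gradient, per-quadrature-point
// J = det F, and per-element reference areas (quadrature sums).
// [[Rcpp::export]]
List fem_defgrad_cpp(NumericMatrix nodes, IntegerMatrix elems, NumericVector u) {
  const int ne = elems.nrow();
  NumericMatrix Fbar(ne, 4);
  NumericMatrix Jqp(ne, 3);
  NumericVector area(ne);
  double N[6], dN[12], dNdX[12], J0[4], J0i[4];
  for (int e = 0; e < ne; ++e) {
    int cn[6];
    double xe[12], ue[12];
    for (int a = 0; a < 6; ++a) {
      cn[a] = elems(e, a) - 1;
      xe[2 * a] = nodes(cn[a], 0); xe[2 * a + 1] = nodes(cn[a], 1);
      ue[2 * a] = u[2 * cn[a]];    ue[2 * a + 1] = u[2 * cn[a] + 1];
    }
    double Fs[4] = {0, 0, 0, 0}, wtot = 0.0;
    for (int q = 0; q < 3; ++q) {
      t6_shape(QP[q][0], QP[q][1], N, dN);
      J0[0] = J0[1] = J0[2] = J0[3] = 0.0;
      for (int a = 0; a < 6; ++a) {
        J0[0] += dN[2 * a] * xe[2 * a];
        J0[1] += dN[2 * a + 1] * xe[2 * a];
        J0[2] += dN[2 * a] * xe[2 * a + 1];
        J0[3] += dN[2 * a + 1] * xe[2 * a + 1];
      }
      const double detJ0 = J0[0] * J0[3] - J0[1] * J0[2];
      J0i[0] = J0[3] / detJ0; J0i[1] = -J0[1] / detJ0;
      J0i[2] = -J0[2] / detJ0; J0i[3] = J0[0] / detJ0;
      for (int a = 0; a < 6; ++a) {
        dNdX[2 * a]     = dN[2 * a] * J0i[0] + dN[2 * a + 1] * J0i[2];
        dNdX[2 * a + 1] = dN[2 * a] * J0i[1] + dN[2 * a + 1] * J0i[3];
      }
      double F[4] = {1.0, 0.0, 0.0, 1.0};
      for (int a = 0; a < 6; ++a) {
        F[0] += ue[2 * a] * dNdX[2 * a];
        F[1] += ue[2 * a] * dNdX[2 * a + 1];
        F[2] += ue[2 * a + 1] * dNdX[2 * a];
        F[3] += ue[2 * a + 1] * dNdX[2 * a + 1];
      }
      const double w = QW * detJ0;
      for (int m = 0; m < 4; ++m) Fs[m] += w * F[m];
      Jqp(e, q) = F[0] * F[3] - F[1] * F[2];
      wtot += w;
      area[e] += w;
    }
    for (int m = 0; m < 4; ++m) Fbar(e, m) = Fs[m] / wtot;
  }
  return List::create(_["F"] = Fbar, _["Jqp"] = Jqp, _["area"] = area);
}
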