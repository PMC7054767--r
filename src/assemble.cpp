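#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Element assembly for the P2/P1 (Taylor-Hood) discretization of the
// generalized Navier-Stokes momentum/continuity system on triangles.
//
// Velocity block K collects (rho/dt) mass (backward Euler), the symmetric-
// gradient viscous form 2 mu(s(u_n)) D(u):D(v) with the viscosity lagged at
// the previous velocity, and the linearized convection rho (u_n . grad) u.
// B is the divergence coupling int L_k d_b N_j.  All quantities are SI.
//
// Dof layout (1-based): ux_i = i (i = 1..n2), uy_i = n2 + i with
// n2 = nv + ne; pressure dofs follow at 2 n2 + 1 .. 2 n2 + nv.
//
// Two entry points share the element worker: .assemble_ns returns global
// triplets (pattern + values); .assemble_fill accumulates values directly
// into a cached CSC slot layout for the fixed-pattern time loop.

// 7-point degree-5 quadrature (barycentric, weights sum to 1)
static const double QW[7] = {
  0.225,
  0.13239415278850619, 0.13239415278850619, 0.13239415278850619,
  0.12593918054482713, 0.12593918054482713, 0.12593918054482713};
static const double QA[7] = {
  1.0 / 3.0,
  0.059715871789769797, 0.47014206410511511, 0.47014206410511511,
  0.79742698535308732, 0.10128650732345633, 0.10128650732345633};
static const double QB[7] = {
  1.0 / 3.0,
  0.47014206410511511, 0.059715871789769797, 0.47014206410511511,
  0.10128650732345633, 0.79742698535308732, 0.10128650732345633};

struct RefBasis {
  double N[7][6];
  double dN[6][2][7];
  RefBasis() {
    const double g1[2] = {-1, -1}, g2[2] = {1, 0}, g3[2] = {0, 1};
    for (int q = 0; q < 7; ++q) {
      double L2 = QA[q], L3 = QB[q], L1 = 1.0 - L2 - L3;
      N[q][0] = L1 * (2 * L1 - 1);
      N[q][1] = L2 * (2 * L2 - 1);
      N[q][2] = L3 * (2 * L3 - 1);
      N[q][3] = 4 * L2 * L3; // edge opposite vertex 1
      N[q][4] = 4 * L3 * L1; // edge opposite vertex 2
      N[q][5] = 4 * L1 * L2; // edge opposite vertex 3
      for (int d = 0; d < 2; ++d) {
        dN[0][d][q] = (4 * L1 - 1) * g1[d];
        dN[1][d][q] = (4 * L2 - 1) * g2[d];
        dN[2][d][q] = (4 * L3 - 1) * g3[d];
        dN[3][d][q] = 4 * (L2 * g3[d] + L3 * g2[d]);
        dN[4][d][q] = 4 * (L3 * g1[d] + L1 * g3[d]);
        dN[5][d][q] = 4 * (L1 * g2[d] + L2 * g1[d]);
      }
    }
  }
};
static const RefBasis REF;

// Compute the local matrices of one element about the lagged velocity.
static inline void element_mats(
    const double* cx, const double* cy, const int* tri_row,
    const int* edge_row, int nv, int n2, const double* u_lag,
    int visc_model, double mu_const, double mu0, double mu_inf,
    double lambda, double nexp, double rho, double dt,
    bool steady, bool convect,
    int* g, double Kloc[12][12], double Bloc[3][12], double rloc[12]) {
  int v1 = tri_row[0] - 1, v2 = tri_row[1] - 1, v3 = tri_row[2] - 1;
  double x1 = cx[v1], y1 = cy[v1];
  double J11 = cx[v2] - x1, J12 = cx[v3] - x1;
  double J21 = cy[v2] - y1, J22 = cy[v3] - y1;
  double det = J11 * J22 - J12 * J21;
  double adet = std::fabs(det);
  double it11 = J22 / det, it12 = -J21 / det;
  double it21 = -J12 / det, it22 = J11 / det;

  g[0] = v1 + 1; g[1] = v2 + 1; g[2] = v3 + 1;
  g[3] = nv + edge_row[0];
  g[4] = nv + edge_row[1];
  g[5] = nv + edge_row[2];

  for (int i = 0; i < 12; ++i) {
    rloc[i] = 0;
    for (int j = 0; j < 12; ++j) Kloc[i][j] = 0;
  }
  for (int k = 0; k < 3; ++k)
    for (int j = 0; j < 12; ++j) Bloc[k][j] = 0;

  for (int q = 0; q < 7; ++q) {
    double w = 0.5 * QW[q] * adet;
    double dNx[6], dNy[6];
    for (int i = 0; i < 6; ++i) {
      dNx[i] = it11 * REF.dN[i][0][q] + it12 * REF.dN[i][1][q];
      dNy[i] = it21 * REF.dN[i][0][q] + it22 * REF.dN[i][1][q];
    }
    double ux = 0, uy = 0, g11 = 0, g12 = 0, g21 = 0, g22 = 0;
    for (int i = 0; i < 6; ++i) {
      double a = u_lag[g[i] - 1];
      double b = u_lag[n2 + g[i] - 1];
      ux += a * REF.N[q][i]; uy += b * REF.N[q][i];
      g11 += a * dNx[i]; g12 += a * dNy[i];
      g21 += b * dNx[i]; g22 += b * dNy[i];
    }
    double mu;
    if (visc_model == 1) {
      double d12 = 0.5 * (g12 + g21);
      double s = std::sqrt(2.0 * (g11 * g11 + g22 * g22 + 2 * d12 * d12));
      mu = mu_inf + (mu0 - mu_inf) *
        std::pow(1.0 + lambda * lambda * s * s, (nexp - 1.0) / 2.0);
    } else {
      mu = mu_const;
    }
    double md = steady ? 0.0 : rho / dt;
    for (int i = 0; i < 6; ++i) {
      double Ni = REF.N[q][i];
      double conv_i = convect ? rho * Ni : 0.0;
      for (int j = 0; j < 6; ++j) {
        double gg = dNx[i] * dNx[j] + dNy[i] * dNy[j];
        double diag = mu * gg + md * Ni * REF.N[q][j];
        if (convect) diag += conv_i * (ux * dNx[j] + uy * dNy[j]);
        // cross term of 2 mu D(u):D(v)
        Kloc[i][j]         += w * (diag + mu * dNx[j] * dNx[i]);
        Kloc[i][6 + j]     += w * mu * dNy[j] * dNx[i];
        Kloc[6 + i][j]     += w * mu * dNx[j] * dNy[i];
        Kloc[6 + i][6 + j] += w * (diag + mu * dNy[j] * dNy[i]);
      }
      if (!steady) {
        rloc[i] += w * md * Ni * ux;
        rloc[6 + i] += w * md * Ni * uy;
      }
    }
    double Lq[3] = {1.0 - QA[q] - QB[q], QA[q], QB[q]};
    for (int k = 0; k < 3; ++k) {
      for (int j = 0; j < 6; ++j) {
        Bloc[k][j] += w * Lq[k] * dNx[j];
        Bloc[k][6 + j] += w * Lq[k] * dNy[j];
      }
    }
  }
}

// [[Rcpp::export(name = ".assemble_ns")]]
List assemble_ns(NumericMatrix coords, IntegerMatrix tri,
                 IntegerMatrix tri_edges, int ne,
                 NumericVector u_lag,
                 int visc_model, double mu_const, double mu0, double mu_inf,
                 double lambda, double nexp, double rho, double dt,
                 bool steady, bool convect) {
  const int nv = coords.nrow();
  const int nt = tri.nrow();
  const int n2 = nv + ne;

  IntegerVector Ki(nt * 144), Kj(nt * 144);
  NumericVector Kx(nt * 144);
  IntegerVector Bi(nt * 36), Bj(nt * 36);
  NumericVector Bx(nt * 36);
  NumericVector rhs(2 * n2);

  std::vector<double> cx(nv), cy(nv);
  for (int i = 0; i < nv; ++i) { cx[i] = coords(i, 0); cy[i] = coords(i, 1); }

  int kk = 0, kb = 0;
  int g[6]; double Kloc[12][12], Bloc[3][12], rloc[12];
  int trow[3], erow[3];
  for (int t = 0; t < nt; ++t) {
    for (int k = 0; k < 3; ++k) { trow[k] = tri(t, k); erow[k] = tri_edges(t, k); }
    element_mats(cx.data(), cy.data(), trow, erow, nv, n2, u_lag.begin(),
                 visc_model, mu_const, mu0, mu_inf, lambda, nexp, rho, dt,
                 steady, convect, g, Kloc, Bloc, rloc);
    for (int i = 0; i < 6; ++i) {
      for (int a = 0; a < 2; ++a) {
        int gi = g[i] + a * n2;
        rhs[gi - 1] += rloc[a * 6 + i];
        for (int j = 0; j < 6; ++j) {
          for (int b = 0; b < 2; ++b) {
            Ki[kk] = gi;
            Kj[kk] = g[j] + b * n2;
            Kx[kk] = Kloc[a * 6 + i][b * 6 + j];
            ++kk;
          }
        }
      }
    }
    for (int k = 0; k < 3; ++k) {
      for (int j = 0; j < 6; ++j) {
        for (int b = 0; b < 2; ++b) {
          Bi[kb] = trow[k];
          Bj[kb] = g[j] + b * n2;
          Bx[kb] = Bloc[k][b * 6 + j];
          ++kb;
        }
      }
    }
  }
  return List::create(_["ki"] = Ki, _["kj"] = Kj, _["kx"] = Kx,
                      _["bi"] = Bi, _["bj"] = Bj, _["bx"] = Bx,
                      _["rhs"] = rhs);
}

// Fixed-pattern fill: accumulates element values directly into the reduced
// CSC value vector xs (via precomputed slot streams, same entry order as
// .assemble_ns) and collects Dirichlet-column contributions into rhsdir
// (indexed by reduced row).  redmap[dof] = reduced index (0 if Dirichlet),
// over the full layout [ux, uy, p].
// [[Rcpp::export(name = ".assemble_fill")]]
List assemble_fill(NumericMatrix coords, IntegerMatrix tri,
                   IntegerMatrix tri_edges, int ne,
                   NumericVector u_lag,
                   int visc_model, double mu_const, double mu0, double mu_inf,
                   double lambda, double nexp, double rho, double dt,
                   bool steady, bool convect,
                   IntegerVector slotK, IntegerVector slotB,
                   IntegerVector slotTB,
                   IntegerVector redmap, NumericVector dirval,
                   int nnz, int nfree) {
  const int nv = coords.nrow();
  const int nt = tri.nrow();
  const int n2 = nv + ne;

  NumericVector xs(nnz), rhsdir(nfree), rhs(2 * n2);
  std::vector<double> cx(nv), cy(nv);
  for (int i = 0; i < nv; ++i) { cx[i] = coords(i, 0); cy[i] = coords(i, 1); }

  int kk = 0, kb = 0;
  int g[6]; double Kloc[12][12], Bloc[3][12], rloc[12];
  int trow[3], erow[3];
  for (int t = 0; t < nt; ++t) {
    for (int k = 0; k < 3; ++k) { trow[k] = tri(t, k); erow[k] = tri_edges(t, k); }
    element_mats(cx.data(), cy.data(), trow, erow, nv, n2, u_lag.begin(),
                 visc_model, mu_const, mu0, mu_inf, lambda, nexp, rho, dt,
                 steady, convect, g, Kloc, Bloc, rloc);
    for (int i = 0; i < 6; ++i) {
      for (int a = 0; a < 2; ++a) {
        int gi = g[i] + a * n2;
        int ri = redmap[gi - 1];
        if (ri) rhs[gi - 1] += rloc[a * 6 + i];
        for (int j = 0; j < 6; ++j) {
          for (int b = 0; b < 2; ++b) {
            double v = Kloc[a * 6 + i][b * 6 + j];
            int s = slotK[kk++];
            if (s > 0) {
              xs[s - 1] += v;
            } else if (ri) {
              int gj = g[j] + b * n2;
              if (!redmap[gj - 1]) rhsdir[ri - 1] += v * dirval[gj - 1];
            }
          }
        }
      }
    }
    for (int k = 0; k < 3; ++k) {
      int rp = redmap[2 * n2 + trow[k] - 1];
      for (int j = 0; j < 6; ++j) {
        for (int b = 0; b < 2; ++b) {
          double v = Bloc[k][b * 6 + j];
          int gj = g[j] + b * n2;
          int sB = slotB[kb], sT = slotTB[kb];
          ++kb;
          if (sB > 0) xs[sB - 1] += v;        // continuity row
          else if (rp && !redmap[gj - 1]) rhsdir[rp - 1] += v * dirval[gj - 1];
          if (sT > 0) xs[sT - 1] -= v;        // -t(B) pressure gradient
        }
      }
    }
  }
  return List::create(_["xs"] = xs, _["rhsdir"] = rhsdir, _["rhs"] = rhs);
}

// Shear rate of the P2 velocity field at triangle centroids (diagnostics).
// [[Rcpp::export(name = ".shear_field")]]
NumericVector shear_field(NumericMatrix coords, IntegerMatrix tri,
                          IntegerMatrix tri_edges, int ne,
                          NumericVector u) {
  const int nv = coords.nrow();
  const int nt = tri.nrow();
  const int n2 = nv + ne;
  NumericVector out(nt);
  const double c = 1.0 / 3.0;
  const double g1[2] = {-1, -1}, g2[2] = {1, 0}, g3[2] = {0, 1};
  for (int t = 0; t < nt; ++t) {
    int v1 = tri(t, 0) - 1, v2 = tri(t, 1) - 1, v3 = tri(t, 2) - 1;
    double J11 = coords(v2, 0) - coords(v1, 0);
    double J12 = coords(v3, 0) - coords(v1, 0);
    double J21 = coords(v2, 1) - coords(v1, 1);
    double J22 = coords(v3, 1) - coords(v1, 1);
    double det = J11 * J22 - J12 * J21;
    double it11 = J22 / det, it12 = -J21 / det;
    double it21 = -J12 / det, it22 = J11 / det;
    int g[6] = {v1 + 1, v2 + 1, v3 + 1,
                nv + tri_edges(t, 0), nv + tri_edges(t, 1),
                nv + tri_edges(t, 2)};
    double dl[6][2];
    for (int d = 0; d < 2; ++d) {
      dl[0][d] = (4 * c - 1) * g1[d];
      dl[1][d] = (4 * c - 1) * g2[d];
      dl[2][d] = (4 * c - 1) * g3[d];
      dl[3][d] = 4 * (c * g3[d] + c * g2[d]);
      dl[4][d] = 4 * (c * g1[d] + c * g3[d]);
      dl[5][d] = 4 * (c * g2[d] + c * g1[d]);
    }
    double g11 = 0, g12 = 0, g21 = 0, g22 = 0;
    for (int i = 0; i < 6; ++i) {
      double dx = it11 * dl[i][0] + it12 * dl[i][1];
      double dy = it21 * dl[i][0] + it22 * dl[i][1];
      double a = u[g[i] - 1], b = u[n2 + g[i] - 1];
      g11 += a * dx; g12 += a * dy; g21 += b * dx; g22 += b * dy;
    }
    double d12 = 0.5 * (g12 + g21);
    out[t] = std::sqrt(2.0 * (g11 * g11 + g22 * g22 + 2 * d12 * d12));
  }
  return out;
}
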