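#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Quasi-static incompressible transversely isotropic hyperelasticity kernels.
// Taylor-Hood P2/P1 tetrahedra: quadratic displacements on 10-node tets,
// linear hydrostatic-pressure multiplier on the 4 vertices. Element residuals
// are analytic; element tangents are forward finite differences of the
// residual (the residual stays exact, so converged solutions are unaffected).
//
// Units: mm, kPa (stress, energy density), mN-consistent forces.

static const double QP_A = 0.5854101966249685; // 4-point degree-2 tet rule
static const double QP_B = 0.1381966011250105;

struct ElemScratch {
  double dN[4][10][3];  // shape gradients per qp (depends on geometry only)
  double lam[4][4];     // P1 barycentric values per qp
  double N10[4][10];    // P2 values per qp
  double w[4];          // quadrature weights (include |detJ|/6 * 1/4)
  double f0[3];
};

static inline double det3(const double F[3][3]) {
  return F[0][0]*(F[1][1]*F[2][2]-F[1][2]*F[2][1])
       - F[0][1]*(F[1][0]*F[2][2]-F[1][2]*F[2][0])
       + F[0][2]*(F[1][0]*F[2][1]-F[1][1]*F[2][0]);
}

static inline void inv3(const double F[3][3], double J, double Fi[3][3]) {
  const double id = 1.0 / J;
  Fi[0][0] =  (F[1][1]*F[2][2]-F[1][2]*F[2][1])*id;
  Fi[0][1] = -(F[0][1]*F[2][2]-F[0][2]*F[2][1])*id;
  Fi[0][2] =  (F[0][1]*F[1][2]-F[0][2]*F[1][1])*id;
  Fi[1][0] = -(F[1][0]*F[2][2]-F[1][2]*F[2][0])*id;
  Fi[1][1] =  (F[0][0]*F[2][2]-F[0][2]*F[2][0])*id;
  Fi[1][2] = -(F[0][0]*F[1][2]-F[0][2]*F[1][0])*id;
  Fi[2][0] =  (F[1][0]*F[2][1]-F[1][1]*F[2][0])*id;
  Fi[2][1] = -(F[0][0]*F[2][1]-F[0][1]*F[2][0])*id;
  Fi[2][2] =  (F[0][0]*F[1][1]-F[0][1]*F[1][0])*id;
}

static inline double cap_exp(double x) { return std::exp(x > 60.0 ? 60.0 : x); }

// Element residual: 30 displacement dofs + 4 multiplier dofs.
// Returns false if det F <= 0 was met at a quadrature point.
static bool elem_residual(const ElemScratch &S,
                          const double ue[10][3], const double pe[4],
                          double a, double b, double af, double bf,
                          double eta, double Ta, bool fiber_comp,
                          double re[34],
                          double *acc_vol, double *acc_jerr, double *minJ,
                          double sig_acc[6]) {
  for (int i = 0; i < 34; ++i) re[i] = 0.0;
  bool ok = true;
  for (int q = 0; q < 4; ++q) {
    double F[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int n = 0; n < 10; ++n)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[i][j] += ue[n][i]*S.dN[q][n][j];
    const double J = det3(F);
    if (!(J > 0.0)) { ok = false; }
    double Fi[3][3];
    inv3(F, (J > 1e-12 || J < -1e-12) ? J : 1e-12, Fi);

    // C = F^T F, invariants
    double C[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        C[i][j] = F[0][i]*F[0][j] + F[1][i]*F[1][j] + F[2][i]*F[2][j];
    const double I1 = C[0][0] + C[1][1] + C[2][2];
    double Cf[3];
    for (int i = 0; i < 3; ++i)
      Cf[i] = C[i][0]*S.f0[0] + C[i][1]*S.f0[1] + C[i][2]*S.f0[2];
    const double I4 = S.f0[0]*Cf[0] + S.f0[1]*Cf[1] + S.f0[2]*Cf[2];

    // 2nd Piola-Kirchhoff stress of the passive law
    const double c1 = a * cap_exp(b*(I1 - 3.0));
    double c4 = 2.0 * af * (I4 - 1.0) * cap_exp(bf*(I4-1.0)*(I4-1.0));
    if (!fiber_comp && I4 < 1.0) c4 = 0.0;
    // P = F S + p J F^{-T} + J sigma_a F^{-T}
    double pq = 0.0;
    for (int v = 0; v < 4; ++v) pq += S.lam[q][v]*pe[v];

    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double FS = c1*F[i][j] + c4*(F[i][0]*S.f0[0]+F[i][1]*S.f0[1]+F[i][2]*S.f0[2])*S.f0[j];
        P[i][j] = FS + pq*J*Fi[j][i];
      }

    double sig_a[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    if (Ta > 0.0) {
      double ff[3] = { F[0][0]*S.f0[0]+F[0][1]*S.f0[1]+F[0][2]*S.f0[2],
                       F[1][0]*S.f0[0]+F[1][1]*S.f0[1]+F[1][2]*S.f0[2],
                       F[2][0]*S.f0[0]+F[2][1]*S.f0[1]+F[2][2]*S.f0[2] };
      const double nrm = std::sqrt(ff[0]*ff[0]+ff[1]*ff[1]+ff[2]*ff[2]);
      if (nrm > 1e-12) { ff[0]/=nrm; ff[1]/=nrm; ff[2]/=nrm; }
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          sig_a[i][j] = Ta*((1.0-eta)*ff[i]*ff[j] + (i==j ? eta : 0.0));
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0.0;
          for (int k = 0; k < 3; ++k) s += sig_a[i][k]*Fi[j][k];
          P[i][j] += J*s;
        }
    }

    const double w = S.w[q];
    for (int n = 0; n < 10; ++n)
      for (int i = 0; i < 3; ++i)
        re[3*n+i] += w*(P[i][0]*S.dN[q][n][0] + P[i][1]*S.dN[q][n][1] + P[i][2]*S.dN[q][n][2]);
    for (int v = 0; v < 4; ++v)
      re[30+v] += w*(J - 1.0)*S.lam[q][v];

    if (acc_vol) {
      *acc_vol += w;
      *acc_jerr += w*std::fabs(J - 1.0);
      if (J < *minJ) *minJ = J;
      // mean Cauchy stress sigma = (1/J) P F^T (includes multiplier + active)
      double sig[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0.0;
          for (int k = 0; k < 3; ++k) s += P[i][k]*F[j][k];
          sig[i][j] = s / (J > 1e-12 ? J : 1e-12);
        }
      sig_acc[0] += w*sig[0][0]; sig_acc[1] += w*sig[1][1]; sig_acc[2] += w*sig[2][2];
      sig_acc[3] += w*0.5*(sig[0][1]+sig[1][0]);
      sig_acc[4] += w*0.5*(sig[0][2]+sig[2][0]);
      sig_acc[5] += w*0.5*(sig[1][2]+sig[2][1]);
    }
  }
  return ok;
}

// [[Rcpp::export(name = ".fe_assemble")]]
List fe_assemble(NumericMatrix nodes, IntegerMatrix conn,
                 NumericMatrix u, NumericVector pmult,
                 NumericMatrix fibers, NumericVector mat,
                 double Ta, bool fiber_comp, int nv,
                 bool tangent, double eps_u, double eps_p) {
  const int nt = conn.nrow();
  const int nP2 = nodes.nrow();
  const int ndof = 3*nP2 + nv;
  const double a = mat[0], b = mat[1], af = mat[2], bf = mat[3], eta = mat[4];

  NumericVector res(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (tangent) { ti.reserve((size_t)nt*1156); tj.reserve((size_t)nt*1156); tx.reserve((size_t)nt*1156); }

  // quadrature barycentric coordinates
  double lamq[4][4];
  for (int q = 0; q < 4; ++q)
    for (int v = 0; v < 4; ++v) lamq[q][v] = (q == v) ? QP_A : QP_B;

  double acc_vol = 0.0, acc_jerr = 0.0, minJ = 1e30;
  double sig_acc[6] = {0,0,0,0,0,0};
  bool all_ok = true;

  ElemScratch S;
  double ue[10][3], pe[4], re0[34], re1[34];
  int gdof[34];

  for (int e = 0; e < nt; ++e) {
    int vid[10];
    for (int n = 0; n < 10; ++n) vid[n] = conn(e,n) - 1;
    // geometry from vertex nodes
    double X[4][3];
    for (int v = 0; v < 4; ++v)
      for (int i = 0; i < 3; ++i) X[v][i] = nodes(vid[v], i);
    double Jm[3][3];
    for (int i = 0; i < 3; ++i)
      for (int c = 0; c < 3; ++c) Jm[i][c] = X[c+1][i] - X[0][i];
    const double detJ = det3(Jm);
    double Ji[3][3];
    inv3(Jm, detJ, Ji);
    // grad lambda: rows of J^{-1} give grad of (lambda2,3,4); lambda1 = -sum
    double gl[4][3];
    for (int c = 0; c < 3; ++c) {
      gl[1][c] = Ji[0][c]; gl[2][c] = Ji[1][c]; gl[3][c] = Ji[2][c];
      gl[0][c] = -(Ji[0][c]+Ji[1][c]+Ji[2][c]);
    }
    static const int E1[6] = {0,0,0,1,1,2}, E2[6] = {1,2,3,2,3,3};
    for (int q = 0; q < 4; ++q) {
      S.w[q] = std::fabs(detJ)/24.0;
      for (int v = 0; v < 4; ++v) {
        S.lam[q][v] = lamq[q][v];
        S.N10[q][v] = lamq[q][v]*(2.0*lamq[q][v]-1.0);
        for (int c = 0; c < 3; ++c)
          S.dN[q][v][c] = (4.0*lamq[q][v]-1.0)*gl[v][c];
      }
      for (int k = 0; k < 6; ++k) {
        const int i = E1[k], j = E2[k];
        S.N10[q][4+k] = 4.0*lamq[q][i]*lamq[q][j];
        for (int c = 0; c < 3; ++c)
          S.dN[q][4+k][c] = 4.0*(lamq[q][i]*gl[j][c] + lamq[q][j]*gl[i][c]);
      }
    }
    for (int c = 0; c < 3; ++c) S.f0[c] = fibers(e,c);

    for (int n = 0; n < 10; ++n)
      for (int i = 0; i < 3; ++i) ue[n][i] = u(vid[n], i);
    for (int v = 0; v < 4; ++v) pe[v] = pmult[vid[v]];

    bool ok = elem_residual(S, ue, pe, a, b, af, bf, eta, Ta, fiber_comp,
                            re0, &acc_vol, &acc_jerr, &minJ, sig_acc);
    if (!ok) all_ok = false;

    for (int n = 0; n < 10; ++n)
      for (int i = 0; i < 3; ++i) gdof[3*n+i] = 3*vid[n] + i;
    for (int v = 0; v < 4; ++v) gdof[30+v] = 3*nP2 + vid[v];

    for (int d = 0; d < 34; ++d) res[gdof[d]] += re0[d];

    if (tangent) {
      for (int d = 0; d < 34; ++d) {
        const double eps = (d < 30) ? eps_u : eps_p;
        if (d < 30) ue[d/3][d%3] += eps; else pe[d-30] += eps;
        elem_residual(S, ue, pe, a, b, af, bf, eta, Ta, fiber_comp,
                      re1, NULL, NULL, NULL, NULL);
        if (d < 30) ue[d/3][d%3] -= eps; else pe[d-30] -= eps;
        const double ieps = 1.0/eps;
        for (int r = 0; r < 34; ++r) {
          const double kv = (re1[r]-re0[r])*ieps;
          if (kv != 0.0) {
            ti.push_back(gdof[r]+1); tj.push_back(gdof[d]+1); tx.push_back(kv);
          }
        }
      }
    }
  }

  NumericVector sig(6);
  for (int i = 0; i < 6; ++i) sig[i] = (acc_vol > 0) ? sig_acc[i]/acc_vol : 0.0;
  List out = List::create(
    _["res"] = res,
    _["volume"] = acc_vol,
    _["mean_abs_Jm1"] = (acc_vol > 0) ? acc_jerr/acc_vol : 0.0,
    _["min_detF"] = minJ,
    _["mean_cauchy"] = sig,
    _["ok"] = all_ok);
  if (tangent) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}

// ---- follower (deformed-normal) pressure faces: quadratic triangles ----

struct FaceScratch {
  double N[6][6];       // qp x node
  double dNxi[6][6], dNeta[6][6];
  double w[6];
};

static void face_setup(FaceScratch &S) {
  const double A1 = 0.445948490915965, W1 = 0.223381589678011;
  const double A2 = 0.091576213509771, W2 = 0.109951743655322;
  double l1[6], l2[6], l3[6];
  double lamset[6][3] = {
    {1-2*A1, A1, A1}, {A1, 1-2*A1, A1}, {A1, A1, 1-2*A1},
    {1-2*A2, A2, A2}, {A2, 1-2*A2, A2}, {A2, A2, 1-2*A2}};
  double wset[6] = {W1, W1, W1, W2, W2, W2};
  for (int q = 0; q < 6; ++q) { l1[q]=lamset[q][0]; l2[q]=lamset[q][1]; l3[q]=lamset[q][2]; S.w[q]=0.5*wset[q]; }
  for (int q = 0; q < 6; ++q) {
    const double a1 = l1[q], a2 = l2[q], a3 = l3[q];
    // nodes: v1 v2 v3 m12 m13 m23
    S.N[q][0] = a1*(2*a1-1); S.N[q][1] = a2*(2*a2-1); S.N[q][2] = a3*(2*a3-1);
    S.N[q][3] = 4*a1*a2; S.N[q][4] = 4*a1*a3; S.N[q][5] = 4*a2*a3;
    // d lambda / d xi = (-1, 1, 0); d lambda / d eta = (-1, 0, 1)
    S.dNxi[q][0] = -(4*a1-1); S.dNxi[q][1] = 4*a2-1; S.dNxi[q][2] = 0;
    S.dNxi[q][3] = 4*(a1 - a2); S.dNxi[q][4] = -4*a3; S.dNxi[q][5] = 4*a3;
    S.dNeta[q][0] = -(4*a1-1); S.dNeta[q][1] = 0; S.dNeta[q][2] = 4*a3-1;
    S.dNeta[q][3] = -4*a2; S.dNeta[q][4] = 4*(a1 - a3); S.dNeta[q][5] = 4*a2;
  }
}

static void face_residual(const FaceScratch &S, const double xe[6][3],
                          double pval, double re[18]) {
  for (int i = 0; i < 18; ++i) re[i] = 0.0;
  for (int q = 0; q < 6; ++q) {
    double a1[3] = {0,0,0}, a2[3] = {0,0,0};
    for (int n = 0; n < 6; ++n)
      for (int i = 0; i < 3; ++i) {
        a1[i] += xe[n][i]*S.dNxi[q][n];
        a2[i] += xe[n][i]*S.dNeta[q][n];
      }
    const double nx = a1[1]*a2[2]-a1[2]*a2[1];
    const double ny = a1[2]*a2[0]-a1[0]*a2[2];
    const double nz = a1[0]*a2[1]-a1[1]*a2[0];
    // traction t = -p n (n outward from the solid); residual = internal - external
    for (int n = 0; n < 6; ++n) {
      const double c = pval*S.N[q][n]*S.w[q];
      re[3*n+0] += c*nx; re[3*n+1] += c*ny; re[3*n+2] += c*nz;
    }
  }
}

// [[Rcpp::export(name = ".fe_assemble_pressure")]]
List fe_assemble_pressure(NumericMatrix nodes, IntegerMatrix faces,
                          NumericVector pvals, NumericMatrix u,
                          int ndof, bool tangent, double eps_u) {
  const int nf = faces.nrow();
  NumericVector res(ndof);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (tangent) { ti.reserve((size_t)nf*324); tj.reserve((size_t)nf*324); tx.reserve((size_t)nf*324); }
  FaceScratch S;
  face_setup(S);
  double xe[6][3], re0[18], re1[18];
  int gdof[18];
  for (int f = 0; f < nf; ++f) {
    int vid[6];
    for (int n = 0; n < 6; ++n) vid[n] = faces(f,n) - 1;
    for (int n = 0; n < 6; ++n)
      for (int i = 0; i < 3; ++i) xe[n][i] = nodes(vid[n], i) + u(vid[n], i);
    face_residual(S, xe, pvals[f], re0);
    for (int n = 0; n < 6; ++n)
      for (int i = 0; i < 3; ++i) gdof[3*n+i] = 3*vid[n]+i;
    for (int d = 0; d < 18; ++d) res[gdof[d]] += re0[d];
    if (tangent) {
      for (int d = 0; d < 18; ++d) {
        xe[d/3][d%3] += eps_u;
        face_residual(S, xe, pvals[f], re1);
        xe[d/3][d%3] -= eps_u;
        const double ieps = 1.0/eps_u;
        for (int r = 0; r < 18; ++r) {
          const double kv = (re1[r]-re0[r])*ieps;
          if (kv != 0.0) { ti.push_back(gdof[r]+1); tj.push_back(gdof[d]+1); tx.push_back(kv); }
        }
      }
    }
  }
  List out = List::create(_["res"] = res);
  if (tangent) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}
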