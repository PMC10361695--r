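// Element-level kernels for the quasi-static hyperelastic solver:
//  - one-term Ogden (exponent 2) stress and consistent tangent, closed form,
//  - internal force / stiffness assembly over linear tetrahedra with a
//    single quadrature point, with optional multiplicative isotropic
//    eigenstrain (growth factor g, F_elastic = F / g),
//  - follower (or dead) surface pressure force and load stiffness,
//  - label rasterization of tetrahedra onto a voxel grid.
// Units are mm-kPa throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 3x3 helpers; column-major storage m[i + 3*j].
static inline double det3(const double* F) {
  return F[0] * (F[4] * F[8] - F[7] * F[5])
       - F[3] * (F[1] * F[8] - F[7] * F[2])
       + F[6] * (F[1] * F[5] - F[4] * F[2]);
}

static inline void invT3(const double* F, double J, double* B) {
  // B = F^{-T} = cof(F) / J with cof[i][j] the (i,j) cofactor
  double c00 = F[4] * F[8] - F[7] * F[5];
  double c10 = -(F[3] * F[8] - F[6] * F[5]);
  double c20 = F[3] * F[7] - F[6] * F[4];
  double c01 = -(F[1] * F[8] - F[7] * F[2]);
  double c11 = F[0] * F[8] - F[6] * F[2];
  double c21 = -(F[0] * F[7] - F[6] * F[1]);
  double c02 = F[1] * F[5] - F[4] * F[2];
  double c12 = -(F[0] * F[5] - F[3] * F[2]);
  double c22 = F[0] * F[4] - F[3] * F[1];
  // F^{-1} = cof^T / J, so F^{-T} = cof / J with cof[i][j] = c_ij (i row, j col)
  B[0] = c00 / J; B[1] = c10 / J; B[2] = c20 / J;
  B[3] = c01 / J; B[4] = c11 / J; B[5] = c21 / J;
  B[6] = c02 / J; B[7] = c12 / J; B[8] = c22 / J;
}

// Energy, PK1 stress, and (optionally) tangent of the exponent-2 Ogden model.
// A[(i+3j) + 9*(k+3l)] = dP_ij/dF_kl.
static void ogden2(const double* F, double mu, double kappa,
                   double* psi, double* P, double* A, bool wantA) {
  double J = det3(F);
  double B[9];
  invT3(F, J, B);
  double I1 = 0.0;
  for (int q = 0; q < 9; ++q) I1 += F[q] * F[q];
  double Jm23 = std::pow(J, -2.0 / 3.0);
  *psi = 0.5 * mu * (Jm23 * I1 - 3.0) + 0.25 * kappa * (J * J - 1.0 - 2.0 * std::log(J));
  double kv = 0.5 * kappa * (J * J - 1.0);
  for (int q = 0; q < 9; ++q)
    P[q] = mu * Jm23 * (F[q] - (I1 / 3.0) * B[q]) + kv * B[q];
  if (!wantA) return;
  // A = mu*Jm23*(del - 2/3 F (x) B)
  //   - mu/3*Jm23*(-2/3 I1 B(x)B + 2 B(x)F + I1 dB)
  //   + kappa/2*(2 J^2 B(x)B + (J^2-1) dB),  dB_ijkl = -B_il B_kj
  for (int l = 0; l < 3; ++l)
    for (int k = 0; k < 3; ++k)
      for (int j = 0; j < 3; ++j)
        for (int i = 0; i < 3; ++i) {
          double del = (i == k && j == l) ? 1.0 : 0.0;
          double Fij = F[i + 3 * j], Bij = B[i + 3 * j];
          double Fkl = F[k + 3 * l], Bkl = B[k + 3 * l];
          double dB = -B[i + 3 * l] * B[k + 3 * j];
          double val = mu * Jm23 * (del - (2.0 / 3.0) * Fij * Bkl)
            - (mu / 3.0) * Jm23 * (-(2.0 / 3.0) * I1 * Bij * Bkl + 2.0 * Bij * Fkl + I1 * dB)
            + 0.5 * kappa * (2.0 * J * J * Bij * Bkl + (J * J - 1.0) * dB);
          A[(i + 3 * j) + 9 * (k + 3 * l)] = val;
        }
}

// Assemble internal forces, energy, deformation gradients, and (optionally)
// the material+geometric stiffness triplets over all tetrahedra.
// u: length 3N displacement vector (dof order: node-major x,y,z).
// g: per-element isotropic growth factor (1 = none); elastic F_e = F/g,
//    energy density g^3 Psi(F_e), P_total = g^2 P(F_e), A_total = g A(F_e).
// [[Rcpp::export(name = ".asm_internal")]]
List asm_internal(NumericMatrix nodes, IntegerMatrix tets, NumericVector u,
                  NumericVector mu_e, NumericVector kappa_e, NumericVector g_e,
                  bool want_tangent) {
  const int N = nodes.nrow(), M = tets.nrow();
  NumericVector fint(3 * N);
  NumericMatrix Fout(9, M);
  double energy = 0.0;
  int bad = 0;
  IntegerVector ti, tj;
  NumericVector tx;
  if (want_tangent) {
    ti = IntegerVector(144 * M);
    tj = IntegerVector(144 * M);
    tx = NumericVector(144 * M);
  }
  for (int e = 0; e < M; ++e) {
    int n1 = tets(e, 0) - 1, n2 = tets(e, 1) - 1, n3 = tets(e, 2) - 1, n4 = tets(e, 3) - 1;
    double a[3], b[3], c[3];
    for (int d = 0; d < 3; ++d) {
      a[d] = nodes(n2, d) - nodes(n1, d);
      b[d] = nodes(n3, d) - nodes(n1, d);
      c[d] = nodes(n4, d) - nodes(n1, d);
    }
    double det = a[0] * (b[1] * c[2] - b[2] * c[1])
               - a[1] * (b[0] * c[2] - b[2] * c[0])
               + a[2] * (b[0] * c[1] - b[1] * c[0]);
    double V = det / 6.0;
    // shape gradients: rows of D^{-1} for nodes 2..4, node 1 = -sum
    double G[4][3];
    double r2[3] = { (b[1] * c[2] - b[2] * c[1]) / det,
                     (b[2] * c[0] - b[0] * c[2]) / det,
                     (b[0] * c[1] - b[1] * c[0]) / det };
    double r3[3] = { (c[1] * a[2] - c[2] * a[1]) / det,
                     (c[2] * a[0] - c[0] * a[2]) / det,
                     (c[0] * a[1] - c[1] * a[0]) / det };
    double r4[3] = { (a[1] * b[2] - a[2] * b[1]) / det,
                     (a[2] * b[0] - a[0] * b[2]) / det,
                     (a[0] * b[1] - a[1] * b[0]) / det };
    for (int d = 0; d < 3; ++d) {
      G[1][d] = r2[d]; G[2][d] = r3[d]; G[3][d] = r4[d];
      G[0][d] = -(r2[d] + r3[d] + r4[d]);
    }
    int nid[4] = { n1, n2, n3, n4 };
    // F = I + sum_a u_a (x) grad N_a
    double F[9] = { 1, 0, 0, 0, 1, 0, 0, 0, 1 };
    for (int aI = 0; aI < 4; ++aI)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[i + 3 * j] += u[3 * nid[aI] + i] * G[aI][j];
    for (int q = 0; q < 9; ++q) Fout(q, e) = F[q];
    double Jtot = det3(F);
    if (!(Jtot > 0.0)) { if (bad == 0) bad = e + 1; continue; }
    double g = g_e[e];
    double Fe[9];
    for (int q = 0; q < 9; ++q) Fe[q] = F[q] / g;
    if (!(det3(Fe) > 0.0)) { if (bad == 0) bad = e + 1; continue; }
    double psi, P[9], A[81];
    ogden2(Fe, mu_e[e], kappa_e[e], &psi, P, want_tangent ? A : (double*)nullptr,
           want_tangent);
    double g2 = g * g;
    energy += V * g * g2 * psi;
    for (int aI = 0; aI < 4; ++aI)
      for (int i = 0; i < 3; ++i) {
        double s = 0.0;
        for (int j = 0; j < 3; ++j) s += P[i + 3 * j] * G[aI][j];
        fint[3 * nid[aI] + i] += V * g2 * s;
      }
    if (want_tangent) {
      int base = 144 * e, q = 0;
      for (int aI = 0; aI < 4; ++aI)
        for (int i = 0; i < 3; ++i)
          for (int bI = 0; bI < 4; ++bI)
            for (int k = 0; k < 3; ++k) {
              double s = 0.0;
              for (int j = 0; j < 3; ++j)
                for (int l = 0; l < 3; ++l)
                  s += A[(i + 3 * j) + 9 * (k + 3 * l)] * G[aI][j] * G[bI][l];
              ti[base + q] = 3 * nid[aI] + i + 1;
              tj[base + q] = 3 * nid[bI] + k + 1;
              tx[base + q] = V * g * s;
              ++q;
            }
    }
  }
  List out = List::create(_["fint"] = fint, _["energy"] = energy,
                          _["F"] = Fout, _["bad_element"] = bad);
  if (want_tangent) { out["ti"] = ti; out["tj"] = tj; out["tx"] = tx; }
  return out;
}

// Surface pressure load (magnitude p, acting along each triangle's stored
// normal direction) and, for follower mode, its load stiffness.
// Nodal force on each of the 3 nodes: (p/6) (x2-x1) x (x3-x1), evaluated on
// current (follower) or reference (dead) coordinates.
// [[Rcpp::export(name = ".asm_pressure")]]
List asm_pressure(NumericMatrix nodes, IntegerMatrix tris, NumericVector u,
                  double p, bool follower, bool want_tangent) {
  const int N = nodes.nrow(), K = tris.nrow();
  NumericVector fext(3 * N);
  IntegerVector ti, tj;
  NumericVector tx;
  bool tng = want_tangent && follower;
  if (tng) {
    ti = IntegerVector(81 * K);
    tj = IntegerVector(81 * K);
    tx = NumericVector(81 * K);
  }
  for (int f = 0; f < K; ++f) {
    int n[3] = { tris(f, 0) - 1, tris(f, 1) - 1, tris(f, 2) - 1 };
    double x[3][3];
    for (int aI = 0; aI < 3; ++aI)
      for (int d = 0; d < 3; ++d) {
        x[aI][d] = nodes(n[aI], d);
        if (follower) x[aI][d] += u[3 * n[aI] + d];
      }
    double aV[3], bV[3];
    for (int d = 0; d < 3; ++d) { aV[d] = x[1][d] - x[0][d]; bV[d] = x[2][d] - x[0][d]; }
    double cr[3] = { aV[1] * bV[2] - aV[2] * bV[1],
                     aV[2] * bV[0] - aV[0] * bV[2],
                     aV[0] * bV[1] - aV[1] * bV[0] };
    for (int aI = 0; aI < 3; ++aI)
      for (int d = 0; d < 3; ++d)
        fext[3 * n[aI] + d] += (p / 6.0) * cr[d];
    if (tng) {
      // d(a x b)/dx1 = skew(b) - skew(a); /dx2 = -skew(b); /dx3 = skew(a)
      auto skew = [](const double* v, double* S) {
        S[0] = 0;      S[3] = -v[2]; S[6] = v[1];
        S[1] = v[2];   S[4] = 0;     S[7] = -v[0];
        S[2] = -v[1];  S[5] = v[0];  S[8] = 0;
      };
      double Sa[9], Sb[9], D[3][9];
      skew(aV, Sa); skew(bV, Sb);
      for (int q = 0; q < 9; ++q) {
        D[0][q] = Sb[q] - Sa[q];
        D[1][q] = -Sb[q];
        D[2][q] = Sa[q];
      }
      int base = 81 * f, q = 0;
      for (int aI = 0; aI < 3; ++aI)
        for (int i = 0; i < 3; ++i)
          for (int bI = 0; bI < 3; ++bI)
            for (int k = 0; k < 3; ++k) {
              ti[base + q] = 3 * n[aI] + i + 1;
              tj[base + q] = 3 * n[bI] + k + 1;
              tx[base + q] = (p / 6.0) * D[bI][i + 3 * k];
              ++q;
            }
    }
  }
  List out = List::create(_["fext"] = fext);
  if (tng) { out["ti"] = ti; out["tj"] = tj; out["tx"] = tx; }
  return out;
}

// Rasterize element region labels onto a voxel grid by point-in-tet tests at
// voxel centers. Voxel center of index (i,j,k) (0-based) is
// origin + spacing * (index + 0.5). Returns an integer vector (column-major
// i fastest) with 0 = no element, else the element's region code.
// [[Rcpp::export(name = ".rasterize_labels")]]
IntegerVector rasterize_labels(NumericMatrix nodes, IntegerMatrix tets,
                               IntegerVector region_code, NumericVector origin,
                               NumericVector spacing, IntegerVector dims) {
  const int M = tets.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(nx * ny * nz);
  const double tol = -1e-9;
  for (int e = 0; e < M; ++e) {
    double X[4][3];
    for (int aI = 0; aI < 4; ++aI)
      for (int d = 0; d < 3; ++d) X[aI][d] = nodes(tets(e, aI) - 1, d);
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(std::min(X[0][d], X[1][d]), std::min(X[2][d], X[3][d]));
      hi[d] = std::max(std::max(X[0][d], X[1][d]), std::max(X[2][d], X[3][d]));
    }
    int i0[3], i1[3];
    bool empty = false;
    for (int d = 0; d < 3; ++d) {
      i0[d] = (int)std::ceil((lo[d] - origin[d]) / spacing[d] - 0.5);
      i1[d] = (int)std::floor((hi[d] - origin[d]) / spacing[d] - 0.5);
      if (i0[d] < 0) i0[d] = 0;
      int cap = (d == 0 ? nx : (d == 1 ? ny : nz)) - 1;
      if (i1[d] > cap) i1[d] = cap;
      if (i0[d] > i1[d]) empty = true;
    }
    if (empty) continue;
    // barycentric setup: solve D lambda = x - X1
    double a[3], b[3], c[3];
    for (int d = 0; d < 3; ++d) {
      a[d] = X[1][d] - X[0][d]; b[d] = X[2][d] - X[0][d]; c[d] = X[3][d] - X[0][d];
    }
    double det = a[0] * (b[1] * c[2] - b[2] * c[1])
               - a[1] * (b[0] * c[2] - b[2] * c[0])
               + a[2] * (b[0] * c[1] - b[1] * c[0]);
    if (det == 0.0) continue;
    double inv[9]; // rows of D^{-1}
    inv[0] = (b[1] * c[2] - b[2] * c[1]) / det;
    inv[1] = (b[2] * c[0] - b[0] * c[2]) / det;
    inv[2] = (b[0] * c[1] - b[1] * c[0]) / det;
    inv[3] = (c[1] * a[2] - c[2] * a[1]) / det;
    inv[4] = (c[2] * a[0] - c[0] * a[2]) / det;
    inv[5] = (c[0] * a[1] - c[1] * a[0]) / det;
    inv[6] = (a[1] * b[2] - a[2] * b[1]) / det;
    inv[7] = (a[2] * b[0] - a[0] * b[2]) / det;
    inv[8] = (a[0] * b[1] - a[1] * b[0]) / det;
    int code = region_code[e];
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i) {
          double r[3] = { origin[0] + spacing[0] * (i + 0.5) - X[0][0],
                          origin[1] + spacing[1] * (j + 0.5) - X[0][1],
                          origin[2] + spacing[2] * (k + 0.5) - X[0][2] };
          double l2 = inv[0] * r[0] + inv[1] * r[1] + inv[2] * r[2];
          double l3 = inv[3] * r[0] + inv[4] * r[1] + inv[5] * r[2];
          double l4 = inv[6] * r[0] + inv[7] * r[1] + inv[8] * r[2];
          double l1 = 1.0 - l2 - l3 - l4;
          if (l1 >= tol && l2 >= tol && l3 >= tol && l4 >= tol)
            lab[i + nx * (j + (long)ny * k)] = code;
        }
  }
  return lab;
}
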