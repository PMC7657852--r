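// Element kernels for linear isotropic elasticity on tetrahedra:
// 4-node (constant strain) and 10-node (quadratic, 4-point Gauss) elements.
// Units: mm, MPa, N.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat iso_D(double E, double nu) {
  double c = E / ((1.0 + nu) * (1.0 - 2.0 * nu));
  mat D(6, 6, fill::zeros);
  D(0, 0) = D(1, 1) = D(2, 2) = c * (1.0 - nu);
  D(0, 1) = D(0, 2) = D(1, 0) = D(1, 2) = D(2, 0) = D(2, 1) = c * nu;
  D(3, 3) = D(4, 4) = D(5, 5) = c * (1.0 - 2.0 * nu) / 2.0;
  return D;
}

// gradients of barycentric coordinates for an affine tet; returns 4x3,
// row i = grad L_i; vol receives the signed volume
static mat bary_grads(const mat &X, double &vol6) {
  mat J(3, 3);
  for (int k = 0; k < 3; ++k) {
    J(k, 0) = X(1, k) - X(0, k);
    J(k, 1) = X(2, k) - X(0, k);
    J(k, 2) = X(3, k) - X(0, k);
  }
  vol6 = det(J);
  mat Jinv = inv(J);
  mat G(4, 3, fill::zeros);
  // grad of reference coords xi_1..xi_3 (= L2..L4) are rows of Jinv
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k) G(i + 1, k) = Jinv(i, k);
  G.row(0) = -(G.row(1) + G.row(2) + G.row(3));
  return G;
}

// B matrix (6 x 3n) from shape-function gradients (n x 3)
static mat build_B(const mat &dN) {
  int n = dN.n_rows;
  mat B(6, 3 * n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    double gx = dN(i, 0), gy = dN(i, 1), gz = dN(i, 2);
    B(0, 3 * i) = gx;
    B(1, 3 * i + 1) = gy;
    B(2, 3 * i + 2) = gz;
    B(3, 3 * i) = gy; B(3, 3 * i + 1) = gx;       // gamma_xy
    B(4, 3 * i + 1) = gz; B(4, 3 * i + 2) = gy;   // gamma_yz
    B(5, 3 * i) = gz; B(5, 3 * i + 2) = gx;       // gamma_zx
  }
  return B;
}

// quadratic shape-function gradients at barycentric point L (length 4),
// given constant barycentric gradients G (4 x 3); node order:
// 1-4 corners, 5=(12), 6=(23), 7=(31), 8=(14), 9=(24), 10=(34)
static mat tet10_dN(const vec &L, const mat &G) {
  mat dN(10, 3);
  for (int i = 0; i < 4; ++i)
    dN.row(i) = (4.0 * L(i) - 1.0) * G.row(i);
  int ed[6][2] = {{0, 1}, {1, 2}, {2, 0}, {0, 3}, {1, 3}, {2, 3}};
  for (int e = 0; e < 6; ++e)
    dN.row(4 + e) = 4.0 * (L(ed[e][0]) * G.row(ed[e][1]) +
                           L(ed[e][1]) * G.row(ed[e][0]));
  return dN;
}

// [[Rcpp::export]]
Rcpp::List tet_stiffness_batch(const arma::mat &nodes,
                               const arma::imat &tets,
                               double E, double nu) {
  int m = tets.n_rows;
  int npe = tets.n_cols;  // 4 or 10
  if (npe != 4 && npe != 10) Rcpp::stop("tets must have 4 or 10 columns");
  mat D = iso_D(E, nu);
  int ndof = 3 * npe;
  arma::ivec II(m * ndof * ndof), JJ(m * ndof * ndof);
  arma::vec XX(m * ndof * ndof);
  arma::vec vols(m);

  // 4-point degree-2 rule
  double a = 0.5854101966249685, b = 0.1381966011250105;
  mat qp = {{a, b, b, b}, {b, a, b, b}, {b, b, a, b}, {b, b, b, a}};

  for (int e = 0; e < m; ++e) {
    mat X(4, 3);
    for (int i = 0; i < 4; ++i)
      for (int k = 0; k < 3; ++k) X(i, k) = nodes(tets(e, i) - 1, k);
    double vol6;
    mat G = bary_grads(X, vol6);
    double vol = vol6 / 6.0;
    vols(e) = vol;
    mat Ke(ndof, ndof, fill::zeros);
    if (npe == 4) {
      mat B = build_B(G);
      Ke = B.t() * D * B * vol;
    } else {
      for (int q = 0; q < 4; ++q) {
        vec L = qp.row(q).t();
        mat B = build_B(tet10_dN(L, G));
        Ke += B.t() * D * B * (vol / 4.0);
      }
    }
    int base = e * ndof * ndof;
    int cnt = 0;
    for (int i = 0; i < npe; ++i)
      for (int di = 0; di < 3; ++di) {
        int gi = 3 * (tets(e, i) - 1) + di + 1;
        for (int j = 0; j < npe; ++j)
          for (int dj = 0; dj < 3; ++dj) {
            int gj = 3 * (tets(e, j) - 1) + dj + 1;
            II(base + cnt) = gi;
            JJ(base + cnt) = gj;
            XX(base + cnt) = Ke(3 * i + di, 3 * j + dj);
            ++cnt;
          }
      }
  }
  return Rcpp::List::create(Rcpp::Named("i") = II, Rcpp::Named("j") = JJ,
                            Rcpp::Named("x") = XX, Rcpp::Named("vol") = vols);
}

// per-element stress evaluated at the four corner nodes (and centroid).
// returns m x 30 matrix: 4 corners x 6 Voigt components, then centroid x 6
// Voigt order: xx, yy, zz, xy, yz, zx (true stresses)
// [[Rcpp::export]]
arma::mat tet_stress_batch(const arma::mat &nodes,
                           const arma::imat &tets,
                           const arma::vec &u,
                           double E, double nu) {
  int m = tets.n_rows;
  int npe = tets.n_cols;
  mat D = iso_D(E, nu);
  mat out(m, 30);
  mat corners = {{1., 0., 0., 0.}, {0., 1., 0., 0.},
                 {0., 0., 1., 0.}, {0., 0., 0., 1.},
                 {0.25, 0.25, 0.25, 0.25}};
  for (int e = 0; e < m; ++e) {
    mat X(4, 3);
    for (int i = 0; i < 4; ++i)
      for (int k = 0; k < 3; ++k) X(i, k) = nodes(tets(e, i) - 1, k);
    double vol6;
    mat G = bary_grads(X, vol6);
    vec ue(3 * npe);
    for (int i = 0; i < npe; ++i)
      for (int k = 0; k < 3; ++k) ue(3 * i + k) = u(3 * (tets(e, i) - 1) + k);
    if (npe == 4) {
      vec s = D * (build_B(G) * ue);
      for (int c = 0; c < 5; ++c)
        for (int k = 0; k < 6; ++k) out(e, 6 * c + k) = s(k);
    } else {
      for (int c = 0; c < 5; ++c) {
        vec L = corners.row(c).t();
        vec s = D * (build_B(tet10_dN(L, G)) * ue);
        for (int k = 0; k < 6; ++k) out(e, 6 * c + k) = s(k);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::vec tet_volumes(const arma::mat &nodes, const arma::imat &tets) {
  int m = tets.n_rows;
  vec v(m);
  for (int e = 0; e < m; ++e) {
    mat X(4, 3);
    for (int i = 0; i < 4; ++i)
      for (int k = 0; k < 3; ++k) X(i, k) = nodes(tets(e, i) - 1, k);
    double vol6;
    bary_grads(X, vol6);
    v(e) = vol6 / 6.0;
  }
  return v;
}
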