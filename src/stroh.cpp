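// Stroh-formalism surface-wave solver for a transversely isotropic half-space.
//
// Geometry: the symmetry (fiber) axis is Z, the free surface is the Y-Z plane,
// depth increases along +X into the solid.  A surface wave propagates within
// the surface at angle theta from the symmetry axis, i.e. along
// n = (0, sin t, cos t); the depth direction is m = (1, 0, 0).
//
// Partial waves u = a * exp(i k (n.x + p m.x - v t)).  The sextic eigenproblem
//   [Q - rho v^2 I + p (R + R^T) + p^2 T] a = 0,
//   Q_ik = C_ijkl n_j n_l,  R_ik = C_ijkl n_j m_l,  T_ik = C_ijkl m_j m_l,
// is linearised into the standard 6x6 Stroh matrix N acting on (a, b) with
// b = (R^T + p T) a the traction amplitude on the surface.  The three modes
// with Im(p) > 0 decay with depth; with A, B the 3x3 matrices of their a and b
// parts, the surface impedance Z = -i B A^{-1} is Hermitian for subsonic v and
// det(Z) is real, positive at v -> 0, and vanishes at the Rayleigh speed
// (Barnett-Lothe).  The solver root-finds Re det(Z) in v.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static int voigt(int i, int j) {
  if (i == j) return i;
  int s = i + j;           // 0-based: (1,2)->3, (0,2)->4, (0,1)->5
  if (s == 3) return 3;    // i,j in {1,2}
  if (s == 2) return 4;    // i,j in {0,2}
  return 5;                // i,j in {0,1}
}

// contraction M_ik = C_ijkl u_j w_l from the 6x6 Voigt matrix
static mat contract(const mat& C, const vec& u, const vec& w) {
  mat M(3, 3, fill::zeros);
  for (int i = 0; i < 3; ++i)
    for (int k = 0; k < 3; ++k) {
      double s = 0.0;
      for (int j = 0; j < 3; ++j)
        for (int l = 0; l < 3; ++l)
          s += C(voigt(i, j), voigt(k, l)) * u(j) * w(l);
      M(i, k) = s;
    }
  return M;
}

// Re det of the surface impedance at trial speed v; NaN when mode selection
// fails (supersonic trial speed or defective eigenbasis).  Works for any
// dimension d (3 in general; 2 for the decoupled sagittal problem at
// symmetry directions, where the out-of-plane shear branch separates and
// must not enter the boundary condition).
static double impedance_det(const mat& Q, const mat& R, const mat& T,
                            double rho, double v) {
  const uword d = Q.n_rows;
  mat Ti = inv(T);
  mat N(2 * d, 2 * d);
  N.submat(0, 0, d - 1, d - 1) = -Ti * R.t();
  N.submat(0, d, d - 1, 2 * d - 1) = Ti;
  N.submat(d, 0, 2 * d - 1, d - 1) = R * Ti * R.t() - Q + rho * v * v * eye(d, d);
  N.submat(d, d, 2 * d - 1, 2 * d - 1) = -R * Ti;

  cx_vec p;
  cx_mat xi;
  if (!eig_gen(p, xi, N)) return datum::nan;

  // d modes decaying with depth: largest Im(p)
  uvec ord = sort_index(imag(p), "descend");
  if (imag(p(ord(d - 1))) <= 0) return datum::nan;
  cx_mat A(d, d), B(d, d);
  for (uword c = 0; c < d; ++c) {
    A.col(c) = xi.submat(0, ord(c), d - 1, ord(c));
    B.col(c) = xi.submat(d, ord(c), 2 * d - 1, ord(c));
  }
  cx_mat Ainv;
  if (!inv(Ainv, A)) return datum::nan;
  cx_mat Z = cx_double(0, -1) * B * Ainv;
  return real(det(Z));
}

// At theta = 0 or 90 deg the displacement component normal to the sagittal
// (depth, propagation) plane decouples; restrict Q, R, T to the sagittal
// components so the decoupled bulk shear branch cannot block the root.
static bool sagittal_reduce(double theta, mat& Q, mat& R, mat& T) {
  double s = std::abs(std::sin(theta)), c = std::abs(std::cos(theta));
  uvec keep;
  if (s < 1e-12) keep = {0, 2};       // along-fiber: x and z move
  else if (c < 1e-12) keep = {0, 1};  // across-fiber: x and y move
  else return false;
  Q = Q.submat(keep, keep);
  R = R.submat(keep, keep);
  T = T.submat(keep, keep);
  return true;
}

// [[Rcpp::export]]
Rcpp::NumericVector stroh_residual_cpp(const arma::mat& C, double rho,
                                       double theta, Rcpp::NumericVector v) {
  vec n = {0.0, std::sin(theta), std::cos(theta)};
  vec m = {1.0, 0.0, 0.0};
  mat Q = contract(C, n, n), R = contract(C, n, m), T = contract(C, m, m);
  sagittal_reduce(theta, Q, R, T);
  Rcpp::NumericVector out(v.size());
  for (int i = 0; i < v.size(); ++i)
    out[i] = impedance_det(Q, R, T, rho, v[i]);
  return out;
}

// Root-find Re det Z(v) on (v_lo, v_hi): coarse scan for the lowest-speed sign
// change (fundamental mode), then bisection.  Returns (speed, residual, status)
// with status 0 ok, 1 no sign change found.
// [[Rcpp::export]]
Rcpp::List rayleigh_root_cpp(const arma::mat& C, double rho, double theta,
                             double v_lo, double v_hi, double rel_tol,
                             int n_scan) {
  vec n = {0.0, std::sin(theta), std::cos(theta)};
  vec m = {1.0, 0.0, 0.0};
  mat Q = contract(C, n, n), R = contract(C, n, m), T = contract(C, m, m);
  sagittal_reduce(theta, Q, R, T);

  // Coarse bracketing.  Mode selection fails (NaN) beyond the transonic
  // limit, which for off-symmetry directions can sit below the nominal
  // bulk-speed bound v_hi; on hitting NaN the scan recurses into the last
  // finite interval, since the root may hug the transonic boundary
  // (the large-anisotropy regime where the surface wave degenerates onto
  // the bulk shear branch).
  double lo = v_lo, hi = v_hi;
  double a = lo, fa = impedance_det(Q, R, T, rho, a);
  double b = datum::nan, fb = datum::nan;
  bool found = false;
  for (int pass = 0; pass < 8 && !found; ++pass) {
    double step = (hi - lo) / n_scan;
    a = lo; fa = impedance_det(Q, R, T, rho, a);
    bool hit_nan = false;
    for (int i = 1; i <= n_scan; ++i) {
      double x = lo + i * step;
      double fx = impedance_det(Q, R, T, rho, x);
      if (!std::isfinite(fx)) {
        hi = x; lo = a; hit_nan = true; break;  // refine toward the boundary
      }
      if (std::isfinite(fa) && ((fa > 0) != (fx > 0))) {
        b = x; fb = fx; found = true; break;
      }
      a = x; fa = fx;
    }
    if (!found && !hit_nan) break;              // genuinely no sign change
    if (!found && (hi - lo) < rel_tol * hi) {
      // residual runs into the transonic boundary without crossing:
      // surface mode degenerate with the limiting bulk wave
      return Rcpp::List::create(Rcpp::Named("speed") = a,
                                Rcpp::Named("residual") = fa,
                                Rcpp::Named("status") = 0);
    }
  }
  if (!found)
    return Rcpp::List::create(Rcpp::Named("speed") = NA_REAL,
                              Rcpp::Named("residual") = NA_REAL,
                              Rcpp::Named("status") = 1);

  // Illinois false-position refinement (bisection fallback every 4th step
  // and on NaN, which can only appear at the supersonic edge)
  for (int it = 0; it < 200 && (b - a) > rel_tol * b; ++it) {
    double x;
    if (it % 4 == 3 || !std::isfinite(fb) || fb == fa)
      x = 0.5 * (a + b);
    else {
      x = (a * fb - b * fa) / (fb - fa);
      if (!(x > a && x < b)) x = 0.5 * (a + b);
    }
    double fx = impedance_det(Q, R, T, rho, x);
    if (!std::isfinite(fx)) { b = x; fb = datum::nan; continue; }
    if ((fx > 0) == (fa > 0)) { a = x; fa = fx; fb *= 0.5; }
    else { b = x; fb = fx; fa *= 0.5; }
  }
  double root = 0.5 * (a + b);
  return Rcpp::List::create(
      Rcpp::Named("speed") = root,
      Rcpp::Named("residual") = impedance_det(Q, R, T, rho, root),
      Rcpp::Named("status") = 0);
}
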