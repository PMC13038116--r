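// Nonnegativity-constrained quadratic programming kernels.
//
// Solves min_x 1/2 x'Qx + f'x subject to x >= 0 with a Lawson-Hanson-type
// active-set iteration on the Gram system (the bound-constrained special case
// of a primal active-set QP method). Warm-startable from a previous solution,
// which is how the re-weighted-l1 inner iterations and neighbouring pixels
// reuse supports.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Solve on the passive set; ridge-regularizes if the reduced Gram is singular.
static bool passive_solve(const mat& Q, const vec& f, const uvec& P, vec& z,
                          double scl) {
  if (P.n_elem == 0) { z.reset(); return true; }
  mat Qpp = Q.submat(P, P);
  vec fp = -f.elem(P);
  if (solve(z, Qpp, fp, solve_opts::likely_sympd + solve_opts::no_approx))
    return true;
  Qpp.diag() += 1e-10 * scl;
  return solve(z, Qpp, fp);
}

// Core solver. x must enter feasible (>= 0); its support seeds the passive
// set. Returns outer iteration count, or -(count) if the cap was hit.
static int nnqp_core(const mat& Q, const vec& f, vec& x, int max_iter,
                     double tol) {
  const uword p = Q.n_rows;
  const double scl = std::max(1.0, Q.diag().max());
  const double tau = tol * std::max(1.0, norm(f, "inf"));
  std::vector<uword> Pv;
  for (uword j = 0; j < p; ++j) if (x(j) > 0) Pv.push_back(j);
  int outer = 0;
  bool refine_first = !Pv.empty(); // make a warm start optimal on its support
  while (outer < max_iter) {
    ++outer;
    uvec P(Pv);
    if (!refine_first) {
      vec w = -(f + Q * x); // negative gradient
      // mask passive entries
      for (uword k = 0; k < P.n_elem; ++k) w(P(k)) = -datum::inf;
      uword jmax = 0;
      double wmax = w.n_elem ? w.max(jmax) : -datum::inf;
      if (!std::isfinite(wmax) || wmax <= tau) return outer; // KKT satisfied
      Pv.push_back(jmax);
      std::sort(Pv.begin(), Pv.end());
      P = uvec(Pv);
    }
    refine_first = false;
    // inner loop: restore feasibility of the passive-set solution
    for (uword inner = 0; inner <= p + 1; ++inner) {
      vec z;
      if (!passive_solve(Q, f, P, z, scl)) return -outer;
      bool allpos = true;
      for (uword k = 0; k < z.n_elem; ++k)
        if (z(k) <= 0) { allpos = false; break; }
      if (allpos) {
        x.zeros();
        for (uword k = 0; k < P.n_elem; ++k) x(P(k)) = z(k);
        break;
      }
      // step toward z until the first passive variable hits zero
      double alpha = 1.0;
      for (uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0) {
          double xi = x(P(k));
          double a = xi / (xi - z(k));
          if (a < alpha) alpha = a;
        }
      }
      std::vector<uword> Pnew;
      for (uword k = 0; k < P.n_elem; ++k) {
        double xv = x(P(k)) + alpha * (z(k) - x(P(k)));
        if (xv > 1e-12) { x(P(k)) = xv; Pnew.push_back(P(k)); }
        else x(P(k)) = 0.0;
      }
      if (Pnew.empty()) { x.zeros(); Pv.clear(); break; }
      Pv = Pnew;
      P = uvec(Pv);
    }
    // resync Pv with x support
    Pv.clear();
    for (uword j = 0; j < p; ++j) if (x(j) > 0) Pv.push_back(j);
  }
  return -outer;
}

// [[Rcpp::export]]
Rcpp::List nnqp_solve_cpp(const arma::mat& Q, const arma::vec& f,
                          const arma::vec& x0, int max_iter, double tol) {
  vec x = x0;
  x.elem(find(x < 0)).zeros();
  int it = nnqp_core(Q, f, x, max_iter, tol);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("iterations") = std::abs(it),
                            Rcpp::Named("converged") = (it > 0) ? 1 : 0);
}

// Batch weighted nonnegative LASSO over pixels sharing one Gram matrix.
// Pixel i solves min 1/2 a'Qa - qlin_i'a + pen_i'a, a >= 0, warm-started from
// the corresponding column of Awarm.
// [[Rcpp::export]]
Rcpp::List nnlasso_batch_cpp(const arma::mat& Q, const arma::mat& Qlin,
                             const arma::mat& Pen, const arma::mat& Awarm,
                             int max_iter, double tol) {
  const uword M = Q.n_rows, N = Qlin.n_cols;
  mat A(M, N);
  Rcpp::IntegerVector failed;
  for (uword i = 0; i < N; ++i) {
    vec f = -Qlin.col(i) + Pen.col(i);
    vec x = Awarm.col(i);
    x.elem(find(x < 0)).zeros();
    int it = nnqp_core(Q, f, x, max_iter, tol);
    if (it <= 0) failed.push_back(i + 1);
    A.col(i) = x;
  }
  return Rcpp::List::create(Rcpp::Named("A") = A,
                            Rcpp::Named("failed") = failed);
}
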