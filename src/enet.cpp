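// Pathwise block coordinate descent for the multi-response elastic net
// with a grouped (row-wise L2) penalty:
//
//   min over B of  (1/2n) ||Y - X B||_F^2
//                  + lambda * sum_j [ alpha * ||B_j.||_2
//                                     + (1-alpha)/2 * ||B_j.||_2^2 ]
//
// where B_j. is feature j's coefficient row across the q responses, so a
// feature enters or leaves the model for all responses jointly. Solved
// along a decreasing lambda sequence with warm starts. Each lambda is
// handled with an active-set strategy: coordinate descent runs over a
// candidate set to convergence (max coefficient update < tol), then a
// single BLAS-level gradient evaluation over all features checks the
// optimality conditions of the inactive ones; violators join the
// candidate set and the cycle repeats. The block update for feature j is
// the grouped soft-threshold
//
//   B_j. <- z * max(0, 1 - lambda*alpha/||z||) / (v_j + lambda*(1-alpha)),
//   z = x_j'R/n + v_j B_j.,  v_j = ||x_j||^2/n,
//
// which for one response reduces to the scalar soft-threshold/ridge form.
//
// X and Y are expected column-centered (intercepts handled by the caller);
// any column scaling is absorbed through v_j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// block update for feature j; returns max absolute coefficient change
static inline double update_feature(const mat& X, mat& R, mat& B, uword j,
                                    double vj, double lam_l1, double lam_l2,
                                    double* z) {
  const uword n = X.n_rows, q = B.n_cols;
  const double* xj = X.colptr(j);
  double zn2 = 0.0;
  for (uword k = 0; k < q; ++k) {
    const double* rk = R.colptr(k);
    double acc = 0.0;
    for (uword i = 0; i < n; ++i) acc += xj[i] * rk[i];
    z[k] = acc / (double)n + vj * B(j, k);
    zn2 += z[k] * z[k];
  }
  const double zn = std::sqrt(zn2);
  double scale = 0.0;
  if (zn > lam_l1 && vj > 1e-12) scale = (1.0 - lam_l1 / zn) / (vj + lam_l2);
  double dmax = 0.0;
  for (uword k = 0; k < q; ++k) {
    const double bnew = scale * z[k];
    const double d = bnew - B(j, k);
    const double ad = std::fabs(d);
    if (ad > 0.0) {
      double* rk = R.colptr(k);
      for (uword i = 0; i < n; ++i) rk[i] -= xj[i] * d;
      B(j, k) = bnew;
      if (ad > dmax) dmax = ad;
    }
  }
  return dmax;
}

// [[Rcpp::export]]
arma::cube enet_path_cpp(const arma::mat& X, const arma::mat& Y,
                         double alpha, const arma::vec& lambdas,
                         double tol, int max_iter) {
  const uword n = X.n_rows, p = X.n_cols, q = Y.n_cols;
  if (Y.n_rows != n) Rcpp::stop("X and Y row counts differ");
  if (!X.is_finite() || !Y.is_finite()) Rcpp::stop("non-finite values in X or Y");

  vec v(p);
  for (uword j = 0; j < p; ++j) v(j) = dot(X.col(j), X.col(j)) / (double)n;

  mat B(p, q, fill::zeros);
  mat R = Y;
  cube out(p, q, lambdas.n_elem);
  std::vector<double> z(q);
  std::vector<uword> cand;
  cand.reserve(p);
  std::vector<char> in_cand(p, 0);

  for (uword l = 0; l < lambdas.n_elem; ++l) {
    const double lam = lambdas(l);
    const double lam_l1 = lam * alpha;
    const double lam_l2 = lam * (1.0 - alpha);

    // warm-start candidates: rows active at the previous lambda
    cand.clear();
    std::fill(in_cand.begin(), in_cand.end(), 0);
    for (uword j = 0; j < p; ++j) {
      bool active = false;
      for (uword k = 0; k < q; ++k) if (B(j, k) != 0.0) { active = true; break; }
      if (active) { cand.push_back(j); in_cand[j] = 1; }
    }

    int iter = 0;
    while (true) {
      // coordinate descent over the candidate set to convergence
      while (true) {
        double dmax = 0.0;
        for (uword a = 0; a < cand.size(); ++a) {
          const uword j = cand[a];
          const double d = update_feature(X, R, B, j, v(j), lam_l1, lam_l2, z.data());
          if (d > dmax) dmax = d;
        }
        if (++iter > max_iter)
          Rcpp::stop("elastic net did not converge at lambda=%g after %d sweeps "
                     "(last max update %g, tol %g)", lam, iter, dmax, tol);
        if (dmax < tol || cand.empty()) break;
      }
      // optimality check over all features: for inactive rows the
      // gradient group norm must not exceed the L1 threshold
      mat Z = (X.t() * R) / (double)n; // p x q, BLAS
      bool violated = false;
      for (uword j = 0; j < p; ++j) {
        if (in_cand[j]) continue;
        double zn2 = 0.0;
        for (uword k = 0; k < q; ++k) zn2 += Z(j, k) * Z(j, k);
        if (std::sqrt(zn2) > lam_l1 * (1.0 + 1e-12) + tol) {
          cand.push_back(j);
          in_cand[j] = 1;
          violated = true;
        }
      }
      if (!violated) break;
    }
    out.slice(l) = B;
  }
  return out;
}
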