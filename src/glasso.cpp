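// Block coordinate-descent graphical lasso (Friedman, Hastie & Tibshirani 2008)
// with warm starts along a penalty path. Solves
//   max_Theta  log det Theta - tr(S Theta) - rho * ||Theta||_1(offdiag)
// by cycling lasso subproblems on the columns of the working covariance W.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void glasso_one(const arma::mat& S, double rho, arma::mat& W, arma::mat& B,
                       int maxit, double tol, bool& converged) {
  const int p = S.n_rows;
  double offsum = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) offsum += std::fabs(S(i, j));
  const double thr = tol * std::max(offsum / std::max(1, p * (p - 1)), 1e-12);

  std::vector<arma::uvec> drop(p);
  for (int j = 0; j < p; ++j) {
    arma::uvec idx(p - 1);
    int k = 0;
    for (int i = 0; i < p; ++i) if (i != j) idx(k++) = i;
    drop[j] = idx;
  }

  converged = false;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const arma::uvec& idx = drop[j];
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12(p - 1);
      for (int m = 0; m < p - 1; ++m) s12(m) = S(idx(m), j);
      arma::vec b = B.col(j);
      for (int cd = 0; cd < 200; ++cd) {
        double cdmax = 0.0;
        for (int m = 0; m < p - 1; ++m) {
          double x = s12(m) - arma::dot(W11.row(m).t(), b) + W11(m, m) * b(m);
          double bn = 0.0;
          if (x > rho) bn = (x - rho) / W11(m, m);
          else if (x < -rho) bn = (x + rho) / W11(m, m);
          cdmax = std::max(cdmax, std::fabs(bn - b(m)));
          b(m) = bn;
        }
        if (cdmax < thr) break;
      }
      B.col(j) = b;
      arma::vec w12 = W11 * b;
      for (int m = 0; m < p - 1; ++m) {
        delta = std::max(delta, std::fabs(W(idx(m), j) - w12(m)));
        W(idx(m), j) = w12(m);
        W(j, idx(m)) = w12(m);
      }
    }
    if (delta < thr) { converged = true; break; }
  }
}

static arma::mat theta_from_WB(const arma::mat& W, const arma::mat& B) {
  const int p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    arma::vec b = B.col(j);
    double dot = 0.0;
    int k = 0;
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      dot += W(i, j) * b(k);
      ++k;
    }
    double t22 = 1.0 / std::max(W(j, j) - dot, 1e-12);
    Theta(j, j) = t22;
    k = 0;
    for (int i = 0; i < p; ++i) {
      if (i == j) continue;
      Theta(i, j) = -b(k) * t22;
      ++k;
    }
  }
  // symmetrize; keep the sparsity pattern symmetric (a pair is zero unless
  // both column problems kept it active)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      if (Theta(i, j) == 0.0 || Theta(j, i) == 0.0) {
        Theta(i, j) = Theta(j, i) = 0.0;
      } else {
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = Theta(j, i) = v;
      }
    }
  return Theta;
}

// [[Rcpp::export]]
List cc_glasso(const arma::mat& S, double rho, int maxit = 200, double tol = 1e-4) {
  const int p = S.n_rows;
  if (rho < 1e-10) {
    arma::mat Theta;
    arma::mat Sj = S;
    bool ok = arma::inv_sympd(Theta, Sj);
    if (!ok) {
      Sj.diag() += 1e-8;
      Theta = arma::inv(Sj);
    }
    return List::create(_["Theta"] = Theta, _["W"] = S, _["converged"] = true);
  }
  arma::mat W = S;
  W.diag() += rho;
  arma::mat B(p - 1, p, arma::fill::zeros);
  bool conv = false;
  glasso_one(S, rho, W, B, maxit, tol, conv);
  arma::mat Theta = theta_from_WB(W, B);
  return List::create(_["Theta"] = Theta, _["W"] = W, _["converged"] = conv);
}

// Path solver: rhos must be sorted decreasing; warm starts carry W and B.
// [[Rcpp::export]]
List cc_glasso_path(const arma::mat& S, const arma::vec& rhos, int maxit = 200,
                    double tol = 1e-4) {
  const int p = S.n_rows;
  const int L = rhos.n_elem;
  arma::mat W = S;
  W.diag() += rhos(0);
  arma::mat B(p - 1, p, arma::fill::zeros);
  List thetas(L);
  LogicalVector conv(L);
  for (int l = 0; l < L; ++l) {
    double rho = rhos(l);
    // keep current W but refresh the diagonal for the new penalty
    for (int j = 0; j < p; ++j) W(j, j) = S(j, j) + rho;
    bool ok = false;
    glasso_one(S, rho, W, B, maxit, tol, ok);
    thetas[l] = theta_from_WB(W, B);
    conv[l] = ok;
  }
  return List::create(_["Theta"] = thetas, _["converged"] = conv);
}
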