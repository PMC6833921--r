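// Inner solver for one alternating least-squares subproblem in canonical
// form: minimize 0.5 * ||A - X B||_F^2 over X with B fixed. Mirrors the
// pure-R reference implementation (scg_core_r) step for step: spectral
// conjugate gradient directions with a two-branch theta/beta recursion,
// descent safeguard, and Armijo-type backtracking over powers of rho. The
// subproblem is an exact quadratic, so the objective along a direction is
// evaluated from cached Gram products.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double DENOM_GUARD = 1e-300;

// [[Rcpp::export(name = ".scg_core_cpp")]]
Rcpp::List scg_core_cpp(const arma::mat& A, const arma::mat& B,
                        const arma::mat& X0,
                        double delta1, double delta2, double eta, double rho,
                        double inner_epsilon, int max_inner_iter,
                        int max_backtracks) {
  mat BBt = B * B.t();
  mat ABt = A * B.t();
  double cA = 0.5 * accu(square(A));
  mat X = X0;
  double fval = cA - accu(X % ABt) + 0.5 * accu(X % (X * BBt));
  mat G = X * BBt - ABt;
  mat D, Xp, Gp;
  std::vector<double> f_trace;
  f_trace.push_back(fval);
  std::vector<double> gnorm_trace;
  int restarts = 0, n_iter = 0;
  bool converged = false;

  for (int k = 0; k < max_inner_iter; ++k) {
    double gn2 = accu(square(G));
    double gnorm = std::sqrt(gn2);
    gnorm_trace.push_back(gnorm);
    if (!std::isfinite(gnorm))
      Rcpp::stop("numerical failure: non-finite gradient");
    if (gnorm <= inner_epsilon) { converged = true; break; }

    if (k == 0) {
      D = -G;
    } else {
      double gp2 = accu(square(Gp));
      mat s = X - Xp;
      mat y = G - Gp;
      double gy = accu(G % y);
      mat ybar = y - G * (gy / gn2);
      double dy = accu(D % y);
      double dg = accu(D % G);
      double dybar = accu(D % ybar);
      double theta = 0.0, beta = 0.0;
      bool degenerate = false;
      if (dybar > eta * gp2) {
        if (std::abs(dybar) < DENOM_GUARD) {
          degenerate = true;
        } else {
          double gs = accu(G % s);
          theta = (dy - dg * gs / gn2) / dybar;
          beta = (gy - gs) / dybar;
        }
      } else {
        double denom = -accu(D % Gp);
        if (std::abs(denom) < DENOM_GUARD || std::abs(gp2) < DENOM_GUARD) {
          degenerate = true;
        } else {
          double ggp = accu(G % Gp);
          theta = (dy - dg * ggp / gn2) / denom;
          beta = gy / gp2;
        }
      }
      if (degenerate) {
        D = -G; ++restarts;
      } else {
        mat Dnew = -theta * G + beta * D;
        if (!Dnew.is_finite() || accu(G % Dnew) >= 0) {
          D = -G; ++restarts;   // descent safeguard
        } else {
          D = Dnew;
        }
      }
    }

    double gd = 0.0, dn2 = 0.0, dBd = 0.0, alpha = 1.0, f_new = fval;
    mat DBBt;
    bool accepted = false;
    // a conjugate direction of extreme norm can make every power-of-rho
    // step violate the curvature-penalty term; retry once from steepest
    // descent before giving up
    for (int attempt = 0; attempt < 2 && !accepted; ++attempt) {
      gd = accu(G % D);
      dn2 = accu(square(D));
      DBBt = D * BBt;
      dBd = accu(D % DBBt);
      alpha = 1.0;
      for (int l = 0; l <= max_backtracks; ++l) {
        f_new = fval + alpha * gd + 0.5 * alpha * alpha * dBd;
        if (f_new <= fval + delta1 * alpha * gd - delta2 * alpha * alpha * dn2) {
          accepted = true; break;
        }
        alpha *= rho;
      }
      if (!accepted) {
        if (attempt == 0 && accu(square(D + G)) > 0) {
          D = -G; ++restarts;
        } else {
          Rcpp::stop("line search failed: no step within %d backtracks "
                     "(|<g,d>| = %g, ||d||^2 = %g)", max_backtracks,
                     std::abs(gd), dn2);
        }
      }
    }

    Xp = X; Gp = G;
    X += alpha * D;
    G += alpha * DBBt;
    fval = f_new;
    f_trace.push_back(fval);
    n_iter = k + 1;
    if (!X.is_finite())
      Rcpp::stop("numerical failure: non-finite iterate");
  }

  double final_gnorm = gnorm_trace.empty() ? NA_REAL : gnorm_trace.back();
  return Rcpp::List::create(
    Rcpp::Named("X") = X,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = n_iter,
    Rcpp::Named("f_trace") = f_trace,
    Rcpp::Named("gnorm_trace") = gnorm_trace,
    Rcpp::Named("final_gnorm") = final_gnorm,
    Rcpp::Named("restarts") = restarts);
}
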