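// Sequential minimal optimization for the soft-margin SVM dual with
// per-example box constraints 0 <= alpha_i <= C_i (linear kernel).
// Needed because the transductive objective penalizes labeled examples,
// positive-labeled unlabeled examples and negative-labeled unlabeled
// examples with three different costs, which rules out off-the-shelf
// scalar-C solvers. Working-set selection is the maximal violating pair
// (Keerthi et al.); updates are the Platt two-variable analytic solve.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".smoSolve")]]
List smoSolve(const arma::mat& X, const arma::ivec& y,
              const arma::vec& Cvec, double eps, int maxIter,
              const arma::vec& alphaStart) {
  const arma::uword n = X.n_rows;
  const arma::uword d = X.n_cols;

  arma::vec alpha = arma::clamp(alphaStart, 0.0, arma::datum::inf);
  for (arma::uword t = 0; t < n; ++t)
    if (alpha(t) > Cvec(t)) alpha(t) = Cvec(t);

  arma::vec yd = arma::conv_to<arma::vec>::from(y);
  arma::vec w(d, arma::fill::zeros);
  for (arma::uword t = 0; t < n; ++t)
    if (alpha(t) != 0.0) w += alpha(t) * yd(t) * X.row(t).t();
  arma::vec f = X * w;                       // f_t = w . x_t (no bias)
  arma::vec kdiag = arma::sum(arma::square(X), 1);

  int iter = 0;
  bool converged = false;
  const double tau = 1e-12;

  arma::vec viol(n);
  while (iter < maxIter) {
    // first index: maximal violation over I_up, with
    // viol_t = -y_t grad_t and grad_t = y_t f_t - 1
    double up = -arma::datum::inf, lo = arma::datum::inf;
    arma::sword i = -1;
    for (arma::uword t = 0; t < n; ++t) {
      viol(t) = yd(t) - f(t);                    // = -y_t G_t
      bool inUp  = (y(t) > 0 && alpha(t) < Cvec(t)) ||
                   (y(t) < 0 && alpha(t) > 0.0);
      bool inLow = (y(t) < 0 && alpha(t) < Cvec(t)) ||
                   (y(t) > 0 && alpha(t) > 0.0);
      if (inUp && viol(t) > up) { up = viol(t); i = t; }
      if (inLow && viol(t) < lo) lo = viol(t);
    }
    if (i < 0 || up - lo < eps) { converged = true; break; }
    // second index by maximal second-order gain against i
    arma::vec Ki = X * X.row(i).t();
    arma::sword j = -1;
    double best = 0.0;
    for (arma::uword t = 0; t < n; ++t) {
      bool inLow = (y(t) < 0 && alpha(t) < Cvec(t)) ||
                   (y(t) > 0 && alpha(t) > 0.0);
      if (!inLow || viol(t) >= up) continue;
      double bt = up - viol(t);
      double at = kdiag(i) + kdiag(t) - 2.0 * Ki(t);
      if (at < tau) at = tau;
      double gain = bt * bt / at;
      if (gain > best) { best = gain; j = t; }
    }
    if (j < 0) { converged = true; break; }

    const double s  = yd(i) * yd(j);
    const double Ei = f(i) - yd(i), Ej = f(j) - yd(j);
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha(j) - alpha(i));
      H = std::min(Cvec(j), Cvec(i) + alpha(j) - alpha(i));
    } else {
      L = std::max(0.0, alpha(i) + alpha(j) - Cvec(i));
      H = std::min(Cvec(j), alpha(i) + alpha(j));
    }
    double eta = kdiag(i) + kdiag(j) - 2.0 * Ki(j);
    if (eta < tau) eta = tau;
    double ajNew = alpha(j) + yd(j) * (Ei - Ej) / eta;
    if (ajNew < L) ajNew = L; else if (ajNew > H) ajNew = H;
    // snap to exact bounds so numerical dust cannot re-enter the working sets
    if (ajNew < 1e-12 * Cvec(j)) ajNew = 0.0;
    else if (ajNew > Cvec(j) * (1.0 - 1e-12)) ajNew = Cvec(j);
    const double daj = ajNew - alpha(j);
    if (std::fabs(daj) < 1e-16) break;       // blocked step: bail, not converged
    const double dai = -s * daj;
    alpha(j) = ajNew;
    alpha(i) += dai;
    if (alpha(i) < 1e-12 * Cvec(i)) alpha(i) = 0.0;
    else if (alpha(i) > Cvec(i) * (1.0 - 1e-12)) alpha(i) = Cvec(i);

    const arma::vec dw = dai * yd(i) * X.row(i).t() + daj * yd(j) * X.row(j).t();
    w += dw;
    f += X * dw;
    ++iter;
  }

  // bias from KKT conditions: free SVs when available, else interval midpoint
  double bLo = -arma::datum::inf, bHi = arma::datum::inf;
  double bSum = 0.0;
  int nFree = 0;
  for (arma::uword t = 0; t < n; ++t) {
    const double lowTol = 1e-8 * Cvec(t);
    if (alpha(t) > lowTol && alpha(t) < Cvec(t) - lowTol) {
      bSum += yd(t) - f(t);
      ++nFree;
    } else if (alpha(t) <= lowTol) {            // y(f+b) >= 1
      if (y(t) > 0) bLo = std::max(bLo, 1.0 - f(t));
      else          bHi = std::min(bHi, -1.0 - f(t));
    } else {                                    // alpha at C: y(f+b) <= 1
      if (y(t) > 0) bHi = std::min(bHi, 1.0 - f(t));
      else          bLo = std::max(bLo, -1.0 - f(t));
    }
  }
  double b;
  if (nFree > 0) b = bSum / nFree;
  else if (std::isfinite(bLo) && std::isfinite(bHi)) b = 0.5 * (bLo + bHi);
  else if (std::isfinite(bLo)) b = bLo;
  else if (std::isfinite(bHi)) b = bHi;
  else b = 0.0;

  return List::create(_["alpha"] = alpha, _["w"] = w, _["b"] = b,
                      _["iterations"] = iter, _["converged"] = converged);
}
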