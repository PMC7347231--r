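// Exact t-distributed stochastic neighbour embedding (O(n^2)).
// Per-point bandwidths are calibrated to the requested perplexity by binary
// search on the Gaussian precision; the low-dimensional map uses Student-t
// (df = 1) affinities with the standard gradient, momentum schedule and
// early exaggeration.  The initial map coordinates are supplied from R so
// the embedding is fully reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using arma::mat;
using arma::vec;

// [[Rcpp::export]]
arma::mat tsne_cpp(const arma::mat& X, arma::mat Y, double perplexity,
                   int max_iter, double eta, double exaggeration,
                   int exaggeration_iter) {
  const int n = X.n_rows;
  const double logU = std::log(perplexity);

  // squared Euclidean distances in the input space
  vec sq = arma::sum(arma::square(X), 1);
  mat D = -2.0 * (X * X.t());
  D.each_col() += sq;
  D.each_row() += sq.t();
  D.diag().zeros();

  // conditional affinities with per-point precision beta
  mat P(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -arma::datum::inf, betamax = arma::datum::inf;
    vec Di = D.row(i).t();
    Di[i] = arma::datum::inf;
    vec Pi;
    for (int tries = 0; tries < 50; ++tries) {
      Pi = arma::exp(-Di * beta);
      Pi[i] = 0;
      double sumP = arma::accu(Pi);
      if (sumP <= 0) sumP = 1e-300;
      double H = std::log(sumP) + beta * arma::dot(Di.replace(arma::datum::inf, 0.0), Pi) / sumP;
      Pi /= sumP;
      double diff = H - logU;
      if (std::abs(diff) < 1e-5) break;
      if (diff > 0) {
        betamin = beta;
        beta = std::isfinite(betamax) ? (beta + betamax) / 2.0 : beta * 2.0;
      } else {
        betamax = beta;
        beta = std::isfinite(betamin) ? (beta + betamin) / 2.0 : beta / 2.0;
      }
    }
    P.row(i) = Pi.t();
  }
  P = (P + P.t()) / (2.0 * n);
  P.transform([](double v) { return std::max(v, 1e-12); });

  const int d = Y.n_cols;
  mat dY(n, d, arma::fill::zeros), iY(n, d, arma::fill::zeros);
  mat gains(n, d, arma::fill::ones);
  double momentum = 0.5;

  for (int iter = 0; iter < max_iter; ++iter) {
    const double ex = iter < exaggeration_iter ? exaggeration : 1.0;
    // Student-t affinities in the map
    vec sqy = arma::sum(arma::square(Y), 1);
    mat num = -2.0 * (Y * Y.t());
    num.each_col() += sqy;
    num.each_row() += sqy.t();
    num = 1.0 / (1.0 + num);
    num.diag().zeros();
    double sumQ = std::max(arma::accu(num), 1e-300);

    // gradient: 4 * sum_j (ex*P - Q)_ij * num_ij * (y_i - y_j)
    mat L = (ex * P - num / sumQ) % num;
    vec rs = arma::sum(L, 1);
    mat G = 4.0 * (arma::diagmat(rs) * Y - L * Y);

    // adaptive gains as in the reference implementation
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < d; ++k) {
        bool same = (G(i, k) > 0) == (iY(i, k) > 0);
        gains(i, k) = same ? std::max(gains(i, k) * 0.8, 0.01)
                           : gains(i, k) + 0.2;
      }
    iY = momentum * iY - eta * (gains % G);
    Y += iY;
    Y.each_row() -= arma::mean(Y, 0);
    if (iter == 250) momentum = 0.8;
  }
  return Y;
}
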