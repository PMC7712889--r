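#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Scaled forward-backward pass for one sequence.
// logB: T x K log observation densities; logpi: K; A: K x K (linear scale).
// Returns smoothed posteriors (gamma), summed transition counts (xi_sum),
// the first-timepoint posterior and the sequence log-likelihood.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(const arma::mat& logB, const arma::vec& logpi, const arma::mat& A) {
  const int T = logB.n_rows, K = logB.n_cols;
  arma::mat alpha(T, K), beta(T, K), b(T, K);
  arma::vec c(T), mx(T);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    mx(t) = logB.row(t).max();
    b.row(t) = arma::exp(logB.row(t) - mx(t));
  }

  arma::rowvec pi = arma::exp(logpi.t() - logpi.max());
  pi /= arma::accu(pi);

  alpha.row(0) = pi % b.row(0);
  c(0) = arma::accu(alpha.row(0));
  alpha.row(0) /= c(0);
  loglik += std::log(c(0)) + mx(0) + logpi.max() -
            std::log(arma::accu(arma::exp(logpi - logpi.max())));
  for (int t = 1; t < T; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * A) % b.row(t);
    c(t) = arma::accu(alpha.row(t));
    if (c(t) <= 0) stop("numerical underflow in forward pass");
    alpha.row(t) /= c(t);
    loglik += std::log(c(t)) + mx(t);
  }

  beta.row(T - 1).ones();
  arma::mat xi_sum(K, K, arma::fill::zeros);
  for (int t = T - 2; t >= 0; --t) {
    arma::rowvec bb = b.row(t + 1) % beta.row(t + 1);
    // xi_t(i,j) proportional to alpha_t(i) A(i,j) b_{t+1}(j) beta_{t+1}(j)
    arma::mat xi = (A.each_col() % alpha.row(t).t());
    xi.each_row() %= bb;
    double tot = arma::accu(xi);
    if (tot > 0) xi_sum += xi / tot;
    beta.row(t) = (A * bb.t()).t() / c(t + 1);
  }

  arma::mat gamma = alpha % beta;
  gamma.each_col() /= arma::sum(gamma, 1);

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi_sum,
                      _["loglik"] = loglik,
                      _["gamma1"] = arma::rowvec(gamma.row(0)));
}

// Viterbi decoding in log space. Ties break toward the lowest state index
// (strict improvement required to switch), so outputs are deterministic.
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(const arma::mat& logB, const arma::vec& logpi,
                          const arma::mat& logA) {
  const int T = logB.n_rows, K = logB.n_cols;
  arma::mat delta(T, K);
  arma::imat psi(T, K, arma::fill::zeros);

  delta.row(0) = logpi.t() + logB.row(0);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = delta(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = delta(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }

  IntegerVector path(T);
  int arg = 0;
  double best = delta(T - 1, 0);
  for (int j = 1; j < K; ++j) {
    if (delta(T - 1, j) > best) { best = delta(T - 1, j); arg = j; }
  }
  path[T - 1] = arg + 1;
  for (int t = T - 2; t >= 0; --t) {
    arg = psi(t + 1, arg);
    path[t] = arg + 1;
  }
  return path;
}
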