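#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// NIPALS PLS1 with X deflation. Returns, for every component count
// a = 1..ncomp, the regression coefficients on the original (uncentered)
// scale plus the matching intercept, so callers can scan component counts
// from one fit. Stops early when the residual X'y norm collapses.
// [[Rcpp::export(name = ".pls1_nipals")]]
Rcpp::List pls1_nipals(const arma::mat& X, const arma::vec& y, int ncomp) {
  const int n = X.n_rows, p = X.n_cols;
  const int amax = std::min(ncomp, std::min(n - 1, p));
  arma::rowvec xbar = arma::mean(X, 0);
  const double ybar = arma::mean(y);
  arma::mat Xd = X.each_row() - xbar;
  arma::vec yd = y - ybar;

  arma::mat W(p, std::max(amax, 1)), P(p, std::max(amax, 1));
  arma::vec q(std::max(amax, 1));
  arma::mat B(p, std::max(amax, 1), arma::fill::zeros);
  arma::vec b0(std::max(amax, 1), arma::fill::zeros);

  int used = 0;
  for (int a = 0; a < amax; ++a) {
    arma::vec w = Xd.t() * yd;
    const double nw = arma::norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    arma::vec t = Xd * w;
    const double tt = arma::dot(t, t);
    if (tt < 1e-12) break;
    arma::vec pv = Xd.t() * t / tt;
    const double qa = arma::dot(yd, t) / tt;
    Xd -= t * pv.t();
    yd -= qa * t;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qa;
    ++used;

    arma::mat Wa = W.cols(0, a);
    arma::mat PtW = P.cols(0, a).t() * Wa;
    arma::vec beta;
    if (!arma::solve(beta, PtW, q.subvec(0, a))) { --used; break; }
    B.col(a) = Wa * beta;
    b0(a) = ybar - arma::dot(xbar, B.col(a));
  }

  if (used == 0)
    return Rcpp::List::create(
        Rcpp::Named("coefficients") = arma::mat(p, 1, arma::fill::zeros),
        Rcpp::Named("intercepts") = arma::vec(1).fill(ybar),
        Rcpp::Named("ncomp") = 0);

  return Rcpp::List::create(
      Rcpp::Named("coefficients") = arma::mat(B.cols(0, used - 1)),
      Rcpp::Named("intercepts") = arma::vec(b0.subvec(0, used - 1)),
      Rcpp::Named("ncomp") = used);
}

// K-fold cross-validated RMSE of NIPALS PLS1 for component counts
// 1..ncomp. fold_id is 1-based fold membership per row (computed by the
// caller so the split is seeded once per task). Component counts that a
// fold cannot support reuse that fold's largest attainable model.
// [[Rcpp::export(name = ".pls1_cv_rmse")]]
arma::vec pls1_cv_rmse(const arma::mat& X, const arma::vec& y, int ncomp,
                       const arma::ivec& fold_id) {
  const int n = X.n_rows, p = X.n_cols;
  const int amax = std::min(ncomp, std::min(n - 2, p));
  const int nfold = fold_id.max();
  arma::vec sse(std::max(amax, 1), arma::fill::zeros);

  for (int f = 1; f <= nfold; ++f) {
    arma::uvec test = arma::find(fold_id == f);
    arma::uvec train = arma::find(fold_id != f);
    if (test.n_elem == 0 || train.n_elem < 3) continue;
    arma::mat Xtr = X.rows(train);
    arma::vec ytr = y(train);
    Rcpp::List fit = pls1_nipals(Xtr, ytr, amax);
    arma::mat B = fit["coefficients"];
    arma::vec b0 = fit["intercepts"];
    const int got = fit["ncomp"];
    arma::mat Xte = X.rows(test);
    arma::vec yte = y(test);
    for (int a = 0; a < std::max(amax, 1); ++a) {
      const int use = std::min(a, std::max(got - 1, 0));
      arma::vec pred = Xte * B.col(use) + b0(use);
      sse(a) += arma::accu(arma::square(yte - pred));
    }
  }
  return arma::sqrt(sse / static_cast<double>(n));
}
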