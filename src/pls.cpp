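#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// NIPALS PLS1 on already-centered data.  Returns weights W, x-loadings P,
// y-loadings q and the cumulative regression-coefficient matrix B where
// B.col(k-1) is the coefficient vector for a k-component model,
// B_k = W_k (P_k' W_k)^{-1} q_k.  Stops early when the residual covariance
// collapses; `achieved` reports the number of components actually extracted.
static void nipals_pls1(const mat& Xc, const vec& yc, int ncomp,
                        mat& W, mat& P, vec& q, mat& B, int& achieved) {
  const uword p = Xc.n_cols;
  mat E = Xc;
  vec f = yc;
  W.set_size(p, ncomp); P.set_size(p, ncomp); q.set_size(ncomp);
  int a = 0;
  for (; a < ncomp; ++a) {
    vec w = E.t() * f;
    double nw = norm(w, 2);
    if (nw < 1e-12) break;
    w /= nw;
    vec t = E * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pv = E.t() * t / tt;
    double qa = dot(f, t) / tt;
    E -= t * pv.t();
    f -= qa * t;
    W.col(a) = w;
    P.col(a) = pv;
    q(a) = qa;
  }
  achieved = a;
  if (a == 0) {
    // degenerate: y uncorrelated with X; coefficients are all zero
    W.set_size(p, 0); P.set_size(p, 0); q.set_size(0);
    B = zeros<mat>(p, 1);
    return;
  }
  W = W.head_cols(a); P = P.head_cols(a); q = q.head(a);
  B.set_size(p, a);
  mat R = P.t() * W;          // a x a, upper triangular for PLS1
  for (int k = 1; k <= a; ++k) {
    vec bk = solve(trimatu(R.submat(0, 0, k - 1, k - 1)), q.head(k));
    B.col(k - 1) = W.head_cols(k) * bk;
  }
}

// [[Rcpp::export]]
Rcpp::List cppPlsFit(const arma::mat& X, const arma::vec& y, int ncomp) {
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat W, P, B; vec q; int achieved = 0;
  nipals_pls1(Xc, yc, ncomp, W, P, q, B, achieved);
  return Rcpp::List::create(
    Rcpp::Named("xMean") = xm.t(),
    Rcpp::Named("yMean") = ym,
    Rcpp::Named("W") = W,
    Rcpp::Named("P") = P,
    Rcpp::Named("q") = q,
    Rcpp::Named("B") = B,
    Rcpp::Named("achieved") = achieved);
}

// Venetian-blind K-fold cross-validation RMSECV for component counts
// 1..ncomp.  Sample i (0-based) belongs to fold i % folds.  Each training
// split is centered on its own means.  When a fold's training set supports
// fewer than ncomp components, predictions for the missing counts reuse the
// largest achieved model.
// [[Rcpp::export]]
arma::vec cppPlsCv(const arma::mat& X, const arma::vec& y, int ncomp,
                   int folds, const arma::ivec& foldId) {
  const uword n = X.n_rows;
  vec sse = zeros<vec>(ncomp);
  for (int f = 0; f < folds; ++f) {
    uvec te = find(foldId == f);
    uvec tr = find(foldId != f);
    if (te.n_elem == 0 || tr.n_elem < 2) continue;
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    vec ytr = y(tr), yte = y(te);
    rowvec xm = mean(Xtr, 0);
    double ym = mean(ytr);
    mat Xc = Xtr.each_row() - xm;
    vec yc = ytr - ym;
    int cap = std::min<int>(ncomp, (int)tr.n_elem - 1);
    mat W, P, B; vec q; int achieved = 0;
    nipals_pls1(Xc, yc, cap, W, P, q, B, achieved);
    mat Xtec = Xte.each_row() - xm;
    for (int k = 1; k <= ncomp; ++k) {
      int use = std::min(k, std::max(achieved, 1));
      vec pred = Xtec * B.col(use - 1) + ym;
      vec err = pred - yte;
      sse(k - 1) += dot(err, err);
    }
  }
  return sqrt(sse / (double)n);
}
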