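#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// SIMPLS (de Jong 1993) on centred X0 (n x p) and Y0 (n x q).
// Fills R (p x A) and Q (q x A); the coefficient matrix truncated at a
// components is B_a = R[, 1:a] %*% t(Q[, 1:a]).  Returns the number of
// components actually extracted (deflation can exhaust the covariance
// early on low-rank inputs).
static int simpls_core(const mat& X0, const mat& Y0, int A, mat& R, mat& Q) {
  const uword p = X0.n_cols, q = Y0.n_cols;
  mat S = X0.t() * Y0;  // p x q cross-covariance
  mat V(p, (uword)A, fill::zeros);
  R.zeros(p, (uword)A);
  Q.zeros(q, (uword)A);
  int a_done = 0;
  for (int a = 0; a < A; ++a) {
    vec eval;
    mat evec;
    if (!eig_sym(eval, evec, S.t() * S)) break;
    vec qa = evec.col(q - 1);  // dominant right singular vector of S
    vec r = S * qa;
    vec t = X0 * r;
    t -= mean(t);
    double nt = norm(t);
    if (nt < 1e-12) break;
    t /= nt;
    r /= nt;
    vec pa = X0.t() * t;
    vec qv = Y0.t() * t;
    vec v = pa;
    if (a > 0) {
      mat Vp = V.head_cols((uword)a);
      v -= Vp * (Vp.t() * pa);
    }
    double nv = norm(v);
    if (nv < 1e-12) break;
    v /= nv;
    S -= v * (v.t() * S);  // deflate the covariance, not the data
    V.col(a) = v;
    R.col(a) = r;
    Q.col(a) = qv;
    a_done = a + 1;
  }
  return a_done;
}

// [[Rcpp::export(name = ".simpls_fit_cpp")]]
Rcpp::List simpls_fit_cpp(const arma::mat& X, const arma::mat& Y, int ncomp) {
  const uword n = X.n_rows;
  int A = std::min<int>(ncomp, std::min<int>((int)n - 1, (int)X.n_cols));
  if (A < 1) A = 1;
  rowvec xm = mean(X, 0);
  rowvec ym = mean(Y, 0);
  mat X0 = X.each_row() - xm;
  mat Y0 = Y.each_row() - ym;
  mat R, Q;
  int a_done = simpls_core(X0, Y0, A, R, Q);
  if (a_done < 1) a_done = 1;  // R, Q zero-filled: constant-mean predictor
  return Rcpp::List::create(
      Rcpp::Named("R") = R.head_cols((uword)a_done),
      Rcpp::Named("Q") = Q.head_cols((uword)a_done),
      Rcpp::Named("xmeans") = xm.t(), Rcpp::Named("ymeans") = ym.t(),
      Rcpp::Named("ncomp") = a_done);
}

// Cross-validated sum of squared prediction errors of the indicator
// matrix, for every truncation 1..ncomp in one pass.  foldid holds fold
// labels 1..F per row.  Returns an ncomp-vector of RMSECV values; when
// deflation stops early inside a fold the last reachable coefficient
// matrix is carried forward, so later entries stay defined.
// [[Rcpp::export(name = ".simpls_cv_rmsecv_cpp")]]
arma::vec simpls_cv_rmsecv_cpp(const arma::mat& X, const arma::mat& Y,
                               int ncomp, const arma::ivec& foldid) {
  const uword n = X.n_rows, q = Y.n_cols;
  const int F = (int)foldid.max();
  vec sse(std::max(ncomp, 1), fill::zeros);
  for (int f = 1; f <= F; ++f) {
    uvec te = find(foldid == f);
    uvec tr = find(foldid != f);
    if (te.n_elem == 0 || tr.n_elem < 2) continue;
    mat Xtr = X.rows(tr), Ytr = Y.rows(tr);
    mat Xte = X.rows(te), Yte = Y.rows(te);
    int A = std::min<int>(ncomp,
                          std::min<int>((int)tr.n_elem - 1, (int)X.n_cols));
    if (A < 1) A = 1;
    rowvec xm = mean(Xtr, 0), ym = mean(Ytr, 0);
    mat X0 = Xtr.each_row() - xm;
    mat Y0 = Ytr.each_row() - ym;
    mat R, Q;
    int a_done = simpls_core(X0, Y0, A, R, Q);
    mat Xte0 = Xte.each_row() - xm;
    mat pred(te.n_elem, q);
    pred.each_row() = ym;  // zero-component (mean) prediction
    for (int a = 0; a < ncomp; ++a) {
      if (a < a_done) pred += (Xte0 * R.col(a)) * Q.col(a).t();
      sse((uword)a) += accu(square(pred - Yte));
    }
  }
  return sqrt(sse / double(n * q));
}
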