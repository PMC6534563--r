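// Cross-validated ridge regression with efficient leave-one-out selection
// of the penalty inside each training fold. Standardization uses training
// statistics only; out-of-fold predictions are returned concatenated.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::vec ridge_cv_oof(const arma::mat& X, const arma::vec& y,
                       const arma::ivec& folds, const arma::vec& grid) {
  const unsigned int n = X.n_rows, p = X.n_cols;
  const int k = folds.max();
  vec oof(n, fill::zeros);

  for (int f = 1; f <= k; ++f) {
    uvec te = find(folds == f);
    uvec tr = find(folds != f);
    mat Xtr = X.rows(tr);
    vec ytr = y.elem(tr);
    rowvec mx = mean(Xtr, 0);
    rowvec sx = stddev(Xtr, 0, 0);
    sx.elem(find(sx == 0)).ones();
    mat Z = (Xtr.each_row() - mx).each_row() / sx;
    double my = mean(ytr);
    vec yc = ytr - my;

    vec d; mat V;
    eig_sym(d, V, Z.t() * Z);
    d.elem(find(d < 0)).zeros();
    mat U = Z * V;                // columns orthogonal, |u_j|^2 = d_j
    vec Uy = U.t() * yc;
    mat U2 = square(U);

    double best_mse = datum::inf;
    double best_lam = grid(0);
    for (unsigned int g = 0; g < grid.n_elem; ++g) {
      vec shrink = 1.0 / (d + grid(g));
      vec yhat = U * (shrink % Uy);
      vec hii = U2 * shrink;
      hii.transform([](double v) { return v > 1.0 - 1e-8 ? 1.0 - 1e-8 : v; });
      vec r = (yc - yhat) / (1.0 - hii);
      double mse = dot(r, r) / yc.n_elem;
      if (mse < best_mse) { best_mse = mse; best_lam = grid(g); }
    }
    vec beta_z = V * (Uy / (d + best_lam));
    mat Xte = X.rows(te);
    mat Zt = (Xte.each_row() - mx).each_row() / sx;
    oof.elem(te) = Zt * beta_z + my;
  }
  return oof;
}
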