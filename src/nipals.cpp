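// NIPALS partial least squares core (PLS1/PLS2) used by fit_plsr(),
// cross_validate_q2() and bootstrap_coefficients().  Inputs are assumed
// centred (and usually scaled); no standardization happens here.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One NIPALS fit.  X: n x p, Y: n x q, both deflated in place.
// Returns weights W (unit columns), scores T, X-loadings P, Y-weights C,
// Y-scores U and the residual Y sum of squares after each component.
static void nipals_core(mat X, mat Y, const int A, const double tol,
                        const int max_iter,
                        mat &W, mat &T, mat &P, mat &C, mat &U,
                        vec &ss_y) {
  const uword p = X.n_cols, q = Y.n_cols;
  W.set_size(p, A); T.set_size(X.n_rows, A); P.set_size(p, A);
  C.set_size(q, A); U.set_size(X.n_rows, A); ss_y.set_size(A + 1);
  ss_y(0) = accu(square(Y));

  for (int a = 0; a < A; ++a) {
    vec w(p), t, c(q), u;
    if (q == 1) {
      // PLS1: closed-form component, no inner iteration
      w = X.t() * Y.col(0);
      double nw = norm(w, 2);
      if (nw <= 0) Rcpp::stop("zero X'y weight vector: no covariance left at component %d", a + 1);
      w /= nw;
      t = X * w;
      c(0) = dot(Y.col(0), t) / dot(t, t);
      u = Y.col(0) / c(0);
    } else {
      // Start the inner loop at its fixed point: the NIPALS weight vector
      // converges to the dominant left singular vector of Z = X'Y, obtained
      // exactly from the q x q eigenproblem Z'Z v = s v, u0 = Y v.  The loop
      // then verifies/polishes the fixed point, so near-degenerate response
      // blocks (tiny eigengaps) do not stall the power iteration.
      mat Z = X.t() * Y;
      vec eigval; mat eigvec;
      if (!eig_sym(eigval, eigvec, Z.t() * Z))
        Rcpp::stop("eigendecomposition of the Y-weight problem failed");
      u = Y * eigvec.col(eigvec.n_cols - 1);
      if (norm(u, 2) <= 0) u = Y.col(0);
      vec t_old(X.n_rows, fill::zeros);
      int it = 0;
      for (;; ++it) {
        if (it >= max_iter)
          Rcpp::stop("NIPALS inner loop failed to converge in %d iterations", max_iter);
        w = X.t() * u;
        double nw = norm(w, 2);
        if (nw <= 0) Rcpp::stop("zero weight vector at component %d", a + 1);
        w /= nw;
        t = X * w;
        c = Y.t() * t / dot(t, t);
        double nc = norm(c, 2);
        if (nc <= 0) Rcpp::stop("zero Y-weight vector at component %d", a + 1);
        u = Y * c / dot(c, c);
        if (norm(t - t_old, 2) <= tol * std::max(1.0, norm(t, 2))) break;
        t_old = t;
      }
    }
    double tt = dot(t, t);
    if (tt <= 0) Rcpp::stop("degenerate score vector at component %d", a + 1);
    vec pl = X.t() * t / tt;
    X -= t * pl.t();
    Y -= t * c.t();          // c is the regression of Y on t
    W.col(a) = w; T.col(a) = t; P.col(a) = pl; C.col(a) = c; U.col(a) = u;
    ss_y(a + 1) = accu(square(Y));
  }
}

// beta (p x q) for an a-component model from cumulative W, P, C
static mat beta_at(const mat &W, const mat &P, const mat &C, const int a) {
  mat Wa = W.cols(0, a - 1), Pa = P.cols(0, a - 1), Ca = C.cols(0, a - 1);
  return Wa * solve(Pa.t() * Wa, Ca.t());
}

// [[Rcpp::export]]
Rcpp::List nipals_fit(const arma::mat &X, const arma::mat &Y, const int A,
                      const double tol, const int max_iter) {
  mat W, T, P, C, U; vec ss_y;
  nipals_core(X, Y, A, tol, max_iter, W, T, P, C, U, ss_y);
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("T") = T, Rcpp::Named("P") = P,
    Rcpp::Named("C") = C, Rcpp::Named("U") = U,
    Rcpp::Named("beta") = beta_at(W, P, C, A),
    Rcpp::Named("ss_y") = ss_y);
}

// Held-out predictions for components 1..A: returns n_test x q x A cube
// flattened as a list of matrices.
// [[Rcpp::export]]
Rcpp::List nipals_cv_predict(const arma::mat &Xtrain, const arma::mat &Ytrain,
                             const arma::mat &Xtest, const int A,
                             const double tol, const int max_iter) {
  mat W, T, P, C, U; vec ss_y;
  nipals_core(Xtrain, Ytrain, A, tol, max_iter, W, T, P, C, U, ss_y);
  Rcpp::List out(A);
  for (int a = 1; a <= A; ++a)
    out[a - 1] = Rcpp::wrap(mat(Xtest * beta_at(W, P, C, a)));
  return out;
}

// Case-resampling bootstrap: idx is an n x B matrix of 1-based row indices
// drawn in R (so reproducibility follows R's RNG).  Returns a p*q x B matrix
// of vectorized coefficient matrices.
// [[Rcpp::export]]
arma::mat nipals_boot(const arma::mat &X, const arma::mat &Y,
                      const arma::umat &idx, const int A,
                      const double tol, const int max_iter) {
  const uword B = idx.n_cols, p = X.n_cols, q = Y.n_cols;
  mat out(p * q, B);
  for (uword b = 0; b < B; ++b) {
    uvec rows = idx.col(b) - 1;
    mat W, T, P, C, U; vec ss_y;
    nipals_core(X.rows(rows), Y.rows(rows), A, tol, max_iter, W, T, P, C, U, ss_y);
    out.col(b) = vectorise(beta_at(W, P, C, A));
  }
  return out;
}
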