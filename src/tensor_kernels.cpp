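// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

//' Batched weighted least-squares solve for the log-linear tensor model.
//'
//' Solves, independently for every voxel v, the weighted normal equations
//' argmin_b || sqrt(W[,v]) * (X b - Y[,v]) ||^2 where X is the shared
//' diffusion design matrix (m gradients x p=6 tensor elements), Y holds the
//' per-voxel negative log-attenuations and W the per-voxel weights
//' (predicted squared signals for one-pass reweighting).
//'
//' @param X m x p design matrix.
//' @param Y m x n matrix, one column per voxel.
//' @param W m x n positive weight matrix, one column per voxel.
//' @return p x n matrix of coefficients.
//' @keywords internal
// [[Rcpp::export(name = ".wls_batch")]]
arma::mat wls_batch(const arma::mat& X, const arma::mat& Y, const arma::mat& W) {
    const uword m = X.n_rows, p = X.n_cols, n = Y.n_cols;
    if (Y.n_rows != m || W.n_rows != m || W.n_cols != n)
        Rcpp::stop("dimension mismatch in wls_batch");
    mat B(p, n);
    mat Xw(m, p);
    vec sw(m);
    for (uword v = 0; v < n; ++v) {
        sw = sqrt(W.col(v));
        Xw = X.each_col() % sw;
        vec yw = Y.col(v) % sw;
        vec b;
        bool ok = solve(b, Xw, yw, solve_opts::no_approx);
        if (!ok) {
            // rank-deficient after weighting; fall back to minimum-norm solution
            b = pinv(Xw) * yw;
        }
        B.col(v) = b;
    }
    return B;
}

//' Batched symmetric 3x3 eigendecomposition.
//'
//' @param D n x 6 matrix of unique tensor elements in the order
//'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
//' @return list with `values` (n x 3, descending) and `vectors` (n x 9,
//'   column-major 3x3 per row, eigenvectors in the columns matching the
//'   sorted eigenvalues; sign fixed so the first nonzero component is
//'   non-negative).
//' @keywords internal
// [[Rcpp::export(name = ".eig3_batch")]]
Rcpp::List eig3_batch(const arma::mat& D) {
    const uword n = D.n_rows;
    if (D.n_cols != 6) Rcpp::stop("expected n x 6 tensor matrix");
    mat values(n, 3);
    mat vectors(n, 9);
    mat33 T;
    vec3 ev;
    mat33 V;
    for (uword v = 0; v < n; ++v) {
        T(0, 0) = D(v, 0); T(1, 1) = D(v, 1); T(2, 2) = D(v, 2);
        T(0, 1) = T(1, 0) = D(v, 3);
        T(0, 2) = T(2, 0) = D(v, 4);
        T(1, 2) = T(2, 1) = D(v, 5);
        eig_sym(ev, V, T);          // ascending
        for (int j = 0; j < 3; ++j) {
            int src = 2 - j;        // descending order
            values(v, j) = ev(src);
            vec3 e = V.col(src);
            // deterministic sign: first component of magnitude > tol sets it
            for (int c = 0; c < 3; ++c) {
                if (std::abs(e(c)) > 1e-12) {
                    if (e(c) < 0) e = -e;
                    break;
                }
            }
            vectors(v, 3 * j + 0) = e(0);
            vectors(v, 3 * j + 1) = e(1);
            vectors(v, 3 * j + 2) = e(2);
        }
    }
    return Rcpp::List::create(Rcpp::Named("values") = values,
                              Rcpp::Named("vectors") = vectors);
}
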