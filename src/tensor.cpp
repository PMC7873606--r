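#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Iteratively reweighted linear least squares tensor fit, batched over
// voxels.  S: n_meas x n_vox signal matrix; X: n_meas x 7 design matrix
// with rows [1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz].
// Iteration 0 is ordinary log-linear least squares; iterations k > 0
// reweight each measurement by the squared model-predicted signal.
// Signals <= 0 are clamped to `floor` before the log.
// Returns 7 x n_vox coefficients [log S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]
// and a per-voxel success flag.
// [[Rcpp::export(name = ".tensor_irls_cpp")]]
List tensor_irls_cpp(const arma::mat &S, const arma::mat &X, int n_iter,
                     double floor_val) {
    const arma::uword nm = S.n_rows, nv = S.n_cols;
    if (X.n_rows != nm) stop("design/signal row mismatch");
    arma::mat Y = arma::log(arma::clamp(S, floor_val, arma::datum::inf));
    arma::mat beta(7, nv, arma::fill::zeros);
    LogicalVector ok(nv, true);

    arma::mat XtX = X.t() * X;
    arma::mat beta0;
    if (!arma::solve(beta0, XtX, X.t() * Y, arma::solve_opts::no_approx)) {
        stop("rank-deficient tensor design: too few independent directions");
    }
    beta = beta0;

    for (int it = 0; it < n_iter; ++it) {
        for (arma::uword v = 0; v < nv; ++v) {
            arma::vec pred = X * beta.col(v);
            arma::vec w = arma::exp(2.0 * pred);        // predicted S^2
            w = arma::clamp(w, 1e-12, arma::datum::inf);
            arma::mat Xw = X.each_col() % w;
            arma::vec b;
            if (arma::solve(b, X.t() * Xw, Xw.t() * Y.col(v),
                            arma::solve_opts::no_approx) &&
                b.is_finite()) {
                beta.col(v) = b;
            } else {
                ok[v] = false;
            }
        }
    }
    if (!beta.is_finite()) {
        for (arma::uword v = 0; v < nv; ++v)
            if (!beta.col(v).is_finite()) ok[v] = false;
    }
    return List::create(_["beta"] = wrap(beta), _["ok"] = ok);
}

// Eigen-decomposition of the fitted tensors: returns eigenvalues sorted
// descending (3 x n_vox) and the principal eigenvector (3 x n_vox).
// [[Rcpp::export(name = ".tensor_eigs_cpp")]]
List tensor_eigs_cpp(const arma::mat &beta) {
    const arma::uword nv = beta.n_cols;
    arma::mat evals(3, nv), evec1(3, nv);
    for (arma::uword v = 0; v < nv; ++v) {
        arma::mat33 D = {{beta(1, v), beta(4, v), beta(5, v)},
                         {beta(4, v), beta(2, v), beta(6, v)},
                         {beta(5, v), beta(6, v), beta(3, v)}};
        arma::vec ev;
        arma::mat V;
        if (!arma::eig_sym(ev, V, D)) {
            evals.col(v).fill(arma::datum::nan);
            evec1.col(v).fill(arma::datum::nan);
            continue;
        }
        // eig_sym is ascending; flip to descending
        evals(0, v) = ev(2); evals(1, v) = ev(1); evals(2, v) = ev(0);
        evec1.col(v) = V.col(2);
    }
    return List::create(_["evals"] = wrap(evals), _["evec1"] = wrap(evec1));
}
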