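#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Constrained spherical deconvolution, batched over voxels.
//
// S      : n_dirs x n_vox DW signals (b>0 shell, b0-normalized)
// Fmat   : n_dirs x n_coef forward convolution matrix (response (x) SH basis)
// Bmesh  : n_mesh x n_coef SH basis at the constraint directions
// n_init : number of leading coefficients used for the unconstrained
//          low-order initial fit (e.g. 15 for lmax 4)
// Iterated hard constraint: mesh amplitudes below tau * mean(initial
// amplitudes) select rows of Bmesh whose squared amplitude is penalized
// with weight lambda^2; iterate to a fixed constraint set or n_iter.
// [[Rcpp::export(name = ".csd_fit_cpp")]]
List csd_fit_cpp(const arma::mat &S, const arma::mat &Fmat,
                 const arma::mat &Bmesh, int n_init, double lambda,
                 double tau, int n_iter) {
    const arma::uword nd = Fmat.n_rows, nc = Fmat.n_cols,
                      nv = S.n_cols, nm = Bmesh.n_rows;
    if (S.n_rows != nd) stop("signal/forward-matrix row mismatch");
    if (Bmesh.n_cols != nc) stop("mesh basis column mismatch");
    if (n_init < 1 || (arma::uword)n_init > nc) stop("invalid n_init");

    // With lmax-8 super-resolution F'F alone is rank deficient (fewer
    // directions than coefficients); a tiny ridge keeps the degenerate
    // empty-constraint case (near-isotropic voxels) solvable without
    // measurably perturbing constrained fits.
    const double ridge = 1e-8 * arma::trace(Fmat.t() * Fmat) / nc;
    const arma::mat FtF = Fmat.t() * Fmat +
        ridge * arma::eye<arma::mat>(nc, nc);
    const arma::mat Finit = Fmat.cols(0, n_init - 1);
    arma::mat init_solver = arma::pinv(Finit);
    const double l2 = lambda * lambda;

    arma::mat X(nc, nv, arma::fill::zeros);
    IntegerVector iters(nv);
    LogicalVector converged(nv);

    for (arma::uword v = 0; v < nv; ++v) {
        arma::vec s = S.col(v);
        arma::vec x(nc, arma::fill::zeros);
        x.head(n_init) = init_solver * s;
        arma::vec amp0 = Bmesh * x;
        const double thr = tau * arma::mean(amp0);
        const arma::vec Fts = Fmat.t() * s;

        arma::uvec prev;
        bool conv = false;
        int it = 0;
        for (; it < n_iter; ++it) {
            arma::uvec neg = arma::find(Bmesh * x < thr);
            if (it > 0 && neg.n_elem == prev.n_elem &&
                (neg.n_elem == 0 || arma::all(neg == prev))) {
                conv = true;
                break;
            }
            prev = neg;
            arma::mat M = FtF;
            if (neg.n_elem > 0) {
                const arma::mat Bneg = Bmesh.rows(neg);
                M += l2 * (Bneg.t() * Bneg);
            }
            arma::vec xn;
            if (!arma::solve(xn, M, Fts, arma::solve_opts::likely_sympd) ||
                !xn.is_finite())
                break;
            x = xn;
        }
        X.col(v) = x;
        iters[v] = it;
        converged[v] = conv;
    }
    return List::create(_["coeffs"] = wrap(X), _["iterations"] = iters,
                        _["converged"] = converged);
}
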