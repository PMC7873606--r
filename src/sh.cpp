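#include <Rcpp.h>
#include "shlib.h"

using namespace Rcpp;

// Basis matrix: one row per direction, one column per even-order SH
// coefficient (see shlib.h for the convention).
// [[Rcpp::export(name = ".sh_basis_cpp")]]
NumericMatrix sh_basis_cpp(NumericMatrix dirs, int lmax) {
    if (dirs.ncol() != 3) stop("dirs must be an n x 3 matrix");
    if (lmax < 0 || lmax > 30 || lmax % 2 != 0)
        stop("lmax must be a non-negative even integer <= 30");
    const int n = dirs.nrow();
    const int nc = tractfd::sh_ncoef(lmax);
    NumericMatrix B(n, nc);
    std::vector<double> buf(nc);
    for (int i = 0; i < n; ++i) {
        tractfd::sh_eval(dirs(i, 0), dirs(i, 1), dirs(i, 2), lmax, buf.data());
        for (int j = 0; j < nc; ++j) B(i, j) = buf[j];
    }
    return B;
}
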