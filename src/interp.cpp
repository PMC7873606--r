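#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation of a 3D volume at fractional 0-based voxel
// coordinates (voxel center at integer index).  Points outside
// [0, dim-1] in any axis yield NA; NA at any contributing corner
// propagates to NA.
// [[Rcpp::export(name = ".trilinear_cpp")]]
NumericVector trilinear_cpp(NumericVector vol, IntegerVector dim,
                            NumericMatrix pts) {
    if (dim.size() != 3) stop("dim must have length 3");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    if ((R_xlen_t)nx * ny * nz != vol.size()) stop("dim/volume mismatch");
    const int n = pts.nrow();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
        if (!(x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 &&
              z >= 0 && z <= nz - 1)) {
            out[i] = NA_REAL;
            continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 > nx - 2) x0 = nx - 2 > 0 ? nx - 2 : 0;
        if (y0 > ny - 2) y0 = ny - 2 > 0 ? ny - 2 : 0;
        if (z0 > nz - 2) z0 = nz - 2 > 0 ? nz - 2 : 0;
        const int x1 = x0 + 1 < nx ? x0 + 1 : x0;
        const int y1 = y0 + 1 < ny ? y0 + 1 : y0;
        const int z1 = z0 + 1 < nz ? z0 + 1 : z0;
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        double acc = 0.0;
        bool na = false;
        for (int cz = 0; cz < 2 && !na; ++cz)
            for (int cy = 0; cy < 2 && !na; ++cy)
                for (int cx = 0; cx < 2 && !na; ++cx) {
                    const double w = (cx ? fx : 1 - fx) * (cy ? fy : 1 - fy) *
                                     (cz ? fz : 1 - fz);
                    if (w == 0) continue;
                    const int ix = cx ? x1 : x0, iy = cy ? y1 : y0,
                              iz = cz ? z1 : z0;
                    const double v =
                        vol[(R_xlen_t)ix + nx * ((R_xlen_t)iy + (R_xlen_t)ny * iz)];
                    if (ISNAN(v)) { na = true; break; }
                    acc += w * v;
                }
        out[i] = na ? NA_REAL : acc;
    }
    return out;
}

// Squared-distance-minimizing nearest vertex on a densely sampled
// polyline for each query point.  Returns 1-based index and distance.
// [[Rcpp::export(name = ".polyline_nearest_cpp")]]
List polyline_nearest_cpp(NumericMatrix pts, NumericMatrix line) {
    const int n = pts.nrow(), m = line.nrow();
    IntegerVector idx(n);
    NumericVector dist(n);
    for (int i = 0; i < n; ++i) {
        double best = R_PosInf;
        int bj = 0;
        const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
        for (int j = 0; j < m; ++j) {
            const double dx = px - line(j, 0), dy = py - line(j, 1),
                         dz = pz - line(j, 2);
            const double d = dx * dx + dy * dy + dz * dz;
            if (d < best) { best = d; bj = j; }
        }
        idx[i] = bj + 1;
        dist[i] = std::sqrt(best);
    }
    return List::create(_["index"] = idx, _["distance"] = dist);
}
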