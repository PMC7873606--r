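#include <Rcpp.h>
#include <cmath>
#include "shlib.h"

using namespace Rcpp;

// Probabilistic FOD tractography.  FOD SH coefficients are trilinearly
// interpolated; candidate step directions are drawn uniformly within the
// curvature cone and one is selected with probability proportional to the
// product of FOD amplitudes at the midpoint and endpoint of the candidate
// step (two-point arc approximation of arc-wise integration).  Uses R's
// RNG, so runs are reproducible from set.seed().

namespace {

struct Field {
    const double *coeffs;   // ncoef x nvox
    int nc, nx, ny, nz;
    const double *w2v;      // 4x4 col-major world -> voxel

    void world2vox(const double *p, double *v) const {
        for (int r = 0; r < 3; ++r)
            v[r] = w2v[r] * p[0] + w2v[r + 4] * p[1] + w2v[r + 8] * p[2] +
                   w2v[r + 12];
    }
    // trilinear interpolation of all coefficients; false if outside grid
    bool coeff_at(const double *vox, double *out) const {
        const double x = vox[0], y = vox[1], z = vox[2];
        if (!(x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 && z >= 0 &&
              z <= nz - 1))
            return false;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        if (x0 > nx - 2 && nx > 1) x0 = nx - 2;
        if (y0 > ny - 2 && ny > 1) y0 = ny - 2;
        if (z0 > nz - 2 && nz > 1) z0 = nz - 2;
        const int x1 = x0 + 1 < nx ? x0 + 1 : x0;
        const int y1 = y0 + 1 < ny ? y0 + 1 : y0;
        const int z1 = z0 + 1 < nz ? z0 + 1 : z0;
        const double fx = x - x0, fy = y - y0, fz = z - z0;
        for (int j = 0; j < nc; ++j) out[j] = 0.0;
        for (int cz = 0; cz < 2; ++cz)
            for (int cy = 0; cy < 2; ++cy)
                for (int cx = 0; cx < 2; ++cx) {
                    const double w = (cx ? fx : 1 - fx) *
                                     (cy ? fy : 1 - fy) * (cz ? fz : 1 - fz);
                    if (w == 0) continue;
                    const int ix = cx ? x1 : x0, iy = cy ? y1 : y0,
                              iz = cz ? z1 : z0;
                    const double *c =
                        coeffs + (size_t)nc * (ix + nx * (iy + (size_t)ny * iz));
                    for (int j = 0; j < nc; ++j) out[j] += w * c[j];
                }
        return true;
    }
    // FOD amplitude at world point p along direction d; -1 if outside
    double amplitude(const double *p, const double *d, int lmax,
                     double *cbuf, double *bbuf) const {
        double v[3];
        world2vox(p, v);
        if (!coeff_at(v, cbuf)) return -1.0;
        tractfd::sh_eval(d[0], d[1], d[2], lmax, bbuf);
        double a = 0.0;
        for (int j = 0; j < nc; ++j) a += cbuf[j] * bbuf[j];
        return a;
    }
};

void ortho_frame(const double *d, double *e1, double *e2) {
    double a[3] = {1, 0, 0};
    if (std::fabs(d[0]) > 0.9) { a[0] = 0; a[1] = 1; }
    e1[0] = d[1] * a[2] - d[2] * a[1];
    e1[1] = d[2] * a[0] - d[0] * a[2];
    e1[2] = d[0] * a[1] - d[1] * a[0];
    const double n = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    for (int i = 0; i < 3; ++i) e1[i] /= n;
    e2[0] = d[1] * e1[2] - d[2] * e1[1];
    e2[1] = d[2] * e1[0] - d[0] * e1[2];
    e2[2] = d[0] * e1[1] - d[1] * e1[0];
}

// uniform direction within cone of half-angle `ang` around d
void cone_sample(const double *d, double ang, double *out) {
    const double ct = 1.0 - unif_rand() * (1.0 - std::cos(ang));
    const double st = std::sqrt(1.0 - ct * ct < 0 ? 0 : 1.0 - ct * ct);
    const double phi = 2.0 * M_PI * unif_rand();
    double e1[3], e2[3];
    ortho_frame(d, e1, e2);
    for (int i = 0; i < 3; ++i)
        out[i] = ct * d[i] + st * (std::cos(phi) * e1[i] + std::sin(phi) * e2[i]);
}

int categorical(const double *w, int n, double total) {
    double u = unif_rand() * total, acc = 0.0;
    for (int i = 0; i < n; ++i) {
        acc += w[i];
        if (u <= acc) return i;
    }
    return n - 1;
}

} // namespace

// [[Rcpp::export(name = ".track_cpp")]]
List track_cpp(NumericMatrix coeffs, IntegerVector dim, NumericMatrix w2v,
               NumericMatrix v2w, IntegerMatrix seed_vox,
               LogicalVector include_mask, int lmax, double step,
               double max_angle, double cutoff, double min_len,
               double max_len, int n_target, double max_attempt_factor,
               int n_cand, int n_init_cand) {
    Field f;
    f.coeffs = coeffs.begin();
    f.nc = coeffs.nrow();
    f.nx = dim[0]; f.ny = dim[1]; f.nz = dim[2];
    f.w2v = w2v.begin();
    if ((R_xlen_t)f.nx * f.ny * f.nz != coeffs.ncol())
        stop("coefficient field does not match grid");
    if (seed_vox.nrow() == 0) stop("empty seed mask");
    if (tractfd::sh_ncoef(lmax) != f.nc) stop("lmax does not match ncoef");

    const int nseed = seed_vox.nrow();
    const int max_pts = (int)std::floor(max_len / step) + 1;
    const long max_attempts =
        (long)std::ceil(max_attempt_factor * (double)n_target);

    std::vector<double> cbuf(f.nc), bbuf(f.nc);
    List out_sl(n_target);
    IntegerVector out_seed(n_target);
    int n_acc = 0;
    long attempts = 0;
    long rej_short = 0, rej_long = 0, rej_include = 0, rej_init = 0;

    std::vector<double> fwd, bwd;   // flattened xyz triplets
    fwd.reserve(3 * max_pts);
    bwd.reserve(3 * max_pts);

    while (n_acc < n_target && attempts < max_attempts) {
        ++attempts;
        // seed point: uniform within a random seed-mask voxel
        const int k = std::min((int)(unif_rand() * nseed), nseed - 1);
        double vox[3], p0[4];
        for (int i = 0; i < 3; ++i) vox[i] = seed_vox(k, i) + unif_rand() - 0.5;
        for (int r = 0; r < 3; ++r)
            p0[r] = v2w(r, 0) * vox[0] + v2w(r, 1) * vox[1] +
                    v2w(r, 2) * vox[2] + v2w(r, 3);

        // initial direction ~ FOD amplitude over the sphere
        std::vector<double> cd(3 * n_init_cand), cw(n_init_cand);
        double tot = 0.0;
        for (int i = 0; i < n_init_cand; ++i) {
            const double z = 2.0 * unif_rand() - 1.0;
            const double phi = 2.0 * M_PI * unif_rand();
            const double s = std::sqrt(1.0 - z * z < 0 ? 0 : 1.0 - z * z);
            cd[3 * i] = s * std::cos(phi);
            cd[3 * i + 1] = s * std::sin(phi);
            cd[3 * i + 2] = z;
            const double a = f.amplitude(p0, &cd[3 * i], lmax, cbuf.data(),
                                         bbuf.data());
            cw[i] = a >= cutoff ? a : 0.0;
            tot += cw[i];
        }
        if (tot <= 0) { ++rej_init; continue; }
        const int ci = categorical(cw.data(), n_init_cand, tot);
        double d0[3] = {cd[3 * ci], cd[3 * ci + 1], cd[3 * ci + 2]};

        // a track still growing when it reaches the length cap is discarded
        bool over = false;
        fwd.clear();
        bwd.clear();
        for (int side = 0; side < 2 && !over; ++side) {
            std::vector<double> &pts = side == 0 ? fwd : bwd;
            double p[3] = {p0[0], p0[1], p0[2]};
            double d[3] = {side == 0 ? d0[0] : -d0[0],
                           side == 0 ? d0[1] : -d0[1],
                           side == 0 ? d0[2] : -d0[2]};
            for (;;) {
                if ((int)(fwd.size() + bwd.size()) / 3 + 1 >= max_pts) {
                    over = true;
                    break;
                }
                double cdir[3 * 16], wgt[16];
                double wtot = 0.0;
                const int nc2 = n_cand > 16 ? 16 : n_cand;
                for (int i = 0; i < nc2; ++i) {
                    cone_sample(d, max_angle, &cdir[3 * i]);
                    double mid[3], end[3];
                    for (int j = 0; j < 3; ++j) {
                        mid[j] = p[j] + 0.5 * step * cdir[3 * i + j];
                        end[j] = p[j] + step * cdir[3 * i + j];
                    }
                    const double am = f.amplitude(mid, &cdir[3 * i], lmax,
                                                  cbuf.data(), bbuf.data());
                    const double ae = am >= cutoff
                                          ? f.amplitude(end, &cdir[3 * i],
                                                        lmax, cbuf.data(),
                                                        bbuf.data())
                                          : -1.0;
                    wgt[i] = (am >= cutoff && ae >= cutoff) ? am * ae : 0.0;
                    wtot += wgt[i];
                }
                if (wtot <= 0) break;   // natural termination
                const int sel = categorical(wgt, nc2, wtot);
                for (int j = 0; j < 3; ++j) {
                    d[j] = cdir[3 * sel + j];
                    p[j] += step * d[j];
                }
                pts.push_back(p[0]);
                pts.push_back(p[1]);
                pts.push_back(p[2]);
            }
        }
        const int np = (int)(fwd.size() + bwd.size()) / 3 + 1;
        const double len = step * (np - 1);
        if (over || len > max_len) { ++rej_long; continue; }
        if (np < 2 || len < min_len) { ++rej_short; continue; }

        // assemble caudal-agnostic order: reversed backward, seed, forward
        NumericMatrix sl(np, 3);
        int r = 0;
        for (int i = (int)bwd.size() / 3 - 1; i >= 0; --i, ++r)
            for (int j = 0; j < 3; ++j) sl(r, j) = bwd[3 * i + j];
        for (int j = 0; j < 3; ++j) sl(r, j) = p0[j];
        ++r;
        for (int i = 0; i < (int)fwd.size() / 3; ++i, ++r)
            for (int j = 0; j < 3; ++j) sl(r, j) = fwd[3 * i + j];

        // inclusion: any point inside the include mask (nearest voxel)
        bool inc = false;
        for (int i = 0; i < np && !inc; ++i) {
            double pw[3] = {sl(i, 0), sl(i, 1), sl(i, 2)}, v[3];
            f.world2vox(pw, v);
            const int ix = (int)std::lround(v[0]), iy = (int)std::lround(v[1]),
                      iz = (int)std::lround(v[2]);
            if (ix >= 0 && ix < f.nx && iy >= 0 && iy < f.ny && iz >= 0 &&
                iz < f.nz &&
                include_mask[(R_xlen_t)ix + f.nx * ((R_xlen_t)iy +
                                                    (R_xlen_t)f.ny * iz)])
                inc = true;
        }
        if (!inc) { ++rej_include; continue; }

        out_sl[n_acc] = sl;
        out_seed[n_acc] = k + 1;
        ++n_acc;
    }

    if (n_acc < n_target) {
        out_sl = out_sl[Range(0, n_acc > 0 ? n_acc - 1 : 0)];
        if (n_acc == 0) out_sl = List(0);
    }
    return List::create(
        _["streamlines"] = out_sl, _["seed_index"] = out_seed,
        _["n_accepted"] = n_acc, _["attempts"] = (double)attempts,
        _["rejected"] = List::create(
            _["no_init_direction"] = (double)rej_init,
            _["too_short"] = (double)rej_short,
            _["too_long"] = (double)rej_long,
            _["no_inclusion"] = (double)rej_include));
}
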