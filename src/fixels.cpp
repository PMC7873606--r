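#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>

using namespace Rcpp;

// FOD lobe segmentation on a sphere mesh, batched over voxels.
//
// amps      : n_mesh x n_vox FOD amplitudes at the mesh vertices
// neighbors : n_mesh x max_degree 0-based vertex adjacency, -1 padded
// weights   : per-vertex quadrature weights (sum ~ 4*pi)
// dirs      : n_mesh x 3 unit vertex directions
// antipode  : 0-based index of each vertex's antipodal partner
// peak_frac : maxima below peak_frac * global max are merged into the
//             adjacent lobe with the strongest peak
// Every vertex with positive amplitude is assigned to a local maximum by
// steepest ascent along mesh edges; lobe FD = sum(w_v * A_v); antipodal
// lobe pairs are reported once with FD = (I + I_antipode) / 2.
// [[Rcpp::export(name = ".fixel_segment_cpp")]]
List fixel_segment_cpp(NumericMatrix amps, IntegerMatrix neighbors,
                       NumericVector weights, NumericMatrix dirs,
                       IntegerVector antipode, double peak_frac) {
    const int nm = amps.nrow(), nv = amps.ncol(), deg = neighbors.ncol();
    List out(nv);
    std::vector<int> root(nm);
    std::vector<double> integral(nm);

    for (int v = 0; v < nv; ++v) {
        const double *a = &amps(0, v);
        double gmax = 0.0;
        for (int i = 0; i < nm; ++i)
            if (a[i] > gmax) gmax = a[i];
        if (gmax <= 0) {
            out[v] = List::create(_["dir"] = NumericMatrix(0, 3),
                                  _["fd"] = NumericVector(0),
                                  _["peak"] = NumericVector(0));
            continue;
        }
        // steepest ascent assignment
        for (int i = 0; i < nm; ++i) {
            if (a[i] <= 0) { root[i] = -1; continue; }
            int best = i;
            double ba = a[i];
            for (int d = 0; d < deg; ++d) {
                const int nb = neighbors(i, d);
                if (nb < 0) break;
                if (a[nb] > ba) { ba = a[nb]; best = nb; }
            }
            root[i] = best;
        }
        for (int i = 0; i < nm; ++i) {
            if (root[i] < 0) continue;
            int r = i;
            int guard = 0;
            while (root[r] != r && guard++ < nm) r = root[r];
            root[i] = r;
        }
        // lobe integrals
        std::fill(integral.begin(), integral.end(), 0.0);
        for (int i = 0; i < nm; ++i)
            if (root[i] >= 0) integral[root[i]] += weights[i] * a[i];

        // merge sub-threshold maxima into adjacent lobes
        const double thr = peak_frac * gmax;
        bool merged = true;
        while (merged) {
            merged = false;
            int weakest = -1;
            for (int i = 0; i < nm; ++i)
                if (root[i] == i && a[i] < thr &&
                    (weakest < 0 || a[i] < a[weakest]))
                    weakest = i;
            if (weakest < 0) break;
            // adjacent lobe with the strongest peak
            int target = -1;
            for (int i = 0; i < nm; ++i) {
                if (root[i] != weakest) continue;
                for (int d = 0; d < deg; ++d) {
                    const int nb = neighbors(i, d);
                    if (nb < 0) break;
                    const int rn = root[nb];
                    if (rn >= 0 && rn != weakest &&
                        (target < 0 || a[rn] > a[target]))
                        target = rn;
                }
            }
            if (target >= 0) {
                for (int i = 0; i < nm; ++i)
                    if (root[i] == weakest) root[i] = target;
                integral[target] += integral[weakest];
                integral[weakest] = 0.0;
                merged = true;
            } else {
                // isolated noise lobe: drop it
                for (int i = 0; i < nm; ++i)
                    if (root[i] == weakest) root[i] = -1;
                integral[weakest] = 0.0;
                merged = true;
            }
        }

        // pair antipodal lobes; report each axis once with a sub-mesh
        // direction estimate: amplitude-weighted mean of the lobe-pair
        // vertices, sign-aligned with the peak vertex
        std::map<int, int> seen;   // root -> output slot
        std::vector<double> fd, peak;
        std::vector<int> peak_vtx, root_a, root_b;
        for (int i = 0; i < nm; ++i) {
            if (root[i] != i || integral[i] <= 0) continue;
            if (seen.count(i)) continue;
            const int av = antipode[i];
            int r2 = (av >= 0 && root[av] >= 0) ? root[av] : -1;
            double I = integral[i];
            int pv = i;
            if (r2 >= 0 && r2 != i) {
                I = 0.5 * (integral[i] + integral[r2]);
                if (a[r2] > a[i]) pv = r2;
                seen[r2] = 1;
            } else if (r2 == i) {
                I = 0.5 * integral[i];   // lobe spans both hemispheres
            }
            seen[i] = 1;
            fd.push_back(I);
            peak.push_back(a[pv]);
            peak_vtx.push_back(pv);
            root_a.push_back(i);
            root_b.push_back(r2);
        }
        const int k = (int)fd.size();
        NumericMatrix fdir(k, 3);
        NumericVector ffd(k), fpk(k);
        for (int j = 0; j < k; ++j) {
            const int pv = peak_vtx[j];
            double acc[3] = {0, 0, 0};
            for (int i = 0; i < nm; ++i) {
                if (root[i] != root_a[j] &&
                    !(root_b[j] >= 0 && root[i] == root_b[j]))
                    continue;
                double dp = 0;
                for (int c = 0; c < 3; ++c) dp += dirs(i, c) * dirs(pv, c);
                const double s = dp >= 0 ? 1.0 : -1.0;
                for (int c = 0; c < 3; ++c)
                    acc[c] += s * a[i] * weights[i] * dirs(i, c);
            }
            double nrm = std::sqrt(acc[0] * acc[0] + acc[1] * acc[1] +
                                   acc[2] * acc[2]);
            if (nrm < 1e-12) {
                for (int c = 0; c < 3; ++c) acc[c] = dirs(pv, c);
                nrm = 1.0;
            }
            for (int c = 0; c < 3; ++c) fdir(j, c) = acc[c] / nrm;
            ffd[j] = fd[j];
            fpk[j] = peak[j];
        }
        out[v] = List::create(_["dir"] = fdir, _["fd"] = ffd, _["peak"] = fpk);
    }
    return out;
}

// Tract fixel density: each streamline step (voxel, tangent) is assigned
// to the angularly nearest fixel in that voxel if within max_angle.
// step_vox    : 0-based linear voxel index per step (-1 = outside)
// tangents    : n_step x 3 unit tangents
// fix_offset  : length n_vox + 1; fixels of voxel v are rows
//               fix_offset[v] .. fix_offset[v+1]-1 (0-based) of fix_dirs
// [[Rcpp::export(name = ".fixel_tdi_cpp")]]
IntegerVector fixel_tdi_cpp(IntegerVector step_vox, NumericMatrix tangents,
                            IntegerVector fix_offset, NumericMatrix fix_dirs,
                            double max_angle) {
    const int ns = step_vox.size();
    const int nf = fix_dirs.nrow();
    IntegerVector counts(nf);
    const double cmin = std::cos(max_angle);
    for (int s = 0; s < ns; ++s) {
        const int v = step_vox[s];
        if (v < 0) continue;
        const int f0 = fix_offset[v], f1 = fix_offset[v + 1];
        int best = -1;
        double bc = cmin;
        for (int fidx = f0; fidx < f1; ++fidx) {
            double dp = 0.0;
            for (int c = 0; c < 3; ++c) dp += tangents(s, c) * fix_dirs(fidx, c);
            dp = std::fabs(dp);   // axes, not signed directions
            if (dp >= bc) { bc = dp; best = fidx; }
        }
        if (best >= 0) ++counts[best];
    }
    return counts;
}
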