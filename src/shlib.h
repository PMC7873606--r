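#ifndef TRACTFD_SHLIB_H
#define TRACTFD_SHLIB_H

#include <cmath>

// Real, symmetric (even-order) spherical-harmonic basis.
//
// Convention (documented in ?sh_basis and the fixel/FOD file sidecars):
//   * only even l = 0, 2, ..., lmax;
//   * within each l, m runs -l, ..., -1, 0, 1, ..., l;
//   * m = 0 : N_l0 P_l0(cos theta)
//     m > 0 : sqrt(2) N_lm P_lm(cos theta) cos(m phi)
//     m < 0 : sqrt(2) N_l|m| P_l|m|(cos theta) sin(|m| phi)
//   with N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and associated Legendre
//   functions WITHOUT the Condon-Shortley phase.
// Coefficient count: (lmax+1)(lmax+2)/2 (45 for lmax = 8).

namespace tractfd {

inline int sh_ncoef(int lmax) { return (lmax + 1) * (lmax + 2) / 2; }

// Evaluate the basis at unit direction (x, y, z); writes sh_ncoef(lmax)
// values into out.
inline void sh_eval(double x, double y, double z, int lmax, double *out) {
    const double r = std::sqrt(x * x + y * y + z * z);
    if (r > 0) { x /= r; y /= r; z /= r; }
    const double ct = z;                       // cos(theta)
    const double st2 = 1.0 - ct * ct;
    const double st = st2 > 0 ? std::sqrt(st2) : 0.0;
    const double phi = std::atan2(y, x);

    // associated Legendre P[l][m], no Condon-Shortley phase
    const int L = lmax;
    double P[32][32];
    P[0][0] = 1.0;
    for (int m = 1; m <= L; ++m)
        P[m][m] = P[m - 1][m - 1] * (2.0 * m - 1.0) * st;
    for (int m = 0; m < L; ++m)
        P[m + 1][m] = ct * (2.0 * m + 1.0) * P[m][m];
    for (int m = 0; m <= L; ++m)
        for (int l = m + 2; l <= L; ++l)
            P[l][m] = ((2.0 * l - 1.0) * ct * P[l - 1][m] -
                       (l + m - 1.0) * P[l - 2][m]) / (l - m);

    const double fourpi = 4.0 * M_PI;
    int j = 0;
    for (int l = 0; l <= L; l += 2) {
        for (int m = -l; m <= l; ++m) {
            const int am = m < 0 ? -m : m;
            // N_lm = sqrt((2l+1)/(4pi) * (l-am)!/(l+am)!)
            double ratio = 1.0;
            for (int k = l - am + 1; k <= l + am; ++k) ratio /= k;
            const double N = std::sqrt((2.0 * l + 1.0) / fourpi * ratio);
            double v = N * P[l][am];
            if (m > 0)      v *= std::sqrt(2.0) * std::cos(am * phi);
            else if (m < 0) v *= std::sqrt(2.0) * std::sin(am * phi);
            out[j++] = v;
        }
    }
}

} // namespace tractfd

#endif
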