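#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gaussian surrogate probability maps, computed and normalised in one
// pass. centers is 5x3 (world mm); output dim c(dims, 6), class 0 first.
// [[Rcpp::export]]
NumericVector c_surrogate_maps(IntegerVector dims, NumericVector spacing,
                               NumericVector origin, NumericMatrix direction,
                               NumericMatrix centers, double sigma2,
                               double background) {
    const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
    const R_xlen_t nvox = (R_xlen_t)n0 * n1 * n2;
    NumericVector out(nvox * 6);
    double* o = out.begin();
    double cx[5], cy[5], cz[5];
    for (int c = 0; c < 5; ++c) {
        cx[c] = centers(c, 0);
        cy[c] = centers(c, 1);
        cz[c] = centers(c, 2);
    }
    // world position advances by direction(,a)*spacing[a] per step of axis a
    double dxi[3], dxj[3], dxk[3];
    for (int r = 0; r < 3; ++r) {
        dxi[r] = direction(r, 0) * spacing[0];
        dxj[r] = direction(r, 1) * spacing[1];
        dxk[r] = direction(r, 2) * spacing[2];
    }
    const double inv2s2 = 1.0 / (2.0 * sigma2);
    R_xlen_t idx = 0;
    double s[6];
    for (int k = 0; k < n2; ++k) {
        for (int j = 0; j < n1; ++j) {
            double wx = origin[0] + dxj[0] * j + dxk[0] * k;
            double wy = origin[1] + dxj[1] * j + dxk[1] * k;
            double wz = origin[2] + dxj[2] * j + dxk[2] * k;
            for (int i = 0; i < n0; ++i, ++idx) {
                s[0] = background;
                double tot = background;
                for (int c = 0; c < 5; ++c) {
                    const double ddx = wx - cx[c], ddy = wy - cy[c],
                                 ddz = wz - cz[c];
                    const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                    s[c + 1] = std::exp(-d2 * inv2s2);
                    tot += s[c + 1];
                }
                for (int c = 0; c < 6; ++c)
                    o[idx + c * nvox] = s[c] / tot;
                wx += dxi[0];
                wy += dxi[1];
                wz += dxi[2];
            }
        }
    }
    out.attr("dim") = IntegerVector::create(n0, n1, n2, 6);
    return out;
}
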