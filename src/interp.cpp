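#include <Rcpp.h>
using namespace Rcpp;

// Mirror (reflect-without-repeat) index into [0, n-1]; period 2n-2.
static inline int mirror_index(int i, int n) {
    if (n == 1) return 0;
    const int period = 2 * n - 2;
    i %= period;
    if (i < 0) i += period;
    if (i >= n) i = period - i;
    return i;
}

// Catmull-Rom cubic convolution weights for fractional offset t in [0,1).
static inline void cr_weights(double t, double w[4]) {
    const double t2 = t * t, t3 = t2 * t;
    w[0] = -0.5 * t3 + t2 - 0.5 * t;
    w[1] =  1.5 * t3 - 2.5 * t2 + 1.0;
    w[2] = -1.5 * t3 + 2.0 * t2 + 0.5 * t;
    w[3] =  0.5 * t3 - 0.5 * t2;
}

static inline double sample_tricubic(const double* v, const int* dim,
                                     double x, double y, double z) {
    const int ix = (int)std::floor(x), iy = (int)std::floor(y),
              iz = (int)std::floor(z);
    double wx[4], wy[4], wz[4];
    cr_weights(x - ix, wx);
    cr_weights(y - iy, wy);
    cr_weights(z - iz, wz);
    int jx[4], jy[4], jz[4];
    for (int k = 0; k < 4; ++k) {
        jx[k] = mirror_index(ix - 1 + k, dim[0]);
        jy[k] = mirror_index(iy - 1 + k, dim[1]);
        jz[k] = mirror_index(iz - 1 + k, dim[2]);
    }
    const R_xlen_t sxy = (R_xlen_t)dim[0] * dim[1];
    double acc = 0.0;
    for (int c = 0; c < 4; ++c) {
        double accy = 0.0;
        const R_xlen_t offz = jz[c] * sxy;
        for (int b = 0; b < 4; ++b) {
            const R_xlen_t off = offz + (R_xlen_t)jy[b] * dim[0];
            double accx = 0.0;
            for (int a = 0; a < 4; ++a)
                accx += wx[a] * v[off + jx[a]];
            accy += wy[b] * accx;
        }
        acc += wz[c] * accy;
    }
    return acc;
}

// Sample a volume with tricubic (Catmull-Rom) interpolation at fractional
// 0-based voxel coordinates given as an n x 3 matrix.
// [[Rcpp::export]]
NumericVector c_interp_tricubic(NumericVector vol, IntegerVector dim,
                                NumericMatrix pts) {
    if (dim.size() != 3) stop("dim must have length 3");
    const int d[3] = {dim[0], dim[1], dim[2]};
    if ((R_xlen_t)d[0] * d[1] * d[2] != vol.size())
        stop("volume length does not match dim");
    const R_xlen_t n = pts.nrow();
    NumericVector out(n);
    const double* v = vol.begin();
    for (R_xlen_t i = 0; i < n; ++i)
        out[i] = sample_tricubic(v, d, pts(i, 0), pts(i, 1), pts(i, 2));
    return out;
}

// Resample onto a new voxel lattice: output voxel index j (0-based) is
// sampled at input fractional index A %*% j + b. A is 3x3, b length 3.
// [[Rcpp::export]]
NumericVector c_resample_affine(NumericVector vol, IntegerVector dim,
                                IntegerVector outdim, NumericMatrix A,
                                NumericVector b) {
    if (dim.size() != 3 || outdim.size() != 3)
        stop("dim and outdim must have length 3");
    const int d[3] = {dim[0], dim[1], dim[2]};
    if ((R_xlen_t)d[0] * d[1] * d[2] != vol.size())
        stop("volume length does not match dim");
    const int n0 = outdim[0], n1 = outdim[1], n2 = outdim[2];
    NumericVector out((R_xlen_t)n0 * n1 * n2);
    const double* v = vol.begin();
    double* o = out.begin();
    R_xlen_t idx = 0;
    for (int k = 0; k < n2; ++k) {
        for (int j = 0; j < n1; ++j) {
            const double bx = A(0, 1) * j + A(0, 2) * k + b[0];
            const double by = A(1, 1) * j + A(1, 2) * k + b[1];
            const double bz = A(2, 1) * j + A(2, 2) * k + b[2];
            for (int i = 0; i < n0; ++i, ++idx) {
                const double x = A(0, 0) * i + bx;
                const double y = A(1, 0) * i + by;
                const double z = A(2, 0) * i + bz;
                o[idx] = sample_tricubic(v, d, x, y, z);
            }
        }
    }
    out.attr("dim") = outdim;
    return out;
}
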