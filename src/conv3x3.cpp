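#include <Rcpp.h>
using namespace Rcpp;

// im2col for a 3x3 same-size convolution with zero padding on an
// [h, w, n, c] array: M[r, k*c + ch] = X(i+dy, j+dx, m, ch) for row
// r = (i, j, m), offset index k = kx * 3 + ky over (dx, dy) in
// {-1,0,1}^2 (dy fastest). The convolution itself is then a BLAS
// matrix product M %*% W.

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector X, int h, int w, int n, int c) {
    const int hwn = h * w * n;
    NumericMatrix M(hwn, 9 * c);
    double *mp = REAL(M);
    const double *x = REAL(X);
    for (int kx = 0; kx < 3; kx++) {
        const int dx = kx - 1;
        for (int ky = 0; ky < 3; ky++) {
            const int dy = ky - 1;
            const int k = kx * 3 + ky;
            for (int ch = 0; ch < c; ch++) {
                double *col = mp + (size_t)(k * c + ch) * hwn;
                const double *xc = x + (size_t)ch * hwn;
                for (int m = 0; m < n; m++) {
                    const int mOff = m * h * w;
                    for (int j = 0; j < w; j++) {
                        const int jj = j + dx;
                        double *dst = col + mOff + j * h;
                        if (jj < 0 || jj >= w) {
                            std::fill(dst, dst + h, 0.0);
                            continue;
                        }
                        const double *src = xc + mOff + jj * h;
                        const int lo = (dy < 0) ? -dy : 0;
                        const int hi = (dy > 0) ? h - dy : h;
                        if (lo > 0) std::fill(dst, dst + lo, 0.0);
                        for (int i = lo; i < hi; i++) dst[i] = src[i + dy];
                        if (hi < h) std::fill(dst + hi, dst + h, 0.0);
                    }
                }
            }
        }
    }
    return M;
}

// Scatter-add transpose of im2col3: folds dM [hwn, 9c] back onto the
// input array [h, w, n, c].
// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix dM, int h, int w, int n, int c) {
    const int hwn = h * w * n;
    NumericVector dX((size_t)hwn * c);
    double *dx = REAL(dX);
    const double *mp = REAL(dM);
    for (int kx = 0; kx < 3; kx++) {
        const int dx_ = kx - 1;
        for (int ky = 0; ky < 3; ky++) {
            const int dy = ky - 1;
            const int k = kx * 3 + ky;
            for (int ch = 0; ch < c; ch++) {
                const double *col = mp + (size_t)(k * c + ch) * hwn;
                double *xc = dx + (size_t)ch * hwn;
                for (int m = 0; m < n; m++) {
                    const int mOff = m * h * w;
                    for (int j = 0; j < w; j++) {
                        const int jj = j + dx_;
                        if (jj < 0 || jj >= w) continue;
                        const double *src = col + mOff + j * h;
                        double *dst = xc + mOff + jj * h;
                        const int lo = (dy < 0) ? -dy : 0;
                        const int hi = (dy > 0) ? h - dy : h;
                        for (int i = lo; i < hi; i++) dst[i + dy] += src[i];
                    }
                }
            }
        }
    }
    dX.attr("dim") = IntegerVector::create(h, w, n, c);
    return dX;
}

// Fused ReLU + 2x2 mean pooling: P = pool(max(Z, 0)) where Z is the
// [hwn, F] conv output over an [h, w, n] grid.
// [[Rcpp::export]]
NumericVector reluPool2(NumericMatrix Z, int h, int w, int n) {
    const int F = Z.ncol();
    const int h2 = h / 2, w2 = w / 2;
    NumericVector P((size_t)h2 * w2 * n * F);
    double *p = REAL(P);
    const double *z = REAL(Z);
    for (int f = 0; f < F; f++) {
        const double *zf = z + (size_t)f * h * w * n;
        double *pf = p + (size_t)f * h2 * w2 * n;
        for (int m = 0; m < n; m++) {
            for (int j = 0; j < w2; j++) {
                const double *c0 = zf + m * h * w + (2 * j) * h;
                const double *c1 = c0 + h;
                double *dst = pf + m * h2 * w2 + j * h2;
                for (int i = 0; i < h2; i++) {
                    const double a = std::max(c0[2 * i], 0.0);
                    const double b = std::max(c0[2 * i + 1], 0.0);
                    const double cc = std::max(c1[2 * i], 0.0);
                    const double d = std::max(c1[2 * i + 1], 0.0);
                    dst[i] = (a + b + cc + d) * 0.25;
                }
            }
        }
    }
    P.attr("dim") = IntegerVector::create(h2, w2, n, F);
    return P;
}

// Backward of the fused ReLU + mean pool: spreads dP / 4 to positions
// where Z > 0.
// [[Rcpp::export]]
NumericMatrix reluPool2Bwd(NumericVector dP, NumericMatrix Z, int h, int w,
                           int n) {
    const int F = Z.ncol();
    const int h2 = h / 2, w2 = w / 2;
    NumericMatrix dZ((size_t)h * w * n, F);
    double *dz = REAL(dZ);
    const double *z = REAL(Z);
    const double *dp = REAL(dP);
    for (int f = 0; f < F; f++) {
        const double *zf = z + (size_t)f * h * w * n;
        double *dzf = dz + (size_t)f * h * w * n;
        const double *dpf = dp + (size_t)f * h2 * w2 * n;
        for (int m = 0; m < n; m++) {
            for (int j = 0; j < w2; j++) {
                const double *src = dpf + m * h2 * w2 + j * h2;
                double *c0 = dzf + m * h * w + (2 * j) * h;
                double *c1 = c0 + h;
                const double *z0 = zf + m * h * w + (2 * j) * h;
                const double *z1 = z0 + h;
                for (int i = 0; i < h2; i++) {
                    const double g = src[i] * 0.25;
                    if (z0[2 * i] > 0) c0[2 * i] += g;
                    if (z0[2 * i + 1] > 0) c0[2 * i + 1] += g;
                    if (z1[2 * i] > 0) c1[2 * i] += g;
                    if (z1[2 * i + 1] > 0) c1[2 * i + 1] += g;
                }
            }
        }
    }
    return dZ;
}
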