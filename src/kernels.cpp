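#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// 0 outside the grid: out-of-field fill value for all geometric ops
static inline double getvox(const double* a, const int* d, int i, int j, int k) {
    if (i < 0 || j < 0 || k < 0 || i >= d[0] || j >= d[1] || k >= d[2]) return 0.0;
    return a[i + (R_xlen_t)d[0] * (j + (R_xlen_t)d[1] * k)];
}

// Pull-resample a 3D volume. M maps 0-based target voxel indices to 0-based
// source voxel indices (M = solve(src_affine) %*% target_affine).
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector src_dim,
                                  NumericMatrix M, IntegerVector out_dim,
                                  bool linear) {
    int d[3] = {src_dim[0], src_dim[1], src_dim[2]};
    const double* s = REAL(src);
    int n0 = out_dim[0], n1 = out_dim[1], n2 = out_dim[2];
    NumericVector out((R_xlen_t)n0 * n1 * n2);
    double* o = REAL(out);
    double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
    double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
    double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
    R_xlen_t idx = 0;
    for (int k = 0; k < n2; ++k) {
        for (int j = 0; j < n1; ++j) {
            double xj = m01*j + m02*k + m03;
            double yj = m11*j + m12*k + m13;
            double zj = m21*j + m22*k + m23;
            for (int i = 0; i < n0; ++i, ++idx) {
                double x = m00*i + xj, y = m10*i + yj, z = m20*i + zj;
                if (linear) {
                    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                        z0 = (int)std::floor(z);
                    double fx = x - x0, fy = y - y0, fz = z - z0;
                    double v = 0.0;
                    for (int dz = 0; dz < 2; ++dz)
                        for (int dy = 0; dy < 2; ++dy)
                            for (int dx = 0; dx < 2; ++dx) {
                                double w = (dx ? fx : 1.0 - fx) *
                                           (dy ? fy : 1.0 - fy) *
                                           (dz ? fz : 1.0 - fz);
                                if (w != 0.0)
                                    v += w * getvox(s, d, x0 + dx, y0 + dy, z0 + dz);
                            }
                    o[idx] = v;
                } else {
                    int xi = (int)std::floor(x + 0.5);
                    int yi = (int)std::floor(y + 0.5);
                    int zi = (int)std::floor(z + 0.5);
                    o[idx] = getvox(s, d, xi, yi, zi);
                }
            }
        }
    }
    return out;
}

// Translate every axial slice k in-plane by (dx[k], dy[k]) voxels:
// out(i,j,k) = src(i + dx[k], j + dy[k], k), zero fill outside.
// [[Rcpp::export]]
NumericVector shift_slices_cpp(NumericVector src, IntegerVector dims,
                               NumericVector dx, NumericVector dy, bool linear) {
    int d[3] = {dims[0], dims[1], dims[2]};
    const double* s = REAL(src);
    NumericVector out((R_xlen_t)d[0] * d[1] * d[2]);
    double* o = REAL(out);
    R_xlen_t idx = 0;
    for (int k = 0; k < d[2]; ++k) {
        double ddx = dx[k], ddy = dy[k];
        for (int j = 0; j < d[1]; ++j) {
            for (int i = 0; i < d[0]; ++i, ++idx) {
                double x = i + ddx, y = j + ddy;
                if (linear) {
                    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
                    double fx = x - x0, fy = y - y0;
                    double v = 0.0;
                    for (int b = 0; b < 2; ++b)
                        for (int a = 0; a < 2; ++a) {
                            double w = (a ? fx : 1.0 - fx) * (b ? fy : 1.0 - fy);
                            if (w != 0.0)
                                v += w * getvox(s, d, x0 + a, y0 + b, k);
                        }
                    o[idx] = v;
                } else {
                    int xi = (int)std::floor(x + 0.5);
                    int yi = (int)std::floor(y + 0.5);
                    o[idx] = getvox(s, d, xi, yi, k);
                }
            }
        }
    }
    return out;
}

// 3D connected components by breadth-first search under 6/18/26-connectivity.
// Labels are dense 1..n in first-encounter (column-major) order.
// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
    int d0 = dims[0], d1 = dims[1], d2 = dims[2];
    R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
    IntegerVector lab(n);
    std::vector<int> ndi, ndj, ndk;
    for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
                int m = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (m == 0) continue;
                if ((connectivity == 6 && m > 1) ||
                    (connectivity == 18 && m > 2)) continue;
                ndi.push_back(di); ndj.push_back(dj); ndk.push_back(dk);
            }
    int nb = (int)ndi.size();
    int next = 0;
    std::queue<R_xlen_t> q;
    for (R_xlen_t p = 0; p < n; ++p) {
        if (mask[p] == 0 || lab[p] != 0) continue;
        lab[p] = ++next;
        q.push(p);
        while (!q.empty()) {
            R_xlen_t c = q.front(); q.pop();
            int ci = (int)(c % d0);
            int cj = (int)((c / d0) % d1);
            int ck = (int)(c / ((R_xlen_t)d0 * d1));
            for (int t = 0; t < nb; ++t) {
                int i = ci + ndi[t], j = cj + ndj[t], k = ck + ndk[t];
                if (i < 0 || j < 0 || k < 0 || i >= d0 || j >= d1 || k >= d2)
                    continue;
                R_xlen_t p2 = i + (R_xlen_t)d0 * (j + (R_xlen_t)d1 * k);
                if (mask[p2] != 0 && lab[p2] == 0) {
                    lab[p2] = next;
                    q.push(p2);
                }
            }
        }
    }
    return lab;
}

// For each row of A (points, n x 3), the Euclidean distance to the nearest
// row of B. Empty B gives Inf.
// [[Rcpp::export]]
NumericVector nn_min_dist_cpp(NumericMatrix A, NumericMatrix B) {
    int na = A.nrow(), nb = B.nrow();
    NumericVector out(na);
    for (int i = 0; i < na; ++i) {
        double best = R_PosInf;
        double ax = A(i,0), ay = A(i,1), az = A(i,2);
        for (int j = 0; j < nb; ++j) {
            double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
            double d2 = dx*dx + dy*dy + dz*dz;
            if (d2 < best) best = d2;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}
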