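#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1-D squared distance transform along one line (Felzenszwalb & Huttenlocher,
// lower envelope of parabolas). f holds squared distances on entry (Inf where
// no site yet); w2 is the squared voxel spacing along this axis. Exact for
// weighted squared distances.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& site, std::vector<int>& v,
                 std::vector<double>& z, int n, double w2) {
    const double INF = std::numeric_limits<double>::infinity();
    int m = 0; // finite parabola sites, in increasing position
    for (int q = 0; q < n; ++q)
        if (f[q] < INF) site[m++] = q;
    if (m == 0) {
        for (int q = 0; q < n; ++q) d[q] = INF;
        return;
    }
    int k = 0;
    v[0] = site[0];
    z[0] = -INF;
    z[1] = INF;
    for (int s = 1; s < m; ++s) {
        int q = site[s];
        double fq = f[q] + w2 * (double)q * q;
        double sep;
        while (true) {
            int p = v[k];
            sep = (fq - (f[p] + w2 * (double)p * p)) / (2.0 * w2 * (q - p));
            if (sep <= z[k] && k > 0) --k; else break;
        }
        ++k;
        v[k] = q;
        z[k] = sep;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < (double)q) ++k;
        int p = v[k];
        d[q] = w2 * (double)(q - p) * (double)(q - p) + f[p];
    }
}

// Exact squared Euclidean distance transform of a 3-D zero set.
// zero_set: logical 3-D array (TRUE = distance 0); spacing: mm per voxel axis.
// Returns squared distances in mm^2 (all Inf if the zero set is empty).
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector zero_set, NumericVector spacing) {
    IntegerVector dims = zero_set.attr("dim");
    if (dims.size() != 3) stop("zero_set must be a 3-D array");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double INF = std::numeric_limits<double>::infinity();
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = zero_set[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax), site(nmax);

    const double w2x = spacing[0] * spacing[0];
    const double w2y = spacing[1] * spacing[1];
    const double w2z = spacing[2] * spacing[2];

    // pass along x (fastest-varying index)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, site, v, z, nx, w2x);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, site, v, z, ny, w2y);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
            dt1d(f, d, site, v, z, nz, w2z);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
        }

    out.attr("dim") = dims;
    return out;
}
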