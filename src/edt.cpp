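#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform, separable lower-envelope
// algorithm (Felzenszwalb & Huttenlocher 2012) applied along each axis of a
// grid padded with one layer of background, so the image border counts as
// background everywhere in the package.

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
    static const double INF = std::numeric_limits<double>::infinity();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = -1;
    for (int q = 0; q < n; q++) {
        if (f[q] == INF) continue; // infinite parabolas are never part of the envelope
        double s = 0.0;
        while (k >= 0) {
            s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
                (2.0 * q - 2.0 * v[k]);
            if (s <= z[k]) k--; else break;
        }
        if (k < 0) { k = 0; v[0] = q; z[0] = -INF; }
        else { k++; v[k] = q; z[k] = s; }
        z[k + 1] = INF;
    }
    if (k < 0) { // no finite site on this line
        for (int q = 0; q < n; q++) d[q] = INF;
        return;
    }
    k = 0;
    for (int q = 0; q < n; q++) {
        while (z[k + 1] < q) k++;
        d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector fg, IntegerVector dims) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const int pz = nz + 2, py = ny + 2, px = nx + 2;
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> g((size_t)pz * py * px, 0.0);
    // padded layout: index = z + pz*(y + py*x); pad ring stays 0 (background)
    for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
            for (int z = 0; z < nz; z++) {
                size_t src = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
                size_t dst = (size_t)(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1));
                g[dst] = fg[src] ? INF : 0.0;
            }
    std::vector<double> f(std::max(std::max(pz, py), px)), d(f.size());
    // pass along z
    for (int x = 0; x < px; x++)
        for (int y = 0; y < py; y++) {
            size_t base = (size_t)pz * (y + (size_t)py * x);
            for (int z = 0; z < pz; z++) f[z] = g[base + z];
            dt1d(f, d, pz);
            for (int z = 0; z < pz; z++) g[base + z] = d[z];
        }
    // pass along y
    for (int x = 0; x < px; x++)
        for (int z = 0; z < pz; z++) {
            for (int y = 0; y < py; y++) f[y] = g[(size_t)z + (size_t)pz * (y + (size_t)py * x)];
            dt1d(f, d, py);
            for (int y = 0; y < py; y++) g[(size_t)z + (size_t)pz * (y + (size_t)py * x)] = d[y];
        }
    // pass along x
    for (int y = 0; y < py; y++)
        for (int z = 0; z < pz; z++) {
            for (int x = 0; x < px; x++) f[x] = g[(size_t)z + (size_t)pz * (y + (size_t)py * x)];
            dt1d(f, d, px);
            for (int x = 0; x < px; x++) g[(size_t)z + (size_t)pz * (y + (size_t)py * x)] = d[x];
        }
    NumericVector out((size_t)nz * ny * nx);
    for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
            for (int z = 0; z < nz; z++) {
                size_t src = (size_t)(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1));
                size_t dst = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
                out[dst] = std::sqrt(g[src]);
            }
    return out;
}
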