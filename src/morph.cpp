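#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3D median filter over a ball-shaped neighbourhood and grayscale 3x3x3
// morphology used by the distance-ridge seeder. Out-of-grid samples are
// simply omitted from the median; for erosion they count as 0 (the package's
// border-is-background convention, which matters on distance maps).

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericVector median_filter_cpp(NumericVector vol, IntegerVector dims, int radius) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    if (radius <= 0) return clone(vol);
    std::vector<int> off;
    for (int dx = -radius; dx <= radius; dx++)
        for (int dy = -radius; dy <= radius; dy++)
            for (int dz = -radius; dz <= radius; dz++)
                if (dz * dz + dy * dy + dx * dx <= radius * radius) {
                    off.push_back(dz); off.push_back(dy); off.push_back(dx);
                }
    const int nb = (int)off.size() / 3;
    NumericVector out((size_t)nz * ny * nx);
    std::vector<double> buf(nb);
    for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
            for (int z = 0; z < nz; z++) {
                int m = 0;
                for (int k = 0; k < nb; k++) {
                    int zz = z + off[3 * k], yy = y + off[3 * k + 1], xx = x + off[3 * k + 2];
                    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
                    buf[m++] = vol[(size_t)zz + (size_t)nz * (yy + (size_t)ny * xx)];
                }
                std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
                double med = buf[m / 2];
                if (m % 2 == 0) {
                    double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
                    med = 0.5 * (med + lo);
                }
                out[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] = med;
            }
    return out;
}

// flat 3x3x3 grayscale erosion (op = 0) or dilation (op = 1)
// [[Rcpp::export(name = ".gray_morph3_cpp")]]
NumericVector gray_morph3_cpp(NumericVector vol, IntegerVector dims, int op) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    NumericVector out((size_t)nz * ny * nx);
    for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
            for (int z = 0; z < nz; z++) {
                double acc = op ? R_NegInf : R_PosInf;
                for (int dx = -1; dx <= 1; dx++)
                    for (int dy = -1; dy <= 1; dy++)
                        for (int dz = -1; dz <= 1; dz++) {
                            int zz = z + dz, yy = y + dy, xx = x + dx;
                            double v;
                            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                                v = 0.0; // outside grid: background value
                            else
                                v = vol[(size_t)zz + (size_t)nz * (yy + (size_t)ny * xx)];
                            if (op) { if (v > acc) acc = v; } else { if (v < acc) acc = v; }
                        }
                out[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] = acc;
            }
    return out;
}
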