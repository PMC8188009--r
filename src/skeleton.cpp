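#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Topology-preserving 3D thinning. A foreground voxel is "simple" (deletable
// without changing topology) when both topological numbers of Bertrand &
// Malandain are 1: one 26-connected foreground component in the punctured
// 26-neighbourhood, and one 6-connected background component in the
// 18-neighbourhood touching a face neighbour. Border voxels are deleted
// sequentially in order of increasing distance-transform value, which keeps
// the surviving curve medial; voxels with at most one foreground neighbour
// (curve endpoints) are retained.

static inline int idx3(int z, int y, int x, int nz, int ny) {
    return z + nz * (y + ny * x);
}

// extract 3x3x3 neighbourhood into nb[27], index = (dz+1) + 3*(dy+1) + 9*(dx+1)
static void neighbourhood(const int* fg, int z, int y, int x,
                          int nz, int ny, int nx, int* nb) {
    int k = 0;
    for (int dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++)
            for (int dz = -1; dz <= 1; dz++) {
                int zz = z + dz, yy = y + dy, xx = x + dx;
                // note loop order must match index formula below
                int i = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
                    nb[i] = 0;
                else
                    nb[i] = fg[idx3(zz, yy, xx, nz, ny)];
                k++;
            }
}

static inline void unpack(int i, int& dz, int& dy, int& dx) {
    dz = i % 3 - 1; dy = (i / 3) % 3 - 1; dx = i / 9 - 1;
}

// number of 26-connected foreground components in N26(p) (centre excluded)
static int t26_object(const int* nb) {
    bool seen[27] = {false};
    int ncomp = 0;
    for (int s = 0; s < 27; s++) {
        if (s == 13 || !nb[s] || seen[s]) continue;
        ncomp++;
        int stack[27], top = 0;
        stack[top++] = s; seen[s] = true;
        while (top) {
            int c = stack[--top];
            int cz, cy, cx; unpack(c, cz, cy, cx);
            for (int t = 0; t < 27; t++) {
                if (t == 13 || !nb[t] || seen[t]) continue;
                int tz, ty, tx; unpack(t, tz, ty, tx);
                if (std::abs(tz - cz) <= 1 && std::abs(ty - cy) <= 1 && std::abs(tx - cx) <= 1) {
                    seen[t] = true; stack[top++] = t;
                }
            }
        }
    }
    return ncomp;
}

// number of 6-connected background components of N18(p) that touch a face
// neighbour of p
static int t6_background(const int* nb) {
    bool in18[27] = {false};
    for (int s = 0; s < 27; s++) {
        int dz, dy, dx; unpack(s, dz, dy, dx);
        int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (m == 1 || m == 2) in18[s] = true;
    }
    bool seen[27] = {false};
    int ncomp = 0;
    for (int s = 0; s < 27; s++) {
        if (!in18[s] || nb[s] || seen[s]) continue;
        int dz0, dy0, dx0; unpack(s, dz0, dy0, dx0);
        if (std::abs(dz0) + std::abs(dy0) + std::abs(dx0) != 1) continue; // grow only from face neighbours
        ncomp++;
        int stack[27], top = 0;
        stack[top++] = s; seen[s] = true;
        while (top) {
            int c = stack[--top];
            int cz, cy, cx; unpack(c, cz, cy, cx);
            for (int t = 0; t < 27; t++) {
                if (!in18[t] || nb[t] || seen[t]) continue;
                int tz, ty, tx; unpack(t, tz, ty, tx);
                if (std::abs(tz - cz) + std::abs(ty - cy) + std::abs(tx - cx) == 1) {
                    seen[t] = true; stack[top++] = t;
                }
            }
        }
    }
    return ncomp;
}

static bool is_simple(const int* nb) {
    return t26_object(nb) == 1 && t6_background(nb) == 1;
}

static int n26_count(const int* nb) {
    int n = 0;
    for (int s = 0; s < 27; s++) if (s != 13 && nb[s]) n++;
    return n;
}

// [[Rcpp::export(name = ".skeletonize_cpp")]]
LogicalVector skeletonize_cpp(LogicalVector fgv, IntegerVector dims, NumericVector edt) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const size_t n = (size_t)nz * ny * nx;
    std::vector<int> fg(n);
    for (size_t i = 0; i < n; i++) fg[i] = fgv[i] ? 1 : 0;
    static const int fdz[6] = {1, -1, 0, 0, 0, 0};
    static const int fdy[6] = {0, 0, 1, -1, 0, 0};
    static const int fdx[6] = {0, 0, 0, 0, 1, -1};
    int nb[27];
    bool changed = true;
    std::vector<std::pair<double, int> > cand;
    while (changed) {
        changed = false;
        cand.clear();
        for (int x = 0; x < nx; x++)
            for (int y = 0; y < ny; y++)
                for (int z = 0; z < nz; z++) {
                    int i = idx3(z, y, x, nz, ny);
                    if (!fg[i]) continue;
                    bool border = false;
                    for (int f = 0; f < 6; f++) {
                        int zz = z + fdz[f], yy = y + fdy[f], xx = x + fdx[f];
                        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx ||
                            !fg[idx3(zz, yy, xx, nz, ny)]) { border = true; break; }
                    }
                    if (border) cand.push_back(std::make_pair(edt[i], i));
                }
        std::sort(cand.begin(), cand.end());
        for (size_t k = 0; k < cand.size(); k++) {
            int i = cand[k].second;
            if (!fg[i]) continue;
            int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
            neighbourhood(fg.data(), z, y, x, nz, ny, nx, nb);
            if (n26_count(nb) <= 1) continue; // endpoint, keep
            if (is_simple(nb)) { fg[i] = 0; changed = true; }
        }
    }
    LogicalVector out(n);
    for (size_t i = 0; i < n; i++) out[i] = fg[i] != 0;
    return out;
}
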