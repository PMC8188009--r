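#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on the (optionally
// block-resampled) scalar field, padded with one layer of background so the
// mesh is closed. Each grid cube is split into six tetrahedra around its
// main diagonal — a conforming decomposition, so shared cube faces carry the
// same diagonal and the welded mesh is watertight. Iso-vertices are linear
// interpolations along tetrahedron edges and are deduplicated by their
// global (node, node) edge key. Triangle winding is fixed geometrically so
// face normals point out of the foreground.

struct MeshAcc {
    std::vector<double> V;          // x3: z, y, x
    std::vector<int> F;             // x3: 0-based vertex ids
    std::unordered_map<uint64_t, int> edge_vertex;
};

static int edge_vert(MeshAcc& m, uint64_t ga, uint64_t gb,
                     const double* pa, const double* pb, double va, double vb) {
    uint64_t key = (ga < gb) ? (ga << 32 | gb) : (gb << 32 | ga);
    std::unordered_map<uint64_t, int>::iterator it = m.edge_vertex.find(key);
    if (it != m.edge_vertex.end()) return it->second;
    double t = va / (va - vb); // va, vb have opposite signs
    int id = (int)(m.V.size() / 3);
    for (int i = 0; i < 3; i++) m.V.push_back(pa[i] + t * (pb[i] - pa[i]));
    m.edge_vertex[key] = id;
    return id;
}

static void add_tri(MeshAcc& m, int a, int b, int c, const double* ref_in) {
    // orient so the normal points away from ref_in (an interior point)
    const double* p0 = &m.V[3 * a];
    const double* p1 = &m.V[3 * b];
    const double* p2 = &m.V[3 * c];
    double e1[3], e2[3], n[3], d[3];
    for (int i = 0; i < 3; i++) { e1[i] = p1[i] - p0[i]; e2[i] = p2[i] - p0[i]; }
    n[0] = e1[1] * e2[2] - e1[2] * e2[1];
    n[1] = e1[2] * e2[0] - e1[0] * e2[2];
    n[2] = e1[0] * e2[1] - e1[1] * e2[0];
    for (int i = 0; i < 3; i++) d[i] = (p0[i] + p1[i] + p2[i]) / 3.0 - ref_in[i];
    double dp = n[0] * d[0] + n[1] * d[1] + n[2] * d[2];
    if (dp < 0) { int t = b; b = c; c = t; }
    m.F.push_back(a); m.F.push_back(b); m.F.push_back(c);
}

// [[Rcpp::export(name = ".march_tets_cpp")]]
List march_tets_cpp(NumericVector field, IntegerVector dims, double iso) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const int pz = nz + 2, py = ny + 2, px = nx + 2;
    std::vector<double> f((size_t)pz * py * px, 0.0);
    for (int x = 0; x < nx; x++)
        for (int y = 0; y < ny; y++)
            for (int z = 0; z < nz; z++)
                f[(size_t)(z + 1) + (size_t)pz * ((y + 1) + (size_t)py * (x + 1))] =
                    field[(size_t)z + (size_t)nz * (y + (size_t)ny * x)];
    MeshAcc m;
    // six tetrahedra {0, e[k], e[k+1], 7} cycling edge corners around the
    // main diagonal 0 -> 7; corner bits: 1 = +z, 2 = +y, 4 = +x
    static const int cyc[7] = {1, 3, 2, 6, 4, 5, 1};
    double pos[8][3];
    double val[8];
    uint64_t gid[8];
    for (int x = 0; x < px - 1; x++)
        for (int y = 0; y < py - 1; y++)
            for (int z = 0; z < pz - 1; z++) {
                bool any_in = false, any_out = false;
                for (int b = 0; b < 8; b++) {
                    int dz = b & 1, dy = (b >> 1) & 1, dx = (b >> 2) & 1;
                    int zz = z + dz, yy = y + dy, xx = x + dx;
                    val[b] = f[(size_t)zz + (size_t)pz * (yy + (size_t)py * xx)] - iso;
                    pos[b][0] = zz - 1.0; pos[b][1] = yy - 1.0; pos[b][2] = xx - 1.0;
                    gid[b] = (uint64_t)zz + (uint64_t)pz * (yy + (uint64_t)py * xx);
                    if (val[b] > 0) any_in = true; else any_out = true;
                }
                if (!any_in || !any_out) continue;
                for (int k = 0; k < 6; k++) {
                    int t[4] = {0, cyc[k], cyc[k + 1], 7};
                    int ins[4], outs[4], ni = 0, no = 0;
                    for (int q = 0; q < 4; q++) {
                        if (val[t[q]] > 0) ins[ni++] = t[q]; else outs[no++] = t[q];
                    }
                    if (ni == 0 || ni == 4) continue;
                    if (ni == 1) {
                        int a = ins[0];
                        int v0 = edge_vert(m, gid[a], gid[outs[0]], pos[a], pos[outs[0]], val[a], val[outs[0]]);
                        int v1 = edge_vert(m, gid[a], gid[outs[1]], pos[a], pos[outs[1]], val[a], val[outs[1]]);
                        int v2 = edge_vert(m, gid[a], gid[outs[2]], pos[a], pos[outs[2]], val[a], val[outs[2]]);
                        add_tri(m, v0, v1, v2, pos[a]);
                    } else if (ni == 3) {
                        int a = outs[0];
                        int v0 = edge_vert(m, gid[ins[0]], gid[a], pos[ins[0]], pos[a], val[ins[0]], val[a]);
                        int v1 = edge_vert(m, gid[ins[1]], gid[a], pos[ins[1]], pos[a], val[ins[1]], val[a]);
                        int v2 = edge_vert(m, gid[ins[2]], gid[a], pos[ins[2]], pos[a], val[ins[2]], val[a]);
                        double ref[3];
                        for (int i = 0; i < 3; i++)
                            ref[i] = (pos[ins[0]][i] + pos[ins[1]][i] + pos[ins[2]][i]) / 3.0;
                        add_tri(m, v0, v1, v2, ref);
                    } else { // ni == 2
                        int a = ins[0], b = ins[1], cth = outs[0], d = outs[1];
                        int q0 = edge_vert(m, gid[a], gid[cth], pos[a], pos[cth], val[a], val[cth]);
                        int q1 = edge_vert(m, gid[a], gid[d], pos[a], pos[d], val[a], val[d]);
                        int q2 = edge_vert(m, gid[b], gid[d], pos[b], pos[d], val[b], val[d]);
                        int q3 = edge_vert(m, gid[b], gid[cth], pos[b], pos[cth], val[b], val[cth]);
                        double ref[3];
                        for (int i = 0; i < 3; i++) ref[i] = 0.5 * (pos[a][i] + pos[b][i]);
                        add_tri(m, q0, q1, q2, ref);
                        add_tri(m, q0, q2, q3, ref);
                    }
                }
            }
    const int nv = (int)(m.V.size() / 3), nf = (int)(m.F.size() / 3);
    NumericMatrix V(nv, 3);
    IntegerMatrix F(nf, 3);
    for (int i = 0; i < nv; i++)
        for (int j = 0; j < 3; j++) V(i, j) = m.V[3 * i + j];
    for (int i = 0; i < nf; i++)
        for (int j = 0; j < 3; j++) F(i, j) = m.F[3 * i + j] + 1; // 1-based for R
    return List::create(_["vertices"] = V, _["triangles"] = F);
}

// one or more passes of umbrella Laplacian smoothing with relaxation factor
// lambda over the unique vertex adjacency; vertices flagged in `fixed` are
// pinned (used for vertices on the image bounding box, so smoothing does not
// round the junction between the surface proper and its artificial caps)
// [[Rcpp::export(name = ".smooth_mesh_cpp")]]
NumericMatrix smooth_mesh_cpp(NumericMatrix V, IntegerMatrix F, double lambda, int iters,
                              LogicalVector fixed) {
    const int nv = V.nrow(), nf = F.nrow();
    std::vector<std::vector<int> > adj(nv);
    for (int i = 0; i < nf; i++) {
        int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
        int e[6] = {a, b, b, c, c, a};
        for (int k = 0; k < 3; k++) {
            int u = e[2 * k], w = e[2 * k + 1];
            adj[u].push_back(w);
            adj[w].push_back(u);
        }
    }
    for (int i = 0; i < nv; i++) {
        std::sort(adj[i].begin(), adj[i].end());
        adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
    }
    NumericMatrix cur = clone(V);
    for (int it = 0; it < iters; it++) {
        NumericMatrix nxt(nv, 3);
        for (int i = 0; i < nv; i++) {
            if (adj[i].empty() || (fixed.size() == nv && fixed[i])) {
                for (int j = 0; j < 3; j++) nxt(i, j) = cur(i, j);
                continue;
            }
            for (int j = 0; j < 3; j++) {
                double s = 0.0;
                for (size_t k = 0; k < adj[i].size(); k++) s += cur(adj[i][k], j);
                s /= adj[i].size();
                nxt(i, j) = cur(i, j) + lambda * (s - cur(i, j));
            }
        }
        cur = nxt;
    }
    return cur;
}
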