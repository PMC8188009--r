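#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Stochastic fitting of locally maximal ellipsoids. An ellipsoid seeded as a
// small sphere grows by a fixed increment until surface sample points hit
// background ("contact sensitivity" hits register a collision); the mean
// contact vector defines the first semi-axis, growth then continues in the
// orthogonal plane, and a hill-climbing phase of small random rotations and
// translations coupled with in-plane growth looks for a larger ellipsoid.
// All randomness comes from R's RNG so runs are reproducible via set.seed().
//
// Coordinates are continuous (z, y, x) with voxel centres at integers,
// 0-based; a sample point lies in the voxel obtained by rounding, and
// anything outside the grid is background.

struct Ell {
    double c[3];   // centre (z, y, x)
    double r[3];   // semi-axis lengths, axis 0 = first-contact axis
    double A[9];   // column j = direction of axis j; A[3*j + i] = component i
};

struct Grid {
    const int* fg;
    int nz, ny, nx;
    inline bool background(double pz, double py, double px) const {
        int z = (int)std::lround(pz), y = (int)std::lround(py), x = (int)std::lround(px);
        if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return true;
        return fg[(size_t)z + (size_t)nz * (y + (size_t)ny * x)] == 0;
    }
    inline bool outside(double pz, double py, double px) const {
        int z = (int)std::lround(pz), y = (int)std::lround(py), x = (int)std::lround(px);
        return z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx;
    }
};

static void unit_sphere_dir(double* u) {
    double n2 = 0.0;
    do {
        n2 = 0.0;
        for (int i = 0; i < 3; i++) { u[i] = norm_rand(); n2 += u[i] * u[i]; }
    } while (n2 < 1e-12);
    double inv = 1.0 / std::sqrt(n2);
    for (int i = 0; i < 3; i++) u[i] *= inv;
}

// direction on the unit sphere, area-weighted for the map onto the ellipsoid
// surface (rejection against the surface-element Jacobian), so the mapped
// points are uniform with respect to ellipsoid surface area
static void ellipsoid_dir(const double* r, double* u) {
    const double p01 = r[0] * r[1], p02 = r[0] * r[2], p12 = r[1] * r[2];
    const double gmax = std::max(p01, std::max(p02, p12));
    while (true) {
        unit_sphere_dir(u);
        double g = std::sqrt(p12 * p12 * u[0] * u[0] + p02 * p02 * u[1] * u[1] +
                             p01 * p01 * u[2] * u[2]);
        if (unif_rand() * gmax <= g) return;
    }
}

static inline void surface_point(const Ell& e, const double* u, double* p) {
    for (int i = 0; i < 3; i++) {
        p[i] = e.c[i];
        for (int j = 0; j < 3; j++) p[i] += e.A[3 * j + i] * e.r[j] * u[j];
    }
}

struct Contacts {
    int hits;
    double mean[3]; // mean of (contact point - centre)
};

// samples up to nvec surface points but stops as soon as `cs` of them hit
// background: a collision is "cs points hit", and the contact vector is the
// mean over exactly those first cs hits. Stopping early matters: averaging
// hits from both faces of a thin symmetric plate would cancel to a
// meaningless near-zero vector.
static Contacts detect(const Ell& e, const Grid& g, int nvec, int cs) {
    Contacts ct; ct.hits = 0; ct.mean[0] = ct.mean[1] = ct.mean[2] = 0.0;
    double u[3], p[3];
    for (int k = 0; k < nvec; k++) {
        ellipsoid_dir(e.r, u);
        surface_point(e, u, p);
        if (g.background(p[0], p[1], p[2])) {
            ct.hits++;
            for (int i = 0; i < 3; i++) ct.mean[i] += p[i] - e.c[i];
            if (ct.hits >= cs) break;
        }
    }
    if (ct.hits > 0) for (int i = 0; i < 3; i++) ct.mean[i] /= ct.hits;
    return ct;
}

// full-sample collision test used by the growth phases: counts all hits
// among nvec samples and, when a collision registers, returns the mean of
// the hits lying on the same side as the first one (positive dot product).
// The one-sided mean keeps the contact vector meaningful when both faces of
// a thin symmetric structure are hit in the same round, while averaging out
// the sampling noise of a single hit point.
static Contacts detect_collision(const Ell& e, const Grid& g, int nvec) {
    double u[3], p[3];
    std::vector<double> hits;
    hits.reserve(16);
    for (int k = 0; k < nvec; k++) {
        ellipsoid_dir(e.r, u);
        surface_point(e, u, p);
        if (g.background(p[0], p[1], p[2]))
            for (int i = 0; i < 3; i++) hits.push_back(p[i] - e.c[i]);
    }
    Contacts ct; ct.hits = (int)(hits.size() / 3);
    ct.mean[0] = ct.mean[1] = ct.mean[2] = 0.0;
    if (ct.hits > 0) {
        int n_same = 0;
        for (int h = 0; h < ct.hits; h++) {
            double dp = hits[0] * hits[3 * h] + hits[1] * hits[3 * h + 1] +
                        hits[2] * hits[3 * h + 2];
            if (dp >= 0) {
                for (int i = 0; i < 3; i++) ct.mean[i] += hits[3 * h + i];
                n_same++;
            }
        }
        for (int i = 0; i < 3; i++) ct.mean[i] /= n_same;
    }
    return ct;
}

static int count_outside(const Ell& e, const Grid& g, int nvec) {
    int n = 0;
    double u[3], p[3];
    for (int k = 0; k < nvec; k++) {
        ellipsoid_dir(e.r, u);
        surface_point(e, u, p);
        if (g.outside(p[0], p[1], p[2])) n++;
    }
    return n;
}

// grow the axes flagged in free[] by inc until a collision registers;
// returns the collided state in e and the collision's mean contact vector
static bool grow_until(Ell& e, const Grid& g, const bool* free_ax, double inc,
                       int nvec, int cs, double* mean_out) {
    const double rmax = 2.0 * (g.nz + g.ny + g.nx);
    while (true) {
        Contacts ct = detect_collision(e, g, nvec);
        if (ct.hits >= cs) {
            for (int i = 0; i < 3; i++) mean_out[i] = ct.mean[i];
            return true;
        }
        for (int j = 0; j < 3; j++) if (free_ax[j]) e.r[j] += inc;
        if (e.r[0] > rmax || e.r[1] > rmax || e.r[2] > rmax) return false; // safety net
    }
}

static void contract(Ell& e, double factor) {
    for (int j = 0; j < 3; j++) e.r[j] *= factor;
}

// orthonormal frame with column 0 = v (normalized)
static void frame_from(const double* v, double* A) {
    double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    double a0[3];
    if (n < 1e-12) { unit_sphere_dir(a0); }
    else for (int i = 0; i < 3; i++) a0[i] = v[i] / n;
    // pick the cardinal axis least aligned with a0
    int k = 0; double amin = std::fabs(a0[0]);
    for (int i = 1; i < 3; i++) if (std::fabs(a0[i]) < amin) { amin = std::fabs(a0[i]); k = i; }
    double t[3] = {0, 0, 0}; t[k] = 1.0;
    double a1[3];
    double dp = t[0] * a0[0] + t[1] * a0[1] + t[2] * a0[2];
    for (int i = 0; i < 3; i++) a1[i] = t[i] - dp * a0[i];
    double n1 = std::sqrt(a1[0] * a1[0] + a1[1] * a1[1] + a1[2] * a1[2]);
    for (int i = 0; i < 3; i++) a1[i] /= n1;
    double a2[3] = {a0[1] * a1[2] - a0[2] * a1[1],
                    a0[2] * a1[0] - a0[0] * a1[2],
                    a0[0] * a1[1] - a0[1] * a1[0]};
    for (int i = 0; i < 3; i++) { A[i] = a0[i]; A[3 + i] = a1[i]; A[6 + i] = a2[i]; }
}

// rotate the frame by angle about axis w (Rodrigues), A <- R A. The axis is
// normalized here and the frame re-orthonormalized afterwards: feeding a
// slightly non-unit axis (e.g. a frame column carrying rounding error) into
// Rodrigues shrinks the frame by the norm error per application, and that
// error compounds exponentially over hundreds of accepted proposals.
static void rotate_frame(double* A, const double* w_in, double ang) {
    double wn = std::sqrt(w_in[0] * w_in[0] + w_in[1] * w_in[1] + w_in[2] * w_in[2]);
    if (wn < 1e-12) return;
    double w[3] = {w_in[0] / wn, w_in[1] / wn, w_in[2] / wn};
    double c = std::cos(ang), s = std::sin(ang), C = 1.0 - c;
    double R[9] = {
        c + w[0] * w[0] * C,        w[0] * w[1] * C - w[2] * s, w[0] * w[2] * C + w[1] * s,
        w[0] * w[1] * C + w[2] * s, c + w[1] * w[1] * C,        w[1] * w[2] * C - w[0] * s,
        w[0] * w[2] * C - w[1] * s, w[1] * w[2] * C + w[0] * s, c + w[2] * w[2] * C};
    double B[9];
    for (int j = 0; j < 3; j++)
        for (int i = 0; i < 3; i++) {
            B[3 * j + i] = 0.0;
            for (int k = 0; k < 3; k++) B[3 * j + i] += R[3 * k + i] * A[3 * j + k];
        }
    // Gram-Schmidt re-orthonormalization
    double n0 = std::sqrt(B[0] * B[0] + B[1] * B[1] + B[2] * B[2]);
    for (int i = 0; i < 3; i++) B[i] /= n0;
    double d01 = B[0] * B[3] + B[1] * B[4] + B[2] * B[5];
    for (int i = 0; i < 3; i++) B[3 + i] -= d01 * B[i];
    double n1 = std::sqrt(B[3] * B[3] + B[4] * B[4] + B[5] * B[5]);
    for (int i = 0; i < 3; i++) B[3 + i] /= n1;
    B[6] = B[1] * B[5] - B[2] * B[4];
    B[7] = B[2] * B[3] - B[0] * B[5];
    B[8] = B[0] * B[4] - B[1] * B[3];
    std::copy(B, B + 9, A);
}

struct FitCfg {
    int nvec, cs, maxit;
    double inc, maxdrift, contract_factor, rot_max;
};

// returns valid flag; on success fills e with the locally maximal ellipsoid
static bool fit_one(const double* seed, const Grid& g, const FitCfg& cfg, Ell& e) {
    for (int i = 0; i < 3; i++) { e.c[i] = seed[i]; e.r[i] = cfg.inc; }
    double z_axis[3] = {1.0, 0.0, 0.0};
    frame_from(z_axis, e.A); // identity-ish frame; irrelevant while spherical
    // initial sphere must not already collide; shrink once, then give up
    if (detect(e, g, cfg.nvec, cfg.cs).hits >= cfg.cs) {
        for (int i = 0; i < 3; i++) e.r[i] = cfg.inc / 2.0;
        if (detect(e, g, cfg.nvec, cfg.cs).hits >= cfg.cs) return false;
    }
    const bool all_ax[3] = {true, true, true};
    const bool in_plane[3] = {false, true, true};
    double mcv[3];
    // phase 1: uniform spherical growth to first contact
    if (!grow_until(e, g, all_ax, cfg.inc, cfg.nvec, cfg.cs, mcv)) return false;
    // refine the contact direction with a denser sample of the collided
    // state: the handful of hits that registered the collision carry
    // sampling noise of up to the contact-cap angle
    {
        Contacts ct = detect_collision(e, g, 10 * cfg.nvec);
        if (ct.hits > 0) for (int i = 0; i < 3; i++) mcv[i] = ct.mean[i];
    }
    frame_from(mcv, e.A); // first semi-axis along the mean contact vector
    contract(e, cfg.contract_factor);
    // phase 2: growth in the plane orthogonal to the first semi-axis
    if (!grow_until(e, g, in_plane, cfg.inc, cfg.nvec, cfg.cs, mcv)) return false;
    {
        Contacts ct = detect_collision(e, g, 10 * cfg.nvec);
        if (ct.hits > 0) for (int i = 0; i < 3; i++) mcv[i] = ct.mean[i];
    }
    // align the second axis with the in-plane component of this collision's
    // contact vector, so the third axis points along the locally freest
    // direction (e.g. down the long axis of a rod)
    {
        double dp = mcv[0] * e.A[0] + mcv[1] * e.A[1] + mcv[2] * e.A[2];
        double a1[3] = {mcv[0] - dp * e.A[0], mcv[1] - dp * e.A[1], mcv[2] - dp * e.A[2]};
        double n1 = std::sqrt(a1[0] * a1[0] + a1[1] * a1[1] + a1[2] * a1[2]);
        if (n1 > 1e-9) {
            for (int i = 0; i < 3; i++) e.A[3 + i] = a1[i] / n1;
            e.A[6] = e.A[1] * e.A[5] - e.A[2] * e.A[4];
            e.A[7] = e.A[2] * e.A[3] - e.A[0] * e.A[5];
            e.A[8] = e.A[0] * e.A[4] - e.A[1] * e.A[3];
        }
    }
    contract(e, cfg.contract_factor);
    // phase 3: stochastic refinement; every proposal couples a small
    // perturbation with one increment of in-plane growth and is kept only if
    // contact-free, so accepted volumes increase monotonically
    int since = 0, attempts = 0;
    const int max_attempts = 10 * cfg.maxit;
    while (since < cfg.maxit && attempts < max_attempts) {
        attempts++;
        Ell cand = e;
        double typ = unif_rand();
        if (typ < 0.2) {
            double w[3]; unit_sphere_dir(w);
            rotate_frame(cand.A, w, unif_rand() * cfg.rot_max);
        } else if (typ < 0.4) {
            // recalculate the in-plane growth directions: spin the frame
            // about the first (contact) axis by an arbitrary angle, so the
            // random in-plane direction that best fits the local structure
            // can be discovered and extended
            double w[3] = {cand.A[0], cand.A[1], cand.A[2]};
            rotate_frame(cand.A, w, unif_rand() * 2.0 * M_PI);
        } else if (typ < 0.6) {
            double d[3];
            do { for (int i = 0; i < 3; i++) d[i] = (2.0 * unif_rand() - 1.0) * cfg.inc; }
            while (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] > cfg.inc * cfg.inc);
            for (int i = 0; i < 3; i++) cand.c[i] += d[i];
            double dr[3] = {cand.c[0] - seed[0], cand.c[1] - seed[1], cand.c[2] - seed[2]};
            double nd = std::sqrt(dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2]);
            if (nd > cfg.maxdrift)
                for (int i = 0; i < 3; i++) cand.c[i] = seed[i] + dr[i] * (cfg.maxdrift / nd);
        }
        // couple the perturbation with one increment of growth so accepted
        // proposals always increase the volume: perturbations grow a random
        // in-plane axis (the free directions); the unperturbed branch may
        // also regrow the first-contact axis after its collision
        // contractions
        int j;
        if (typ < 0.6) { j = (unif_rand() < 0.5) ? 1 : 2; }
        else { j = (int)(unif_rand() * 3.0); if (j > 2) j = 2; }
        cand.r[j] += cfg.inc;
        if (detect(cand, g, cfg.nvec, cfg.cs).hits < cfg.cs) { e = cand; since = 0; }
        else since++;
    }
    // validity: discard when more than half of the surface samples fall
    // outside the image bounds
    if (2 * count_outside(e, g, cfg.nvec) > cfg.nvec) return false;
    return true;
}

static void sort_axes(Ell& e, double* out_r, double* out_A) {
    int ord[3] = {0, 1, 2};
    for (int i = 0; i < 2; i++)  // tiny insertion sort, stable
        for (int j = 0; j < 2 - i; j++)
            if (e.r[ord[j]] > e.r[ord[j + 1]]) std::swap(ord[j], ord[j + 1]);
    for (int j = 0; j < 3; j++) {
        out_r[j] = e.r[ord[j]];
        for (int i = 0; i < 3; i++) out_A[3 * j + i] = e.A[3 * ord[j] + i];
    }
}

// Fit one ellipsoid per seed. Returns an n x 16 matrix: centre (z,y,x),
// sorted semi-axes (a,b,c), axis directions (a: z,y,x; b: z,y,x; c: z,y,x),
// valid flag.
// [[Rcpp::export(name = ".fit_ellipsoids_cpp")]]
NumericMatrix fit_ellipsoids_cpp(NumericMatrix seeds, LogicalVector fgv, IntegerVector dims,
                                 List params) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    std::vector<int> fg((size_t)nz * ny * nx);
    for (size_t i = 0; i < fg.size(); i++) fg[i] = fgv[i] ? 1 : 0;
    Grid g; g.fg = fg.data(); g.nz = nz; g.ny = ny; g.nx = nx;
    FitCfg cfg;
    cfg.nvec = as<int>(params["n_vectors"]);
    cfg.cs = as<int>(params["contact_sensitivity"]);
    cfg.maxit = as<int>(params["max_iterations"]);
    cfg.inc = as<double>(params["sampling_increment"]);
    cfg.maxdrift = as<double>(params["max_drift"]);
    cfg.contract_factor = as<double>(params["contract_factor"]);
    cfg.rot_max = as<double>(params["rotation_max"]);
    const int n = seeds.nrow();
    NumericMatrix out(n, 16);
    for (int s = 0; s < n; s++) {
        double seed[3] = {seeds(s, 0), seeds(s, 1), seeds(s, 2)};
        Ell e;
        bool ok = fit_one(seed, g, cfg, e);
        if (ok) {
            double r[3], A[9];
            sort_axes(e, r, A);
            out(s, 0) = e.c[0]; out(s, 1) = e.c[1]; out(s, 2) = e.c[2];
            out(s, 3) = r[0]; out(s, 4) = r[1]; out(s, 5) = r[2];
            for (int k = 0; k < 9; k++) out(s, 6 + k) = A[k];
            out(s, 15) = 1.0;
        } else {
            out(s, 15) = 0.0;
        }
        if (s % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Assign to every foreground voxel the 1-based row index (into `ells`,
// already sorted by decreasing volume) of the largest ellipsoid containing
// its centre; 0 when uncovered. ells columns: centre(3), a, b, c, axes(9).
// [[Rcpp::export(name = ".assign_claims_cpp")]]
IntegerVector assign_claims_cpp(LogicalVector fgv, IntegerVector dims, NumericMatrix ells) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const size_t nvox = (size_t)nz * ny * nx;
    IntegerVector claim(nvox);
    for (int id = 0; id < ells.nrow(); id++) {
        double c[3] = {ells(id, 0), ells(id, 1), ells(id, 2)};
        double r[3] = {ells(id, 3), ells(id, 4), ells(id, 5)};
        double A[9];
        for (int k = 0; k < 9; k++) A[k] = ells(id, 6 + k);
        // bounding box: extent along world axis i
        int lo[3], hi[3];
        for (int i = 0; i < 3; i++) {
            double h = std::sqrt(A[i] * A[i] * r[0] * r[0] +
                                 A[3 + i] * A[3 + i] * r[1] * r[1] +
                                 A[6 + i] * A[6 + i] * r[2] * r[2]);
            lo[i] = std::max(0, (int)std::ceil(c[i] - h));
            int n_i = (i == 0) ? nz : (i == 1) ? ny : nx;
            hi[i] = std::min(n_i - 1, (int)std::floor(c[i] + h));
        }
        for (int x = lo[2]; x <= hi[2]; x++)
            for (int y = lo[1]; y <= hi[1]; y++)
                for (int z = lo[0]; z <= hi[0]; z++) {
                    size_t i = (size_t)z + (size_t)nz * (y + (size_t)ny * x);
                    if (!fgv[i] || claim[i]) continue;
                    double d[3] = {z - c[0], y - c[1], x - c[2]};
                    double q = 0.0;
                    for (int j = 0; j < 3; j++) {
                        double t = (A[3 * j] * d[0] + A[3 * j + 1] * d[1] + A[3 * j + 2] * d[2]) / r[j];
                        q += t * t;
                    }
                    if (q <= 1.0) claim[i] = id + 1;
                }
    }
    return claim;
}
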