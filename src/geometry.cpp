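// Mesh intersection core: Moller-style triangle/triangle interval test with
// explicit intersection segments, plus the batched torus-pair machinery
// (analytic band prefilter, AABB broad phase, segment clustering).
// Units are cm throughout.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 vsub(const V3 &a, const V3 &b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 vadd(const V3 &a, const V3 &b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 vscale(double s, const V3 &a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double vdot(const V3 &a, const V3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 vcross(const V3 &a, const V3 &b) {
    return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double vnorm(const V3 &a) { return std::sqrt(vdot(a, a)); }

// distance from point p to the surface of a torus (center c, unit axis a,
// major radius R, minor radius r)
static inline double torus_surf_dist(const V3 &p, const V3 &c, const V3 &a,
                                     double R, double r) {
    V3 q = vsub(p, c);
    double qa = vdot(q, a);
    double qp2 = vdot(q, q) - qa * qa;
    double qp = qp2 > 0 ? std::sqrt(qp2) : 0.0;
    double dR = qp - R;
    return std::fabs(std::sqrt(dR * dR + qa * qa) - r);
}

// --- triangle/plane crossing points -----------------------------------------
// signs: +1 / -1 strictly off plane, 0 on plane (|d| <= eps).
// Collects the points where the triangle boundary meets the plane; for a
// triangle straddling the plane these are 1 or 2 points lying on the
// plane/plane intersection line.
static int plane_crossings(const V3 tri[3], const double d[3], double eps, V3 pts[4]) {
    int sgn[3];
    for (int i = 0; i < 3; ++i)
        sgn[i] = (d[i] > eps) ? 1 : ((d[i] < -eps) ? -1 : 0);
    int np = 0;
    for (int i = 0; i < 3; ++i)
        if (sgn[i] == 0) pts[np++] = tri[i];
    for (int i = 0; i < 3; ++i) {
        int j = (i + 1) % 3;
        if (sgn[i] * sgn[j] < 0) {
            double t = d[i] / (d[i] - d[j]);
            pts[np++] = vadd(tri[i], vscale(t, vsub(tri[j], tri[i])));
        }
    }
    return np;
}

// --- 2D helpers for the coplanar branch --------------------------------------
static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
    return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool point_in_tri2(double px, double py, const double tx[3], const double ty[3]) {
    double d1 = orient2d(tx[0], ty[0], tx[1], ty[1], px, py);
    double d2 = orient2d(tx[1], ty[1], tx[2], ty[2], px, py);
    double d3 = orient2d(tx[2], ty[2], tx[0], ty[0], px, py);
    bool has_neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
    bool has_pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
    return !(has_neg && has_pos);
}

static bool seg_seg_cross2(double ax, double ay, double bx, double by,
                           double cx, double cy, double dx, double dy) {
    double d1 = orient2d(cx, cy, dx, dy, ax, ay);
    double d2 = orient2d(cx, cy, dx, dy, bx, by);
    double d3 = orient2d(ax, ay, bx, by, cx, cy);
    double d4 = orient2d(ax, ay, bx, by, dx, dy);
    return ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0));
}

// project triangles to the plane most orthogonal to n, then 2D overlap test
static bool coplanar_overlap(const V3 T1[3], const V3 T2[3], const V3 &n) {
    double nx = std::fabs(n.x), ny = std::fabs(n.y), nz = std::fabs(n.z);
    int drop = (nx >= ny && nx >= nz) ? 0 : ((ny >= nz) ? 1 : 2);
    double x1[3], y1[3], x2[3], y2[3];
    for (int i = 0; i < 3; ++i) {
        const double c1[3] = {T1[i].x, T1[i].y, T1[i].z};
        const double c2[3] = {T2[i].x, T2[i].y, T2[i].z};
        int u = (drop == 0) ? 1 : 0;
        int v = (drop == 2) ? 1 : 2;
        x1[i] = c1[u]; y1[i] = c1[v];
        x2[i] = c2[u]; y2[i] = c2[v];
    }
    for (int i = 0; i < 3; ++i)
        if (point_in_tri2(x1[i], y1[i], x2, y2) || point_in_tri2(x2[i], y2[i], x1, y1))
            return true;
    for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
            if (seg_seg_cross2(x1[i], y1[i], x1[(i + 1) % 3], y1[(i + 1) % 3],
                               x2[j], y2[j], x2[(j + 1) % 3], y2[(j + 1) % 3]))
                return true;
    return false;
}

// --- triangle/triangle intersection ------------------------------------------
// return code: 0 = disjoint, 1 = proper intersection (seg[0], seg[1] filled,
// possibly zero length), 2 = coplanar overlap (no segment geometry).
static int tri_tri_core(const V3 T1[3], const V3 T2[3], V3 seg[2]) {
    V3 n2 = vcross(vsub(T2[1], T2[0]), vsub(T2[2], T2[0]));
    double diam = 0.0;
    for (int i = 0; i < 3; ++i) {
        diam = std::max(diam, vnorm(vsub(T1[i], T2[0])));
        diam = std::max(diam, vnorm(vsub(T2[i], T2[0])));
    }
    double eps2 = 1e-12 * vnorm(n2) * std::max(diam, 1e-300);

    double d1[3];
    for (int i = 0; i < 3; ++i) d1[i] = vdot(n2, vsub(T1[i], T2[0]));
    bool all_pos = d1[0] > eps2 && d1[1] > eps2 && d1[2] > eps2;
    bool all_neg = d1[0] < -eps2 && d1[1] < -eps2 && d1[2] < -eps2;
    if (all_pos || all_neg) return 0;

    V3 n1 = vcross(vsub(T1[1], T1[0]), vsub(T1[2], T1[0]));
    double eps1 = 1e-12 * vnorm(n1) * std::max(diam, 1e-300);
    double d2[3];
    for (int i = 0; i < 3; ++i) d2[i] = vdot(n1, vsub(T2[i], T1[0]));
    all_pos = d2[0] > eps1 && d2[1] > eps1 && d2[2] > eps1;
    all_neg = d2[0] < -eps1 && d2[1] < -eps1 && d2[2] < -eps1;
    if (all_pos || all_neg) return 0;

    bool cop1 = std::fabs(d1[0]) <= eps2 && std::fabs(d1[1]) <= eps2 && std::fabs(d1[2]) <= eps2;
    if (cop1) return coplanar_overlap(T1, T2, n2) ? 2 : 0;

    V3 D = vcross(n1, n2);
    double Dn = vnorm(D);
    if (Dn < 1e-300) return 0;  // parallel distinct planes
    D = vscale(1.0 / Dn, D);

    V3 p1[4], p2[4];
    int np1 = plane_crossings(T1, d1, eps2, p1);
    int np2 = plane_crossings(T2, d2, eps1, p2);
    if (np1 == 0 || np2 == 0) return 0;

    double s1lo = 1e300, s1hi = -1e300, s2lo = 1e300, s2hi = -1e300;
    V3 q1lo, q1hi, q2lo, q2hi;
    for (int i = 0; i < np1; ++i) {
        double s = vdot(D, p1[i]);
        if (s < s1lo) { s1lo = s; q1lo = p1[i]; }
        if (s > s1hi) { s1hi = s; q1hi = p1[i]; }
    }
    for (int i = 0; i < np2; ++i) {
        double s = vdot(D, p2[i]);
        if (s < s2lo) { s2lo = s; q2lo = p2[i]; }
        if (s > s2hi) { s2hi = s; q2hi = p2[i]; }
    }
    double tol = 1e-12 * std::max(diam, 1.0);
    double lo = std::max(s1lo, s2lo), hi = std::min(s1hi, s2hi);
    if (lo > hi + tol) return 0;
    seg[0] = (s1lo >= s2lo) ? q1lo : q2lo;
    seg[1] = (s1hi <= s2hi) ? q1hi : q2hi;
    return 1;
}

static void check_tri(const V3 T[3]) {
    V3 n = vcross(vsub(T[1], T[0]), vsub(T[2], T[0]));
    if (0.5 * vnorm(n) <= 1e-12)
        stop("degenerate input triangle (area <= 1e-12 cm^2)");
}

static inline V3 row3(const NumericMatrix &m, int i) {
    return v3(m(i, 0), m(i, 1), m(i, 2));
}

// [[Rcpp::export]]
List cpp_tri_tri(NumericMatrix t1, NumericMatrix t2) {
    V3 T1[3], T2[3], seg[2];
    for (int i = 0; i < 3; ++i) { T1[i] = row3(t1, i); T2[i] = row3(t2, i); }
    check_tri(T1); check_tri(T2);
    int code = tri_tri_core(T1, T2, seg);
    if (code == 0)
        return List::create(_["hit"] = false, _["coplanar"] = false,
                            _["segment"] = R_NilValue);
    if (code == 2)
        return List::create(_["hit"] = true, _["coplanar"] = true,
                            _["segment"] = R_NilValue);
    NumericMatrix s(2, 3);
    s(0, 0) = seg[0].x; s(0, 1) = seg[0].y; s(0, 2) = seg[0].z;
    s(1, 0) = seg[1].x; s(1, 1) = seg[1].y; s(1, 2) = seg[1].z;
    return List::create(_["hit"] = true, _["coplanar"] = false, _["segment"] = s);
}

// Batched boolean test: each row of a1/a2 is a flattened triangle
// (x1,y1,z1,x2,y2,z2,x3,y3,z3).
// [[Rcpp::export]]
LogicalVector cpp_tri_tri_batch(NumericMatrix a1, NumericMatrix a2) {
    int n = a1.nrow();
    if (a2.nrow() != n) stop("triangle batches differ in length");
    LogicalVector out(n);
    V3 T1[3], T2[3], seg[2];
    for (int k = 0; k < n; ++k) {
        for (int i = 0; i < 3; ++i) {
            T1[i] = v3(a1(k, 3 * i), a1(k, 3 * i + 1), a1(k, 3 * i + 2));
            T2[i] = v3(a2(k, 3 * i), a2(k, 3 * i + 1), a2(k, 3 * i + 2));
        }
        out[k] = tri_tri_core(T1, T2, seg) > 0;
    }
    return out;
}

// --- union-find ---------------------------------------------------------------
struct UF {
    std::vector<int> p;
    UF(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
    int find(int i) { while (p[i] != i) { p[i] = p[p[i]]; i = p[i]; } return i; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
};

static inline long long cellkey(double x, double y, double z, double h) {
    long long ix = (long long)std::floor(x / h) + (1LL << 20);
    long long iy = (long long)std::floor(y / h) + (1LL << 20);
    long long iz = (long long)std::floor(z / h) + (1LL << 20);
    return (ix << 42) | (iy << 21) | iz;
}

// Pairwise intersection of two clipped torus meshes.
// V*: vertex matrices (n x 3); F*: 1-based triangle index matrices (m x 3);
// tor*: c(cx,cy,cz, ax,ay,az, R, r) or length 0 to disable the band filter;
// margin*: analytic band half-width for prefiltering mesh * against the other
// torus surface; cluster_eps: endpoint-linking tolerance for components.
// [[Rcpp::export]]
List cpp_pair_components(NumericMatrix V1, IntegerMatrix F1, NumericVector tor1,
                         NumericMatrix V2, IntegerMatrix F2, NumericVector tor2,
                         double margin1, double margin2, double cluster_eps) {
    int n1 = V1.nrow(), n2 = V2.nrow(), m1 = F1.nrow(), m2 = F2.nrow();
    List empty = List::create(
        _["centroids"] = NumericMatrix(0, 3), _["lengths"] = NumericVector(0),
        _["comp_nseg"] = IntegerVector(0), _["n_segments"] = 0,
        _["n_hits"] = 0, _["n_coplanar"] = 0, _["identical"] = false);
    if (n1 == 0 || n2 == 0 || m1 == 0 || m2 == 0) return empty;

    // whole-mesh bounds
    double lo1[3] = {1e300, 1e300, 1e300}, hi1[3] = {-1e300, -1e300, -1e300};
    double lo2[3] = {1e300, 1e300, 1e300}, hi2[3] = {-1e300, -1e300, -1e300};
    for (int i = 0; i < n1; ++i)
        for (int k = 0; k < 3; ++k) {
            lo1[k] = std::min(lo1[k], V1(i, k)); hi1[k] = std::max(hi1[k], V1(i, k));
        }
    for (int i = 0; i < n2; ++i)
        for (int k = 0; k < 3; ++k) {
            lo2[k] = std::min(lo2[k], V2(i, k)); hi2[k] = std::max(hi2[k], V2(i, k));
        }
    bool same = (n1 == n2);
    for (int k = 0; k < 3 && same; ++k)
        same = std::fabs(lo1[k] - lo2[k]) < 1e-9 && std::fabs(hi1[k] - hi2[k]) < 1e-9;
    if (same) {
        List out = clone(empty);
        out["identical"] = true;
        return out;
    }
    for (int k = 0; k < 3; ++k)
        if (lo1[k] > hi2[k] + 1e-12 || lo2[k] > hi1[k] + 1e-12) return empty;

    // analytic band prefilter: a triangle of mesh 1 can only meet mesh 2 if
    // one of its vertices is within margin1 of torus 2's exact surface
    std::vector<int> keep1, keep2;
    if (tor2.size() == 8) {
        V3 c = v3(tor2[0], tor2[1], tor2[2]), a = v3(tor2[3], tor2[4], tor2[5]);
        std::vector<double> dv(n1);
        for (int i = 0; i < n1; ++i)
            dv[i] = torus_surf_dist(row3(V1, i), c, a, tor2[6], tor2[7]);
        for (int t = 0; t < m1; ++t) {
            double dm = std::min(dv[F1(t, 0) - 1], std::min(dv[F1(t, 1) - 1], dv[F1(t, 2) - 1]));
            if (dm <= margin1) keep1.push_back(t);
        }
    } else {
        for (int t = 0; t < m1; ++t) keep1.push_back(t);
    }
    if (tor1.size() == 8) {
        V3 c = v3(tor1[0], tor1[1], tor1[2]), a = v3(tor1[3], tor1[4], tor1[5]);
        std::vector<double> dv(n2);
        for (int i = 0; i < n2; ++i)
            dv[i] = torus_surf_dist(row3(V2, i), c, a, tor1[6], tor1[7]);
        for (int t = 0; t < m2; ++t) {
            double dm = std::min(dv[F2(t, 0) - 1], std::min(dv[F2(t, 1) - 1], dv[F2(t, 2) - 1]));
            if (dm <= margin2) keep2.push_back(t);
        }
    } else {
        for (int t = 0; t < m2; ++t) keep2.push_back(t);
    }
    if (keep1.empty() || keep2.empty()) return empty;

    // per-triangle AABBs of the survivors
    size_t k1 = keep1.size(), k2 = keep2.size();
    std::vector<double> b1(6 * k1), b2(6 * k2);
    for (size_t t = 0; t < k1; ++t) {
        for (int k = 0; k < 3; ++k) { b1[6 * t + k] = 1e300; b1[6 * t + 3 + k] = -1e300; }
        for (int v = 0; v < 3; ++v) {
            int iv = F1(keep1[t], v) - 1;
            for (int k = 0; k < 3; ++k) {
                b1[6 * t + k] = std::min(b1[6 * t + k], V1(iv, k));
                b1[6 * t + 3 + k] = std::max(b1[6 * t + 3 + k], V1(iv, k));
            }
        }
    }
    for (size_t t = 0; t < k2; ++t) {
        for (int k = 0; k < 3; ++k) { b2[6 * t + k] = 1e300; b2[6 * t + 3 + k] = -1e300; }
        for (int v = 0; v < 3; ++v) {
            int iv = F2(keep2[t], v) - 1;
            for (int k = 0; k < 3; ++k) {
                b2[6 * t + k] = std::min(b2[6 * t + k], V2(iv, k));
                b2[6 * t + 3 + k] = std::max(b2[6 * t + 3 + k], V2(iv, k));
            }
        }
    }

    std::vector<double> segs;  // x1 y1 z1 x2 y2 z2 per positive-length segment
    std::vector<double> seglen;
    int n_hits = 0, n_cop = 0;
    V3 T1[3], T2[3], seg[2];
    for (size_t t = 0; t < k1; ++t) {
        for (int v = 0; v < 3; ++v) T1[v] = row3(V1, F1(keep1[t], v) - 1);
        for (size_t u = 0; u < k2; ++u) {
            bool off = false;
            for (int k = 0; k < 3; ++k)
                if (b1[6 * t + k] > b2[6 * u + 3 + k] || b2[6 * u + k] > b1[6 * t + 3 + k]) {
                    off = true; break;
                }
            if (off) continue;
            for (int v = 0; v < 3; ++v) T2[v] = row3(V2, F2(keep2[u], v) - 1);
            int code = tri_tri_core(T1, T2, seg);
            if (code == 0) continue;
            ++n_hits;
            if (code == 2) { ++n_cop; continue; }
            double len = vnorm(vsub(seg[1], seg[0]));
            if (len > 1e-12) {
                segs.push_back(seg[0].x); segs.push_back(seg[0].y); segs.push_back(seg[0].z);
                segs.push_back(seg[1].x); segs.push_back(seg[1].y); segs.push_back(seg[1].z);
                seglen.push_back(len);
            }
        }
    }

    int S = (int)seglen.size();
    if (S == 0) {
        List out = clone(empty);
        out["n_hits"] = n_hits;
        out["n_coplanar"] = n_cop;
        return out;
    }

    // cluster segments whose endpoints come within cluster_eps
    UF uf(S);
    double h = std::max(cluster_eps, 1e-6);
    std::unordered_map<long long, std::vector<int> > grid;
    grid.reserve(4 * S);
    for (int s = 0; s < S; ++s)
        for (int e = 0; e < 2; ++e)
            grid[cellkey(segs[6 * s + 3 * e], segs[6 * s + 3 * e + 1],
                         segs[6 * s + 3 * e + 2], h)].push_back(s);
    double eps2c = cluster_eps * cluster_eps;
    for (int s = 0; s < S; ++s) {
        for (int e = 0; e < 2; ++e) {
            double px = segs[6 * s + 3 * e], py = segs[6 * s + 3 * e + 1],
                   pz = segs[6 * s + 3 * e + 2];
            long long ix = (long long)std::floor(px / h);
            long long iy = (long long)std::floor(py / h);
            long long iz = (long long)std::floor(pz / h);
            for (long long dx = -1; dx <= 1; ++dx)
                for (long long dy = -1; dy <= 1; ++dy)
                    for (long long dz = -1; dz <= 1; ++dz) {
                        long long key = (((ix + dx) + (1LL << 20)) << 42) |
                                        (((iy + dy) + (1LL << 20)) << 21) |
                                        ((iz + dz) + (1LL << 20));
                        std::unordered_map<long long, std::vector<int> >::iterator it =
                            grid.find(key);
                        if (it == grid.end()) continue;
                        const std::vector<int> &cand = it->second;
                        for (size_t c = 0; c < cand.size(); ++c) {
                            int s2 = cand[c];
                            if (s2 <= s) continue;
                            for (int e2 = 0; e2 < 2; ++e2) {
                                double qx = segs[6 * s2 + 3 * e2] - px;
                                double qy = segs[6 * s2 + 3 * e2 + 1] - py;
                                double qz = segs[6 * s2 + 3 * e2 + 2] - pz;
                                if (qx * qx + qy * qy + qz * qz <= eps2c) {
                                    uf.unite(s, s2);
                                    break;
                                }
                            }
                        }
                    }
        }
    }

    std::unordered_map<int, int> root2comp;
    std::vector<double> cx, cy, cz, clen;
    std::vector<int> cn;
    for (int s = 0; s < S; ++s) {
        int r = uf.find(s);
        int ci;
        std::unordered_map<int, int>::iterator it = root2comp.find(r);
        if (it == root2comp.end()) {
            ci = (int)cx.size();
            root2comp[r] = ci;
            cx.push_back(0); cy.push_back(0); cz.push_back(0);
            clen.push_back(0); cn.push_back(0);
        } else ci = it->second;
        double mx = 0.5 * (segs[6 * s] + segs[6 * s + 3]);
        double my = 0.5 * (segs[6 * s + 1] + segs[6 * s + 4]);
        double mz = 0.5 * (segs[6 * s + 2] + segs[6 * s + 5]);
        cx[ci] += mx * seglen[s]; cy[ci] += my * seglen[s]; cz[ci] += mz * seglen[s];
        clen[ci] += seglen[s]; cn[ci] += 1;
    }
    int K = (int)cx.size();
    NumericMatrix cent(K, 3);
    NumericVector lens(K);
    IntegerVector nsc(K);
    for (int k = 0; k < K; ++k) {
        cent(k, 0) = cx[k] / clen[k];
        cent(k, 1) = cy[k] / clen[k];
        cent(k, 2) = cz[k] / clen[k];
        lens[k] = clen[k];
        nsc[k] = cn[k];
    }
    return List::create(
        _["centroids"] = cent, _["lengths"] = lens, _["comp_nseg"] = nsc,
        _["n_segments"] = S, _["n_hits"] = n_hits, _["n_coplanar"] = n_cop,
        _["identical"] = false);
}
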