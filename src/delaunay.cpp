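#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Incremental (Bowyer-Watson) Delaunay triangulation for d >= 2 with a
// ghost vertex: the triangulation is bootstrapped from one full-rank
// simplex of input points, and every convex-hull facet is paired with a
// "ghost" simplex whose circumsphere is the open halfspace beyond the
// facet.  A query point falls inside a ghost circumsphere exactly when
// it is on the opposite side of the facet from the centroid of the
// data, which keeps hull insertions exact without a distorting
// super-simplex.  Points are normalised to [-1, 1]^d; a final
// empty-circumsphere validation pass flags failures (cospherical or
// otherwise degenerate configurations), which the caller escapes by
// jittering and retrying.

namespace {

const int GHOST = -1;

struct Simplex {
    std::vector<int> v;          // d+1 vertex ids; v[0] may be GHOST
    std::vector<double> centre;  // circumcentre (real simplices)
    double r2;
    bool alive;
    bool ghost() const { return v[0] == GHOST; }
};

bool solveLin(std::vector<std::vector<double> >& A, std::vector<double>& b,
              std::vector<double>& x, double tol) {
    int d = (int)b.size();
    for (int col = 0; col < d; ++col) {
        int piv = col;
        for (int r = col + 1; r < d; ++r)
            if (std::fabs(A[r][col]) > std::fabs(A[piv][col])) piv = r;
        if (std::fabs(A[piv][col]) < tol) return false;
        std::swap(A[piv], A[col]);
        std::swap(b[piv], b[col]);
        for (int r = col + 1; r < d; ++r) {
            double f = A[r][col] / A[col][col];
            for (int c = col; c < d; ++c) A[r][c] -= f * A[col][c];
            b[r] -= f * b[col];
        }
    }
    x.assign(d, 0.0);
    for (int r = d - 1; r >= 0; --r) {
        double s = b[r];
        for (int c = r + 1; c < d; ++c) s -= A[r][c] * x[c];
        x[r] = s / A[r][r];
    }
    return true;
}

struct Triangulator {
    int n, d;
    std::vector<std::vector<double> > P;   // normalised points
    std::vector<double> centroid;
    std::vector<Simplex> simp;
    bool degenerate;

    double dist2(const std::vector<double>& a,
                 const std::vector<double>& b) const {
        double s = 0.0;
        for (int j = 0; j < d; ++j) { double t = a[j] - b[j]; s += t * t; }
        return s;
    }

    // signed volume-like determinant of the facet (d real points) and q
    double facetSide(const std::vector<int>& f,
                     const std::vector<double>& q) const {
        std::vector<std::vector<double> > M(d, std::vector<double>(d));
        for (int r = 1; r < d; ++r)
            for (int c = 0; c < d; ++c)
                M[r - 1][c] = P[f[r]][c] - P[f[0]][c];
        for (int c = 0; c < d; ++c) M[d - 1][c] = q[c] - P[f[0]][c];
        // small determinant by Gaussian elimination
        double det = 1.0;
        for (int col = 0; col < d; ++col) {
            int piv = col;
            for (int r = col + 1; r < d; ++r)
                if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
            if (std::fabs(M[piv][col]) < 1e-300) return 0.0;
            if (piv != col) { std::swap(M[piv], M[col]); det = -det; }
            det *= M[col][col];
            for (int r = col + 1; r < d; ++r) {
                double fr = M[r][col] / M[col][col];
                for (int c = col; c < d; ++c) M[r][c] -= fr * M[col][c];
            }
        }
        return det;
    }

    bool setSphere(Simplex& s) {
        std::vector<std::vector<double> > A(d, std::vector<double>(d));
        std::vector<double> b(d);
        double n0 = 0.0;
        for (int j = 0; j < d; ++j) n0 += P[s.v[0]][j] * P[s.v[0]][j];
        for (int i = 1; i <= d; ++i) {
            double ni = 0.0;
            for (int j = 0; j < d; ++j) {
                A[i - 1][j] = 2.0 * (P[s.v[i]][j] - P[s.v[0]][j]);
                ni += P[s.v[i]][j] * P[s.v[i]][j];
            }
            b[i - 1] = ni - n0;
        }
        if (!solveLin(A, b, s.centre, 1e-13)) return false;
        s.r2 = dist2(P[s.v[0]], s.centre);
        return true;
    }

    // does the circumsphere of s (halfspace for ghost) contain point q?
    bool inSphere(const Simplex& s, const std::vector<double>& q) const {
        if (s.ghost()) {
            std::vector<int> f(s.v.begin() + 1, s.v.end());
            double sq = facetSide(f, q);
            double sc = facetSide(f, centroid);
            // beyond the hull facet, or right on its plane (cautious)
            return sq * sc < 0.0 || std::fabs(sq) < 1e-12;
        }
        return dist2(q, s.centre) < s.r2;
    }

    void insert(int ip) {
        std::vector<int> bad;
        for (size_t s = 0; s < simp.size(); ++s)
            if (simp[s].alive && inSphere(simp[s], P[ip]))
                bad.push_back((int)s);
        if (bad.empty()) { degenerate = true; return; }
        std::map<std::vector<int>, int> fcount;
        for (int bs : bad)
            for (int skip = 0; skip <= d; ++skip) {
                std::vector<int> f;
                for (int k = 0; k <= d; ++k)
                    if (k != skip) f.push_back(simp[bs].v[k]);
                std::sort(f.begin(), f.end());
                fcount[f]++;
            }
        for (int bs : bad) simp[bs].alive = false;
        for (std::map<std::vector<int>, int>::iterator it = fcount.begin();
             it != fcount.end() && !degenerate; ++it) {
            if (it->second != 1) continue;
            Simplex ns;
            ns.v = it->first;            // sorted: GHOST (-1) stays first
            ns.v.push_back(ip);
            std::sort(ns.v.begin(), ns.v.end());
            ns.alive = true;
            if (!ns.ghost() && !setSphere(ns)) { degenerate = true; return; }
            simp.push_back(ns);
        }
    }
};

} // namespace

// [[Rcpp::export(name = ".delaunayEdges")]]
List delaunayEdges(NumericMatrix pts) {
    const int n = pts.nrow(), d = pts.ncol();
    Triangulator T;
    T.n = n; T.d = d; T.degenerate = false;
    T.P.assign(n, std::vector<double>(d));
    // translation + uniform scaling only: circumsphere containment is
    // preserved under similarity transforms, not under per-axis scaling
    {
        std::vector<double> cen(d);
        double h = 0.0;
        for (int j = 0; j < d; ++j) {
            double lo = pts(0, j), hi = pts(0, j);
            for (int i = 1; i < n; ++i) {
                lo = std::min(lo, pts(i, j));
                hi = std::max(hi, pts(i, j));
            }
            cen[j] = 0.5 * (lo + hi);
            h = std::max(h, 0.5 * (hi - lo));
        }
        if (h <= 0) h = 1.0;
        for (int i = 0; i < n; ++i)
            for (int j = 0; j < d; ++j)
                T.P[i][j] = (pts(i, j) - cen[j]) / h;
    }
    // the inside-hull reference point is set after bootstrapping: the
    // barycentre of the initial simplex lies strictly inside it, and
    // stays inside every later (grown) hull

    // bootstrap: greedily pick d+1 affinely independent points
    std::vector<int> base;
    base.push_back(0);
    for (int i = 1; i < n && (int)base.size() <= d; ++i) {
        std::vector<int> cand = base;
        cand.push_back(i);
        // rank check via Gram determinant of difference vectors
        int k = (int)cand.size() - 1;
        std::vector<std::vector<double> > G(k, std::vector<double>(k));
        for (int a = 0; a < k; ++a)
            for (int b = 0; b < k; ++b) {
                double s = 0.0;
                for (int j = 0; j < d; ++j)
                    s += (T.P[cand[a + 1]][j] - T.P[cand[0]][j]) *
                         (T.P[cand[b + 1]][j] - T.P[cand[0]][j]);
                G[a][b] = s;
            }
        double det = 1.0;
        bool ok = true;
        for (int col = 0; col < k && ok; ++col) {
            int piv = col;
            for (int r = col + 1; r < k; ++r)
                if (std::fabs(G[r][col]) > std::fabs(G[piv][col])) piv = r;
            if (std::fabs(G[piv][col]) < 1e-18) { ok = false; break; }
            std::swap(G[piv], G[col]);
            det *= G[col][col];
            for (int r = col + 1; r < k; ++r) {
                double fr = G[r][col] / G[col][col];
                for (int c2 = col; c2 < k; ++c2)
                    G[r][c2] -= fr * G[col][c2];
            }
        }
        if (ok) base = cand;
    }
    bool degenerate = (int)base.size() < d + 1;

    if (!degenerate) {
        Simplex s0;
        s0.v = base;
        std::sort(s0.v.begin(), s0.v.end());
        s0.alive = true;
        if (!T.setSphere(s0)) degenerate = true;
        else {
            T.centroid.assign(d, 0.0);
            for (int k = 0; k <= d; ++k)
                for (int j = 0; j < d; ++j)
                    T.centroid[j] += T.P[s0.v[k]][j] / (d + 1);
            T.simp.push_back(s0);
            for (int skip = 0; skip <= d; ++skip) {  // ghost per facet
                Simplex g;
                g.v.push_back(GHOST);
                for (int k = 0; k <= d; ++k)
                    if (k != skip) g.v.push_back(s0.v[k]);
                g.alive = true;
                T.simp.push_back(g);
            }
            std::vector<bool> used(n, false);
            for (int b : base) used[b] = true;
            for (int i = 0; i < n && !T.degenerate; ++i)
                if (!used[i]) T.insert(i);
            degenerate = T.degenerate;
        }
    }

    std::set<std::pair<int, int> > edges;
    if (!degenerate) {
        std::vector<bool> seen(n, false);
        for (size_t s = 0; s < T.simp.size() && !degenerate; ++s) {
            const Simplex& sx = T.simp[s];
            if (!sx.alive || sx.ghost()) continue;
            // validation: no input point strictly inside the circumsphere
            for (int q = 0; q < n; ++q) {
                bool own = false;
                for (int k = 0; k <= d; ++k)
                    if (sx.v[k] == q) { own = true; break; }
                if (own) continue;
                if (T.dist2(T.P[q], sx.centre) < sx.r2 * (1.0 - 1e-9)) {
                    degenerate = true;
                    break;
                }
            }
            for (int a = 0; a <= d; ++a) {
                seen[sx.v[a]] = true;
                for (int b = a + 1; b <= d; ++b)
                    edges.insert(std::make_pair(std::min(sx.v[a], sx.v[b]),
                                                std::max(sx.v[a], sx.v[b])));
            }
        }
        if (!degenerate)
            for (int i = 0; i < n; ++i)
                if (!seen[i]) degenerate = true;   // lost vertex
    }

    IntegerMatrix em(degenerate ? 0 : (int)edges.size(), 2);
    if (!degenerate) {
        int r = 0;
        for (std::set<std::pair<int, int> >::iterator it = edges.begin();
             it != edges.end(); ++it, ++r) {
            em(r, 0) = it->first + 1;   // 1-based for R
            em(r, 1) = it->second + 1;
        }
    }
    return List::create(_["edges"] = em, _["degenerate"] = degenerate);
}
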