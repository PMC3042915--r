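#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Fast univariate level-set scan used by the gene-filtering step.
// For each gene (row of the input matrix) it fits a Gaussian KDE with the
// normal-reference bandwidth h = shrinkage * s * (4 / (3 n))^(1/5),
// evaluates it at the sample points, and sweeps the cut level c downward
// over the unique fitted density values.  In one dimension the Delaunay
// neighbour graph is the chain over the sort order, so the connected
// components of {x_i : f(x_i) > c} are maximal runs of retained
// consecutive order statistics.  Two extraction rules are supported:
//   rule 0 ("tree-leaves"): the number of clusters is the number of
//     modes that mature, i.e. runs reaching minCoreSize members before
//     merging with another matured run (cluster-tree branches);
//   rule 1 ("max-count"): the maximum, over the sweep (including c = 0),
//     of the number of simultaneous runs with >= minCoreSize members.
// Genes with zero sample variance report one cluster.

namespace {

const double INV_SQRT_2PI = 0.3989422804014327;

// cluster-count scan for one gene; dens in position (sorted-x) order.
// cuts: decreasing cut levels ending at 0; component structure is
// examined only at these checkpoints.
int scanChain(const std::vector<double>& dens, int minCoreSize, int rule,
              const std::vector<double>& cuts) {
    const int n = (int)dens.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return dens[a] > dens[b];
    });

    std::vector<bool> active(n, false);
    // per-run state, stored at both endpoints of the run:
    // size; nLeaf (unfrozen leaves inside: 0/1 after checkpointing);
    // dead (contains frozen leaves)
    std::vector<int> left(n), right(n), size(n, 0), nlf(n, 0);
    std::vector<bool> dead(n, false);
    int best = 0, events = 0;

    size_t t = 0;
    for (double cut : cuts) {
        while (t < (size_t)n && dens[ord[t]] > cut) {
            int i = ord[t];
            active[i] = true;
            int lo = i, hi = i, sz = 1, lf = 0;
            bool dd = false;
            if (i > 0 && active[i - 1]) {
                lo = left[i - 1];
                sz += size[lo]; lf += nlf[lo]; dd = dd || dead[lo];
            }
            if (i + 1 < n && active[i + 1]) {
                hi = right[i + 1];
                sz += size[hi]; lf += nlf[hi]; dd = dd || dead[hi];
            }
            left[i] = lo; left[hi] = lo;
            right[i] = hi; right[lo] = hi;
            size[lo] = sz; size[hi] = sz;
            nlf[lo] = lf; nlf[hi] = lf;
            dead[lo] = dd; dead[hi] = dd;
            ++t;
        }
        // checkpoint: walk the runs
        int nBig = 0;
        for (int i = 0; i < n; ++i) {
            if (!active[i] || (i > 0 && active[i - 1])) continue;
            int lo = i, hi = right[i];
            if (size[lo] >= minCoreSize) ++nBig;
            int lf = nlf[lo];
            bool dd = dead[lo];
            if (lf >= 2 || (lf == 1 && dd)) {        // modes meet: freeze
                lf = 0; dd = true;
            } else if (lf == 0 && !dd && size[lo] >= minCoreSize) {
                ++events;                            // new mode matures
                lf = 1;
            }
            nlf[lo] = lf; nlf[hi] = lf;
            dead[lo] = dd; dead[hi] = dd;
        }
        if (nBig > best) best = nBig;
    }
    int out = (rule == 1) ? best : events;
    return out > 0 ? out : 1;
}

} // namespace

// [[Rcpp::export(name = ".geneClusterCountsCpp")]]
IntegerVector geneClusterCountsCpp(NumericMatrix expr, double shrinkage,
                                   int minCoreSize, int rule, int nGrid) {
    const int p = expr.nrow(), n = expr.ncol();
    IntegerVector out(p);
    if (n < 2) stop("need at least 2 samples");
    const double factor = std::pow(4.0 / (3.0 * n), 0.2);

    std::vector<double> x(n), xs(n), dens(n);
    std::vector<int> ord(n);
    for (int g = 0; g < p; ++g) {
        double m = 0.0;
        for (int i = 0; i < n; ++i) { x[i] = expr(g, i); m += x[i]; }
        m /= n;
        double ss = 0.0;
        for (int i = 0; i < n; ++i) ss += (x[i] - m) * (x[i] - m);
        double s = std::sqrt(ss / (n - 1));
        if (!(s > 0.0)) { out[g] = 1; continue; }  // constant gene
        double h = shrinkage * s * factor;

        for (int i = 0; i < n; ++i) ord[i] = i;
        std::sort(ord.begin(), ord.end(), [&](int a, int b) {
            return x[a] < x[b];
        });
        for (int i = 0; i < n; ++i) xs[i] = x[ord[i]];

        for (int i = 0; i < n; ++i) {
            double acc = 0.0;
            for (int k = 0; k < n; ++k) {
                double u = (xs[i] - xs[k]) / h;
                acc += std::exp(-0.5 * u * u);
            }
            dens[i] = acc * INV_SQRT_2PI / (n * h);
        }
        // checkpoint grid: nGrid equispaced levels over [0, max density],
        // or every unique fitted value when nGrid == 0
        std::vector<double> cuts;
        if (nGrid > 0) {
            double mx = *std::max_element(dens.begin(), dens.end());
            for (int k = nGrid - 1; k >= 1; --k)
                cuts.push_back(mx * k / nGrid);
            cuts.push_back(0.0);
        } else {
            cuts = dens;
            std::sort(cuts.begin(), cuts.end(), std::greater<double>());
            cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
            cuts.push_back(0.0);
        }
        out[g] = scanChain(dens, minCoreSize, rule, cuts);
    }
    return out;
}
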