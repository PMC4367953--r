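#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Minimum-cost perfect assignment on a dense square matrix via shortest
// augmenting paths with dual potentials (Kuhn-Munkres family, O(n^3)).
// Returns, for each column j (1..n), the row assigned to it.
//
// Maximisation is handled by the R wrapper (negate the weights).
// [[Rcpp::export(name = ".lsap_min_cpp")]]
IntegerVector lsap_min_cpp(NumericMatrix cost) {
    const int n = cost.nrow();
    if (cost.ncol() != n) stop("cost matrix must be square");
    const double INF = std::numeric_limits<double>::infinity();

    // 1-indexed with a virtual 0 slot, classical potentials formulation
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
    std::vector<int> p(n + 1, 0), way(n + 1, 0);
    std::vector<bool> used(n + 1);

    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::fill(minv.begin(), minv.end(), INF);
        std::fill(used.begin(), used.end(), false);
        do {
            used[j0] = true;
            int i0 = p[j0], j1 = -1;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            if (j1 < 0) stop("assignment failed (non-finite costs?)");
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else          minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
    }

    IntegerVector row_of_col(n);
    for (int j = 1; j <= n; ++j) row_of_col[j - 1] = p[j];
    return row_of_col;
}
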