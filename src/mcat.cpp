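#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Scan engine for the (matched) Cochran-Armitage trend tests.
//
// method 0: CAT   -- pooled 2x3 trend statistic X_T2 over all unit members
// method 1: MCAT1 -- Y_U = sum over units of the linear statistic X_U
//                    (finite-population corrected, Var(X_U) = 1 per unit)
// method 2: MCAT2 -- |sum over units of sgn(f_ca - f_co) * X_T2|
//
// Within-unit permutation of the case/control labels is performed once per
// cycle and shared across SNPs (required for minP validity). Units rendered
// monomorphic or one-sided at a SNP contribute nothing and do not count
// towards M for that SNP.

struct SnpStat {
    double stat;   // NA_REAL if untestable
    int m;         // usable units
};

static inline void unit_stat(const int* g, const std::vector<int>& members,
                             const std::vector<signed char>& cs,
                             double& xu, double& xt2, int& sgn, bool& usable) {
    int n1[3] = {0, 0, 0}, n2[3] = {0, 0, 0}; // controls, cases by genotype
    for (size_t k = 0; k < members.size(); ++k) {
        int idx = members[k];
        int gk = g[idx];
        if (gk < 0) continue;
        if (cs[idx]) ++n2[gk]; else ++n1[gk];
    }
    int nco = n1[0] + n1[1] + n1[2];
    int nca = n2[0] + n2[1] + n2[2];
    int N = nco + nca;
    int c2 = n1[1] + n2[1], c3 = n1[2] + n2[2];
    double D = (double)N * (c2 + 4.0 * c3) - std::pow(c2 + 2.0 * c3, 2.0);
    if (nco == 0 || nca == 0 || D <= 0.0) { usable = false; return; }
    usable = true;
    double U = (double)nco * (n2[1] + 2.0 * n2[2]) - (double)nca * (n1[1] + 2.0 * n1[2]);
    xt2 = ((double)N / ((double)nco * nca)) * U * U / D;
    xu  = std::sqrt((N - 1.0) / ((double)nco * nca)) * U / std::sqrt(D);
    // reference-allele (first column) frequency difference, exact in integers
    long long lhs = (long long)(2 * n2[0] + n2[1]) * nco;
    long long rhs = (long long)(2 * n1[0] + n1[1]) * nca;
    sgn = (lhs > rhs) - (lhs < rhs);
}

static SnpStat snp_stat(const int* g, int method,
                        const std::vector<std::vector<int> >& members,
                        const std::vector<signed char>& cs) {
    SnpStat out; out.stat = NA_REAL; out.m = 0;
    if (method == 0) {
        int n1[3] = {0, 0, 0}, n2[3] = {0, 0, 0};
        for (size_t u = 0; u < members.size(); ++u)
            for (size_t k = 0; k < members[u].size(); ++k) {
                int idx = members[u][k];
                int gk = g[idx];
                if (gk < 0) continue;
                if (cs[idx]) ++n2[gk]; else ++n1[gk];
            }
        int nco = n1[0] + n1[1] + n1[2], nca = n2[0] + n2[1] + n2[2];
        int N = nco + nca;
        int c2 = n1[1] + n2[1], c3 = n1[2] + n2[2];
        double D = (double)N * (c2 + 4.0 * c3) - std::pow(c2 + 2.0 * c3, 2.0);
        if (nco == 0 || nca == 0 || D <= 0.0) return out;
        double U = (double)nco * (n2[1] + 2.0 * n2[2]) - (double)nca * (n1[1] + 2.0 * n1[2]);
        out.stat = ((double)N / ((double)nco * nca)) * U * U / D;
        out.m = 1;
        return out;
    }
    double acc = 0.0;
    int m = 0;
    for (size_t u = 0; u < members.size(); ++u) {
        const std::vector<int>& mb = members[u];
        double xu = 0.0, xt2 = 0.0;
        int sg = 0;
        bool ok = false;
        if (mb.size() == 2) {            // pair fast path
            int ga = g[mb[0]], gb = g[mb[1]];
            if (ga >= 0 && gb >= 0 && ga != gb && cs[mb[0]] != cs[mb[1]]) {
                int gc = cs[mb[0]] ? ga : gb;   // case genotype
                int go = cs[mb[0]] ? gb : ga;   // control genotype
                ok = true;
                xu = (gc > go) ? 1.0 : -1.0;
                xt2 = 2.0;
                sg = (gc > go) ? -1 : 1;        // reference-allele direction
            }
        } else {
            unit_stat(g, mb, cs, xu, xt2, sg, ok);
        }
        if (!ok) continue;
        ++m;
        if (method == 1) acc += xu;
        else             acc += sg * xt2;
    }
    if (m == 0) return out;
    out.m = m;
    out.stat = (method == 2) ? std::fabs(acc) : acc;
    return out;
}

// [[Rcpp::export(name = ".mcat_scan_cpp")]]
List mcat_scan_cpp(IntegerMatrix geno, IntegerVector unit, IntegerVector is_case,
                   int n_units, int method, int B, bool return_null) {
    const int n = geno.nrow(), S = geno.ncol();
    if (unit.size() != n || is_case.size() != n) stop("length mismatch");

    std::vector<std::vector<int> > members(n_units);
    for (int i = 0; i < n; ++i) {
        int u = unit[i];
        if (u == NA_INTEGER || u < 0) continue;
        if (u >= n_units) stop("unit index out of range");
        members[u].push_back(i);
    }

    std::vector<signed char> cs(n, 0);
    for (int i = 0; i < n; ++i) cs[i] = (is_case[i] == 1) ? 1 : 0;

    // copy genotype columns once, recoding NA to -1
    std::vector<int> G((size_t)n * S);
    for (int s = 0; s < S; ++s)
        for (int i = 0; i < n; ++i) {
            int v = geno(i, s);
            G[(size_t)s * n + i] = (v == NA_INTEGER) ? -1 : v;
        }

    NumericVector obs(S), mag(S);
    IntegerVector M(S), exceed(S);
    for (int s = 0; s < S; ++s) {
        SnpStat st = snp_stat(&G[(size_t)s * n], method, members, cs);
        obs[s] = st.stat;
        M[s] = st.m;
        mag[s] = ISNA(st.stat) ? NA_REAL : std::fabs(st.stat);
    }

    NumericMatrix nullmat;
    if (return_null && B > 0) nullmat = NumericMatrix(B, S);

    if (B > 0) {
        std::vector<signed char> pcs(cs);
        std::vector<signed char> tmp;
        for (int b = 0; b < B; ++b) {
            // within-unit Fisher-Yates shuffle of the labels
            for (size_t u = 0; u < members.size(); ++u) {
                const std::vector<int>& mb = members[u];
                size_t k = mb.size();
                if (k < 2) continue;
                tmp.resize(k);
                for (size_t t = 0; t < k; ++t) tmp[t] = pcs[mb[t]];
                for (size_t t = k - 1; t > 0; --t) {
                    size_t r = (size_t)(unif_rand() * (t + 1));
                    if (r > t) r = t;
                    std::swap(tmp[t], tmp[r]);
                }
                for (size_t t = 0; t < k; ++t) pcs[mb[t]] = tmp[t];
            }
            for (int s = 0; s < S; ++s) {
                SnpStat st = snp_stat(&G[(size_t)s * n], method, members, pcs);
                double v = ISNA(st.stat) ? NA_REAL : std::fabs(st.stat);
                if (return_null) nullmat(b, s) = v;
                if (!ISNA(v) && !ISNA(mag[s]) && v >= mag[s]) ++exceed[s];
            }
        }
    }

    List out = List::create(_["stat"] = obs, _["M"] = M,
                            _["exceed"] = exceed, _["B"] = B);
    if (return_null && B > 0) out["null"] = nullmat;
    return out;
}
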